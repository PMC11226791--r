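test_that("f4 matches hand-computed values", {
  expect_equal(f4_statistic(c(0.2, 0.8), c(0.2, 0.8), runif(2), runif(2)), 0)
  expect_equal(f4_statistic(1, 0, 1, 0), 1)
  expect_equal(f4_statistic(c(1, 0), c(0, 0), c(1, 0), c(0, 0)), 0.5)
})

test_that("f4 is antisymmetric in each pair, exactly", {
  set.seed(3)
  for (i in 1:10) {
    a <- runif(20); b <- runif(20); c <- runif(20); d <- runif(20)
    expect_identical(f4_statistic(a, b, c, d), -f4_statistic(b, a, c, d))
    expect_identical(f4_statistic(a, b, c, d), -f4_statistic(a, b, d, c))
    expect_identical(f4_statistic(a, b, c, d), f4_statistic(b, a, d, c))
  }
})

test_that("missing sites are excluded; all-missing input errors", {
  expect_equal(f4_statistic(c(1, NA), c(0, 0), c(1, 1), c(0, 0)), 1)
  expect_error(f4_statistic(NA_real_, 0, 1, 0), "usable")
  expect_error(f4_statistic(c(1, 0), c(0, 0), c(1, 0), 0), "equal length")
})

test_that("a caterpillar 4-taxon tree forces the single quadruplet arrangement", {
  tr <- ape::read.tree(text = "(((p1:1,p2:1):1,p3:2):1,p4:3);")
  set.seed(1)
  m <- matrix(runif(4 * 30), 4, dimnames = list(paste0("p", 1:4), NULL))
  sc <- f4_scan(m, tr)
  tab <- tidy(sc)
  expect_identical(nrow(tab), 1L)
  # cherry (p1, p2) against (p3, p4)
  expect_identical(unlist(tab[1, c("A", "B", "C", "D")], use.names = FALSE),
                   c("p1", "p2", "p3", "p4"))
  expect_equal(sc$max_abs_f4,
               abs(f4_statistic(m["p1", ], m["p2", ], m["p3", ], m["p4", ])))
})

test_that("identical populations give a zero introgression indicator", {
  tr <- default_species_tree()
  m <- matrix(0.4, 7, 25, dimnames = list(tr$tip.label, NULL))
  expect_equal(f4_scan(m, tr)$max_abs_f4, 0)
})

test_that("an unresolved 4-leaf restriction is skipped with a warning", {
  tr <- ape::read.tree(text = "(p1:1,p2:1,p3:1,p4:1);")  # star
  m <- matrix(runif(4 * 10), 4, dimnames = list(paste0("p", 1:4), NULL))
  expect_warning(expect_error(f4_scan(m, tr), "no resolved"), "unresolved")
})

test_that("percentile p-values follow the add-one empirical rule", {
  expect_equal(percentile_p(100, 1:99), 0.01)
  null <- 1:99
  expect_equal(percentile_p(min(null), null), 1)
  null999 <- seq_len(999)
  expect_equal(percentile_p(500, null999), (1 + 500) / 1000)
  # monotone non-increasing in the observed value
  obs <- seq(-2, 2, length.out = 21)
  ps <- vapply(obs, percentile_p, numeric(1), null_values = rnorm(200))
  expect_true(all(diff(ps) <= 0))
})

test_that("Fisher's combined test matches the closed-form survival function", {
  # for m = 2 the chi-square(4) upper tail is exp(-x/2) * (1 + x/2)
  ft <- fisher_combined(c(0.5, 0.5))
  expect_equal(ft$statistic, -2 * (log(0.5) + log(0.5)))
  expect_equal(ft$statistic, 2.7726, tolerance = 1e-4)
  oracle <- exp(-ft$statistic / 2) * (1 + ft$statistic / 2)
  expect_equal(ft$p_value, oracle, tolerance = 1e-12)
  expect_equal(ft$p_value, 0.5966, tolerance = 1e-4)
  expect_identical(ft$df, 4L)

  ft1 <- fisher_combined(1)
  expect_equal(ft1$statistic, 0)
  expect_equal(ft1$p_value, 1)
  expect_error(fisher_combined(c(0.5, 0)), "\\(0, 1]")
  expect_error(fisher_combined(numeric(0)), "at least one")
})

test_that("combining uniform p-values keeps the type-I error calibrated", {
  set.seed(71)
  reps <- 2000
  comb <- vapply(seq_len(reps), function(i)
    fisher_combined(runif(4))$p_value, numeric(1))
  hits <- sum(comb < 0.05)
  ci <- qbinom(c(0.0005, 0.9995), reps, 0.05)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("frequency tables and FASTA alignments load consistently", {
  freqs <- read_allele_freqs(fixture_path("synthetic_freqs.tsv"))
  tr <- ape::read.tree(fixture_path("synthetic_species_tree.nwk"))
  expect_setequal(rownames(freqs), tr$tip.label)

  fa <- alleles_from_fasta(
    stats::setNames(vapply(tr$tip.label, function(p)
      fixture_path(paste0("synthetic_", p, ".fasta")), character(1)),
      tr$tip.label),
    fixture_path("synthetic_reference.fasta"))
  expect_equal(fa[rownames(freqs), ], freqs, ignore_attr = TRUE)

  nulls <- as.numeric(readLines(fixture_path("synthetic_null_values.txt")))
  sc <- f4_scan(freqs, tr, null_values = nulls)
  expect_true(sc$percentile_p > 0 && sc$percentile_p <= 1)
  expect_identical(nrow(tidy(sc)), 35L)  # choose(7, 4)
})

test_that("gap and ambiguity columns are excluded from FASTA-derived frequencies", {
  dir <- withr::local_tempdir()
  writeLines(c(">ref", "ACGT"), file.path(dir, "ref.fa"))
  writeLines(c(">h1", "ACGT", ">h2", "AC-T"), file.path(dir, "pop1.fa"))
  writeLines(c(">h1", "TCGT", ">h2", "TCTN"), file.path(dir, "pop2.fa"))
  m <- alleles_from_fasta(c(pop1 = file.path(dir, "pop1.fa"),
                            pop2 = file.path(dir, "pop2.fa")),
                          file.path(dir, "ref.fa"))
  # site 3 has a gap in pop1, site 4 has an N in pop2: both dropped
  expect_identical(attr(m, "site_index"), c(1L, 2L))
  expect_equal(m["pop1", ], c(0, 0), ignore_attr = TRUE)
  expect_equal(m["pop2", ], c(1, 0), ignore_attr = TRUE)
})
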