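test_that("the Wright-Fisher simulator is reproducible from its seed", {
  p <- sd_params(r = 0.1, s = 0.5, k = 1, R = 10)
  a <- simulate_wright_fisher(inv_theta0(0.2), p, N = 200, generations = 10,
                              replicates = 3, seed = 123)
  b <- simulate_wright_fisher(inv_theta0(0.2), p, N = 200, generations = 10,
                              replicates = 3, seed = 123)
  d <- simulate_wright_fisher(inv_theta0(0.2), p, N = 200, generations = 10,
                              replicates = 3, seed = 124)
  expect_identical(a, b)
  expect_false(identical(a, d))
  # counts sum to N every generation
  counts <- as.matrix(a[, genotype_labels()])
  expect_true(all(rowSums(counts) == 200))
})

test_that("neutral finite populations drift around a constant mean", {
  p <- sd_params(r = 0, s = 0.5, k = 0, R = 10)
  sim <- simulate_wright_fisher(inv_theta0(0.3), p, N = 1000, generations = 50,
                                replicates = 200, seed = 31)
  g50 <- sim[sim$generation == 50, ]
  m <- mean(g50$Ab)
  se <- sd(g50$Ab) / sqrt(nrow(g50))
  expect_lt(abs(m - 0.3), 3 * se)
})

test_that("an all-sterile population is recorded as extinct and truncated", {
  p <- sd_params(r = 0, s = 1, k = 1, R = 10)
  sim <- simulate_wright_fisher(genotype_frequencies(c(`ab|ab` = 1)), p,
                                N = 50, generations = 5, replicates = 2,
                                seed = 2)
  expect_true(all(attr(sim, "extinct")))
  expect_true(all(sim$generation == 0))
})

test_that("zero drift intensity leaves all populations identical with f4 = 0", {
  tr <- default_species_tree()
  m <- simulate_species_alleles(tr, n_sites = 50, intensity = 0, seed = 4)
  expect_equal(max(m) - min(m), 0)
  expect_equal(f4_scan(m + 0 * m, tr)$max_abs_f4, 0)
})

test_that("species-allele simulation is seeded and bounded", {
  tr <- default_species_tree()
  a <- simulate_species_alleles(tr, n_sites = 100, seed = 8)
  b <- simulate_species_alleles(tr, n_sites = 100, seed = 8)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(rownames(a), tr$tip.label)
})

test_that("introgression copies donor frequencies into the recipient", {
  tr <- default_species_tree()
  spec <- introgression_spec("sp1", "sp5", 1)  # all sites
  m <- simulate_species_alleles(tr, n_sites = 60, introgression = spec, seed = 5)
  expect_equal(m["sp5", ], m["sp1", ])
  expect_error(simulate_species_alleles(tr, n_sites = 10,
               introgression = introgression_spec("sp1", "nope", 0.5), seed = 1),
               "unknown donor/recipient")
  expect_error(introgression_spec("x", "x", 0.5), "differ")
})

test_that("fixture sets are a pure function of the seed and round-trip", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixtures(d1, seed = 99, n_sites = 40, n_hap = 8, n_null = 10)
  p2 <- write_fixtures(d2, seed = 99, n_sites = 40, n_hap = 8, n_null = 10)
  md5 <- function(ps) unname(tools::md5sum(unname(ps[names(ps) != "manifest"])))
  expect_identical(md5(p1), md5(p2))

  tr <- ape::read.tree(file.path(d1, "synthetic_species_tree.nwk"))
  freqs <- read_allele_freqs(file.path(d1, "synthetic_freqs.tsv"))
  expect_setequal(tr$tip.label, rownames(freqs))
  fa <- alleles_from_fasta(
    stats::setNames(file.path(d1, paste0("synthetic_", rownames(freqs), ".fasta")),
                    rownames(freqs)),
    file.path(d1, "synthetic_reference.fasta"))
  expect_equal(fa[rownames(freqs), ], freqs, ignore_attr = TRUE)
})

test_that("run configurations round-trip through YAML", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "r: 0.1", "s: 0.9", "k: 1", "R: 10",
    "init_freqs:", "  Ab: 0.1", "  aB: 0.9",
    "stop:", "  mode: absolute", "  threshold: 0.001",
    "max_generations: 500"
  ), cfg)
  run <- read_sd_config(cfg)
  expect_equal(run$params$r, 0.1)
  expect_equal(unname(run$theta0[c("Ab|Ab", "aB|aB")]), c(0.1, 0.9))
  expect_identical(run$stop$mode, "absolute")
  fit <- run_sd_config(cfg)
  expect_identical(fit$state, "neutral_killer_coexist")
})
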