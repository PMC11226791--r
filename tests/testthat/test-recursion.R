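test_that("offspring distribution of a selfing double heterozygote", {
  # all surviving self pollen is Ab; female gametes split 0.5/0.5
  p <- sd_params(r = 0, s = 1, k = 1, R = 10)
  g <- build_gamete_matrices(p)
  off <- offspring_distribution("Ab|aB", g, params = p)
  expect_equal(unname(off[c("Ab|Ab", "Ab|aB")]), c(0.5, 0.5))
  expect_equal(sum(off), 1)
})

test_that("pure outcrossing neutral flower breeds true in a monomorphic pool", {
  p <- sd_params(r = 0, s = 0, k = 0, R = 10)
  g <- build_gamete_matrices(p)
  off <- offspring_distribution("AB|AB", g, f = c(1, 0, 0, 0), params = p)
  expect_equal(unname(off["AB|AB"]), 1)
})

test_that("offspring haplotype marginal is the half-female half-pollen mixture", {
  p <- sd_params(r = 0, s = 0.4, k = 0, R = 10)
  g <- build_gamete_matrices(p)
  f <- c(0.4, 0.3, 0.2, 0.1)
  N <- pollen_availability(g, p)
  dose <- t(vapply(seq_len(10), function(j) {
    v <- numeric(4)
    gl <- genotype_labels()[j]
    haps <- strsplit(gl, "|", fixed = TRUE)[[1]]
    for (h in haps) v[match(h, hap_labels())] <- v[match(h, hap_labels())] + 0.5
    v
  }, numeric(4)))
  for (i in c(1, 4, 6, 9)) {
    off <- offspring_distribution(i, g, f = f, params = p)
    marg <- drop(crossprod(dose, off))
    mix <- 0.5 * g$Gf[i, ] + 0.5 * (p$M_self * g$Gm[i, ] + p$M_pool * f) / N[i]
    expect_equal(unname(marg), unname(mix))
  }
})

test_that("offspring probabilities sum to 1 for fertile flowers and 0 otherwise", {
  p <- sd_params(r = 0.2, s = 1, k = 1, R = 10)
  g <- build_gamete_matrices(p)
  N <- pollen_availability(g, p)
  for (i in 1:10) {
    off <- offspring_distribution(i, g, f = rep(0.25, 4), params = p)
    expect_equal(sum(off), if (N[i] > 0) 1 else 0, tolerance = 1e-9)
  }
})

test_that("one step of the recursion matches the hand-enumerated selfing case", {
  p <- sd_params(r = 0, s = 1, k = 1, R = 10)
  th <- genotype_frequencies(c(`Ab|aB` = 1))
  th1 <- sd_step(th, p)
  expect_equal(unname(th1[c("Ab|Ab", "Ab|aB")]), c(0.5, 0.5))
  expect_equal(unname(haplotype_frequencies(th1)), c(0, 0.75, 0.25, 0))
})

test_that("single-homozygote populations are fixed points of the step", {
  p <- sd_params(r = 0.3, s = 0.5, k = 1, R = 10)
  for (gt in c("AB|AB", "Ab|Ab", "aB|aB")) {
    th <- genotype_frequencies(stats::setNames(1, gt))
    expect_equal(sd_step(th, p), th)
  }
})

test_that("without killing, the step is neutral at the allele level", {
  # recombination relaxes haplotypes toward linkage equilibrium, so the
  # exact neutral invariants are the two allele frequencies (any r) and
  # the haplotype frequencies under full linkage (r = 0)
  allele_freqs <- function(theta) {
    h <- haplotype_frequencies(theta)
    c(A = h[["AB"]] + h[["Ab"]], B = h[["AB"]] + h[["aB"]])
  }
  set.seed(9)
  for (i in 1:10) {
    p <- sd_params(r = runif(1, 0, 0.5), s = runif(1), k = 0,
                   R = runif(1, 1, 20))
    th <- genotype_frequencies(as.numeric(rmultinom(1, 100, rep(1, 10))) / 100)
    expect_equal(allele_freqs(sd_step(th, p)), allele_freqs(th),
                 tolerance = 1e-12)
    p0 <- sd_params(r = 0, s = p$s, k = 0, R = p$R)
    expect_equal(haplotype_frequencies(sd_step(th, p0)),
                 haplotype_frequencies(th), tolerance = 1e-12)
  }
})

test_that("a fully sterile population raises an extinction error", {
  # suicide homozygotes under complete selfing: every pollen grain self-killed
  p <- sd_params(r = 0, s = 1, k = 1, R = 10)
  th <- genotype_frequencies(c(`ab|ab` = 1))
  expect_error(sd_step(th, p), "extinct")
})

test_that("haplotype frequencies weigh each genotype by half per copy", {
  expect_equal(unname(haplotype_frequencies(
    genotype_frequencies(c(`Ab|Ab` = 0.1, `aB|aB` = 0.9)))), c(0, 0.1, 0.9, 0))
  expect_equal(unname(haplotype_frequencies(
    genotype_frequencies(c(`Ab|aB` = 1)))), c(0, 0.5, 0.5, 0))
  expect_equal(unname(haplotype_frequencies(
    genotype_frequencies(c(`AB|ab` = 0.5, `Ab|aB` = 0.5)))),
    c(0.25, 0.25, 0.25, 0.25))
})
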