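# shared helpers for the suite

# invasion initial condition: killer homozygotes at f0, sensitive at 1 - f0
inv_theta0 <- function(f0) {
  genotype_frequencies(c(`Ab|Ab` = f0, `aB|aB` = 1 - f0))
}

# the four single-panel trajectory parameter sets (R = 10, k = 1)
panel_params <- list(
  a = sd_params(r = 0,   s = 1e-5, k = 1, R = 10),
  b = sd_params(r = 0,   s = 0.9,  k = 1, R = 10),
  c = sd_params(r = 0.1, s = 1e-5, k = 1, R = 10),
  d = sd_params(r = 0.1, s = 0.9,  k = 1, R = 10)
)

fixture_path <- function(...) {
  system.file("extdata", ..., package = "pollendrive", mustWork = TRUE)
}
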