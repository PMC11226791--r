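#' Read a model run configuration
#'
#' YAML key-value file describing a recursion run: scalar parameters `r`,
#' `s`, `k`, `R` (and optionally `M_total`), initial frequencies
#' `init_freqs` (named by genotype, e.g. `"Ab|Ab": 0.1`, or by haplotype --
#' a bare haplotype name means its homozygote), a `stop` block with `mode`
#' and `threshold` (see [stop_rule()]), and `max_generations`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `params` ([sd_params()]), `theta0`,
#'   `stop` ([stop_rule()]) and `max_generations`, ready to splice into
#'   [sd_iterate()].
#' @export
read_sd_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- sd_params(
    r = cfg$r %||% 0, s = cfg$s %||% 0, k = cfg$k %||% 1,
    R = cfg$R %||% 10, M_total = cfg$M_total %||% 1
  )
  init <- cfg$init_freqs
  if (is.null(init)) stop("config must provide `init_freqs`", call. = FALSE)
  init <- unlist(init)
  # bare haplotype names denote their homozygotes
  hapnames <- names(init) %in% .HAP_NAMES
  names(init)[hapnames] <- paste(names(init)[hapnames], names(init)[hapnames],
                                 sep = "|")
  theta0 <- genotype_frequencies(init, normalize = isTRUE(cfg$normalize))
  stop_cfg <- cfg$stop %||% list()
  stop <- stop_rule(stop_cfg$mode %||% "absolute",
                    threshold = stop_cfg$threshold %||%
                      switch(stop_cfg$mode %||% "absolute",
                             absolute = 0.001, relative = 0.01, none = 0))
  list(params = params, theta0 = theta0, stop = stop,
       max_generations = cfg$max_generations %||% 10000)
}

#' Run a recursion described by a configuration file
#'
#' Convenience wrapper: [read_sd_config()] then [sd_iterate()] with the
#' trajectory recorded.
#'
#' @inheritParams read_sd_config
#' @return An `sd_equilibrium`.
#' @export
run_sd_config <- function(path) {
  cfg <- read_sd_config(path)
  sd_iterate(cfg$theta0, cfg$params, max_generations = cfg$max_generations,
             stop = cfg$stop, record_trajectory = TRUE)
}
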