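#' Stopping rule for long-run iteration
#'
#' Iteration of the recursion is terminated when the killer (`Ab`) or
#' sensitive (`aB`) haplotype frequency falls below a threshold,
#' approximating loss of one of them, or when `max_generations` elapse.
#' Two threshold conventions are supported:
#'
#' * `"absolute"` (default): stop when either frequency drops below a fixed
#'   value, 0.001 by default;
#' * `"relative"`: stop when either frequency drops below `threshold` times
#'   its own initial value (default 0.01, i.e. 1% of the starting
#'   frequency); a haplotype absent initially never triggers the rule;
#' * `"none"`: run for exactly `max_generations` generations (used for
#'   fixed-horizon criteria).
#'
#' @param mode One of `"absolute"`, `"relative"`, `"none"`.
#' @param threshold Absolute frequency (mode `"absolute"`) or fraction of
#'   the initial frequency (mode `"relative"`).
#' @return A list of class `sd_stop_rule`.
#' @export
stop_rule <- function(mode = c("absolute", "relative", "none"),
                      threshold = switch(match.arg(mode), absolute = 0.001,
                                         relative = 0.01, none = 0)) {
  mode <- match.arg(mode)
  if (mode != "none" && (!is.numeric(threshold) || threshold <= 0)) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  structure(list(mode = mode, threshold = threshold), class = "sd_stop_rule")
}

# resolve a stop rule into per-haplotype absolute thresholds (<=0 disables)
resolve_stop <- function(stop, theta0) {
  if (!inherits(stop, "sd_stop_rule")) stop("`stop` must be a stop_rule()", call. = FALSE)
  if (stop$mode == "none") return(c(killer = 0, sensitive = 0))
  if (stop$mode == "absolute") {
    return(c(killer = stop$threshold, sensitive = stop$threshold))
  }
  h0 <- haplotype_frequencies(theta0)
  c(killer = stop$threshold * h0[["Ab"]],
    sensitive = stop$threshold * h0[["aB"]])
}

#' One generation of the deterministic recursion
#'
#' Applies a single generation of the pollen-killer model: gamete
#' production with recombination and killing, pollen-pool formation,
#' fertility weighting, and fertilization by self plus pool pollen. The
#' next-generation genotype frequencies are the fertility-weighted
#' offspring masses renormalized to sum to 1.
#'
#' @inheritParams haplotype_frequencies
#' @param params An [sd_params()] object.
#' @return A genotype-frequency vector of length 10.
#' @examples
#' th <- genotype_frequencies(c(`Ab|aB` = 1))
#' sd_step(th, sd_params(r = 0, s = 1, k = 1, R = 10))
#' @export
sd_step <- function(theta, params) {
  params <- as_sd_params(params)
  theta <- check_theta(theta)
  g <- build_gamete_matrices(params)
  res <- sd_iterate_cpp(theta, g$Gf, g$Gm, .GENO_H1 - 1L, .GENO_H2 - 1L,
                        .HAP_DOSE, params$M_self, params$M_pool, params$R,
                        0, 0, 1L, FALSE)
  if (res$extinct) stop("total reproductive output is zero; population extinct", call. = FALSE)
  if (res$degenerate) stop("population produces no surviving pollen", call. = FALSE)
  stats::setNames(res$theta, .GENO_NAMES)
}

#' Iterate the recursion to (pseudo-)equilibrium
#'
#' Iterates [sd_step()] until the stopping rule fires or `max_generations`
#' elapse, and classifies the terminal population into one of the model's
#' five equilibrium states (or `"unresolved"`).
#'
#' @inheritParams sd_step
#' @param theta0 Initial genotype-frequency vector (length 10, or a named
#'   partial vector accepted by [genotype_frequencies()]).
#' @param max_generations Upper bound on the number of generations.
#' @param stop A [stop_rule()].
#' @param record_trajectory Keep the full per-generation genotype
#'   frequencies (as a tibble accessible via [tidy()]).
#' @param presence_threshold Haplotype frequency above which a haplotype
#'   counts as present when classifying the terminal state.
#' @return An object of class `sd_equilibrium` with elements
#'   `terminal_theta`, `haplotype_freqs`, `generations_run`, `stop_reason`
#'   (`"threshold"` or `"max_generations"`), `state`, `params`, and
#'   optionally `trajectory`. Use [tidy()] for the trajectory and
#'   [glance()] for a one-row summary.
#' @examples
#' fit <- sd_iterate(c(`Ab|Ab` = 0.1, `aB|aB` = 0.9),
#'                   sd_params(r = 0, s = 1e-5, k = 1, R = 10))
#' glance(fit)
#' @export
sd_iterate <- function(theta0, params, max_generations = 10000,
                       stop = stop_rule("absolute"),
                       record_trajectory = FALSE,
                       presence_threshold = 1e-3) {
  params <- as_sd_params(params)
  theta0 <- genotype_frequencies(theta0)
  if (max_generations < 0) stop("`max_generations` must be >= 0", call. = FALSE)
  thr <- resolve_stop(stop, theta0)
  g <- build_gamete_matrices(params)
  res <- sd_iterate_cpp(theta0, g$Gf, g$Gm, .GENO_H1 - 1L, .GENO_H2 - 1L,
                        .HAP_DOSE, params$M_self, params$M_pool, params$R,
                        thr[["killer"]], thr[["sensitive"]],
                        as.integer(max_generations), record_trajectory)
  if (res$extinct) stop("total reproductive output is zero; population extinct", call. = FALSE)
  if (res$degenerate) stop("population produces no surviving pollen", call. = FALSE)
  terminal <- stats::setNames(res$theta, .GENO_NAMES)
  out <- structure(
    list(
      terminal_theta = terminal,
      haplotype_freqs = haplotype_frequencies(terminal),
      generations_run = res$generations,
      stop_reason = res$stop_reason,
      state = classify_equilibrium(terminal, presence_threshold),
      params = params
    ),
    class = "sd_equilibrium"
  )
  if (record_trajectory) {
    traj <- res$trajectory
    colnames(traj) <- .GENO_NAMES
    hap <- traj %*% .HAP_DOSE
    out$trajectory <- dplyr::bind_cols(
      tibble::tibble(generation = 0:res$generations),
      tibble::as_tibble(hap),
      tibble::as_tibble(traj)
    )
  }
  out
}

#' Classify a population into the model's equilibrium states
#'
#' A haplotype is "present" when its frequency exceeds
#' `presence_threshold`. The set of present haplotypes maps onto the five
#' possible equilibrium states of the model -- fixation of the killer,
#' sensitive or neutral haplotype, or coexistence of the neutral haplotype
#' with either the sensitive or the killer -- and any other set (e.g. the
#' suicide haplotype still present, or killer and sensitive both present
#' before convergence) is `"unresolved"`. Killer-sensitive coexistence is
#' not an equilibrium of the model, so it is never reported as one.
#'
#' @inheritParams sd_step
#' @inheritParams sd_iterate
#' @return A single string.
#' @export
classify_equilibrium <- function(theta, presence_threshold = 1e-3) {
  hap <- haplotype_frequencies(check_theta(theta))
  # .HAP_NAMES order is fixed (AB, Ab, aB, ab), so the key is unambiguous
  present <- .HAP_NAMES[hap > presence_threshold]
  key <- paste(present, collapse = "+")
  switch(key,
    "Ab" = "killer_fixed",
    "aB" = "sensitive_fixed",
    "AB" = "neutral_fixed",
    "AB+aB" = "neutral_sensitive_coexist",
    "AB+Ab" = "neutral_killer_coexist",
    "unresolved"
  )
}

#' @export
print.sd_equilibrium <- function(x, ...) {
  cat("<sd_equilibrium>\n")
  cat(sprintf("  generations: %d (stopped: %s)\n", x$generations_run, x$stop_reason))
  cat(sprintf("  state: %s\n", x$state))
  h <- x$haplotype_freqs
  cat(sprintf("  haplotypes: AB=%.4g Ab=%.4g aB=%.4g ab=%.4g\n",
              h[["AB"]], h[["Ab"]], h[["aB"]], h[["ab"]]))
  if (!is.null(x$trajectory)) cat(sprintf("  trajectory: %d generations recorded\n",
                                          nrow(x$trajectory) - 1L))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.sd_equilibrium <- function(x, ...) {
  if (is.null(x$trajectory)) {
    stop("no trajectory recorded; rerun sd_iterate() with record_trajectory = TRUE",
         call. = FALSE)
  }
  x$trajectory
}

#' @importFrom generics glance
#' @export
glance.sd_equilibrium <- function(x, ...) {
  h <- x$haplotype_freqs
  tibble::tibble(
    generations_run = x$generations_run,
    stop_reason = x$stop_reason,
    state = x$state,
    neutral = h[["AB"]], killer = h[["Ab"]],
    sensitive = h[["aB"]], suicide = h[["ab"]]
  )
}

#' Write a recorded trajectory as tab-separated text
#'
#' Emits one row per generation with the four haplotype frequencies and
#' the ten genotype frequencies, full double precision.
#'
#' @param x An `sd_equilibrium` with a recorded trajectory.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
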