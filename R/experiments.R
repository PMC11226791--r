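#' Fate of a killer haplotype invading a sensitive population
#'
#' Starts a population of killer homozygotes (`Ab|Ab`) at frequency
#' `init_killer_freq` and sensitive homozygotes (`aB|aB`) at the
#' complement, iterates to (pseudo-)equilibrium, and classifies the fate of
#' the killer haplotype: `"eliminated"` if its final frequency is below
#' `presence_threshold`, otherwise `"increased"` or `"decreased"` by
#' comparing the final with the initial frequency (ties count as
#' decreased).
#'
#' @inheritParams sd_iterate
#' @param init_killer_freq Initial killer haplotype frequency, in (0, 1).
#' @return A one-row tibble with columns `r`, `s`, `k`, `R`, `f0`,
#'   `killer_final`, `fate`, `state`, `generations`, `stop_reason`.
#' @examples
#' invasion_fate(sd_params(r = 0.1, s = 0.9, R = 10), 0.1)
#' @export
invasion_fate <- function(params, init_killer_freq,
                          stop = stop_rule("absolute"),
                          max_generations = 10000,
                          presence_threshold = 1e-3) {
  params <- as_sd_params(params)
  f0 <- init_killer_freq
  if (!is.numeric(f0) || f0 <= 0 || f0 >= 1) {
    stop("`init_killer_freq` must be in (0, 1)", call. = FALSE)
  }
  fit <- sd_iterate(invasion_theta0(f0), params,
                    max_generations = max_generations, stop = stop,
                    presence_threshold = presence_threshold)
  h <- fit$haplotype_freqs
  killer <- h[["Ab"]]
  fate <- if (killer < presence_threshold) "eliminated"
          else if (killer > f0) "increased" else "decreased"
  tibble::tibble(
    r = params$r, s = params$s, k = params$k, R = params$R, f0 = f0,
    killer_final = killer, sensitive_final = h[["aB"]],
    neutral_final = h[["AB"]], suicide_final = h[["ab"]],
    fate = fate, state = fit$state,
    generations = fit$generations_run, stop_reason = fit$stop_reason
  )
}

invasion_theta0 <- function(f0) {
  genotype_frequencies(c(`Ab|Ab` = f0, `aB|aB` = 1 - f0))
}

#' Invasion-fate sweep over recombination and selfing rates
#'
#' Runs [invasion_fate()] on every cell of an `r` x `s` grid at fixed
#' pollen redundancy and initial killer frequency. Deterministic:
#' repeated sweeps are identical.
#'
#' @param r_grid,s_grid Numeric vectors of recombination and selfing rates.
#' @param R Pollen redundancy level.
#' @param init_killer_freq Initial killer haplotype frequency.
#' @param k Killing efficiency.
#' @inheritParams invasion_fate
#' @return A tibble of class `sd_sweep`, one row per (r, s) cell, with the
#'   columns of [invasion_fate()].
#' @examples
#' sw <- sd_sweep(c(0, 0.1), c(1e-5, 0.9), R = 10, init_killer_freq = 0.1)
#' sw$fate
#' @export
sd_sweep <- function(r_grid, s_grid, R = 10, init_killer_freq = 0.1, k = 1,
                     stop = stop_rule("absolute"), max_generations = 10000,
                     presence_threshold = 1e-3) {
  if (length(r_grid) == 0 || length(s_grid) == 0) {
    stop("`r_grid` and `s_grid` must be nonempty", call. = FALSE)
  }
  cells <- tidyr::expand_grid(r = r_grid, s = s_grid)
  out <- purrr::pmap(cells, function(r, s) {
    invasion_fate(sd_params(r = r, s = s, k = k, R = R), init_killer_freq,
                  stop = stop, max_generations = max_generations,
                  presence_threshold = presence_threshold)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("sd_sweep", class(out))
  out
}

# predicate: does the killer haplotype increase in frequency?
# criterion "terminal": final vs initial frequency at the stop rule's
# pseudo-equilibrium; "horizon": frequency after `horizon` generations.
killer_increases <- function(params, f0, criterion = c("terminal", "horizon"),
                             horizon = 100, stop = stop_rule("absolute"),
                             max_generations = 10000) {
  criterion <- match.arg(criterion)
  if (criterion == "horizon") {
    fit <- sd_iterate(invasion_theta0(f0), params,
                      max_generations = horizon, stop = stop_rule("none"))
  } else {
    fit <- sd_iterate(invasion_theta0(f0), params,
                      max_generations = max_generations, stop = stop)
  }
  fit$haplotype_freqs[["Ab"]] > f0
}

#' Minimum initial frequency for a killer haplotype to spread
#'
#' The killer counts as able to spread from `f0` when its haplotype
#' frequency after `horizon` generations exceeds `f0`. The minimal such
#' `f0` is found by bisection on (0, 1) to absolute tolerance `tol`;
#' the sentinel 1 is returned when the killer cannot spread even from
#' frequencies near 1.
#'
#' @param r,s Recombination and selfing rates.
#' @param R Pollen redundancy.
#' @param k Killing efficiency.
#' @param horizon Number of generations after which frequencies are
#'   compared.
#' @param tol Bisection tolerance on the frequency.
#' @return A single number in (0, 1\].
#' @examples
#' min_invasion_frequency(r = 0, s = 1e-5, R = 10)
#' @export
min_invasion_frequency <- function(r, s, R = 10, k = 1, horizon = 100,
                                   tol = 1e-4) {
  params <- sd_params(r = r, s = s, k = k, R = R)
  g <- function(f0) killer_increases(params, f0, criterion = "horizon",
                                     horizon = horizon)
  hi <- 1 - 1e-3
  if (!g(hi)) return(1)
  lo <- 0 # killer absent: cannot spread, by convention
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Largest recombination rate at which the killer still spreads
#'
#' Bisects on `r` in \[0, 0.5\] for the boundary between killer increase
#' and decrease, at fixed selfing rate, redundancy and initial frequency.
#' The brackets are verified first: if the killer does not increase even at
#' `r = 0` the function returns 0, and if it increases at `r = 0.5` it
#' returns 0.5.
#'
#' @inheritParams min_invasion_frequency
#' @param f0 Initial killer haplotype frequency.
#' @param tol Bisection tolerance on `r`.
#' @param criterion `"terminal"` compares final vs initial frequency under
#'   the stop rule (the convention of the fate grids); `"horizon"` compares
#'   after `horizon` generations (the convention of the minimum-frequency
#'   maps).
#' @param horizon Generations for the `"horizon"` criterion.
#' @return The threshold recombination rate.
#' @export
find_recombination_threshold <- function(s, R = 10, f0 = 0.1, k = 1,
                                         tol = 1e-3,
                                         criterion = c("terminal", "horizon"),
                                         horizon = 100) {
  criterion <- match.arg(criterion)
  g <- function(r) killer_increases(sd_params(r = r, s = s, k = k, R = R),
                                    f0, criterion = criterion, horizon = horizon)
  if (!g(0)) return(0)
  if (g(0.5)) return(0.5)
  lo <- 0; hi <- 0.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Smallest selfing rate at which the killer can spread
#'
#' Bisects on `s` in \[0, 1\] for the spread/no-spread boundary at fixed
#' recombination rate, redundancy and initial frequency. Brackets are
#' verified at both ends: if the killer spreads at `s = 0` the function
#' returns 0. Complete selfing (`s = 1`) freezes the invasion
#' configuration (homozygotes only, no cross-pollination, so no
#' heterozygotes ever form and no killing is expressed), so when `s = 1`
#' does not qualify the upper bracket steps down on a grid (step 0.005) to
#' the largest selfing rate at which the killer does increase; if none
#' exists the sentinel 1 is returned.
#'
#' @inheritParams find_recombination_threshold
#' @param r Recombination rate.
#' @return The threshold selfing rate (0 if the killer spreads at any `s`,
#'   1 if at none).
#' @export
find_selfing_threshold <- function(r, R = 10, f0 = 0.1, k = 1, tol = 1e-3,
                                   criterion = c("terminal", "horizon"),
                                   horizon = 100) {
  criterion <- match.arg(criterion)
  g <- function(s) killer_increases(sd_params(r = r, s = s, k = k, R = R),
                                    f0, criterion = criterion, horizon = horizon)
  if (g(0)) return(0)
  hi <- 1
  while (hi > 0 && !g(hi)) hi <- hi - 0.005
  if (hi <= 0) return(1)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Killer haplotype arising by mutation from the neutral haplotype
#'
#' Models a one-shot origin of the killer in a population segregating the
#' neutral and sensitive haplotypes: killer homozygotes are introduced at
#' frequency `intro_freq` (converted from neutral mass), with no recurrent
#' mutation, and the recursion is iterated to equilibrium.
#'
#' @param neutral_freq,sensitive_freq,intro_freq Initial frequencies of
#'   neutral (`AB|AB`), sensitive (`aB|aB`) and killer (`Ab|Ab`)
#'   homozygotes; must sum to 1. `sensitive_freq` defaults to the
#'   complement.
#' @inheritParams sd_iterate
#' @return An `sd_equilibrium` (with trajectory) carrying two extra
#'   fields: `killer_max`, the maximum killer haplotype frequency attained,
#'   and `spread`, whether the killer's final frequency exceeds
#'   `intro_freq`.
#' @examples
#' fit <- mutation_origin_trajectory(0.1, intro_freq = 1e-3,
#'                                   params = sd_params(r = 0, s = 0.5))
#' fit$killer_max
#' @export
mutation_origin_trajectory <- function(neutral_freq,
                                       sensitive_freq = 1 - neutral_freq - intro_freq,
                                       intro_freq = 1e-3, params,
                                       max_generations = 10000,
                                       stop = stop_rule("absolute")) {
  freqs <- c(neutral_freq, sensitive_freq, intro_freq)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("neutral, sensitive and intro frequencies must be nonnegative and sum to 1",
         call. = FALSE)
  }
  theta0 <- genotype_frequencies(c(`AB|AB` = neutral_freq,
                                   `aB|aB` = sensitive_freq,
                                   `Ab|Ab` = intro_freq))
  fit <- sd_iterate(theta0, params, max_generations = max_generations,
                    stop = stop, record_trajectory = TRUE)
  fit$killer_max <- max(fit$trajectory$Ab)
  fit$spread <- fit$haplotype_freqs[["Ab"]] > intro_freq
  fit
}
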