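#' Model parameters for the pollen-killer recursion
#'
#' Bundles the scalar parameters of the two-locus toxin-antidote model.
#' The pollen supply splits into `M_self = s * M_total` (pollen a flower
#' receives from its own plant) and `M_pool = (1 - s) * M_total` (pollen
#' from the cross-pollination pool), so that the selfing rate is exactly
#' `M_self / (M_self + M_pool)`. Only the ratio matters; `M_total` defaults
#' to 1.
#'
#' @param r Recombination rate between the killer and antidote loci, in
#'   \[0, 0.5\].
#' @param s Selfing rate, in \[0, 1\]. Both endpoints are permitted exactly.
#' @param k Killing efficiency: the probability that an "a"-bearing pollen
#'   grain is destroyed when the plant also carries a "b" allele, in \[0, 1\].
#' @param R Pollen redundancy: pollen delivered per flower divided by the
#'   pollen needed to fertilize all its ovules; must be >= 1. High `R`
#'   buffers fertility against pollen killing.
#' @param M_total Positive pollen-supply scale.
#' @return An object of class `sd_params`: a list with elements `r`, `s`,
#'   `k`, `R`, `M_self`, `M_pool`.
#' @examples
#' sd_params(r = 0.1, s = 0.9)
#' @export
sd_params <- function(r = 0, s = 0, k = 1, R = 10, M_total = 1) {
  check_scalar <- function(x, nm, lo, hi) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop("`", nm, "` must be a finite numeric scalar", call. = FALSE)
    }
    if (x < lo || x > hi) {
      stop("`", nm, "` must be in [", lo, ", ", hi, "], got ", x, call. = FALSE)
    }
    as.numeric(x)
  }
  r <- check_scalar(r, "r", 0, 0.5)
  s <- check_scalar(s, "s", 0, 1)
  k <- check_scalar(k, "k", 0, 1)
  R <- check_scalar(R, "R", 1, Inf)
  M_total <- check_scalar(M_total, "M_total", 0, Inf)
  if (M_total <= 0) stop("`M_total` must be > 0", call. = FALSE)
  structure(
    list(r = r, s = s, k = k, R = R,
         M_self = s * M_total, M_pool = (1 - s) * M_total),
    class = "sd_params"
  )
}

#' @export
print.sd_params <- function(x, ...) {
  cat("<sd_params> pollen-killer model parameters\n")
  cat(sprintf("  r = %g (recombination)   s = %g (selfing)\n", x$r, x$s))
  cat(sprintf("  k = %g (killing)         R = %g (pollen redundancy)\n", x$k, x$R))
  cat(sprintf("  M_self = %g, M_pool = %g\n", x$M_self, x$M_pool))
  invisible(x)
}

as_sd_params <- function(x) {
  if (inherits(x, "sd_params")) return(x)
  if (is.list(x)) return(do.call(sd_params, x[intersect(names(x), c("r", "s", "k", "R", "M_total"))]))
  stop("cannot interpret `params`; use sd_params()", call. = FALSE)
}
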