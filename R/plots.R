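#' Quick-look plot of a haplotype-frequency trajectory
#'
#' @param object An `sd_equilibrium` with a recorded trajectory.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sd_equilibrium <- function(object, ...) {
  traj <- tidy(object)
  long <- traj |>
    dplyr::select("generation", dplyr::all_of(.HAP_NAMES)) |>
    tidyr::pivot_longer(-"generation", names_to = "haplotype",
                        values_to = "frequency") |>
    dplyr::mutate(haplotype = factor(.data$haplotype, levels = .HAP_NAMES,
                                     labels = paste0(.HAP_NAMES, " (",
                                                     .HAP_ROLES[.HAP_NAMES], ")")))
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$frequency,
                                     colour = .data$haplotype)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "generation", y = "haplotype frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Quick-look plot of an invasion-fate sweep
#'
#' Tiles the (r, s) grid by the fate of the killer haplotype.
#'
#' @param object An `sd_sweep` tibble from [sd_sweep()].
#' @param fill One of `"fate"`, `"state"`, `"killer_final"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sd_sweep <- function(object, fill = c("fate", "state", "killer_final"),
                              ...) {
  fill <- match.arg(fill)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$r, .data$s,
                                            fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "recombination rate (r)", y = "selfing rate (s)") +
    ggplot2::theme_minimal()
  if (fill == "fate") {
    p <- p + ggplot2::scale_fill_manual(values = c(
      increased = "#c0392b", decreased = "#2980b9", eliminated = "grey70"))
  }
  p
}

#' Quick-look plot of an f4 scan
#'
#' Histogram of per-quadruplet f4 values with the maximum-|f4| quadruplet
#' marked.
#'
#' @param object An `f4_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.f4_scan <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(.data$f4)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$max_f4_signed,
                        colour = "#c0392b", linetype = 2) +
    ggplot2::labs(x = "f4 (tree-consistent quadruplets)", y = "count") +
    ggplot2::theme_minimal()
}
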