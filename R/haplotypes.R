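#' Haplotype and genotype index conventions
#'
#' The two-locus toxin-antidote system has two alleles per locus (A/a, B/b)
#' and four haplotypes, indexed in the fixed order AB, Ab, aB, ab:
#'
#' * `AB` -- "neutral": cannot be killed and does not kill;
#' * `Ab` -- "killer": kills "a"-bearing pollen but cannot itself be killed;
#' * `aB` -- "sensitive": killed when the plant also carries a "b" allele;
#' * `ab` -- "suicide": kills, and is itself killed, in the same plant.
#'
#' The ten diploid genotypes are indexed in the fixed order
#' `AB|AB, AB|Ab, AB|aB, AB|ab, Ab|Ab, Ab|aB, Ab|ab, aB|aB, aB|ab, ab|ab`.
#' `AB|ab` and `Ab|aB` carry the same alleles but different phase and are
#' kept as distinct states because they produce different gametes.
#'
#' @format `hap_labels()` returns a named character vector of length 4;
#'   `genotype_labels()` a character vector of length 10.
#' @name conventions
NULL

# haplotype i encoded as (locus1 allele is "A", locus2 allele is "B")
.HAP_NAMES <- c("AB", "Ab", "aB", "ab")
.HAP_ROLES <- c(AB = "neutral", Ab = "killer", aB = "sensitive", ab = "suicide")
.HAP_L1_A <- c(TRUE, TRUE, FALSE, FALSE)   # carries "A" at locus 1
.HAP_L2_B <- c(TRUE, FALSE, TRUE, FALSE)   # carries "B" at locus 2

# genotype i -> haplotype indices (hap1, hap2), fixed order of the H vector
.GENO_H1 <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L)
.GENO_H2 <- c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L)
.GENO_NAMES <- paste(.HAP_NAMES[.GENO_H1], .HAP_NAMES[.GENO_H2], sep = "|")

# 10 x 4 matrix: haplotype copy number of each genotype / 2
.HAP_DOSE <- local({
  m <- matrix(0, 10, 4, dimnames = list(.GENO_NAMES, .HAP_NAMES))
  for (i in 1:10) {
    m[i, .GENO_H1[i]] <- m[i, .GENO_H1[i]] + 0.5
    m[i, .GENO_H2[i]] <- m[i, .GENO_H2[i]] + 0.5
  }
  m
})

#' @rdname conventions
#' @export
hap_labels <- function() stats::setNames(.HAP_NAMES, .HAP_ROLES[.HAP_NAMES])

#' @rdname conventions
#' @export
genotype_labels <- function() .GENO_NAMES

#' Haplotype frequencies implied by a genotype-frequency vector
#'
#' Each genotype contributes half of its frequency per haplotype copy.
#'
#' @param theta Numeric vector of length 10: genotype frequencies in the
#'   fixed order of [genotype_labels()]. Must be nonnegative and sum to 1.
#' @return A named numeric vector of length 4 (`AB`, `Ab`, `aB`, `ab`)
#'   summing to 1.
#' @examples
#' haplotype_frequencies(genotype_frequencies(c(`Ab|aB` = 1)))
#' @export
haplotype_frequencies <- function(theta) {
  theta <- check_theta(theta)
  drop(crossprod(.HAP_DOSE, theta))[.HAP_NAMES]
}

#' Build a genotype-frequency vector
#'
#' @param x Either a full numeric vector of length 10 (in the order of
#'   [genotype_labels()]), or a named numeric vector giving frequencies for
#'   a subset of genotypes (e.g. `c("Ab|Ab" = 0.1, "aB|aB" = 0.9)`); the
#'   rest are set to 0.
#' @param normalize Divide by the sum (must be > 0) instead of requiring the
#'   entries to sum to 1.
#' @return A named numeric vector of length 10 summing to 1.
#' @examples
#' genotype_frequencies(c(`Ab|Ab` = 0.1, `aB|aB` = 0.9))
#' @export
genotype_frequencies <- function(x, normalize = FALSE) {
  if (length(x) == 10 && (is.null(names(x)) || all(names(x) == .GENO_NAMES))) {
    theta <- as.numeric(x)
  } else {
    if (is.null(names(x))) {
      stop("`x` must be length 10 or a named vector of genotype labels", call. = FALSE)
    }
    bad <- setdiff(names(x), .GENO_NAMES)
    if (length(bad) > 0) {
      stop("unknown genotype label(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    theta <- stats::setNames(numeric(10), .GENO_NAMES)
    theta[names(x)] <- as.numeric(x)
  }
  names(theta) <- .GENO_NAMES
  if (normalize) {
    s <- sum(theta)
    if (s <= 0) stop("frequencies sum to 0; cannot normalize", call. = FALSE)
    theta <- theta / s
  }
  check_theta(theta)
}

# validate and lightly clean a genotype-frequency vector
check_theta <- function(theta, tol = 1e-9) {
  if (length(theta) != 10 || !is.numeric(theta)) {
    stop("`theta` must be a numeric vector of length 10", call. = FALSE)
  }
  if (any(!is.finite(theta))) stop("`theta` has non-finite entries", call. = FALSE)
  if (any(theta < -1e-12)) stop("`theta` has negative entries", call. = FALSE)
  theta <- pmax(theta, 0)
  if (abs(sum(theta) - 1) > tol) {
    stop("`theta` must sum to 1 (got ", format(sum(theta)), ")", call. = FALSE)
  }
  stats::setNames(as.numeric(theta), .GENO_NAMES)
}
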