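#' Gamete-generating matrices
#'
#' Builds the 10 x 4 female (`Gf`) and male (`Gm`) gamete-generating
#' matrices of the model. Row `i`, column `j` is the probability that a
#' gamete from a plant of genotype `i` carries haplotype `j` and (for
#' pollen) survives killing.
#'
#' For a genotype `h1|h2`, meiosis puts mass `(1 - r)/2` on each parental
#' haplotype and `r/2` on each recombinant; masses on identical haplotypes
#' accumulate, so homozygote rows are unaffected by `r`. `Gf` is exactly
#' this distribution. For pollen, every "a"-bearing haplotype (`aB`, `ab`)
#' is destroyed with probability `k` whenever the plant carries at least
#' one "b" allele (i.e. one of its haplotypes is `Ab` or `ab`); `Gm`
#' multiplies those entries by `1 - k`. Row sums of `Gm` below 1 therefore
#' measure pollen lost to killing.
#'
#' @inheritParams sd_iterate
#' @return A list of class `sd_gametes` with 10 x 4 matrices `Gf` and `Gm`
#'   (rows named by genotype, columns by haplotype).
#' @examples
#' g <- build_gamete_matrices(sd_params(r = 0.1, s = 0, k = 1))
#' g$Gm["AB|ab", ]  # 0.5(1-r), 0.5r, 0.5r(1-k), 0.5(1-r)(1-k)
#' @export
build_gamete_matrices <- function(params) {
  params <- as_sd_params(params)
  r <- params$r
  k <- params$k

  Gf <- matrix(0, 10, 4, dimnames = list(.GENO_NAMES, .HAP_NAMES))
  for (i in 1:10) {
    h1 <- .GENO_H1[i]
    h2 <- .GENO_H2[i]
    # recombinants swap the locus-2 allele between the two haplotypes
    r1 <- hap_index(.HAP_L1_A[h1], .HAP_L2_B[h2])
    r2 <- hap_index(.HAP_L1_A[h2], .HAP_L2_B[h1])
    Gf[i, h1] <- Gf[i, h1] + (1 - r) / 2
    Gf[i, h2] <- Gf[i, h2] + (1 - r) / 2
    Gf[i, r1] <- Gf[i, r1] + r / 2
    Gf[i, r2] <- Gf[i, r2] + r / 2
  }

  Gm <- Gf
  carries_b <- !.HAP_L2_B[.GENO_H1] | !.HAP_L2_B[.GENO_H2]  # any "b" allele
  a_bearing <- which(!.HAP_L1_A)                            # haplotypes aB, ab
  Gm[carries_b, a_bearing] <- Gm[carries_b, a_bearing] * (1 - k)

  structure(list(Gf = Gf, Gm = Gm), class = "sd_gametes")
}

# haplotype index from allele content (locus1 "A"?, locus2 "B"?)
hap_index <- function(l1A, l2B) {
  1L + (!l1A) * 2L + (!l2B) * 1L
}

#' Pollen-pool haplotype frequencies
#'
#' The cross-pollination pool receives the surviving pollen of every plant
#' in proportion to its genotype frequency; the pool haplotype frequencies
#' are the normalized product of the male gamete-generating matrix with the
#' genotype-frequency vector.
#'
#' @param gametes An `sd_gametes` object from [build_gamete_matrices()].
#' @inheritParams haplotype_frequencies
#' @return Named numeric vector of length 4 summing to 1.
#' @export
pollen_pool_frequencies <- function(gametes, theta) {
  theta <- check_theta(theta)
  m <- drop(crossprod(gametes$Gm, theta))
  tot <- sum(m)
  if (tot <= 0) {
    stop("population produces no surviving pollen; pool frequencies undefined",
         call. = FALSE)
  }
  m / tot
}

#' Pollen available to a flower of each genotype
#'
#' A flower draws on the shared pool (`M_pool`) plus its own plant's
#' surviving pollen, which is proportional to the row sum of the male
#' gamete-generating matrix: `N_i = M_pool + M_self * rowsum(Gm_i)`.
#'
#' @inheritParams pollen_pool_frequencies
#' @inheritParams sd_iterate
#' @return Named numeric vector of length 10.
#' @export
pollen_availability <- function(gametes, params) {
  params <- as_sd_params(params)
  params$M_pool + params$M_self * rowSums(gametes$Gm)
}

#' Fertility of a flower as a function of available pollen
#'
#' Fertility is the probability that a flower forms an embryo. It is 1
#' whenever available pollen exceeds `(M_pool + M_self) / R` and declines
#' linearly to 0 below that point:
#' `phi_i = min(1, N_i * R / (M_pool + M_self))`.
#'
#' @param N Numeric vector of available pollen per genotype
#'   (see [pollen_availability()]).
#' @inheritParams sd_iterate
#' @return Numeric vector of fertilities in \[0, 1\], same length as `N`.
#' @export
fertility <- function(N, params) {
  params <- as_sd_params(params)
  if (any(N < 0)) stop("`N` must be nonnegative", call. = FALSE)
  pmin(1, N * params$R / (params$M_self + params$M_pool))
}

#' Offspring genotype distribution of one maternal flower
#'
#' Conditional on a flower of genotype `i` being fertilized, the offspring
#' genotype distribution combines a female gamete (drawn from `Gf`) with a
#' pollen haplotype drawn from the flower's own surviving pollen (weight
#' `M_self`) and the shared pool (weight `M_pool`), normalized by the
#' available pollen `N_i`. Phase is tracked: `AB|ab` and `Ab|aB` are
#' distinct offspring states.
#'
#' @param i Maternal genotype index (1..10) or label (e.g. `"Ab|aB"`).
#' @param gametes An `sd_gametes` object.
#' @param f Pollen-pool haplotype frequencies (length 4), from
#'   [pollen_pool_frequencies()]. Ignored when `M_pool = 0`.
#' @inheritParams sd_iterate
#' @return Named numeric vector of length 10 summing to 1, or all zeros if
#'   the flower has no pollen at all (`N_i = 0`).
#' @export
offspring_distribution <- function(i, gametes, f, params) {
  params <- as_sd_params(params)
  if (is.character(i)) i <- match(i, .GENO_NAMES)
  if (is.na(i) || i < 1 || i > 10) stop("invalid genotype index", call. = FALSE)
  if (missing(f)) f <- rep(0, 4)
  offspring_matrix(gametes, f, params)[i, ]
}

# 10 x 10 matrix of p_ij for all maternal genotypes at once; rows of
# zero-pollen genotypes are all zero.
offspring_matrix <- function(gametes, f, params) {
  Gf <- gametes$Gf
  Gm <- gametes$Gm
  # pollen mass reaching a flower of genotype i, by haplotype
  PM <- params$M_self * Gm +
    matrix(params$M_pool * f, 10, 4, byrow = TRUE)
  N <- params$M_pool + params$M_self * rowSums(Gm)
  A <- Gf[, .GENO_H1] * PM[, .GENO_H2]
  B <- Gf[, .GENO_H2] * PM[, .GENO_H1]
  het <- matrix(as.numeric(.GENO_H1 != .GENO_H2), 10, 10, byrow = TRUE)
  p <- A + B * het
  ok <- N > 0
  p[ok, ] <- p[ok, ] / N[ok]
  p[!ok, ] <- 0
  dimnames(p) <- list(.GENO_NAMES, .GENO_NAMES)
  p
}
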