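#' Patterson's f4 statistic
#'
#' `f4(A, B; C, D)` is the mean over sites of
#' `(pA - pB) * (pC - pD)`, where `p` are derived-allele frequencies. Its
#' expectation is 0 when the four populations are related by the unrooted
#' phylogeny `[(A, B), (C, D)]`; introgression between populations on
#' opposite sides of the internal edge shifts it away from 0. Sites with a
#' missing value in any population are excluded.
#'
#' @param pA,pB,pC,pD Numeric vectors of per-site derived-allele
#'   frequencies in \[0, 1\], all the same length.
#' @return A single number.
#' @examples
#' f4_statistic(c(1, 0), c(0, 0), c(1, 0), c(0, 0))  # 0.5
#' @export
f4_statistic <- function(pA, pB, pC, pD) {
  n <- length(pA)
  if (n < 1 || length(pB) != n || length(pC) != n || length(pD) != n) {
    stop("frequency vectors must have equal length >= 1", call. = FALSE)
  }
  ok <- stats::complete.cases(pA, pB, pC, pD)
  if (!any(ok)) stop("no usable sites (all have missing values)", call. = FALSE)
  mean((pA[ok] - pB[ok]) * (pC[ok] - pD[ok]))
}

# Tree-consistent arrangement of every 4-leaf subset of a species tree.
# For each subset the leaves are arranged (A, B; C, D) so that the tree
# restricted to them has unrooted topology [(A, B), (C, D)]; unresolved
# restrictions are skipped with a warning.
tree_quadruplets <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!setequal(tips, labels) || anyDuplicated(tips)) {
    stop("tree leaves must match the population labels exactly", call. = FALSE)
  }
  subsets <- utils::combn(sort(tips), 4, simplify = FALSE)
  rows <- purrr::map(subsets, function(four) {
    tr4 <- ape::unroot(ape::keep.tip(tree, four))
    if (tr4$Nnode < 2) {
      warning("unresolved 4-leaf subtree for {", paste(four, collapse = ", "),
              "}; skipped", call. = FALSE)
      return(NULL)
    }
    # a cherry: an internal node with exactly two leaf children
    nt <- length(tr4$tip.label)
    internal <- unique(tr4$edge[, 1])
    pair <- NULL
    for (nd in internal) {
      kids <- tr4$edge[tr4$edge[, 1] == nd, 2]
      leafkids <- kids[kids <= nt]
      if (length(leafkids) == 2) { pair <- tr4$tip.label[leafkids]; break }
    }
    if (is.null(pair)) return(NULL)
    rest <- setdiff(four, pair)
    # canonical orientation: the pair holding the first label goes in front
    if (!(four[1] %in% pair)) { tmp <- pair; pair <- rest; rest <- tmp }
    tibble::tibble(A = sort(pair)[1], B = sort(pair)[2],
                   C = sort(rest)[1], D = sort(rest)[2])
  })
  dplyr::bind_rows(rows)
}

#' f4 scan of a region: all tree-consistent quadruplets and the maximum
#'
#' Computes `f4(A, B; C, D)` for every 4-population subset, arranged so
#' that the species tree restricted to the four populations has unrooted
#' topology `[(A, B), (C, D)]` (so each f4 has expectation 0 under the
#' tree). The maximum `|f4|` over quadruplets is the region's introgression
#' indicator; when a null distribution of such indicators (e.g. from
#' random regions) is supplied, its empirical percentile p-value is
#' attached via [percentile_p()].
#'
#' @param freqs Populations-by-sites matrix of derived-allele frequencies
#'   with population row names, or a data frame whose first column is the
#'   population label (as read by [read_allele_freqs()]).
#' @param tree A rooted `phylo` species tree whose tip labels are exactly
#'   the population labels.
#' @param null_values Optional numeric vector of the introgression
#'   indicator at null regions.
#' @return An object of class `f4_scan`. [tidy()] returns the
#'   per-quadruplet tibble (`A`, `B`, `C`, `D`, `f4`, `abs_f4`); [glance()]
#'   a one-row summary with `max_abs_f4`, the maximizing quadruplet, the
#'   signed `f4` there, `n_sites`, and `percentile_p` when a null was
#'   given.
#' @examples
#' tr <- ape::read.tree(text = "(((p1,p2),p3),p4);")
#' m <- matrix(runif(4 * 50), 4, dimnames = list(paste0("p", 1:4), NULL))
#' glance(f4_scan(m, tr))
#' @export
f4_scan <- function(freqs, tree, null_values = NULL) {
  freqs <- as_freq_matrix(freqs)
  if (nrow(freqs) < 4) stop("need at least 4 populations", call. = FALSE)
  quads <- tree_quadruplets(tree, rownames(freqs))
  if (nrow(quads) == 0) stop("no resolved quadruplets in the tree", call. = FALSE)
  tab <- quads |>
    dplyr::mutate(
      f4 = purrr::pmap_dbl(quads, function(A, B, C, D) {
        f4_statistic(freqs[A, ], freqs[B, ], freqs[C, ], freqs[D, ])
      }),
      abs_f4 = abs(.data$f4)
    )
  imax <- which.max(tab$abs_f4)
  out <- list(
    table = tab,
    max_abs_f4 = tab$abs_f4[imax],
    max_quadruplet = unlist(tab[imax, c("A", "B", "C", "D")], use.names = FALSE),
    max_f4_signed = tab$f4[imax],
    n_sites = ncol(freqs),
    percentile_p = if (!is.null(null_values)) {
      percentile_p(tab$abs_f4[imax], null_values)
    } else NA_real_
  )
  structure(out, class = "f4_scan")
}

#' @export
print.f4_scan <- function(x, ...) {
  cat("<f4_scan>", nrow(x$table), "tree-consistent quadruplets over",
      x$n_sites, "sites\n")
  cat(sprintf("  max |f4| = %.6g at (%s, %s; %s, %s), signed f4 = %.6g\n",
              x$max_abs_f4, x$max_quadruplet[1], x$max_quadruplet[2],
              x$max_quadruplet[3], x$max_quadruplet[4], x$max_f4_signed))
  if (!is.na(x$percentile_p)) {
    cat(sprintf("  empirical percentile p = %.4g\n", x$percentile_p))
  }
  invisible(x)
}

#' @export
tidy.f4_scan <- function(x, ...) x$table

#' @export
glance.f4_scan <- function(x, ...) {
  tibble::tibble(
    max_abs_f4 = x$max_abs_f4,
    A = x$max_quadruplet[1], B = x$max_quadruplet[2],
    C = x$max_quadruplet[3], D = x$max_quadruplet[4],
    f4_signed = x$max_f4_signed,
    n_quadruplets = nrow(x$table),
    n_sites = x$n_sites,
    percentile_p = x$percentile_p
  )
}

#' Empirical percentile p-value
#'
#' Rank of an observed statistic in a null sample, converted to a p-value
#' with the add-one rule `p = (1 + #\{null >= observed\}) / (1 + n)`, which
#' avoids p = 0.
#'
#' @param observed A single number.
#' @param null_values Nonempty numeric vector of null draws.
#' @return A p-value in (0, 1\].
#' @examples
#' percentile_p(2, rnorm(99))
#' @export
percentile_p <- function(observed, null_values) {
  if (length(null_values) == 0 || !is.numeric(null_values)) {
    stop("`null_values` must be a nonempty numeric vector", call. = FALSE)
  }
  if (length(observed) != 1 || !is.finite(observed)) {
    stop("`observed` must be a single finite number", call. = FALSE)
  }
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via `X^2 = -2 sum(log(p))`, referred to a
#' chi-square distribution with `2m` degrees of freedom.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return An object of class `fisher_combined` with elements `p_values`,
#'   `statistic`, `df`, `p_value`; [glance()] returns them as a one-row
#'   tibble.
#' @examples
#' fisher_combined(c(0.5, 0.5))$p_value  # ~0.5966
#' @export
fisher_combined <- function(p_values) {
  if (length(p_values) < 1) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  x2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  structure(
    list(p_values = as.numeric(p_values), statistic = x2, df = df,
         p_value = stats::pchisq(x2, df = df, lower.tail = FALSE)),
    class = "fisher_combined"
  )
}

#' @export
print.fisher_combined <- function(x, ...) {
  cat(sprintf("Fisher's combined test: X^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.fisher_combined <- function(x, ...) {
  tibble::tibble(locus = seq_along(x$p_values), p_value = x$p_values)
}

#' @export
glance.fisher_combined <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n_loci = length(x$p_values))
}

# coerce allowed input shapes to a populations x sites numeric matrix
as_freq_matrix <- function(freqs) {
  if (is.data.frame(freqs)) {
    pops <- as.character(freqs[[1]])
    m <- as.matrix(freqs[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- pops
    freqs <- m
  }
  if (!is.matrix(freqs) || is.null(rownames(freqs))) {
    stop("`freqs` must be a matrix with population row names or a data frame",
         call. = FALSE)
  }
  rng <- range(freqs, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(rownames(freqs))) {
    stop("duplicated population labels", call. = FALSE)
  }
  freqs
}

#' Read a populations-by-sites allele-frequency table
#'
#' Tab-separated text with a header; the first column holds population
#' labels, remaining columns per-site derived-allele frequencies.
#'
#' @param path File path.
#' @return A numeric matrix with population row names.
#' @export
read_allele_freqs <- function(path) {
  as_freq_matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' Derived-allele frequencies from per-population FASTA alignments
#'
#' Each FASTA file holds the aligned haplotypes sampled from one
#' population; all alignments and the single-sequence reference must have
#' the same width. At each column, the derived-allele frequency of a
#' population is the proportion of its haplotypes whose base differs from
#' the reference base. Columns containing a gap or ambiguity code (any
#' non-ACGT character) in the reference or in any haplotype of any
#' population are excluded.
#'
#' @param paths Character vector of FASTA paths, named by population (file
#'   base names are used when unnamed).
#' @param reference Path to a single-sequence FASTA giving the reference
#'   (ancestral) states.
#' @return A populations-by-sites numeric matrix (usable sites only), with
#'   the original alignment columns in attribute `site_index`.
#' @export
alleles_from_fasta <- function(paths, reference) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.(fa|fasta|fna)$", "", basename(paths))
  }
  ref <- Biostrings::readDNAStringSet(reference)
  if (length(ref) != 1) stop("`reference` must contain exactly one sequence", call. = FALSE)
  width <- Biostrings::width(ref)[1]
  refchars <- strsplit(toupper(as.character(ref[[1]])), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  usable <- refchars %in% acgt
  popchars <- purrr::map(paths, function(p) {
    aln <- Biostrings::readDNAStringSet(p)
    if (any(Biostrings::width(aln) != width)) {
      stop("alignment width in ", p, " differs from the reference", call. = FALSE)
    }
    chars <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
    usable <<- usable & apply(chars, 2, function(col) all(col %in% acgt))
    chars
  })
  if (!any(usable)) stop("no usable sites after excluding gaps/ambiguities", call. = FALSE)
  m <- do.call(rbind, purrr::map(popchars, function(chars) {
    colMeans(chars[, usable, drop = FALSE] !=
               matrix(refchars[usable], nrow(chars), sum(usable), byrow = TRUE))
  }))
  rownames(m) <- names(paths)
  attr(m, "site_index") <- which(usable)
  m
}
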