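#' Finite-population stochastic counterpart of the recursion
#'
#' Wright-Fisher-style forward simulation of the pollen-killer mating
#' model: each of the `N` diploid offspring independently samples a
#' maternal flower with probability proportional to the current empirical
#' genotype frequency times fertility (soft selection), then samples its
#' genotype from that flower's offspring distribution (self pollen plus
#' pollen pool, with killing). At large `N` the per-generation mean
#' converges on the deterministic recursion, which makes this simulator
#' the package's convergence oracle for [sd_iterate()].
#'
#' @inheritParams sd_iterate
#' @param N Diploid population size (>= 2).
#' @param generations Number of generations to simulate.
#' @param replicates Number of independent replicates.
#' @param seed Optional integer seed; the run is reproducible given the
#'   seed and truly independent of the caller's RNG state.
#' @return A tibble with columns `replicate`, `generation`, the four
#'   haplotype frequencies (`AB`, `Ab`, `aB`, `ab`), and the ten genotype
#'   counts (summing to `N`). If every flower is sterile in some
#'   generation the replicate is truncated there and flagged in the
#'   `extinct` attribute.
#' @examples
#' sim <- simulate_wright_fisher(c(`Ab|Ab` = 0.1, `aB|aB` = 0.9),
#'                               sd_params(r = 0, s = 1e-5), N = 500,
#'                               generations = 5, replicates = 2, seed = 1)
#' @export
simulate_wright_fisher <- function(theta0, params, N, generations,
                                   replicates = 1, seed = NULL) {
  params <- as_sd_params(params)
  theta0 <- genotype_frequencies(theta0)
  stopifnot(N >= 2, generations >= 1, replicates >= 1)
  run <- function() {
    g <- build_gamete_matrices(params)
    phi <- fertility(pollen_availability(g, params), params)
    extinct <- logical(replicates)
    rows <- vector("list", replicates)
    for (rep in seq_len(replicates)) {
      counts0 <- drop(stats::rmultinom(1, N, theta0))
      tab <- matrix(NA_integer_, generations + 1, 10)
      tab[1, ] <- counts0
      counts <- counts0
      last <- generations
      for (gen in seq_len(generations)) {
        emp <- counts / N
        w <- emp * phi
        if (sum(w) <= 0) { extinct[rep] <- TRUE; last <- gen - 1L; break }
        male <- drop(crossprod(g$Gm, emp))
        f <- if (sum(male) > 0) male / sum(male) else rep(0, 4)
        if (sum(male) <= 0 && params$M_pool > 0) {
          extinct[rep] <- TRUE; last <- gen - 1L; break
        }
        p <- offspring_matrix(g, f, params)
        mothers <- drop(stats::rmultinom(1, N, w))
        nxt <- integer(10)
        for (i in which(mothers > 0)) {
          nxt <- nxt + drop(stats::rmultinom(1, mothers[i], p[i, ]))
        }
        counts <- nxt
        tab[gen + 1, ] <- counts
      }
      keep <- seq_len(last + 1L)
      colnames(tab) <- .GENO_NAMES
      hap <- (tab[keep, , drop = FALSE] %*% .HAP_DOSE) / N
      rows[[rep]] <- dplyr::bind_cols(
        tibble::tibble(replicate = rep, generation = keep - 1L),
        tibble::as_tibble(hap),
        tibble::as_tibble(tab[keep, , drop = FALSE])
      )
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "extinct") <- extinct
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Introgression event specification
#'
#' Describes a one-off introgression used by
#' [simulate_species_alleles()]: at a given fraction of sites (chosen
#' uniformly at random), the recipient population's allele frequency is
#' replaced by the donor's.
#'
#' @param donor,recipient Tip labels of the species tree (must differ).
#' @param fraction Fraction of sites affected, in \[0, 1\].
#' @return A list of class `introgression_spec`.
#' @export
introgression_spec <- function(donor, recipient, fraction) {
  if (identical(donor, recipient)) stop("donor and recipient must differ", call. = FALSE)
  if (fraction < 0 || fraction > 1) stop("`fraction` must be in [0, 1]", call. = FALSE)
  structure(list(donor = donor, recipient = recipient, fraction = fraction),
            class = "introgression_spec")
}

#' Multi-species biallelic allele frequencies evolved on a tree
#'
#' Each site starts at `root_freq` and evolves down the species tree by
#' independent zero-mean Gaussian drift increments with standard deviation
#' `intensity * sqrt(branch length)`, truncated to \[0, 1\]. Because shared
#' drift cancels, every tree-consistent quadruplet satisfies the f4 null
#' `E[f4] = 0` (up to a small truncation bias at extreme frequencies; keep
#' `intensity` modest). An optional introgression event copies the donor's
#' tip frequency into the recipient at a random fraction of sites.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param n_sites Number of independent sites.
#' @param intensity Drift standard deviation per unit branch length.
#' @param introgression Optional [introgression_spec()].
#' @param root_freq Ancestral allele frequency at the root.
#' @inheritParams simulate_wright_fisher
#' @return A populations-by-sites numeric matrix of allele frequencies.
#' @examples
#' m <- simulate_species_alleles(default_species_tree(), n_sites = 100,
#'                               seed = 1)
#' @export
simulate_species_alleles <- function(tree, n_sites, intensity = 0.05,
                                     introgression = NULL, root_freq = 0.5,
                                     seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1, intensity >= 0)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  if (!is.null(introgression)) {
    miss <- setdiff(c(introgression$donor, introgression$recipient), tree$tip.label)
    if (length(miss) > 0) {
      stop("unknown donor/recipient label(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  run <- function() {
    nt <- length(tree$tip.label)
    root <- nt + 1L
    vals <- vector("list", nt + tree$Nnode)
    vals[[root]] <- rep(root_freq, n_sites)
    ed <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ed$edge))) {
      parent <- ed$edge[e, 1]
      child <- ed$edge[e, 2]
      bl <- ed$edge.length[e]
      x <- vals[[parent]] + stats::rnorm(n_sites, 0, intensity * sqrt(bl))
      vals[[child]] <- pmin(1, pmax(0, x))
    }
    m <- do.call(rbind, vals[seq_len(nt)])
    rownames(m) <- tree$tip.label
    if (!is.null(introgression) && introgression$fraction > 0) {
      n_aff <- round(introgression$fraction * n_sites)
      sites <- sample.int(n_sites, n_aff)
      m[introgression$recipient, sites] <- m[introgression$donor, sites]
    }
    m
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default seven-population ladder species tree
#'
#' A rooted caterpillar tree over populations `sp1`..`sp7` with unit
#' branch lengths, mirroring the shape of a clade of closely related
#' congeneric species. Used by the synthetic generators and fixtures.
#'
#' @return A `phylo` object.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(sp1:6,(sp2:5,(sp3:4,(sp4:3,(sp5:2,(sp6:1,sp7:1):1):1):1):1):1);"
  ))
}

#' Write the synthetic fixture set used by the test suite
#'
#' Emits, deterministically for a given seed: a populations-by-sites
#' allele-frequency TSV, one FASTA alignment per population consistent
#' with it (plus a single-sequence reference FASTA of ancestral states), a
#' Newick species tree, a null-values file (one introgression indicator
#' per line, from no-introgression replicates), and an md5 manifest. All
#' files carry a `synthetic_` prefix: they are simulated, not real data.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the fixture set is a pure function of it.
#' @param n_sites Sites per population.
#' @param n_hap Haplotypes sampled per population (FASTA rows).
#' @param n_null Number of null replicates for the null-values file.
#' @param tree Species tree (defaults to [default_species_tree()]).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_fixtures <- function(dir, seed = 42, n_sites = 200, n_hap = 20,
                           n_null = 99, tree = default_species_tree()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pops <- tree$tip.label
  paths <- c(
    tree = file.path(dir, "synthetic_species_tree.nwk"),
    freqs = file.path(dir, "synthetic_freqs.tsv"),
    ref = file.path(dir, "synthetic_reference.fasta"),
    null = file.path(dir, "synthetic_null_values.txt"),
    manifest = file.path(dir, "synthetic_manifest.md5")
  )
  fasta_paths <- stats::setNames(
    file.path(dir, paste0("synthetic_", pops, ".fasta")), pops)

  withr::with_seed(seed, {
    p <- simulate_species_alleles(tree, n_sites = n_sites)
    # discretize to haplotype counts so FASTA and TSV agree exactly
    counts <- matrix(stats::rbinom(length(p), n_hap, p), nrow(p),
                     dimnames = dimnames(p))
    freqs <- counts / n_hap
    nulls <- vapply(seq_len(n_null), function(i) {
      f4_scan(simulate_species_alleles(tree, n_sites = n_sites),
              tree)$max_abs_f4
    }, numeric(1))
  })

  ape::write.tree(tree, file = paths[["tree"]])
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(population = rownames(freqs)),
                     tibble::as_tibble(freqs, .name_repair = ~ paste0("site", seq_len(n_sites)))),
    paths[["freqs"]])
  ref_seq <- Biostrings::DNAStringSet(stats::setNames(
    paste(rep("A", n_sites), collapse = ""), "reference"))
  Biostrings::writeXStringSet(ref_seq, paths[["ref"]])
  for (pop in pops) {
    seqs <- vapply(seq_len(n_hap), function(h) {
      paste(ifelse(h <= counts[pop, ], "G", "A"), collapse = "")
    }, character(1))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(seqs, paste0(pop, "_h", seq_len(n_hap)))),
      fasta_paths[[pop]])
  }
  writeLines(format(nulls, digits = 15, scientific = FALSE, trim = TRUE),
             paths[["null"]])
  all_paths <- c(paths[c("tree", "freqs", "ref")], fasta_paths, paths["null"])
  md5 <- tools::md5sum(unname(all_paths))
  writeLines(paste(unname(md5), basename(names(md5))), paths[["manifest"]])
  invisible(c(all_paths, paths["manifest"]))
}
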