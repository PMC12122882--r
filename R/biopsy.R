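#' Sample microbiopsies from a simulated phylogeny
#'
#' Emulates laser-capture microdissection of ~100-cell microbiopsies (or
#' single-cell-derived organoid clones when `cells_per_biopsy = 1`). Each
#' biopsy is treated as drawn from one locally dominant clone (the
#' clonal-unit assumption) with a configurable minor admixture from one
#' random sibling clone: the number of admixed cells is binomial with mean
#' `admixture * cells_per_biopsy`.
#'
#' @param tree a [simulate_phylogeny()] result.
#' @param n_biopsies,cells_per_biopsy sampling design (both >= 1).
#' @param seed integer random seed.
#' @param admixture expected admixed cell fraction (default 0.05).
#' @return a numeric matrix (biopsy x mutation) whose entries are the
#'   fraction of biopsy cells carrying each mutation, with attributes
#'   `sites` (the mutation table), `dominant_clone` (per biopsy) and
#'   `tree_trunk` (the generating trunk length).
#' @export
sample_biopsies <- function(tree, n_biopsies, cells_per_biopsy, seed = 1L,
                            admixture = 0.05) {
  stopifnot(inherits(tree, "clonal_phylogeny"))
  if (n_biopsies < 1 || cells_per_biopsy < 1) {
    stop("n_biopsies and cells_per_biopsy must be >= 1")
  }
  if (nrow(tree$nodes) == 0) stop("empty tree")
  set.seed(seed)

  leaves <- tree$nodes[tree$nodes$leaf, ]
  muts <- tree$mutations
  # presence matrix clone x mutation
  presence <- vapply(seq_len(nrow(leaves)), function(i) {
    path <- node_path(tree, leaves$id[i])
    as.numeric(muts$branch %in% path)
  }, numeric(nrow(muts)))
  presence <- t(presence)  # clone x mutation
  rownames(presence) <- leaves$clone

  dom_idx <- sample.int(nrow(leaves), n_biopsies, replace = TRUE,
                        prob = leaves$fraction)
  geno <- matrix(0, nrow = n_biopsies, ncol = nrow(muts),
                 dimnames = list(sprintf("B%02d", seq_len(n_biopsies)),
                                 muts$id))
  dom_clone <- character(n_biopsies)
  for (b in seq_len(n_biopsies)) {
    i <- dom_idx[b]
    dom_clone[b] <- leaves$clone[i]
    n_minor <- if (nrow(leaves) > 1 && admixture > 0) {
      stats::rbinom(1L, cells_per_biopsy, admixture)
    } else 0L
    row <- presence[i, ] * (cells_per_biopsy - n_minor)
    if (n_minor > 0) {
      j <- sample(setdiff(seq_len(nrow(leaves)), i), 1L)
      row <- row + presence[j, ] * n_minor
    }
    geno[b, ] <- row / cells_per_biopsy
  }
  structure(geno,
            sites = muts,
            dominant_clone = dom_clone,
            tree_trunk = tree$trunk_mutation_count)
}

#' Genotypes of bulk tumour pieces
#'
#' A bulk piece (the millions-of-cells chunk that bulk WGS sequences) is a
#' polyclonal mixture: each mutation's cell fraction in the piece is its
#' tumour-wide carrier fraction, modulated by mild local clone enrichment
#' (piece-level clone weights are Dirichlet-distributed around the global
#' clone fractions with concentration `concentration`; large values mean
#' each piece mirrors the whole tumour).
#'
#' @param tree a `clonal_phylogeny`.
#' @param n_pieces number of bulk pieces.
#' @param seed integer random seed.
#' @param concentration Dirichlet concentration of local clone weights
#'   (default 100).
#' @return genotype matrix (piece x mutation) of mutant cell fractions,
#'   with a `sites` attribute.
#' @export
bulk_piece_genotypes <- function(tree, n_pieces = 4L, seed = 1L,
                                 concentration = 100) {
  stopifnot(inherits(tree, "clonal_phylogeny"))
  if (n_pieces < 1) stop("n_pieces must be >= 1")
  set.seed(seed)
  leaves <- tree$nodes[tree$nodes$leaf, ]
  muts <- tree$mutations
  presence <- t(vapply(seq_len(nrow(leaves)), function(i) {
    path <- node_path(tree, leaves$id[i])
    as.numeric(muts$branch %in% path)
  }, numeric(nrow(muts))))
  geno <- matrix(0, n_pieces, nrow(muts),
                 dimnames = list(sprintf("P%02d", seq_len(n_pieces)),
                                 muts$id))
  for (p in seq_len(n_pieces)) {
    g <- stats::rgamma(nrow(leaves), shape = concentration * leaves$fraction)
    w <- if (sum(g) == 0) leaves$fraction else g / sum(g)
    geno[p, ] <- pmin(pmax(as.vector(w %*% presence), 0), 1)
  }
  structure(geno, sites = muts, tree_trunk = tree$trunk_mutation_count)
}
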