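#' Maximum-likelihood assignment of mutations to branches
#'
#' Each mutation is scored against every branch of the tree by a product
#' over samples of binomial likelihoods of the observed mutant read counts:
#' the expected VAF is `0.5 * purity` for samples descending from the
#' branch (diploid heterozygous model) and `epsilon` otherwise. The
#' mutation is assigned to the branch maximising the likelihood; ties are
#' broken towards the larger descendant set, then the lower node id.
#' Mutations with zero mutant reads everywhere are flagged unassignable and
#' excluded from branch lengths. Per-branch raw lengths are updated in
#' place (and scaled lengths recomputed with the tree's current excluded
#' fraction).
#'
#' For variants in concordant non-diploid regions an `expected_vaf` vector
#' (one entry per mutation, `mutant copies / total copies`) can override
#' the diploid 0.5 factor.
#'
#' @param tree a `mutation_tree` whose leaves match the table's tumour
#'   samples.
#' @param table a `variant_table` with the matched normal excluded or
#'   identified.
#' @param purity per-sample tumour purity (scalar or named vector).
#' @param epsilon error VAF for non-descendant samples (clamped to
#'   >= 1e-12).
#' @param expected_vaf optional per-mutation copy-number-aware VAF factor
#'   replacing 0.5.
#' @return the tree with `assignment` (mutation, branch, assignable) and
#'   updated branch lengths.
#' @export
assign_mutations_ml <- function(tree, table, purity = 1, epsilon = 1e-4,
                                expected_vaf = NULL) {
  stopifnot(inherits(tree, "mutation_tree"), inherits(table, "variant_table"))
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  epsilon <- max(epsilon, 1e-12)

  samples <- setdiff(table$samples, table$matched_normal)
  leaves <- tree$label[tree$leaf]
  if (!setequal(leaves, samples)) {
    stop("tree leaves do not match table samples")
  }
  purity <- if (length(purity) == 1) {
    stats::setNames(rep(purity, length(samples)), samples)
  } else purity[samples]

  n_mut <- nrow(table$variants)
  m <- mutant_reads(table)[, samples, drop = FALSE]
  d <- table$depth[, samples, drop = FALSE]
  if (n_mut == 0) {
    tree$assignment <- data.frame(id = character(0), branch = integer(0),
                                  assignable = logical(0))
    return(tree)
  }
  half <- if (is.null(expected_vaf)) rep(0.5, n_mut) else expected_vaf

  desc <- tree_descendants(tree)
  branches <- setdiff(seq_along(tree$parent), tree$root)
  ind <- vapply(branches, function(b) {
    as.numeric(samples %in% desc[[b]])
  }, numeric(length(samples)))          # samples x branches
  # log-likelihood under the descendant model, per mutation and sample
  p1 <- outer(half, purity[samples])    # mutation x sample expected VAF
  ll1 <- stats::dbinom(m, d, p1, log = TRUE)
  ll0 <- stats::dbinom(m, d, epsilon, log = TRUE)
  ll <- ll1 %*% ind + ll0 %*% (1 - ind) # mutation x branch

  n_desc <- vapply(branches, function(b) length(desc[[b]]), integer(1))
  # deterministic tie-break: larger clade first, then lower node id
  ordering <- order(-n_desc, branches)
  ll_ord <- ll[, ordering, drop = FALSE]
  pick <- apply(ll_ord, 1, which.max)
  branch <- branches[ordering][pick]

  assignable <- rowSums(m) > 0
  branch[!assignable] <- NA_integer_

  tree$assignment <- data.frame(
    id = table$variants$id, branch = branch, assignable = assignable,
    stringsAsFactors = FALSE
  )
  raw <- tabulate(branch[assignable], nbins = length(tree$parent))
  tree$branch_raw <- raw
  tree <- scale_branches(tree, tree$excluded_fraction)
  tree
}

#' Scale branch lengths for excluded genome fraction
#'
#' Mutations falling in copy-number-discordant regions are excluded before
#' tree building; branch lengths are rescaled to the full genome as
#' `scaled = raw / (1 - excluded_fraction)`. Topology is unchanged and
#' branch-length ratios are conserved.
#'
#' @param tree a `mutation_tree`.
#' @param excluded_fraction genomic fraction excluded, in `[0, 1)`.
#' @return the tree with updated `branch_scaled` and `excluded_fraction`.
#' @export
scale_branches <- function(tree, excluded_fraction) {
  stopifnot(inherits(tree, "mutation_tree"))
  if (excluded_fraction < 0 || excluded_fraction >= 1) {
    stop("excluded_fraction must lie in [0, 1)")
  }
  tree$excluded_fraction <- excluded_fraction
  tree$branch_scaled <- tree$branch_raw / (1 - excluded_fraction)
  tree
}
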