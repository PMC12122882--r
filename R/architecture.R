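#' Trunk length of a tree
#'
#' The trunk is the branch path from the root to the first node with at
#' least two tumour descendants; its length is the sum of scaled mutation
#' counts along that path. For a ground-truth simulated phylogeny this is
#' the generating trunk mutation count.
#'
#' @param tree a `mutation_tree` or `clonal_phylogeny`.
#' @return mutation count (scaled, for reconstructed trees).
#' @export
trunk_length <- function(tree) UseMethod("trunk_length")

#' @export
trunk_length.clonal_phylogeny <- function(tree) tree$trunk_mutation_count

#' @export
trunk_length.mutation_tree <- function(tree) {
  ch <- tree_children(tree)
  node <- tree$root
  total <- 0
  # descend through the unary chain from the root; the trunk ends at (and
  # includes the incoming branch of) the first node with >= 2 children
  repeat {
    kids <- ch[[node]]
    if (length(kids) != 1L) break
    total <- total + tree$branch_scaled[kids]
    node <- kids
  }
  total
}

#' Mean per-cell mutation burden of a tree
#'
#' The per-cell burden is the total root-to-leaf path length. For a
#' reconstructed `mutation_tree` the unweighted mean over leaves (clonal
#' units) is returned; for a ground-truth `clonal_phylogeny` the
#' clone-fraction-weighted mean.
#'
#' @param tree a `mutation_tree` with assigned mutations, or a
#'   `clonal_phylogeny`.
#' @return mean mutations per cell.
#' @export
per_cell_burden <- function(tree) UseMethod("per_cell_burden")

#' @export
per_cell_burden.clonal_phylogeny <- function(tree) true_per_cell_burden(tree)

#' @export
per_cell_burden.mutation_tree <- function(tree) {
  if (!sum(tree$leaf)) stop("empty tree")
  leaves <- which(tree$leaf)
  depths <- vapply(leaves, function(lf) {
    total <- 0; node <- lf
    while (!is.na(tree$parent[node])) {
      total <- total + tree$branch_scaled[node]
      node <- tree$parent[node]
    }
    total
  }, numeric(1))
  mean(depths)
}

#' Duplex-vs-bulk burden discrepancy
#'
#' @param bulk,duplex [burden_estimate()]s from the same sample.
#' @return a list with `fold_change` (duplex / bulk; `NA` when the bulk
#'   burden is zero) and `abs_difference` (duplex - bulk).
#' @export
burden_discrepancy <- function(bulk, duplex) {
  stopifnot(inherits(bulk, "burden_estimate"),
            inherits(duplex, "burden_estimate"))
  fold <- if (bulk$burden > 0) duplex$burden / bulk$burden else NA_real_
  list(fold_change = fold, abs_difference = duplex$burden - bulk$burden)
}

#' Architecture report
#'
#' Collects the tree-shape and burden statistics that operationalise the
#' comb-versus-sweep distinction for one tumour.
#'
#' @param trunk trunk length (mutations).
#' @param per_cell mean per-cell burden.
#' @param bulk,duplex [burden_estimate()]s.
#' @param threshold detected-fraction cutoff below which the architecture
#'   is called comb (default 0.5); above `sweep_threshold` (default 0.8)
#'   it is called sweep, otherwise intermediate.
#' @param sweep_threshold see above.
#' @return an object of class `architecture_report`.
#' @export
architecture_report <- function(trunk, per_cell, bulk, duplex,
                                threshold = 0.5, sweep_threshold = 0.8) {
  disc <- burden_discrepancy(bulk, duplex)
  detected <- if (per_cell > 0) bulk$burden / per_cell else NA_real_
  rep <- list(
    trunk_length = trunk,
    per_cell_burden = per_cell,
    bulk_burden = bulk$burden,
    duplex_burden = duplex$burden,
    fold_change = disc$fold_change,
    abs_difference = disc$abs_difference,
    detected_fraction = detected,
    class = NA_character_
  )
  rep$class <- classify_architecture(rep, threshold, sweep_threshold)
  structure(rep, class = "architecture_report")
}

#' Classify an architecture from its detected fraction
#'
#' The detected fraction is the bulk burden over the per-cell burden:
#' low values mean bulk sequencing misses most of the per-cell burden
#' (comb-like polyclonal architecture); values near 1 mean the burden is
#' truncal and bulk-visible (sweep architecture). The classifier is
#' invariant to uniform rescaling of all burdens.
#'
#' @param report an `architecture_report` (or list with
#'   `detected_fraction`).
#' @param threshold comb cutoff (default 0.5).
#' @param sweep_threshold sweep cutoff (default 0.8).
#' @return `"comb"`, `"sweep"` or `"intermediate"`.
#' @export
classify_architecture <- function(report, threshold = 0.5,
                                  sweep_threshold = 0.8) {
  f <- report$detected_fraction
  if (is.na(f)) return(NA_character_)
  if (f < threshold) "comb"
  else if (f > sweep_threshold) "sweep"
  else "intermediate"
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("<architecture_report>\n")
  cat(sprintf("  class: %s (detected fraction %.2f)\n", x$class,
              x$detected_fraction))
  cat(sprintf("  trunk %.0f, per-cell %.0f, bulk %.0f, duplex %.0f\n",
              x$trunk_length, x$per_cell_burden, x$bulk_burden,
              x$duplex_burden))
  cat(sprintf("  fold change %.2f, absolute difference %.0f\n",
              x$fold_change, x$abs_difference))
  invisible(x)
}

#' @export
as.data.frame.architecture_report <- function(x, ...) {
  data.frame(
    trunk_length = x$trunk_length, per_cell_burden = x$per_cell_burden,
    bulk_burden = x$bulk_burden, duplex_burden = x$duplex_burden,
    fold_change = x$fold_change, abs_difference = x$abs_difference,
    detected_fraction = x$detected_fraction, class = x$class,
    stringsAsFactors = FALSE
  )
}

#' Order-of-magnitude estimate of total distinct mutations in a tumour
#'
#' Sums distinct mutations over clonal lineages: the shared trunk plus one
#' private complement per lineage (`n_cells / mean_clone_size` lineages,
#' each with `per_cell_private` mutations). Counting per lineage rather
#' than per cell avoids double-counting mutations shared within a clone.
#'
#' @param tree a tree with a trunk (any class supported by
#'   [trunk_length()]).
#' @param n_cells number of tumour cells (>= 1).
#' @param per_cell_private private mutations per lineage.
#' @param mean_clone_size cells per clonal lineage (> 0).
#' @return a list with `estimate` and `magnitude_band`
#'   (`c(10^floor, 10^ceiling)` of log10 estimate).
#' @export
total_distinct_mutations <- function(tree, n_cells, per_cell_private,
                                     mean_clone_size) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (mean_clone_size <= 0) stop("mean_clone_size must be positive")
  est <- trunk_length(tree) + (n_cells / mean_clone_size) * per_cell_private
  list(
    estimate = est,
    magnitude_band = c(10^floor(log10(est)), 10^ceiling(log10(est)))
  )
}
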