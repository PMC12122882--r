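#' Simulate a tumour clonal phylogeny
#'
#' Draws a rooted mutation-bearing tree of tumour lineages under the
#' configured architecture mode. In comb mode the tree is star-like: one
#' trunk branch shared by all tumour cells, then `n_clones` independent
#' lineages with long private branches. In sweep mode the trunk is long and
#' is followed by a chain of nested subclones with the configured cell
#' fractions.
#'
#' Branch lengths (mutation counts) are drawn as: trunk uniform on
#' `trunk_range`; private and internal branches negative-binomial with the
#' configured mean and dispersion. Mutations are placed uniformly on the
#' genome model under an infinite-sites assumption (each mutation on exactly
#' one branch, no recurrence).
#'
#' @param config a [simulation_config()].
#' @param seed integer random seed; fixing it fixes every output.
#' @return an object of class `clonal_phylogeny`: a list with
#'   \describe{
#'     \item{nodes}{data.frame of `id`, `parent` (NA for the root), `leaf`,
#'       `clone` label and cell `fraction` (leaves only).}
#'     \item{mutations}{data.frame of mutation `id`, the `branch` (node id
#'       whose incoming branch carries it), and `chrom`/`pos`/`ref`/`alt`.}
#'     \item{mode, trunk_mutation_count, purity, config}{metadata.}
#'   }
#' @export
simulate_phylogeny <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  set.seed(seed)

  trunk_len <- if (config$trunk_range[1] == config$trunk_range[2]) {
    config$trunk_range[1]
  } else {
    sample(seq(config$trunk_range[1], config$trunk_range[2]), 1L)
  }

  k <- config$n_clones
  if (k == 1L) {
    # degenerate single-lineage tumour: one branch carries everything
    private <- rnbinom_len(1L, config$private_mean, config$private_disp)
    nodes <- data.frame(
      id = c(1L, 2L), parent = c(NA_integer_, 1L),
      leaf = c(FALSE, TRUE),
      clone = c(NA, "C1"), fraction = c(NA, 1),
      stringsAsFactors = FALSE
    )
    branch_of <- rep(2L, trunk_len + private)
    tree <- new_clonal_phylogeny(nodes, branch_of, config,
                                 trunk_mutation_count = trunk_len + private)
    return(tree)
  }

  if (config$mode == "comb") {
    frac <- config$clone_fractions
    if (is.null(frac)) {
      # near-uniform clone fractions (symmetric Dirichlet, concentration
      # 10): comb-mode lineages are near-independent with no clone large
      # enough to mimic a subclonal sweep
      g <- stats::rgamma(k, shape = 10)
      frac <- g / sum(g)
    }
    private <- rnbinom_len(k, config$private_mean, config$private_disp)
    nodes <- data.frame(
      id = seq_len(k + 2L),
      parent = c(NA_integer_, 1L, rep(2L, k)),
      leaf = c(FALSE, FALSE, rep(TRUE, k)),
      clone = c(NA, NA, paste0("C", seq_len(k))),
      fraction = c(NA, NA, frac),
      stringsAsFactors = FALSE
    )
    branch_of <- c(rep(2L, trunk_len), rep(seq_len(k) + 2L, private))
  } else {
    frac <- config$clone_fractions
    # nested chain: trunk node splits leaf 1 vs internal, internal splits
    # leaf 2 vs ..., the last internal split yields the final two leaves
    internal <- rnbinom_len(k - 1L, config$internal_mean, config$private_disp)
    private <- rnbinom_len(k, config$private_mean, config$private_disp)
    ids <- integer(0); parents <- integer(0); leaf <- logical(0)
    clone <- character(0); fraction <- numeric(0); blen <- integer(0)
    add_node <- function(parent, is_leaf, cl, fr, len) {
      ids <<- c(ids, length(ids) + 1L)
      parents <<- c(parents, parent)
      leaf <<- c(leaf, is_leaf)
      clone <<- c(clone, cl)
      fraction <<- c(fraction, fr)
      blen <<- c(blen, len)
      length(ids)
    }
    add_node(NA_integer_, FALSE, NA, NA, 0L)                 # root (normal)
    current <- add_node(1L, FALSE, NA, NA, trunk_len)        # tumour MRCA
    for (i in seq_len(k - 1L)) {
      add_node(current, TRUE, paste0("C", i), frac[i], private[i])
      if (i < k - 1L) {
        current <- add_node(current, FALSE, NA, NA, internal[i])
      } else {
        # deepest subclone: its incoming path carries the last internal
        # branch plus its own private mutations
        add_node(current, TRUE, paste0("C", k), frac[k],
                 internal[i] + private[k])
      }
    }
    nodes <- data.frame(
      id = ids, parent = parents, leaf = leaf, clone = clone,
      fraction = fraction, stringsAsFactors = FALSE
    )
    branch_of <- rep(nodes$id, blen)
  }

  new_clonal_phylogeny(nodes, branch_of, config,
                       trunk_mutation_count = trunk_len)
}

rnbinom_len <- function(n, mean, disp) {
  if (mean == 0) return(integer(n))
  as.integer(stats::rnbinom(n, size = disp, mu = mean))
}

new_clonal_phylogeny <- function(nodes, branch_of, config,
                                 trunk_mutation_count) {
  n_mut <- length(branch_of)
  sites <- sample_sites(n_mut, config$genome)
  mutations <- data.frame(
    id = sprintf("m%05d", seq_len(n_mut)),
    branch = branch_of,
    sites,
    stringsAsFactors = FALSE
  )
  tree <- structure(
    list(
      nodes = nodes,
      mutations = mutations,
      mode = config$mode,
      trunk_mutation_count = as.integer(trunk_mutation_count),
      purity = config$purity,
      config = config
    ),
    class = "clonal_phylogeny"
  )
  validate_clonal_phylogeny(tree)
  tree
}

validate_clonal_phylogeny <- function(tree) {
  nodes <- tree$nodes
  if (sum(is.na(nodes$parent)) != 1L) stop("tree must have exactly one root")
  frac <- nodes$fraction[nodes$leaf]
  if (abs(sum(frac) - 1) > 1e-9) stop("clone fractions must sum to 1")
  if (!all(tree$mutations$branch %in% nodes$id)) {
    stop("mutation assigned to unknown branch")
  }
  invisible(tree)
}

#' @export
print.clonal_phylogeny <- function(x, ...) {
  cat(sprintf(
    "<clonal_phylogeny> %s mode: %d clones, trunk %d mutations, %d mutations total\n",
    x$mode, sum(x$nodes$leaf), x$trunk_mutation_count, nrow(x$mutations)
  ))
  invisible(x)
}

# ---- accessors ------------------------------------------------------------

# node ids on the path root -> node (inclusive)
node_path <- function(tree, node) {
  path <- integer(0)
  while (!is.na(node)) {
    path <- c(node, path)
    node <- tree$nodes$parent[match(node, tree$nodes$id)]
  }
  path
}

# leaf ids below each node (list indexed by node id)
descendant_leaves <- function(tree) {
  nodes <- tree$nodes
  out <- vector("list", nrow(nodes))
  ord <- rev(topo_order(nodes))
  for (id in ord) {
    i <- match(id, nodes$id)
    if (nodes$leaf[i]) {
      out[[id]] <- id
    } else {
      kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
      out[[id]] <- unlist(out[kids])
    }
  }
  out
}

topo_order <- function(nodes) {
  ord <- integer(0)
  queue <- nodes$id[is.na(nodes$parent)]
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    ord <- c(ord, id)
    queue <- c(queue, nodes$id[!is.na(nodes$parent) & nodes$parent == id])
  }
  ord
}

#' Mutation sets and ground-truth summaries of a simulated phylogeny
#'
#' `clone_mutations()` lists the mutation ids carried by one clone (leaf);
#' `carrier_fractions()` gives, for every mutation, the fraction of tumour
#' cells carrying it; `true_per_cell_burden()` is the clone-fraction-weighted
#' mean root-to-leaf path length (the quantity duplex sequencing estimates).
#'
#' @param tree a `clonal_phylogeny`.
#' @param clone clone label, e.g. `"C1"`.
#' @name phylogeny-truth
NULL

#' @rdname phylogeny-truth
#' @export
clone_mutations <- function(tree, clone) {
  leaf_id <- tree$nodes$id[!is.na(tree$nodes$clone) &
                             tree$nodes$clone == clone]
  if (!length(leaf_id)) stop("unknown clone: ", clone)
  path <- node_path(tree, leaf_id)
  tree$mutations$id[tree$mutations$branch %in% path]
}

#' @rdname phylogeny-truth
#' @export
carrier_fractions <- function(tree) {
  dl <- descendant_leaves(tree)
  leaf_frac <- numeric(max(tree$nodes$id))
  leaf_frac[tree$nodes$id[tree$nodes$leaf]] <-
    tree$nodes$fraction[tree$nodes$leaf]
  branch_frac <- vapply(seq_along(dl), function(id) {
    if (is.null(dl[[id]])) 0 else sum(leaf_frac[dl[[id]]])
  }, numeric(1))
  stats::setNames(branch_frac[tree$mutations$branch], tree$mutations$id)
}

#' @rdname phylogeny-truth
#' @export
true_per_cell_burden <- function(tree) {
  sum(carrier_fractions(tree))
}
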