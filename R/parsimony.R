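#' Genotype matrix over clonal units
#'
#' @param presence binary matrix (clonal unit x mutation): 1 if the unit
#'   carries the mutation under the confidence criteria that produced it.
#' @param depth,mut optional integer matrices of the underlying per-unit
#'   read counts (same shape), used by the maximum-likelihood assignment.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(presence, depth = NULL, mut = NULL) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence))) {
    rownames(presence) <- sprintf("U%02d", seq_len(nrow(presence)))
  }
  if (!all(presence %in% c(0, 1))) stop("presence matrix must be binary")
  structure(list(presence = presence, depth = depth, mut = mut),
            class = "genotype_matrix")
}

#' Build a maximum-parsimony tree of clonal units
#'
#' Finds a rooted tree over the clonal units minimising the number of
#' character changes of the binary presence characters, rooted by a
#' zero-mutation outgroup (`"normal"`) representing the matched normal
#' genome. For up to `exhaustive_max` units the search enumerates every
#' rooted binary topology and is exact; beyond that, a greedy
#' perfect-phylogeny construction over compatible characters is refined by
#' leaf-regrafting hill climbing. Ties are broken deterministically by the
#' enumeration order induced by the unit order (lexicographic input
#' order).
#'
#' Identical mutation patterns are collapsed into weighted characters, so
#' the search scales with the number of distinct patterns, not mutations.
#'
#' @param matrix a [genotype_matrix()] with at least 2 units.
#' @param exhaustive_max maximum unit count for exhaustive search
#'   (default 8).
#' @return an object of class `mutation_tree`; see [scale_branches()] and
#'   [assign_mutations_ml()] for branch lengths.
#' @export
build_parsimony_tree <- function(matrix, exhaustive_max = 8L) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  pres <- matrix$presence
  k <- nrow(pres)
  if (k < 2) stop("at least 2 clonal units are required")

  # collapse identical characters
  pat_key <- apply(pres, 2, paste, collapse = "")
  keep <- !duplicated(pat_key)
  pats <- pres[, keep, drop = FALSE]
  w <- as.vector(table(factor(pat_key, levels = pat_key[keep])))

  if (k <= exhaustive_max) {
    topos <- rooted_topologies(k)
    best <- NULL; best_score <- Inf
    for (t in topos) {
      s <- sankoff_score(t, pats, w)
      if (s < best_score) { best_score <- s; best <- t }
    }
    tree <- nested_to_tree(best, rownames(pres))
  } else {
    tree <- greedy_perfect_phylogeny(pats, w, rownames(pres))
    tree <- regraft_hill_climb(tree, pats, w)
    best_score <- tree_score(tree, pats, w)
  }
  tree$parsimony_score <- best_score
  tree
}

# all rooted binary topologies over k leaves, as nested pair lists
# (memoised: 10395 topologies at k = 7, 135135 at k = 8)
.topo_cache <- new.env(parent = emptyenv())
rooted_topologies <- function(k) {
  key <- as.character(k)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  if (k == 1) return(list(1L))
  trees <- list(list(1L, 2L))
  if (k > 2) {
    for (leaf in 3:k) {
      trees <- unlist(lapply(trees, insert_leaf_everywhere, leaf = leaf),
                      recursive = FALSE)
    }
  }
  .topo_cache[[key]] <- trees
  trees
}

insert_leaf_everywhere <- function(t, leaf) {
  out <- list(list(t, leaf))  # attach above t
  if (is.list(t)) {
    for (tl in insert_leaf_everywhere(t[[1]], leaf)) {
      out <- c(out, list(list(tl, t[[2]])))
    }
    for (tr in insert_leaf_everywhere(t[[2]], leaf)) {
      out <- c(out, list(list(t[[1]], tr)))
    }
  }
  out
}

BIG <- 1e9

# weighted small-parsimony score of a nested topology with the root edge
# leading to an all-absent outgroup; pats is unit x pattern binary matrix
sankoff_score <- function(t, pats, w) {
  rec <- function(node) {
    if (!is.list(node)) {
      s <- pats[node, ]
      return(rbind(ifelse(s == 0, 0, BIG), ifelse(s == 1, 0, BIG)))
    }
    a <- rec(node[[1]]); b <- rec(node[[2]])
    c0 <- pmin(a[1, ], a[2, ] + 1) + pmin(b[1, ], b[2, ] + 1)
    c1 <- pmin(a[2, ], a[1, ] + 1) + pmin(b[2, ], b[1, ] + 1)
    rbind(c0, c1)
  }
  cost <- rec(t)
  # outgroup forces ancestral state 0 above the root
  sum(w * pmin(cost[1, ], cost[2, ] + 1))
}

# convert a nested topology over leaf indices to a mutation_tree with a
# "normal" outgroup root above the in-group root
nested_to_tree <- function(t, unit_names) {
  parent <- integer(0); label <- character(0); leaf <- logical(0)
  add <- function(p, lab, is_leaf) {
    parent[length(parent) + 1L] <<- p
    label[length(label) + 1L] <<- lab
    leaf[length(leaf) + 1L] <<- is_leaf
    length(parent)
  }
  root <- add(NA_integer_, "normal", FALSE)
  build <- function(node, p) {
    if (!is.list(node)) {
      add(p, unit_names[node], TRUE)
    } else {
      me <- add(p, NA_character_, FALSE)
      build(node[[1]], me)
      build(node[[2]], me)
      me
    }
  }
  build(t, root)
  new_mutation_tree(parent, label, leaf)
}

new_mutation_tree <- function(parent, label, leaf) {
  n <- length(parent)
  structure(
    list(
      parent = parent, label = label, leaf = leaf,
      root = which(is.na(parent)),
      branch_raw = numeric(n), branch_scaled = numeric(n),
      excluded_fraction = 0,
      parsimony_score = NA_real_,
      assignment = NULL
    ),
    class = "mutation_tree"
  )
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf(
    "<mutation_tree> %d clonal units, parsimony score %s, %s mutations assigned\n",
    sum(x$leaf), format(x$parsimony_score),
    if (is.null(x$assignment)) "no" else format(sum(x$assignment$assignable))
  ))
  invisible(x)
}

# descendant leaf labels per node
tree_descendants <- function(tree) {
  n <- length(tree$parent)
  out <- vector("list", n)
  ord <- rev(tree_topo_order(tree))
  children <- tree_children(tree)
  for (id in ord) {
    out[[id]] <- if (tree$leaf[id]) tree$label[id] else {
      unlist(out[children[[id]]])
    }
  }
  out
}

tree_children <- function(tree) {
  n <- length(tree$parent)
  ch <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(tree$parent[i])) {
      ch[[tree$parent[i]]] <- c(ch[[tree$parent[i]]], i)
    }
  }
  ch
}

tree_topo_order <- function(tree) {
  ord <- integer(0)
  queue <- tree$root
  ch <- tree_children(tree)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    ord <- c(ord, id)
    queue <- c(queue, ch[[id]])
  }
  ord
}

# weighted parsimony score of an explicit (possibly multifurcating) tree
tree_score <- function(tree, pats, w) {
  n <- length(tree$parent)
  npat <- ncol(pats)
  c0 <- matrix(0, n, npat); c1 <- matrix(0, n, npat)
  ch <- tree_children(tree)
  for (id in rev(tree_topo_order(tree))) {
    if (tree$leaf[id]) {
      s <- pats[tree$label[id], ]
      c0[id, ] <- ifelse(s == 0, 0, BIG)
      c1[id, ] <- ifelse(s == 1, 0, BIG)
    } else {
      for (kid in ch[[id]]) {
        c0[id, ] <- c0[id, ] + pmin(c0[kid, ], c1[kid, ] + 1)
        c1[id, ] <- c1[id, ] + pmin(c1[kid, ], c0[kid, ] + 1)
      }
    }
  }
  # root is the normal outgroup: state 0
  sum(w * pmin(c0[tree$root, ], c1[tree$root, ] + 1))
}

# laminar-family construction: accept characters (clades) in decreasing
# weight then size if nested-or-disjoint with everything accepted
greedy_perfect_phylogeny <- function(pats, w, unit_names) {
  k <- length(unit_names)
  clades <- lapply(seq_len(ncol(pats)), function(j) which(pats[, j] == 1))
  sizes <- vapply(clades, length, integer(1))
  informative <- sizes > 1 & sizes < k
  ord <- order(-w * informative, -sizes)
  accepted <- list(seq_len(k))
  for (j in ord) {
    if (!informative[j]) next
    cl <- clades[[j]]
    ok <- all(vapply(accepted, function(a) {
      length(intersect(a, cl)) == 0 || all(cl %in% a) || all(a %in% cl)
    }, logical(1)))
    dup <- any(vapply(accepted, function(a) identical(sort(a), sort(cl)),
                      logical(1)))
    if (ok && !dup) accepted <- c(accepted, list(sort(cl)))
  }
  # build the tree: each clade's parent is the smallest strict superset
  parent <- NA_integer_; label <- "normal"; leaf <- FALSE
  node_of_clade <- integer(length(accepted))
  ord2 <- order(vapply(accepted, length, integer(1)), decreasing = TRUE)
  for (idx in ord2) {
    cl <- accepted[[idx]]
    supers <- which(vapply(accepted, function(a) {
      length(a) > length(cl) && all(cl %in% a)
    }, logical(1)))
    p <- if (!length(supers)) 1L else {
      best <- supers[which.min(vapply(accepted[supers], length, integer(1)))]
      node_of_clade[best]
    }
    parent <- c(parent, p); label <- c(label, NA_character_)
    leaf <- c(leaf, FALSE)
    node_of_clade[idx] <- length(parent)
  }
  for (u in seq_len(k)) {
    containing <- which(vapply(accepted, function(a) u %in% a, logical(1)))
    best <- containing[which.min(vapply(accepted[containing], length,
                                        integer(1)))]
    parent <- c(parent, node_of_clade[best])
    label <- c(label, unit_names[u]); leaf <- c(leaf, TRUE)
  }
  new_mutation_tree(parent, label, leaf)
}

# hill climbing: try re-grafting each unit leaf onto every other node,
# keep any strict improvement, repeat to convergence
regraft_hill_climb <- function(tree, pats, w, max_sweeps = 5L) {
  score <- tree_score(tree, pats, w)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    leaves <- which(tree$leaf)
    for (lf in leaves) {
      targets <- setdiff(which(!tree$leaf), tree$parent[lf])
      for (tg in targets) {
        cand <- tree
        cand$parent[lf] <- tg
        if (!tree_is_valid(cand)) next
        s <- tree_score(cand, pats, w)
        if (s < score) { tree <- cand; score <- s; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  tree
}

tree_is_valid <- function(tree) {
  # acyclic with a single root
  n <- length(tree$parent)
  seen_root <- 0L
  for (i in seq_len(n)) {
    steps <- 0L; node <- i
    while (!is.na(tree$parent[node])) {
      node <- tree$parent[node]
      steps <- steps + 1L
      if (steps > n) return(FALSE)
    }
    if (node == i) seen_root <- seen_root + 1L
  }
  seen_root == 1L
}
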