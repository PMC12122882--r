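# fixture builders and independent oracles shared across tests

# variant_table from plain count matrices (records x samples)
make_table <- function(depth, mut_fwd, mut_rev, mas = NULL, clip = NULL,
                       sample_class = NULL, matched_normal = NA_character_,
                       origin = NULL) {
  depth <- as.matrix(depth)
  n <- nrow(depth)
  if (is.null(colnames(depth))) {
    colnames(depth) <- sprintf("S%02d", seq_len(ncol(depth)))
  }
  fix_dim <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- dimnames(depth)
    m
  }
  variants <- data.frame(
    chrom = rep("chr1", n), pos = seq_len(n) * 1000L,
    ref = rep("A", n), alt = rep("T", n), id = sprintf("v%05d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  if (!is.null(origin)) variants$origin <- origin
  variant_table(
    variants = variants,
    depth = depth, mut_fwd = fix_dim(mut_fwd), mut_rev = fix_dim(mut_rev),
    mas = if (is.null(mas)) NULL else fix_dim(mas),
    clip = if (is.null(clip)) NULL else fix_dim(clip),
    sample_class = sample_class, matched_normal = matched_normal
  )
}

vt_empty <- function() {
  make_table(depth = matrix(integer(0), 0, 1),
             mut_fwd = matrix(integer(0), 0, 1),
             mut_rev = matrix(integer(0), 0, 1))
}

# a single duplex bundle for consensus_call; defaults satisfy every rule
make_bundle <- function(n1 = 2L, n2 = 2L, base1 = "T", base2 = "T",
                        ref = "A", qual = 30L, offset = 20L,
                        mismatches = 1L, margin = 60L) {
  k <- n1 + n2
  list(
    ref = ref,
    reads = data.frame(
      strand = c(rep(1L, n1), rep(2L, n2)),
      base = c(rep(base1, length.out = n1), rep(base2, length.out = n2)),
      qual = rep(qual, length.out = k),
      offset = rep(offset, length.out = k),
      mismatches = rep(mismatches, length.out = k),
      margin = rep(margin, length.out = k),
      stringsAsFactors = FALSE
    )
  )
}

# brute-force enumeration: two-sided exact binomial p-value (sum of
# outcome probabilities no larger than the observed one)
enum_binom_two_sided <- function(x, n, p = 0.5) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# brute-force enumeration: one-sided exact two-proportion p-value
# (hypergeometric tail conditional on the margins)
enum_prop_greater <- function(tm, td, nm, nd) {
  k_total <- tm + nm
  sum(stats::dhyper(tm:min(td, k_total), k_total, td + nd - k_total, td))
}

# hand-built mutation_tree: star over `labels` with given trunk and
# per-leaf private branch lengths
make_star_tree <- function(labels, trunk, private) {
  k <- length(labels)
  parent <- c(NA_integer_, 1L, rep(2L, k))
  label <- c("normal", NA, labels)
  leaf <- c(FALSE, FALSE, rep(TRUE, k))
  tr <- clonarch:::new_mutation_tree(parent, label, leaf)
  tr$branch_raw <- c(0, trunk, rep(private, length.out = k))
  tr$branch_scaled <- tr$branch_raw
  tr
}
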