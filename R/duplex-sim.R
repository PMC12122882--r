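#' Simulate duplex (single-molecule) read bundles
#'
#' Emulates NanoSeq-style duplex sequencing of a polyclonal tissue. Each
#' interrogated bundle-base originates from one original DNA duplex of one
#' cell drawn by clone fraction; a bundle covering a site mutated in that
#' cell carries the variant on both strands, and sequencing errors are
#' injected per read independently. Bundle metadata (reads per strand,
#' consensus base qualities, offsets from the nearer read end,
#' per-read mismatch counts, alignment-score margins) are drawn from
#' configurable clean/noisy mixtures so that every downstream consensus
#' filter can fire.
#'
#' Bundle-bases carrying a true mutation (plus any double-strand-consistent
#' error events) are materialised read-by-read; the vastly more numerous
#' clean reference bundle-bases are accounted in aggregate with exact
#' binomial draws of how many pass the interrogation filters, which is
#' distributionally identical to materialising them. Set
#' `explicit_background = TRUE` (small `interrogated_bases` only) to
#' materialise every bundle read-by-read, e.g. to measure false-positive
#' rates empirically.
#'
#' @param tree a `clonal_phylogeny`.
#' @param interrogated_bases number of duplex bundle-bases sequenced (>= 1).
#' @param error_rate per-read per-base error probability (`0 <= e < 0.1`).
#' @param seed integer random seed.
#' @param reads_per_strand reads sequenced from each strand of a duplex.
#' @param meta list of metadata-distribution knobs:
#'   `p_incomplete` (one strand under-read), `p_low_qual` (a read's
#'   consensus quality below 6), `p_low_margin` (alignment-score margin
#'   <= 50), `mismatch_mean` (Poisson mean of non-focal mismatches per
#'   read), `read_length` (bp; offsets are uniform over half the read).
#'   Use [duplex_meta_clean()] for noise-free metadata.
#' @param explicit_background materialise reference bundle-bases
#'   read-by-read (memory-bound; refuse above 2e6 bases).
#' @return an object of class `duplex_bundle_set`: list with `bundles`
#'   (one row per materialised bundle-base: site, `true_alt`, strand read
#'   counts), `reads` (one row per read: `bundle_id`, `strand`, `base`,
#'   `qual`, `offset`, `mismatches`, `margin`), `n_background` and
#'   `n_background_interrogated` (aggregate clean reference bundle-bases),
#'   and the generating parameters.
#' @export
simulate_duplex_bundles <- function(tree, interrogated_bases,
                                    error_rate = 1e-3, seed = 1L,
                                    reads_per_strand = 2L,
                                    meta = duplex_meta_default(),
                                    explicit_background = FALSE) {
  stopifnot(inherits(tree, "clonal_phylogeny"))
  if (interrogated_bases < 1) stop("interrogated_bases must be >= 1")
  if (error_rate < 0 || error_rate >= 0.1) {
    stop("error_rate must lie in [0, 0.1)")
  }
  set.seed(seed)
  N <- interrogated_bases
  G <- tree$config$genome$diploid_size

  cf <- carrier_fractions(tree)
  muts <- tree$mutations

  # how many bundle-bases land on each mutated site in a carrier cell
  n_cov <- stats::rbinom(length(cf), size = N, prob = pmin(cf / G, 1))
  covered <- rep(seq_along(cf), n_cov)

  bundles <- data.frame(
    bundle_id = integer(0), chrom = character(0), pos = integer(0),
    ref = character(0), true_alt = character(0), stringsAsFactors = FALSE
  )
  if (length(covered)) {
    bundles <- data.frame(
      bundle_id = seq_along(covered),
      chrom = muts$chrom[covered], pos = muts$pos[covered],
      ref = muts$ref[covered], true_alt = muts$alt[covered],
      stringsAsFactors = FALSE
    )
  }

  n_mut_cov <- nrow(bundles)
  n_bg <- N - n_mut_cov

  p_int <- interrogation_pass_prob(meta, reads_per_strand)

  if (explicit_background) {
    if (n_bg > 2e6) stop("explicit background limited to 2e6 bundle-bases")
    if (n_bg > 0) {
      bg <- data.frame(
        bundle_id = n_mut_cov + seq_len(n_bg),
        chrom = "chrB", pos = seq_len(n_bg),
        ref = sample(c("A", "C", "G", "T"), n_bg, replace = TRUE),
        true_alt = NA_character_, stringsAsFactors = FALSE
      )
      bundles <- rbind(bundles, bg)
    }
    n_background <- 0L
    n_background_interrogated <- 0L
    n_fp <- 0L
  } else {
    n_background <- n_bg
    n_background_interrogated <- stats::rbinom(1L, n_bg, p_int)
    # double-strand-consistent error events among interrogated background:
    # all reads of both strands must show the same specific alternative base
    p_fp <- 3 * (error_rate / 3)^(2 * reads_per_strand)
    n_fp <- stats::rbinom(1L, n_background_interrogated, p_fp)
  }

  reads <- simulate_bundle_reads(bundles, error_rate, reads_per_strand, meta)

  if (!explicit_background && n_fp > 0) {
    # materialise the double-strand error events; they arise conditional on
    # having passed the interrogation filters, so metadata is clean and the
    # same wrong base is written on every read of both strands
    n_background_interrogated <- n_background_interrogated - n_fp
    n_background <- n_background - n_fp
    bases <- c("A", "C", "G", "T")
    fp_ref <- sample(bases, n_fp, replace = TRUE)
    fp <- data.frame(
      bundle_id = n_mut_cov + seq_len(n_fp),
      chrom = "chrE", pos = seq_len(n_fp),
      ref = fp_ref, true_alt = NA_character_, stringsAsFactors = FALSE
    )
    fp_reads <- simulate_bundle_reads(fp, 0, reads_per_strand,
                                      duplex_meta_clean())
    fp_alt <- vapply(fp_ref, function(r) sample(setdiff(bases, r), 1L),
                     character(1))
    fp_reads$base <- rep(fp_alt, each = 2L * reads_per_strand)
    fp_reads$offset <- pmax(fp_reads$offset, 8L)
    bundles <- rbind(bundles, fp)
    reads <- rbind(reads, fp_reads)
  }

  structure(
    list(
      bundles = bundles,
      reads = reads,
      n_background = n_background,
      n_background_interrogated = n_background_interrogated,
      interrogated_bases = N,
      error_rate = error_rate,
      reads_per_strand = reads_per_strand,
      meta = meta,
      genome_size = G
    ),
    class = "duplex_bundle_set"
  )
}

#' Duplex metadata distributions
#'
#' `duplex_meta_default()` gives mildly noisy metadata so that every
#' consensus filter fires occasionally; `duplex_meta_clean()` gives
#' metadata that always passes the completeness, quality, margin and
#' mismatch filters (read-end offsets still span the read, since trimming
#' is part of interrogation accounting, not an error mode).
#' @return a named list of metadata knobs (see [simulate_duplex_bundles()]).
#' @export
duplex_meta_default <- function() {
  list(p_incomplete = 0.02, p_low_qual = 0.001, p_low_margin = 0.02,
       mismatch_mean = 0.3, read_length = 150L)
}

#' @rdname duplex_meta_default
#' @export
duplex_meta_clean <- function() {
  list(p_incomplete = 0, p_low_qual = 0, p_low_margin = 0,
       mismatch_mean = 0, read_length = 150L)
}

# P(a bundle-base passes all non-variant-dependent filters)
interrogation_pass_prob <- function(meta, reads_per_strand) {
  n_reads <- 2L * reads_per_strand
  p_margin <- (1 - meta$p_low_margin)^n_reads
  p_mm <- stats::ppois(2, meta$mismatch_mean)^n_reads
  half <- floor(meta$read_length / 2)
  p_offset <- (half + 1 - 8) / (half + 1)  # offset uniform on 0..half, >= 8
  (1 - meta$p_incomplete) * p_margin * p_mm * p_offset
}

# materialise reads for a set of bundle-bases
simulate_bundle_reads <- function(bundles, error_rate, reads_per_strand,
                                  meta) {
  n <- nrow(bundles)
  if (n == 0) {
    return(data.frame(bundle_id = integer(0), strand = integer(0),
                      base = character(0), qual = integer(0),
                      offset = integer(0), mismatches = integer(0),
                      margin = integer(0), stringsAsFactors = FALSE))
  }
  incomplete <- stats::runif(n) < meta$p_incomplete
  n_reads_b <- ifelse(incomplete, reads_per_strand + 1L, 2L * reads_per_strand)
  bundle_id <- rep(bundles$bundle_id, n_reads_b)
  # incomplete bundles have only 1 read on strand 2
  strand <- unlist(lapply(n_reads_b, function(k) {
    if (k == 2L * reads_per_strand) rep(1:2, each = reads_per_strand)
    else c(rep(1L, reads_per_strand), 2L)
  }))
  total <- length(bundle_id)
  truth <- rep(ifelse(is.na(bundles$true_alt), bundles$ref, bundles$true_alt),
               n_reads_b)
  base <- truth
  err <- stats::runif(total) < error_rate
  if (any(err)) {
    bases <- c("A", "C", "G", "T")
    base[err] <- vapply(which(err), function(i) {
      sample(setdiff(bases, truth[i]), 1L)
    }, character(1))
  }
  qual <- ifelse(stats::runif(total) < meta$p_low_qual,
                 sample(2:5, total, replace = TRUE),
                 sample(25:40, total, replace = TRUE))
  half <- floor(meta$read_length / 2)
  # all reads of a bundle cover the same molecule position
  offset_b <- sample(0:half, n, replace = TRUE)
  offset <- rep(offset_b, n_reads_b)
  mismatches <- stats::rpois(total, meta$mismatch_mean)
  margin <- ifelse(stats::runif(total) < meta$p_low_margin,
                   sample(0:50, total, replace = TRUE),
                   sample(51:200, total, replace = TRUE))
  data.frame(bundle_id = bundle_id, strand = strand, base = base,
             qual = as.integer(qual), offset = as.integer(offset),
             mismatches = as.integer(mismatches),
             margin = as.integer(margin), stringsAsFactors = FALSE)
}

#' @export
print.duplex_bundle_set <- function(x, ...) {
  cat(sprintf(
    "<duplex_bundle_set> %.3g interrogated bundle-bases (%d materialised, %.3g aggregate background)\n",
    x$interrogated_bases, nrow(x$bundles), x$n_background
  ))
  invisible(x)
}
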