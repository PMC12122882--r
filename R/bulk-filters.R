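#' Mapping-quality post-processing filter
#'
#' Removes mis-mapping artefacts: a record is kept iff the median alignment
#' score of its supporting reads is >= 140 and fewer than half of those
#' reads are clipped. The record-level statistics are aggregated over the
#' samples that carry mutant reads (median score; mutant-read-weighted mean
#' clipped fraction). Removal counts are logged in the table's
#' `filter_log`, and removed records are stashed for possible rescue.
#'
#' @param table a [variant_table()] carrying `mas`/`clip` annotations.
#' @param min_mas minimum median alignment score (default 140).
#' @param max_clip maximum clipped fraction, exclusive (default 0.5).
#' @return the filtered `variant_table`.
#' @export
qc_filter <- function(table, min_mas = 140, max_clip = 0.5) {
  stopifnot(inherits(table, "variant_table"))
  if (is.null(table$mas) || is.null(table$clip)) {
    stop("missing alignment-score/clipping annotations")
  }
  n <- nrow(table$variants)
  if (n == 0) return(table)
  m <- mutant_reads(table)
  supp <- m > 0
  rec_mas <- vapply(seq_len(n), function(i) {
    j <- supp[i, ]
    if (!any(j)) return(Inf)  # no supporting reads anywhere: nothing to test
    stats::median(table$mas[i, j])
  }, numeric(1))
  rec_clip <- vapply(seq_len(n), function(i) {
    j <- supp[i, ]
    if (!any(j)) return(0)
    sum(table$clip[i, j] * m[i, j]) / sum(m[i, j])
  }, numeric(1))
  keep <- rec_mas >= min_mas & rec_clip < max_clip
  vt_subset(table, keep, "qc_mapping")
}

#' Organoid in-vitro mutation filter
#'
#' Single-cell-derived organoids accumulate mutations in culture; those
#' appear subclonal in the organoid's sequencing. Only mutations with a
#' variant allele fraction strictly greater than `min_vaf` (default 0.3)
#' in at least one organoid sample are kept.
#'
#' @param table a `variant_table` whose samples include organoids.
#' @param min_vaf VAF threshold (strict, default 0.3).
#' @return the filtered `variant_table`.
#' @export
organoid_vaf_filter <- function(table, min_vaf = 0.3) {
  stopifnot(inherits(table, "variant_table"))
  org <- names(table$sample_class)[table$sample_class == "organoid"]
  if (!length(org)) stop("wrong sample class: no organoid samples in table")
  v <- vaf(table)[, org, drop = FALSE]
  v[is.nan(v)] <- 0
  keep <- apply(v, 1, max) > min_vaf
  vt_subset(table, keep, "organoid_vaf")
}

#' Downsample read counts to a reference depth
#'
#' Per record and sample, reads are subsampled without replacement
#' (hypergeometrically) down to `target_depth`, drawing first the mutant
#' total and then its forward-strand part, so strand counts remain
#' consistent. Sites already at or below the target are untouched; if the
#' table's mean depth is below the target the table is returned unchanged
#' with a warning.
#'
#' @param table a `variant_table`.
#' @param target_depth reference depth (default 30).
#' @param seed integer random seed.
#' @return the downsampled `variant_table`.
#' @export
downsample_to_depth <- function(table, target_depth = 30, seed = 1L) {
  stopifnot(inherits(table, "variant_table"))
  if (target_depth <= 0) stop("target depth must be positive")
  if (nrow(table$variants) == 0) return(table)
  if (mean(table$depth) < target_depth) {
    warning("mean depth below target; table returned unchanged")
    return(table)
  }
  set.seed(seed)
  dp <- table$depth; m <- mutant_reads(table); mf <- table$mut_fwd
  over <- which(dp > target_depth)
  if (length(over)) {
    new_m <- stats::rhyper(length(over), m[over], dp[over] - m[over],
                           target_depth)
    new_mf <- ifelse(m[over] > 0,
                     stats::rhyper(length(over), mf[over],
                                   m[over] - mf[over], new_m),
                     0L)
    table$depth[over] <- target_depth
    table$mut_fwd[over] <- as.integer(new_mf)
    table$mut_rev[over] <- as.integer(new_m - new_mf)
  }
  table
}

#' Bulk substitution burden
#'
#' The bulk burden of a sample is the number of substitution records called
#' in it after filtering. Because published probabilistic callers are not
#' re-run here, a transparent detection rule stands in for the caller: a
#' record is called in a sample iff it has at least `min_mut` mutant reads
#' with support on both the forward and reverse strand (the same
#' confidence criteria used for phylogeny construction, minus the VAF
#' cut). Under a comb-like architecture this count captures the trunk and
#' any detectable subclones, and understates the per-cell burden — the
#' artefact this package quantifies.
#'
#' @param table a filtered `variant_table`.
#' @param sample sample name; defaults to the single (or first non-normal)
#'   sample.
#' @param min_mut minimum mutant reads (default 4).
#' @param both_strands require forward and reverse support (default TRUE).
#' @return a [burden_estimate()] with method `"bulk"`.
#' @export
bulk_burden <- function(table, sample = NULL, min_mut = 4L,
                        both_strands = TRUE) {
  stopifnot(inherits(table, "variant_table"))
  if (is.null(sample)) {
    cand <- table$samples[table$samples != table$matched_normal |
                            is.na(table$matched_normal)]
    sample <- cand[1]
  }
  if (nrow(table$variants) == 0) {
    return(burden_estimate(0, "bulk", 0L, 0L))
  }
  called <- bulk_called(table, sample, min_mut, both_strands)
  burden_estimate(
    burden = sum(called), method = "bulk", calls = sum(called),
    interrogated = nrow(table$variants)
  )
}

# per-record detection indicator for one sample
bulk_called <- function(table, sample, min_mut = 4L, both_strands = TRUE) {
  mf <- table$mut_fwd[, sample]
  mr <- table$mut_rev[, sample]
  ok <- (mf + mr) >= min_mut
  if (both_strands) ok <- ok & mf > 0 & mr > 0
  ok
}
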