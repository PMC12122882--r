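#' Germline removal that spares embryonic mosaic variants
#'
#' A record is removed iff (a) its matched-normal counts are consistent
#' with clonal heterozygosity — a two-sided exact binomial test of the
#' normal mutant count against success probability 0.5 is *not* rejected at
#' `alpha_clonal` — and (b) it is not significantly enriched in the tumour
#' samples relative to the normal — a one-sided exact (Fisher) test of the
#' pooled tumour mutant/reference counts against the normal's counts, at
#' `alpha_enrich`. The two-sample exact test is used because the normal VAF
#' is itself a noisy estimate at typical depth; testing pooled tumour reads
#' against the point estimate would call half the genuine germline variants
#' "enriched". Embryonic mosaic variants (low VAF in the normal, high in
#' the tumour) fail (a), and are retained by design.
#'
#' @param table a `variant_table` containing the matched normal sample.
#' @param matched_normal normal sample name; defaults to the table's.
#' @param alpha_clonal significance for the clonal-in-normal test
#'   (default 0.01).
#' @param alpha_enrich significance for the tumour-enrichment test
#'   (default 0.001).
#' @return the filtered `variant_table`.
#' @export
filter_germline <- function(table, matched_normal = NULL,
                            alpha_clonal = 0.01, alpha_enrich = 0.001) {
  stopifnot(inherits(table, "variant_table"))
  if (is.null(matched_normal)) matched_normal <- table$matched_normal
  if (is.na(matched_normal) || !matched_normal %in% table$samples) {
    stop("matched normal sample missing from table")
  }
  n <- nrow(table$variants)
  if (n == 0) return(table)
  tum <- setdiff(table$samples, matched_normal)
  m <- mutant_reads(table)
  nm <- m[, matched_normal]; nd <- table$depth[, matched_normal]
  tm <- rowSums(m[, tum, drop = FALSE])
  td <- rowSums(table$depth[, tum, drop = FALSE])

  p_clonal <- vapply(seq_len(n), function(i) {
    if (nd[i] == 0) return(1)
    stats::binom.test(nm[i], nd[i], 0.5)$p.value
  }, numeric(1))
  clonal_ok <- p_clonal >= alpha_clonal
  # one-sided exact two-proportion test: tumour VAF > normal VAF
  # (only needed where the normal looks clonal)
  p_enrich <- rep(1, n)
  for (i in which(clonal_ok)) {
    p_enrich[i] <- stats::fisher.test(
      matrix(c(tm[i], td[i] - tm[i], nm[i], nd[i] - nm[i]), 2),
      alternative = "greater"
    )$p.value
  }
  germline <- clonal_ok & p_enrich >= alpha_enrich
  vt_subset(table, !germline, "germline")
}

#' Strand-imbalance filter
#'
#' Removes records whose pooled forward/reverse mutant-read split rejects
#' the symmetric null (two-sided exact binomial test against p = 0.5) at
#' `alpha`. Counts too small to be testable (e.g. a single mutant read,
#' p = 1) are retained.
#'
#' @param table a `variant_table` with strand-resolved counts.
#' @param alpha significance threshold (default 0.001).
#' @return the filtered `variant_table`.
#' @export
filter_strand_imbalance <- function(table, alpha = 0.001) {
  stopifnot(inherits(table, "variant_table"))
  n <- nrow(table$variants)
  if (n == 0) return(table)
  tum <- setdiff(table$samples, table$matched_normal)
  if (!length(tum)) tum <- table$samples
  f <- rowSums(table$mut_fwd[, tum, drop = FALSE])
  tot <- f + rowSums(table$mut_rev[, tum, drop = FALSE])
  p <- vapply(seq_len(n), function(i) {
    if (tot[i] == 0) return(1)
    stats::binom.test(f[i], tot[i], 0.5)$p.value
  }, numeric(1))
  vt_subset(table, p >= alpha, "strand_imbalance")
}

#' Per-sample confidence filter
#'
#' Keeps a record iff at least one sample calls it confidently: >= `min_mut`
#' mutant reads, VAF >= `min_vaf`, and mutant reads on both the forward and
#' reverse strand.
#'
#' @param table a `variant_table`.
#' @param min_mut minimum mutant reads (default 4).
#' @param min_vaf minimum VAF (default 0.3, inclusive).
#' @return the filtered `variant_table`.
#' @export
filter_confident_somewhere <- function(table, min_mut = 4L, min_vaf = 0.3) {
  stopifnot(inherits(table, "variant_table"))
  n <- nrow(table$variants)
  if (n == 0) return(table)
  tum <- setdiff(table$samples, table$matched_normal)
  if (!length(tum)) tum <- table$samples
  mf <- table$mut_fwd[, tum, drop = FALSE]
  mr <- table$mut_rev[, tum, drop = FALSE]
  dp <- table$depth[, tum, drop = FALSE]
  m <- mf + mr
  v <- ifelse(dp > 0, m / dp, 0)
  conf <- m >= min_mut & v >= min_vaf & mf > 0 & mr > 0
  vt_subset(table, rowSums(conf) > 0, "confident_somewhere")
}

#' Per-sample copy-number profiles
#'
#' @param segments data.frame with columns `sample`, `chrom`, `start`,
#'   `end` (0-based half-open) and `cn` (total copy number). Segments must
#'   not overlap within a sample and should jointly cover the genome model.
#' @param genome genome model the segments refer to.
#' @return an object of class `cn_profile`.
#' @export
cn_profile <- function(segments, genome = default_genome()) {
  stopifnot(all(c("sample", "chrom", "start", "end", "cn") %in%
                  names(segments)))
  if (any(segments$end <= segments$start)) stop("empty or inverted segment")
  for (s in unique(segments$sample)) {
    for (ch in unique(segments$chrom[segments$sample == s])) {
      seg <- segments[segments$sample == s & segments$chrom == ch, ]
      seg <- seg[order(seg$start), ]
      if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)])) {
        stop("overlapping segments for sample ", s, " on ", ch)
      }
    }
  }
  structure(list(segments = segments, genome = genome), class = "cn_profile")
}

# diploid flat profile for a set of samples
flat_cn_profile <- function(samples, genome = default_genome(), cn = 2L) {
  segments <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample = s, chrom = genome$chrom, start = 0,
               end = genome$length, cn = cn, stringsAsFactors = FALSE)
  }))
  cn_profile(segments, genome)
}

#' Exclude variants in copy-number-discordant regions
#'
#' In `standard` mode a variant is excluded if it falls in a region whose
#' total copy number is not the same across all samples. In
#' `deletion_only` mode (used when nearly the whole genome is discordant,
#' as in heavily rearranged tumours) a variant is excluded only where some
#' sample carries a deletion (copy number below `ploidy`). The genomic
#' fraction excluded is returned so that branch lengths can be rescaled.
#'
#' @param table a `variant_table`.
#' @param profiles a [cn_profile()] covering the genome model for every
#'   sample of interest.
#' @param mode `"standard"` or `"deletion_only"`.
#' @param ploidy baseline ploidy for deletion calling (default 2).
#' @return a list with `table` (filtered) and `excluded_fraction`.
#' @export
exclude_cn_discordant <- function(table, profiles,
                                  mode = c("standard", "deletion_only"),
                                  ploidy = 2L) {
  stopifnot(inherits(table, "variant_table"), inherits(profiles, "cn_profile"))
  mode <- match.arg(mode)
  seg <- profiles$segments
  genome <- profiles$genome
  samples <- unique(seg$sample)

  excluded_len <- 0
  keep <- rep(TRUE, nrow(table$variants))
  for (ci in seq_along(genome$chrom)) {
    ch <- genome$chrom[ci]
    chs <- seg[seg$chrom == ch, ]
    if (nrow(chs) == 0) stop("profile gap: no segments on ", ch)
    # atomic intervals from the union of breakpoints
    brk <- sort(unique(c(0, genome$length[ci], chs$start, chs$end)))
    starts <- brk[-length(brk)]; ends <- brk[-1]
    bad <- vapply(seq_along(starts), function(k) {
      mid <- (starts[k] + ends[k]) / 2
      cn <- vapply(samples, function(s) {
        ss <- chs[chs$sample == s & chs$start <= mid & chs$end > mid, ]
        if (nrow(ss) == 0) stop("profile gap for ", s, " on ", ch)
        ss$cn[1]
      }, numeric(1))
      if (mode == "standard") length(unique(cn)) > 1 else any(cn < ploidy)
    }, logical(1))
    excluded_len <- excluded_len + sum((ends - starts)[bad])
    if (any(bad) && nrow(table$variants)) {
      on_ch <- which(table$variants$chrom == ch)
      if (length(on_ch)) {
        pos0 <- table$variants$pos[on_ch] - 1  # 0-based
        in_bad <- vapply(pos0, function(p) {
          any(starts[bad] <= p & ends[bad] > p)
        }, logical(1))
        keep[on_ch[in_bad]] <- FALSE
      }
    }
  }
  list(
    table = vt_subset(table, keep, "cn_discordant"),
    excluded_fraction = excluded_len / sum(genome$length)
  )
}
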