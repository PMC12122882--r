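#' Duplex consensus calling
#'
#' Applies the single-molecule consensus rules to one read bundle: a
#' variant is called iff the bundle has at least `reads_per_strand` reads
#' from each of the two original strands, every read passes the
#' alignment-score-margin (> 50) and mismatch (<= 2 per read) rules, the
#' call sits at least 8 bp from the nearer read end, both strand consensuses
#' (unanimous within strand) agree on the same non-reference base, and the
#' consensus base quality (the minimum quality over supporting reads, the
#' conservative aggregation) is >= 6.
#'
#' Rejection reasons are reported in a fixed canonical order
#' (`incomplete_bundle`, `alignment_margin`, `mismatch`, `read_end`,
#' `low_quality`); applying the rules in any order changes at most the
#' recorded reason, never the variant/reference/rejected outcome. A
#' bundle-base is *interrogated* iff it passes every
#' non-variant-dependent rule (completeness, margin, mismatch, read-end
#' trim); only interrogated bundle-bases enter the burden denominator.
#'
#' @param bundle a list with elements `ref` (reference base) and `reads`
#'   (data.frame with `strand`, `base`, `qual`, `offset`, `mismatches`,
#'   `margin`), e.g. one bundle extracted from a `duplex_bundle_set`.
#' @param reads_per_strand required reads per strand (default 2).
#' @param min_qual,min_margin,max_mismatches,end_trim filter thresholds.
#' @return a list with `outcome` (`"variant"`, `"reference"` or
#'   `"rejected"`), `reason` (NA unless rejected), `alt` (called base or
#'   NA) and `interrogated` (logical).
#' @export
consensus_call <- function(bundle, reads_per_strand = 2L, min_qual = 6,
                           min_margin = 51, max_mismatches = 2L,
                           end_trim = 8L) {
  r <- bundle$reads
  s1 <- r[r$strand == 1L, , drop = FALSE]
  s2 <- r[r$strand == 2L, , drop = FALSE]

  reject <- function(reason) {
    list(outcome = "rejected", reason = reason, alt = NA_character_,
         interrogated = reason == "low_quality")
  }
  if (nrow(s1) < reads_per_strand || nrow(s2) < reads_per_strand) {
    return(reject("incomplete_bundle"))
  }
  if (any(r$margin < min_margin)) return(reject("alignment_margin"))
  if (any(r$mismatches > max_mismatches)) return(reject("mismatch"))
  if (min(r$offset) < end_trim) return(reject("read_end"))

  cons <- function(x) if (length(unique(x)) == 1L) x[1] else NA_character_
  c1 <- cons(s1$base); c2 <- cons(s2$base)
  if (is.na(c1) || is.na(c2) || c1 != c2 || c1 == bundle$ref) {
    return(list(outcome = "reference", reason = NA_character_,
                alt = NA_character_, interrogated = TRUE))
  }
  if (min(r$qual) < min_qual) return(reject("low_quality"))
  list(outcome = "variant", reason = NA_character_, alt = c1,
       interrogated = TRUE)
}

# vectorised consensus over a whole bundle set; returns a data.frame with
# one row per materialised bundle
consensus_call_set <- function(set, min_qual = 6, min_margin = 51,
                               max_mismatches = 2L, end_trim = 8L) {
  b <- set$bundles
  r <- set$reads
  rps <- set$reads_per_strand
  if (nrow(b) == 0) {
    return(data.frame(bundle_id = integer(0), outcome = character(0),
                      reason = character(0), alt = character(0),
                      interrogated = logical(0), stringsAsFactors = FALSE))
  }
  id <- factor(r$bundle_id, levels = b$bundle_id)
  n1 <- tabulate(id[r$strand == 1L], nbins = nrow(b))
  n2 <- tabulate(id[r$strand == 2L], nbins = nrow(b))
  min_margin_b <- tapply_min(r$margin, id, nrow(b))
  max_mm_b <- -tapply_min(-r$mismatches, id, nrow(b))
  min_off_b <- tapply_min(r$offset, id, nrow(b))
  min_q_b <- tapply_min(r$qual, id, nrow(b))
  # unanimous per-strand consensus base
  cons_base <- function(strand) {
    rr <- r[r$strand == strand, ]
    idf <- factor(rr$bundle_id, levels = b$bundle_id)
    out <- tapply(rr$base, idf, function(x) {
      if (length(unique(x)) == 1L) x[1] else NA_character_
    })
    as.character(out)
  }
  c1 <- cons_base(1L); c2 <- cons_base(2L)

  incomplete <- n1 < rps | n2 < rps
  bad_margin <- min_margin_b < min_margin
  bad_mm <- max_mm_b > max_mismatches
  bad_end <- min_off_b < end_trim
  not_interrogated <- incomplete | bad_margin | bad_mm | bad_end
  agree_alt <- !is.na(c1) & !is.na(c2) & c1 == c2 & c1 != b$ref
  low_q <- agree_alt & min_q_b < min_qual

  outcome <- rep("reference", nrow(b))
  reason <- rep(NA_character_, nrow(b))
  outcome[not_interrogated] <- "rejected"
  reason[bad_end] <- "read_end"
  reason[bad_mm] <- "mismatch"
  reason[bad_margin] <- "alignment_margin"
  reason[incomplete] <- "incomplete_bundle"
  variant <- !not_interrogated & agree_alt & !low_q
  outcome[variant] <- "variant"
  rej_q <- !not_interrogated & low_q
  outcome[rej_q] <- "rejected"
  reason[rej_q] <- "low_quality"

  data.frame(
    bundle_id = b$bundle_id, outcome = outcome, reason = reason,
    alt = ifelse(variant, c1, NA_character_),
    interrogated = !not_interrogated,
    stringsAsFactors = FALSE
  )
}

tapply_min <- function(x, id, n) {
  out <- rep(Inf, n)
  agg <- tapply(x, id, min)
  out[!is.na(agg)] <- agg[!is.na(agg)]
  out
}

#' Burden estimate container
#'
#' @param burden mutations per diploid genome (or a raw call count for the
#'   bulk method).
#' @param method `"bulk"` or `"duplex"`.
#' @param calls number of called variants.
#' @param interrogated interrogated bundle-bases (duplex) or records
#'   examined (bulk).
#' @param genome_size diploid genome size used for scaling.
#' @param adjusted whether a contamination adjustment has been applied.
#' @return an object of class `burden_estimate` with a Poisson (Garwood)
#'   95\% interval on the call count, propagated to the burden scale.
#' @export
burden_estimate <- function(burden, method, calls, interrogated,
                            genome_size = NA_real_, adjusted = FALSE) {
  ci_count <- garwood_interval(calls)
  scale <- if (calls > 0) burden / calls else {
    if (!is.na(genome_size) && interrogated > 0) genome_size / interrogated
    else 1
  }
  structure(
    list(burden = burden, method = method, calls = calls,
         interrogated = interrogated, genome_size = genome_size,
         ci = ci_count * scale, adjusted = adjusted),
    class = "burden_estimate"
  )
}

# exact Poisson 95% interval for a count
garwood_interval <- function(k, conf = 0.95) {
  a <- 1 - conf
  lo <- if (k == 0) 0 else stats::qchisq(a / 2, 2 * k) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * (k + 1)) / 2
  c(lo, hi)
}

#' @export
print.burden_estimate <- function(x, ...) {
  cat(sprintf(
    "<burden_estimate> %.1f mutations per diploid genome (%s%s; %d calls; 95%% CI %.1f-%.1f)\n",
    x$burden, x$method, if (x$adjusted) ", contamination-adjusted" else "",
    x$calls, x$ci[1], x$ci[2]
  ))
  invisible(x)
}

#' Duplex burden per diploid genome
#'
#' The burden is `called variants / interrogated bundle-bases x
#' diploid genome size`, where a bundle-base counts as interrogated iff it
#' passes every non-variant-dependent consensus filter. A Poisson (Garwood)
#' 95\% interval on the variant count is propagated to the burden scale.
#'
#' @param set a `duplex_bundle_set`.
#' @param diploid_genome_size diploid genome size in bases (default the
#'   generating genome model's, 6.2e9 for [default_genome()]).
#' @param ... thresholds passed to the consensus caller.
#' @return a [burden_estimate()] with method `"duplex"`.
#' @export
duplex_burden <- function(set, diploid_genome_size = NULL, ...) {
  stopifnot(inherits(set, "duplex_bundle_set"))
  if (is.null(diploid_genome_size)) diploid_genome_size <- set$genome_size
  res <- consensus_call_set(set, ...)
  calls <- sum(res$outcome == "variant")
  interrogated <- sum(res$interrogated) + set$n_background_interrogated
  if (interrogated == 0) stop("zero interrogated bundle-bases")
  burden_estimate(
    burden = calls / interrogated * diploid_genome_size,
    method = "duplex", calls = calls, interrogated = interrogated,
    genome_size = diploid_genome_size
  )
}

#' Adjust a burden estimate for non-tumour cell contamination
#'
#' Infiltrating immune/stromal cells carry fewer mutations and drag the
#' observed mean down; the tumour-cell burden is recovered as
#' `(observed - fraction * non_tumour_burden) / (1 - fraction)`.
#'
#' @param estimate a [burden_estimate()].
#' @param non_tumour_fraction fraction of non-tumour cells in `[0, 1)`.
#' @param non_tumour_burden per-cell burden of the contaminating cells.
#' @return the adjusted `burden_estimate` (flagged `adjusted`).
#' @export
contamination_adjusted_burden <- function(estimate, non_tumour_fraction,
                                          non_tumour_burden) {
  stopifnot(inherits(estimate, "burden_estimate"))
  if (non_tumour_fraction < 0 || non_tumour_fraction >= 1) {
    stop("non_tumour_fraction must lie in [0, 1)")
  }
  if (non_tumour_fraction == 0) return(estimate)
  f <- non_tumour_fraction
  out <- estimate
  out$burden <- (estimate$burden - f * non_tumour_burden) / (1 - f)
  out$ci <- (estimate$ci - f * non_tumour_burden) / (1 - f)
  out$adjusted <- TRUE
  out
}
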