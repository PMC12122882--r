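#' Multi-sample substitution table
#'
#' The shared container for bulk variant records: one row per substitution
#' (unique chromosome/position/alt key), with per-sample strand-resolved
#' read counts and the QC annotations the post-processing filters use.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` and optionally `id` and `origin` (`somatic`/`germline`/`mosaic`/
#'   `artifact`, used only by simulations as ground truth).
#' @param depth,mut_fwd,mut_rev integer matrices (record x sample): total
#'   depth and mutant reads on the forward/reverse strand.
#' @param mas,clip numeric matrices: median alignment score of supporting
#'   reads and fraction of supporting reads clipped.
#' @param sample_class named character: `"tissue"`, `"organoid"` or
#'   `"normal"` per sample.
#' @param matched_normal name of the matched normal sample, or `NA`.
#' @param calling_mode `"matched"` or `"unmatched"`.
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(variants, depth, mut_fwd, mut_rev,
                          mas = NULL, clip = NULL,
                          sample_class = NULL,
                          matched_normal = NA_character_,
                          calling_mode = c("matched", "unmatched")) {
  calling_mode <- match.arg(calling_mode)
  samples <- colnames(depth)
  if (is.null(samples)) stop("depth matrix must have sample column names")
  if (is.null(variants$id)) {
    variants$id <- sprintf("v%05d", seq_len(nrow(variants)))
  }
  if (is.null(variants$origin)) {
    variants$origin <- rep("somatic", nrow(variants))
  }
  if (is.null(mas)) {
    mas <- matrix(200, nrow(variants), length(samples),
                  dimnames = dimnames(depth))
  }
  if (is.null(clip)) {
    clip <- matrix(0, nrow(variants), length(samples),
                   dimnames = dimnames(depth))
  }
  if (is.null(sample_class)) {
    sample_class <- stats::setNames(rep("tissue", length(samples)), samples)
  }
  vt <- structure(
    list(
      variants = variants,
      samples = samples,
      depth = depth, mut_fwd = mut_fwd, mut_rev = mut_rev,
      mas = mas, clip = clip,
      sample_class = sample_class,
      matched_normal = matched_normal,
      calling_mode = calling_mode,
      filter_log = list(),
      removed = NULL
    ),
    class = "variant_table"
  )
  validate_variant_table(vt)
  vt
}

validate_variant_table <- function(vt) {
  n <- nrow(vt$variants)
  for (m in c("depth", "mut_fwd", "mut_rev", "mas", "clip")) {
    if (nrow(vt[[m]]) != n) stop(m, " matrix does not match variant rows")
  }
  if (any(vt$mut_fwd + vt$mut_rev > vt$depth)) {
    stop("mutant reads exceed depth")
  }
  key <- paste(vt$variants$chrom, vt$variants$pos, vt$variants$alt)
  if (anyDuplicated(key)) stop("duplicate (site, alt) keys")
  invisible(vt)
}

#' Number of records and samples in a variant table
#' @param x a `variant_table`.
#' @export
dim.variant_table <- function(x) c(nrow(x$variants), length(x$samples))

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d records x %d samples (%s calling)\n",
              nrow(x$variants), length(x$samples), x$calling_mode))
  if (length(x$filter_log)) {
    for (nm in names(x$filter_log)) {
      cat(sprintf("  filter %s: removed %d\n", nm, x$filter_log[[nm]]))
    }
  }
  invisible(x)
}

#' Mutant reads and variant allele fractions
#'
#' @param vt a `variant_table`.
#' @return `mutant_reads()`: integer matrix of forward + reverse mutant
#'   reads; `vaf()`: numeric matrix of mutant reads / depth (NaN at zero
#'   depth).
#' @export
mutant_reads <- function(vt) vt$mut_fwd + vt$mut_rev

#' @rdname mutant_reads
#' @export
vaf <- function(vt) {
  v <- mutant_reads(vt) / vt$depth
  v[vt$depth == 0] <- NaN
  v
}

# subset records, stashing removed rows for possible rescue, and logging
vt_subset <- function(vt, keep, filter_name = NULL) {
  keep <- if (is.logical(keep)) which(keep) else keep
  drop <- setdiff(seq_len(nrow(vt$variants)), keep)
  removed <- NULL
  if (length(drop)) {
    removed <- list(
      variants = vt$variants[drop, , drop = FALSE],
      depth = vt$depth[drop, , drop = FALSE],
      mut_fwd = vt$mut_fwd[drop, , drop = FALSE],
      mut_rev = vt$mut_rev[drop, , drop = FALSE],
      mas = vt$mas[drop, , drop = FALSE],
      clip = vt$clip[drop, , drop = FALSE]
    )
  }
  out <- vt
  for (m in c("depth", "mut_fwd", "mut_rev", "mas", "clip")) {
    out[[m]] <- vt[[m]][keep, , drop = FALSE]
  }
  out$variants <- vt$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  if (!is.null(filter_name)) {
    out$filter_log[[filter_name]] <-
      (if (is.null(vt$filter_log[[filter_name]])) 0L
       else vt$filter_log[[filter_name]]) + length(drop)
    if (!is.null(removed)) {
      removed$filter <- filter_name
      out$removed <- c(vt$removed, list(removed))
    }
  }
  out
}
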