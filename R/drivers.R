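#' Cancer gene models for driver annotation
#'
#' Reads a gene-model table: gene symbol, role (`oncogene` or
#' `recessive`), genomic footprint (0-based half-open), an optional
#' comma-separated list of hotspot positions (oncogenes), and an optional
#' regulatory-domain interval. A small synthetic fixture list ships with
#' the package (`system.file("extdata", "driver_genes_synthetic.tsv",
#' package = "clonarch")`); real analyses should supply a curated list.
#'
#' @param path TSV file with columns `gene`, `role`, `chrom`, `start`,
#'   `end`, `hotspots`, `reg_start`, `reg_end` (empty where not
#'   applicable).
#' @return a data.frame of class `gene_models`.
#' @export
read_gene_models <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(all(c("gene", "role", "chrom", "start", "end") %in% names(g)))
  if (!all(g$role %in% c("oncogene", "recessive"))) {
    stop("role must be 'oncogene' or 'recessive'")
  }
  if (any(g$end <= g$start)) stop("invalid gene footprint interval")
  class(g) <- c("gene_models", "data.frame")
  g
}

hotspot_positions <- function(gene_row) {
  if (is.na(gene_row$hotspots) || gene_row$hotspots == "") return(integer(0))
  as.integer(strsplit(gene_row$hotspots, ",")[[1]])
}

new_driver_calls <- function(gene = character(0), event_class = character(0),
                             rule = character(0), detail = character(0)) {
  data.frame(gene = gene, event_class = event_class, rule = rule,
             detail = detail, clonality = rep(NA_character_, length(gene)),
             stringsAsFactors = FALSE)
}

# stable ordering for determinism
sort_calls <- function(calls) {
  calls[order(calls$gene, calls$event_class, calls$detail), , drop = FALSE]
}

#' Annotate small variants as drivers
#'
#' Missense mutations and in-frame indels are drivers iff they hit a
#' canonical hotspot of an oncogene; truncating mutations are drivers iff
#' they disrupt the footprint of a recessive cancer gene. All other
#' consequences are ignored. Variants must arrive with consequence
#' annotations (column `consequence` in the variant data.frame:
#' `missense`, `inframe`, `truncating`, ...).
#'
#' @param variants a `variant_table` or a data.frame with `chrom`, `pos`,
#'   `id` and `consequence`.
#' @param genes a [read_gene_models()] table.
#' @return a data.frame of driver calls (gene, event_class, rule, detail,
#'   clonality), deterministically ordered.
#' @export
annotate_small_variants <- function(variants, genes) {
  v <- if (inherits(variants, "variant_table")) variants$variants else variants
  if (is.null(v$consequence)) stop("variants lack consequence annotations")
  calls <- new_driver_calls()
  if (nrow(v)) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      inside <- v$chrom == g$chrom & v$pos - 1 >= g$start & v$pos - 1 < g$end
      if (g$role == "oncogene") {
        hs <- hotspot_positions(g)
        hit <- inside & v$consequence %in% c("missense", "inframe") &
          v$pos %in% hs
        if (any(hit)) {
          calls <- rbind(calls, new_driver_calls(
            gene = rep(g$gene, sum(hit)),
            event_class = rep("hotspot_missense", sum(hit)),
            rule = rep("oncogene_hotspot", sum(hit)),
            detail = v$id[hit]
          ))
        }
      } else {
        hit <- inside & v$consequence == "truncating"
        if (any(hit)) {
          calls <- rbind(calls, new_driver_calls(
            gene = rep(g$gene, sum(hit)),
            event_class = rep("truncating", sum(hit)),
            rule = rep("recessive_truncating", sum(hit)),
            detail = v$id[hit]
          ))
        }
      }
    }
  }
  sort_calls(calls)
}

#' Rescue recurrently filtered promoter sites
#'
#' Some bona fide driver mutations (e.g. promoter hotspots in simple
#' repeats) systematically fail standard post-processing filters; records
#' previously removed at the listed sites are reinstated with a rescue
#' flag.
#'
#' @param table a filtered `variant_table` (removed records are stashed by
#'   the filters).
#' @param rescue_sites data.frame with `chrom` and `pos` (1-based).
#' @return the `variant_table` with matching records reinstated (flagged
#'   in `variants$rescued`).
#' @export
rescue_promoter_sites <- function(table, rescue_sites) {
  stopifnot(inherits(table, "variant_table"))
  if (is.null(table$variants$rescued)) {
    table$variants$rescued <- rep(FALSE, nrow(table$variants))
  }
  if (is.null(rescue_sites) || nrow(rescue_sites) == 0 ||
      is.null(table$removed)) {
    return(table)
  }
  want <- paste(rescue_sites$chrom, rescue_sites$pos)
  for (blk in table$removed) {
    hit <- paste(blk$variants$chrom, blk$variants$pos) %in% want
    if (!any(hit)) next
    vv <- blk$variants[hit, , drop = FALSE]
    vv$rescued <- TRUE
    for (cc in setdiff(names(table$variants), names(vv))) vv[[cc]] <- NA
    table$variants <- rbind(table$variants, vv[, names(table$variants)])
    for (mname in c("depth", "mut_fwd", "mut_rev", "mas", "clip")) {
      table[[mname]] <- rbind(table[[mname]], blk[[mname]][hit, , drop = FALSE])
    }
  }
  rownames(table$variants) <- NULL
  table
}

#' Annotate copy-number driver events
#'
#' Focal (< 1 Mb) homozygous deletions over recessive genes are drivers;
#' amplifications of oncogenes exceeding the ploidy-dependent threshold
#' (copy number > 4 when diploid, > 8 when tetraploid) are drivers;
#' sub-threshold oncogene amplifications (above ploidy, at or below the
#' threshold) are drivers only when accompanied by significantly elevated
#' RNA expression (z-score >= `z_cutoff`).
#'
#' @param profiles a [cn_profile()].
#' @param genes a [read_gene_models()] table.
#' @param ploidy `"diploid"` or `"tetraploid"`.
#' @param expression_z named numeric vector of per-gene expression
#'   z-scores (missing genes are treated as z = 0).
#' @param z_cutoff z-score required for sub-amplification calls
#'   (default 2).
#' @param focal_max maximum deletion size in bp (default 1e6, exclusive).
#' @return a data.frame of driver calls.
#' @export
annotate_copy_number <- function(profiles, genes,
                                 ploidy = c("diploid", "tetraploid"),
                                 expression_z = NULL, z_cutoff = 2,
                                 focal_max = 1e6) {
  stopifnot(inherits(profiles, "cn_profile"))
  ploidy <- match.arg(ploidy)
  base_cn <- if (ploidy == "diploid") 2 else 4
  amp_thresh <- if (ploidy == "diploid") 4 else 8
  zs <- function(gene) {
    if (is.null(expression_z) || !gene %in% names(expression_z)) 0
    else expression_z[[gene]]
  }
  seg <- profiles$segments
  calls <- new_driver_calls()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    over <- seg[seg$chrom == g$chrom & seg$start < g$end &
                  seg$end > g$start, , drop = FALSE]
    if (!nrow(over)) next
    if (g$role == "recessive") {
      del <- over[over$cn == 0, , drop = FALSE]
      focal <- del[del$end - del$start < focal_max, , drop = FALSE]
      if (nrow(focal)) {
        calls <- rbind(calls, new_driver_calls(
          gene = g$gene, event_class = "homozygous_deletion",
          rule = "focal_homozygous_deletion",
          detail = focal$sample[1]
        ))
      }
    } else {
      amp <- over[over$cn > amp_thresh, , drop = FALSE]
      sub <- over[over$cn > base_cn & over$cn <= amp_thresh, , drop = FALSE]
      if (nrow(amp)) {
        calls <- rbind(calls, new_driver_calls(
          gene = g$gene, event_class = "amplification",
          rule = "amplification_over_threshold",
          detail = amp$sample[1]
        ))
      } else if (nrow(sub) && zs(g$gene) >= z_cutoff) {
        calls <- rbind(calls, new_driver_calls(
          gene = g$gene, event_class = "sub_amplification_with_expression",
          rule = "sub_amplification_expression",
          detail = sub$sample[1]
        ))
      }
    }
  }
  sort_calls(calls)
}

#' Annotate rearrangement driver events
#'
#' Rearrangements are drivers when they generate a whitelisted oncogenic
#' fusion, when a breakpoint disrupts the footprint of a recessive gene,
#' or when they affect the regulatory domain of an oncogene and its RNA
#' expression is elevated (z-score >= `z_cutoff`) — the promoter-swap
#' mechanism by which structurally activated oncogenes are detected.
#'
#' @param breakpoints data.frame with `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (1-based breakpoint coordinates) and optionally `fusion` (a
#'   `"GENEA-GENEB"` label).
#' @param genes a [read_gene_models()] table (with `reg_start`/`reg_end`
#'   for oncogene regulatory domains).
#' @param expression_z named per-gene expression z-scores.
#' @param fusion_whitelist character vector of known oncogenic fusions
#'   (`"GENEA-GENEB"`).
#' @param z_cutoff z-score threshold (default 2).
#' @return a data.frame of driver calls.
#' @export
annotate_rearrangements <- function(breakpoints, genes,
                                    expression_z = NULL,
                                    fusion_whitelist = character(0),
                                    z_cutoff = 2) {
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(breakpoints))) stop("malformed breakpoint table")
  calls <- new_driver_calls()
  if (nrow(breakpoints) == 0) return(calls)
  zs <- function(gene) {
    if (is.null(expression_z) || !gene %in% names(expression_z)) 0
    else expression_z[[gene]]
  }
  bp_in <- function(chrom, pos, start0, end0, gchrom) {
    chrom == gchrom & pos - 1 >= start0 & pos - 1 < end0
  }
  if (!is.null(breakpoints$fusion)) {
    hit <- breakpoints$fusion %in% fusion_whitelist &
      !is.na(breakpoints$fusion)
    for (fu in unique(breakpoints$fusion[hit])) {
      g <- strsplit(fu, "-")[[1]][1]
      calls <- rbind(calls, new_driver_calls(
        gene = g, event_class = "fusion", rule = "whitelist_fusion",
        detail = fu
      ))
    }
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    in_foot <- bp_in(breakpoints$chrom1, breakpoints$pos1,
                     g$start, g$end, g$chrom) |
      bp_in(breakpoints$chrom2, breakpoints$pos2, g$start, g$end, g$chrom)
    if (g$role == "recessive" && any(in_foot)) {
      # a breakpoint through a recessive gene inactivates it like a
      # truncating point mutation would
      calls <- rbind(calls, new_driver_calls(
        gene = g$gene, event_class = "truncating",
        rule = "recessive_footprint_breakpoint",
        detail = sprintf("bp%d", which(in_foot)[1])
      ))
    }
    if (g$role == "oncogene" && !is.na(g$reg_start)) {
      in_reg <- bp_in(breakpoints$chrom1, breakpoints$pos1,
                      g$reg_start, g$reg_end, g$chrom) |
        bp_in(breakpoints$chrom2, breakpoints$pos2,
              g$reg_start, g$reg_end, g$chrom)
      if (any(in_reg) && zs(g$gene) >= z_cutoff) {
        calls <- rbind(calls, new_driver_calls(
          gene = g$gene, event_class = "regulatory_rearrangement",
          rule = "oncogene_regulatory_rearrangement",
          detail = sprintf("bp%d", which(in_reg)[1])
        ))
      }
    }
  }
  sort_calls(calls)
}

#' Attach clonality to driver calls from a phylogeny
#'
#' A driver call is clonal if its mutation is assigned to the trunk of the
#' tree (a branch on the root-to-first-split path), subclonal otherwise.
#' Calls whose detail does not match an assigned mutation id keep `NA`.
#'
#' @param calls a driver-call data.frame whose `detail` holds mutation
#'   ids.
#' @param tree a `mutation_tree` with an `assignment`.
#' @return the calls with `clonality` filled in.
#' @export
assign_clonality <- function(calls, tree) {
  stopifnot(inherits(tree, "mutation_tree"))
  if (is.null(tree$assignment) || nrow(calls) == 0) return(calls)
  ch <- tree_children(tree)
  trunk_nodes <- integer(0)
  node <- tree$root
  repeat {
    kids <- ch[[node]]
    if (length(kids) != 1L) break
    trunk_nodes <- c(trunk_nodes, kids)
    node <- kids
  }
  idx <- match(calls$detail, tree$assignment$id)
  br <- tree$assignment$branch[idx]
  calls$clonality <- ifelse(is.na(br), NA_character_,
                            ifelse(br %in% trunk_nodes, "clonal",
                                   "subclonal"))
  calls
}
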