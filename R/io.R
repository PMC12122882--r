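#' Write a variant table as VCF 4.2
#'
#' Records are 1-based; per-sample FORMAT fields carry total depth (DP),
#' forward/reverse mutant reads (MF/MR), median alignment score of
#' supporting reads (AS) and clipped-read fraction (CF). Sample classes
#' and the matched normal are preserved in header lines so the table
#' round-trips losslessly through [read_vcf()].
#'
#' @param table a `variant_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  v <- table$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=clonarch",
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Simulation ground-truth origin">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##FORMAT=<ID=MF,Number=1,Type=Integer,Description="Mutant reads, forward strand">',
    '##FORMAT=<ID=MR,Number=1,Type=Integer,Description="Mutant reads, reverse strand">',
    '##FORMAT=<ID=AS,Number=1,Type=Float,Description="Median alignment score of supporting reads">',
    '##FORMAT=<ID=CF,Number=1,Type=Float,Description="Fraction of supporting reads clipped">',
    sprintf("##SAMPLE=<ID=%s,Class=%s>", table$samples,
            table$sample_class[table$samples]),
    sprintf("##matched_normal=%s", table$matched_normal),
    sprintf("##calling_mode=%s", table$calling_mode),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")
  )
  rows <- character(nrow(v))
  if (nrow(v)) {
    gt <- matrix("", nrow(v), length(table$samples))
    for (j in seq_along(table$samples)) {
      gt[, j] <- sprintf("%d:%d:%d:%.10g:%.10g",
                         table$depth[, j], table$mut_fwd[, j],
                         table$mut_rev[, j], table$mas[, j],
                         table$clip[, j])
    }
    rows <- vapply(seq_len(nrow(v)), function(i) {
      paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".",
              "PASS", paste0("ORIGIN=", v$origin[i]), "DP:MF:MR:AS:CF",
              gt[i, ]), collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path VCF file.
#' @return a `variant_table`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples)) stop("VCF has no sample columns")

  grab <- function(el) {
    m <- vcfR::extract.gt(vcf, element = el, as.numeric = TRUE)
    if (is.null(m) || nrow(fix) == 0) {
      m <- matrix(numeric(0), 0, length(samples),
                  dimnames = list(NULL, samples))
    }
    m
  }
  origin <- sub("^ORIGIN=", "", fix$INFO)
  variants <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT, id = fix$ID,
    origin = if (length(origin)) origin else character(0),
    stringsAsFactors = FALSE
  )
  cls_lines <- grep("^##SAMPLE=", meta, value = TRUE)
  sample_class <- stats::setNames(rep("tissue", length(samples)), samples)
  for (ln in cls_lines) {
    id <- sub('.*ID=([^,>]+).*', "\\1", ln)
    cl <- sub('.*Class=([^,>]+).*', "\\1", ln)
    if (id %in% samples) sample_class[id] <- cl
  }
  mn <- sub("^##matched_normal=", "",
            grep("^##matched_normal=", meta, value = TRUE))
  cm <- sub("^##calling_mode=", "",
            grep("^##calling_mode=", meta, value = TRUE))
  dp <- grab("DP"); mf <- grab("MF"); mr <- grab("MR")
  as_ <- grab("AS"); cf <- grab("CF")
  storage.mode(dp) <- "integer"
  storage.mode(mf) <- "integer"
  storage.mode(mr) <- "integer"
  rownames(dp) <- rownames(mf) <- rownames(mr) <- rownames(as_) <-
    rownames(cf) <- variants$id
  variant_table(
    variants = variants, depth = dp, mut_fwd = mf, mut_rev = mr,
    mas = as_, clip = cf, sample_class = sample_class,
    matched_normal = if (length(mn) && mn != "NA") mn else NA_character_,
    calling_mode = if (length(cm)) cm else "matched"
  )
}

#' Write/read copy-number segments as BED
#'
#' BED intervals are 0-based half-open; columns are `chrom`, `start`,
#' `end`, `sample`, `cn`.
#'
#' @param profiles a [cn_profile()].
#' @param path BED file.
#' @return `write_bed()`: `path` invisibly; `read_bed()`: a `cn_profile`.
#' @export
write_bed <- function(profiles, path) {
  stopifnot(inherits(profiles, "cn_profile"))
  seg <- profiles$segments
  utils::write.table(
    seg[, c("chrom", "start", "end", "sample", "cn")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_bed
#' @param genome genome model for the profile read back.
#' @export
read_bed <- function(path, genome = default_genome()) {
  seg <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "sample", "cn"))
  cn_profile(seg[, c("sample", "chrom", "start", "end", "cn")], genome)
}

#' Convert trees to ape phylo objects
#'
#' `mutation_tree` leaves become tips plus a zero-length `normal` outgroup
#' tip; branch lengths are scaled mutation counts. `clonal_phylogeny`
#' leaves are the simulated clones with mutation counts per branch.
#'
#' @param tree a `mutation_tree` or `clonal_phylogeny`.
#' @return an `ape::phylo`.
#' @export
as_phylo_tree <- function(tree) UseMethod("as_phylo_tree")

#' @export
as_phylo_tree.mutation_tree <- function(tree) {
  build_phylo(tree$parent, tree$label, tree$leaf, tree$branch_scaled,
              tree$root, outgroup = "normal")
}

#' @export
as_phylo_tree.clonal_phylogeny <- function(tree) {
  blen <- tabulate(tree$mutations$branch, nbins = nrow(tree$nodes))
  build_phylo(tree$nodes$parent, tree$nodes$clone, tree$nodes$leaf,
              blen, tree$nodes$id[is.na(tree$nodes$parent)],
              outgroup = "normal")
}

# parent/label/leaf arrays -> phylo, attaching a zero-length outgroup tip
# at the root so the rooted structure survives Newick round-trips
build_phylo <- function(parent, label, leaf, blen, root, outgroup) {
  n <- length(parent)
  is_tip <- leaf
  n_tip <- sum(is_tip) + 1L  # + outgroup tip hung off the root
  tip_index <- integer(n)
  tip_index[which(is_tip)] <- seq_len(sum(is_tip))
  internal <- which(!is_tip)
  int_index <- integer(n)
  int_index[internal] <- n_tip + seq_along(internal)
  node_id <- ifelse(is_tip, tip_index, int_index)

  nonroot <- which(!is.na(parent))
  edges <- cbind(node_id[parent[nonroot]], node_id[nonroot])
  lens <- blen[nonroot]
  edges <- rbind(edges, c(node_id[root], n_tip))
  lens <- c(lens, 0)
  labels <- c(label[which(is_tip)], outgroup)
  phy <- list(
    edge = edges, edge.length = lens, tip.label = labels,
    Nnode = length(internal)
  )
  class(phy) <- "phylo"
  storage.mode(phy$edge) <- "integer"
  phy <- ape::collapse.singles(phy)
  ape::reorder.phylo(phy, "cladewise")
}

#' Write/read Newick trees
#'
#' Branch lengths are scaled mutation counts. Internal nodes without
#' labels receive generated identifiers on reading.
#'
#' @param tree a `mutation_tree`, `clonal_phylogeny` or `ape::phylo`.
#' @param path Newick file.
#' @return `write_newick()`: `path` invisibly; `read_newick()`: an
#'   `ape::phylo` with internal node labels filled in.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "phylo")) tree else as_phylo_tree(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy$node.label) || any(phy$node.label == "")) {
    lab <- if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label
    lab[lab == ""] <- sprintf("node%d", which(lab == ""))
    phy$node.label <- lab
  }
  phy
}

#' Write/read tab-separated tables
#'
#' Thin wrappers fixing the conventions used across the package (header
#' row, no quoting, no row names).
#'
#' @param x a data.frame.
#' @param path TSV file.
#' @return `write_tsv()`: `path` invisibly; `read_tsv()`: a data.frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Serialise a simulation to fixture files
#'
#' Writes the synthetic observations and the generating ground truth:
#' `variants.vcf` (1-based VCF), `copy_number.bed` (0-based half-open
#' BED), `tree_truth.nwk` (Newick, branch lengths = mutation counts),
#' `genotypes.tsv` (biopsy-by-mutation fractions) and
#' `ground_truth.json`.
#'
#' @param sim a simulation bundle from [simulate_observations()].
#' @param directory output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_fixtures <- function(sim, directory) {
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE)
  }
  paths <- c(
    vcf = file.path(directory, "variants.vcf"),
    bed = file.path(directory, "copy_number.bed"),
    newick = file.path(directory, "tree_truth.nwk"),
    genotypes = file.path(directory, "genotypes.tsv"),
    truth = file.path(directory, "ground_truth.json")
  )
  write_vcf(sim$table, paths["vcf"])
  write_bed(sim$cn, paths["bed"])
  write_newick(sim$tree, paths["newick"])
  geno_df <- data.frame(biopsy = rownames(sim$genotypes),
                        sim$genotypes, check.names = FALSE)
  write_tsv(geno_df, paths["genotypes"])
  truth <- list(
    mode = sim$tree$mode,
    trunk_mutation_count = sim$tree$trunk_mutation_count,
    per_cell_burden = true_per_cell_burden(sim$tree),
    n_clones = sum(sim$tree$nodes$leaf),
    n_mutations = nrow(sim$tree$mutations),
    seed = sim$seed
  )
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
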