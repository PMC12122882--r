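#' Pipeline configuration
#'
#' One configuration object drives a full run: the simulation preset (or
#' explicit simulation parameters), the filter significance levels, the
#' detection rule, the downsampling target and the mandatory seed. Every
#' parameter has a default; the object round-trips unchanged through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param preset a [preset_library()] name, or `NULL` to use `sim` as
#'   given.
#' @param sim a [simulation_config()] (built from `preset` when that is
#'   given).
#' @param seed integer seed; mandatory, no wall-clock seeding.
#' @param target_depth downsampling target for burden analysis (NULL to
#'   skip).
#' @param alpha_clonal,alpha_enrich,alpha_strand filter significance
#'   levels.
#' @param min_mut,min_vaf confidence criteria for calling a mutation in a
#'   sample.
#' @param epsilon ML-assignment error VAF.
#' @param cn_mode `"standard"` or `"deletion_only"`.
#' @param driver_gene optional gene symbol: inject one truncal driver
#'   point mutation into the simulated tumour.
#' @param gene_file gene-model TSV for driver annotation.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "neonatal_comb", sim = NULL,
                            seed = 1L, target_depth = NULL,
                            alpha_clonal = 0.01, alpha_enrich = 0.001,
                            alpha_strand = 0.001,
                            min_mut = 4L, min_vaf = 0.3,
                            epsilon = 1e-4,
                            cn_mode = "standard",
                            driver_gene = NULL,
                            gene_file = system.file(
                              "extdata", "driver_genes_synthetic.tsv",
                              package = "clonarch")) {
  if (is.null(sim)) {
    sim <- if (is.null(preset)) simulation_config() else preset_library(preset)
  }
  structure(
    list(
      preset = preset, sim = sim, seed = as.integer(seed),
      target_depth = target_depth,
      alpha_clonal = alpha_clonal, alpha_enrich = alpha_enrich,
      alpha_strand = alpha_strand,
      min_mut = as.integer(min_mut), min_vaf = min_vaf,
      epsilon = epsilon, cn_mode = cn_mode,
      driver_gene = driver_gene, gene_file = gene_file
    ),
    class = "pipeline_config"
  )
}

#' Serialise a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path YAML file.
#' @return `path` invisibly; `read_pipeline_config()` returns the
#'   `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$genome <- NULL  # reconstructed from defaults on read
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  simargs <- x$sim
  simargs$n_clones <- if (is.null(simargs$clone_fractions)) {
    simargs$n_clones
  } else NULL
  simargs$burden_target <- unlist(simargs$burden_target)
  simargs$trunk_range <- unlist(simargs$trunk_range)
  simargs$clone_fractions <- unlist(simargs$clone_fractions)
  sim <- do.call(simulation_config, simargs[!vapply(simargs, is.null,
                                                    logical(1))])
  pipeline_config(
    preset = x$preset, sim = sim, seed = x$seed,
    target_depth = x$target_depth,
    alpha_clonal = x$alpha_clonal, alpha_enrich = x$alpha_enrich,
    alpha_strand = x$alpha_strand, min_mut = x$min_mut,
    min_vaf = x$min_vaf, epsilon = x$epsilon, cn_mode = x$cn_mode,
    driver_gene = x$driver_gene, gene_file = x$gene_file
  )
}

#' Simulate one tumour's full observation set
#'
#' Runs the simulator end to end for one tumour: phylogeny, microbiopsy
#' genotypes with a matched normal (embryonic mosaic variants included),
#' bulk read counts with injected artefacts, duplex bundles, and flat
#' diploid copy-number profiles. Sub-seeds are derived from `seed` so the
#' whole bundle is reproducible from one integer.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param driver_gene optional gene symbol for a truncal driver (see
#'   [pipeline_config()]).
#' @param gene_file gene models used for driver placement.
#' @return a list (class `simulation_bundle`): `tree`, `genotypes`,
#'   `table` (microbiopsy `variant_table` for phylogeny work),
#'   `table_bulk` (bulk-piece `variant_table` for the burden comparison),
#'   `duplex`, `cn`, `driver_id`, `seed`.
#' @export
simulate_observations <- function(config, seed = 1L, driver_gene = NULL,
                                  gene_file = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_phylogeny(config, seed = seed)
  driver_id <- NULL
  if (!is.null(driver_gene)) {
    genes <- read_gene_models(gene_file)
    tree <- inject_truncal_driver(tree, genes, driver_gene)
    driver_id <- attr(tree, "driver_id")
  }
  geno <- sample_biopsies(tree, config$n_biopsies, config$cells_per_biopsy,
                          seed = seed + 1000L,
                          admixture = config$biopsy_admixture)
  geno <- add_matched_normal(tree, geno,
                             n_mosaic = config$n_mosaic,
                             mosaic_fraction = config$mosaic_fraction,
                             n_germline = config$n_germline,
                             seed = seed + 2000L)
  n_samp <- nrow(geno)
  purity <- c(rep(config$purity, n_samp - 1L), 1)
  vt <- simulate_bulk_reads(
    geno, depth = config$bulk_depth, purity = purity,
    seed = seed + 3000L, n_artifacts = config$n_artifacts,
    sample_class = stats::setNames(
      c(rep("tissue", n_samp - 1L), "normal"), rownames(geno)),
    matched_normal = attr(geno, "normal_name"),
    genome = config$genome
  )
  if (!is.null(driver_id)) {
    vt$variants$consequence <- ifelse(vt$variants$id == driver_id,
                                      attr(tree, "driver_consequence"),
                                      "none")
  }
  duplex <- simulate_duplex_bundles(
    tree, interrogated_bases = config$duplex_bases,
    error_rate = config$duplex_error, seed = seed + 4000L
  )
  # bulk tissue pieces (polyclonal mixtures) for the burden comparison
  bulk_geno <- bulk_piece_genotypes(tree, config$n_bulk_pieces,
                                    seed = seed + 6000L)
  bulk_geno <- add_matched_normal(tree, bulk_geno,
                                  n_mosaic = config$n_mosaic,
                                  mosaic_fraction = config$mosaic_fraction,
                                  n_germline = config$n_germline,
                                  seed = seed + 7000L)
  nb <- nrow(bulk_geno)
  vt_bulk <- simulate_bulk_reads(
    bulk_geno, depth = config$bulk_depth,
    purity = c(rep(config$purity, nb - 1L), 1),
    seed = seed + 8000L, n_artifacts = config$n_artifacts,
    sample_class = stats::setNames(
      c(rep("tissue", nb - 1L), "normal"), rownames(bulk_geno)),
    matched_normal = attr(bulk_geno, "normal_name"),
    genome = config$genome
  )
  cn <- flat_cn_profile(rownames(geno), config$genome)
  structure(
    list(tree = tree, genotypes = geno, table = vt,
         table_bulk = vt_bulk, duplex = duplex,
         cn = cn, driver_id = driver_id, seed = seed),
    class = "simulation_bundle"
  )
}

# place one trunk mutation inside a driver gene so the annotation rules
# can find it; oncogenes get a hotspot missense, recessive genes a
# truncating variant
inject_truncal_driver <- function(tree, genes, gene) {
  g <- genes[genes$gene == gene, ]
  if (nrow(g) != 1) stop("unknown driver gene: ", gene)
  trunk_muts <- which(tree$mutations$branch == 2L)
  if (!length(trunk_muts)) stop("tree has no trunk mutations to convert")
  i <- trunk_muts[1]
  hs <- hotspot_positions(g)
  tree$mutations$chrom[i] <- g$chrom
  tree$mutations$pos[i] <- if (g$role == "oncogene" && length(hs)) {
    hs[1]
  } else {
    as.integer(g$start + 1 + floor((g$end - g$start) / 2))
  }
  attr(tree, "driver_id") <- tree$mutations$id[i]
  attr(tree, "driver_consequence") <-
    if (g$role == "oncogene") "missense" else "truncating"
  tree
}

#' Run the full analysis end to end
#'
#' simulate -> duplex + bulk burden -> phylogeny -> architecture report
#' (-> driver report when a driver was injected); all artefact files are
#' written under `out_dir` and every filter's removal count is logged.
#' Reruns with an identical configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return a list (class `pipeline_result`): `report`
#'   (an [architecture_report()]), `bulk`, `duplex` (burden estimates),
#'   `tree` (the reconstructed `mutation_tree`), `sim` (the simulation
#'   bundle), `drivers` (driver calls or NULL), `filter_log`, `files`.
#' @export
run_end_to_end <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "simulate"
  result <- tryCatch({
    sim <- simulate_observations(config$sim, seed = config$seed,
                                 driver_gene = config$driver_gene,
                                 gene_file = config$gene_file)

    stage <- "bulk_filtering"
    apply_stack <- function(tab) {
      tab <- qc_filter(tab)
      tab <- filter_germline(tab, alpha_clonal = config$alpha_clonal,
                             alpha_enrich = config$alpha_enrich)
      filter_strand_imbalance(tab, alpha = config$alpha_strand)
    }
    vt_bulk <- apply_stack(sim$table_bulk)
    if (!is.null(config$target_depth)) {
      vt_bulk <- downsample_to_depth(vt_bulk, config$target_depth,
                                     seed = config$seed + 5000L)
    }

    stage <- "burden"
    pieces <- setdiff(vt_bulk$samples, vt_bulk$matched_normal)
    bulk_counts <- vapply(pieces, function(s) {
      bulk_burden(vt_bulk, s, min_mut = config$min_mut)$burden
    }, numeric(1))
    bulk_est <- burden_estimate(
      burden = stats::median(bulk_counts), method = "bulk",
      calls = as.integer(stats::median(bulk_counts)),
      interrogated = nrow(vt_bulk$variants)
    )
    duplex_est <- duplex_burden(sim$duplex)

    stage <- "phylogeny"
    vt <- apply_stack(sim$table)
    vt_phylo <- filter_confident_somewhere(vt, min_mut = config$min_mut,
                                           min_vaf = config$min_vaf)
    cn_res <- exclude_cn_discordant(vt_phylo, sim$cn, mode = config$cn_mode)
    vt_phylo <- cn_res$table
    presence <- presence_matrix(vt_phylo, min_mut = config$min_mut)
    gm <- genotype_matrix(presence)
    tree <- build_parsimony_tree(gm)
    tree <- assign_mutations_ml(tree, vt_phylo, purity = config$sim$purity,
                                epsilon = config$epsilon)
    tree <- scale_branches(tree, cn_res$excluded_fraction)

    stage <- "architecture"
    report <- architecture_report(
      trunk = trunk_length(tree),
      per_cell = per_cell_burden(tree),
      bulk = bulk_est, duplex = duplex_est
    )

    stage <- "drivers"
    drivers <- NULL
    if (!is.null(config$driver_gene)) {
      genes <- read_gene_models(config$gene_file)
      drivers <- annotate_small_variants(vt_phylo, genes)
      drivers <- assign_clonality(drivers, tree)
    }

    list(sim = sim, vt = vt, vt_phylo = vt_phylo, tree = tree,
         bulk = bulk_est, duplex = duplex_est, report = report,
         drivers = drivers)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- write_fixtures(result$sim, out_dir)
    tree_path <- file.path(out_dir, "tree_reconstructed.nwk")
    write_newick(result$tree, tree_path)
    burden_path <- file.path(out_dir, "burden.tsv")
    write_tsv(data.frame(
      sample = "tumour",
      method = c("bulk", "duplex"),
      calls = c(result$bulk$calls, result$duplex$calls),
      interrogated = c(result$bulk$interrogated,
                       result$duplex$interrogated),
      burden = c(result$bulk$burden, result$duplex$burden),
      ci_low = c(result$bulk$ci[1], result$duplex$ci[1]),
      ci_high = c(result$bulk$ci[2], result$duplex$ci[2])
    ), burden_path)
    report_path <- file.path(out_dir, "architecture_report.tsv")
    write_tsv(as.data.frame(result$report), report_path)
    json_path <- file.path(out_dir, "architecture_report.json")
    jsonlite::write_json(unclass(result$report), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_path <- file.path(out_dir, "filter_log.tsv")
    fl <- result$vt_phylo$filter_log
    write_tsv(data.frame(filter = names(fl),
                         removed = unlist(fl, use.names = FALSE)),
              log_path)
    files <- c(files, tree = tree_path, burden = burden_path,
               report = report_path, json = json_path, log = log_path)
    if (!is.null(result$drivers)) {
      drv_path <- file.path(out_dir, "drivers.tsv")
      write_tsv(result$drivers, drv_path)
      files <- c(files, drivers = drv_path)
    }
  }

  structure(
    list(report = result$report, bulk = result$bulk,
         duplex = result$duplex, tree = result$tree, sim = result$sim,
         drivers = result$drivers,
         filter_log = result$vt_phylo$filter_log, files = files),
    class = "pipeline_result"
  )
}

#' Per-sample presence matrix under the confidence criteria
#'
#' Binary (clonal unit x mutation) matrix: 1 iff the sample shows at least
#' `min_mut` mutant reads with both strands represented (presence for tree
#' building; the per-record VAF criterion has already been enforced table-
#' wide by [filter_confident_somewhere()]).
#'
#' @param table a `variant_table`.
#' @param min_mut minimum mutant reads.
#' @return binary matrix, tumour samples as rows.
#' @export
presence_matrix <- function(table, min_mut = 4L) {
  tum <- setdiff(table$samples, table$matched_normal)
  pres <- vapply(tum, function(s) {
    as.numeric(bulk_called(table, s, min_mut = min_mut))
  }, numeric(nrow(table$variants)))
  m <- t(pres)
  colnames(m) <- table$variants$id
  rownames(m) <- tum
  m
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}
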