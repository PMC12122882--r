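#' Simulation configuration
#'
#' Bundles every knob of the clonal-architecture simulator. Two architecture
#' modes are supported: `"comb"` (a short trunk followed by many
#' near-independent private lineages, the architecture of normal tissues and
#' of hypomutated infant tumours) and `"sweep"` (a long trunk produced by
#' clonal sweeps, with a small number of large nested subclones, the
#' architecture of conventional cancers).
#'
#' @param mode `"comb"` or `"sweep"`.
#' @param trunk_range integer vector `c(lo, hi)`; the trunk length (mutations
#'   shared by all tumour cells) is drawn uniformly from `lo:hi`.
#' @param private_mean,private_disp mean and dispersion (negative-binomial
#'   `size`) of the private branch length of each terminal clone.
#' @param n_clones number of terminal clones (comb mode).
#' @param clone_fractions optional clone cell fractions (must sum to 1). In
#'   comb mode the default is a symmetric Dirichlet draw; in sweep mode the
#'   default is `c(0.5, 0.3, 0.2)`.
#' @param internal_mean mean length of internal (subclone) branches in sweep
#'   mode.
#' @param bulk_depth target bulk sequencing depth (reads).
#' @param purity tumour purity in (0, 1]; the complement is normal
#'   contamination carrying zero somatic tumour mutations.
#' @param duplex_bases number of duplex bundle-bases interrogated.
#' @param duplex_error per-read per-base error probability for duplex reads.
#' @param n_biopsies,cells_per_biopsy microbiopsy sampling design.
#' @param n_bulk_pieces number of bulk tissue pieces sequenced for the
#'   burden comparison (each a polyclonal mixture of the whole tumour).
#' @param biopsy_admixture expected fraction of biopsy cells drawn from a
#'   random sibling clone rather than the locally dominant clone.
#' @param n_mosaic number of embryonic mosaic variants present at low
#'   fraction in the matched normal but clonal in the tumour.
#' @param mosaic_fraction cell fraction of mosaic variants in the normal.
#' @param n_germline number of germline heterozygous sites simulated in all
#'   samples (exercises the germline filter).
#' @param n_artifacts number of artefact records injected into bulk tables
#'   (exercises the QC and strand-imbalance filters).
#' @param burden_target optional per-cell burden range the preset was
#'   calibrated to (informational).
#' @param genome genome model, see [default_genome()].
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [preset_library()], [simulate_phylogeny()]
#' @export
simulation_config <- function(mode = c("comb", "sweep"),
                              trunk_range = c(9L, 26L),
                              private_mean = 300,
                              private_disp = 10,
                              n_clones = 20L,
                              clone_fractions = NULL,
                              internal_mean = 0,
                              bulk_depth = 30,
                              purity = 1,
                              duplex_bases = 2e9,
                              duplex_error = 1e-3,
                              n_biopsies = 25L,
                              cells_per_biopsy = 100L,
                              biopsy_admixture = 0.05,
                              n_bulk_pieces = 4L,
                              n_mosaic = 2L,
                              mosaic_fraction = 0.1,
                              n_germline = 100L,
                              n_artifacts = 20L,
                              burden_target = NULL,
                              genome = default_genome()) {
  mode <- match.arg(mode)
  if (mode == "sweep" && is.null(clone_fractions)) {
    clone_fractions <- c(0.5, 0.3, 0.2)
  }
  if (!is.null(clone_fractions)) {
    if (abs(sum(clone_fractions) - 1) > 1e-9) {
      stop("clone_fractions must sum to 1")
    }
    n_clones <- length(clone_fractions)
  }
  cfg <- list(
    mode = mode,
    trunk_range = as.integer(trunk_range),
    private_mean = private_mean,
    private_disp = private_disp,
    n_clones = as.integer(n_clones),
    clone_fractions = clone_fractions,
    internal_mean = internal_mean,
    bulk_depth = bulk_depth,
    purity = purity,
    duplex_bases = duplex_bases,
    duplex_error = duplex_error,
    n_biopsies = as.integer(n_biopsies),
    cells_per_biopsy = as.integer(cells_per_biopsy),
    biopsy_admixture = biopsy_admixture,
    n_bulk_pieces = as.integer(n_bulk_pieces),
    n_mosaic = as.integer(n_mosaic),
    mosaic_fraction = mosaic_fraction,
    n_germline = as.integer(n_germline),
    n_artifacts = as.integer(n_artifacts),
    burden_target = burden_target,
    genome = genome
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    length(cfg$trunk_range) == 2L,
    cfg$private_mean >= 0, cfg$private_disp > 0,
    cfg$internal_mean >= 0,
    cfg$bulk_depth >= 1,
    cfg$duplex_bases >= 1,
    cfg$duplex_error >= 0, cfg$duplex_error < 0.1,
    cfg$n_biopsies >= 1, cfg$cells_per_biopsy >= 1,
    cfg$biopsy_admixture >= 0, cfg$biopsy_admixture < 1
  )
  if (cfg$n_clones <= 0) stop("number of clones must be positive")
  if (cfg$trunk_range[2] < cfg$trunk_range[1]) stop("trunk range is empty")
  if (cfg$purity <= 0 || cfg$purity > 1) stop("purity must be in (0, 1]")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  mode: %s; clones: %d; trunk: %d-%d; private mean: %g\n",
              x$mode, x$n_clones, x$trunk_range[1], x$trunk_range[2],
              x$private_mean))
  cat(sprintf("  bulk depth: %gX, purity %.2f; duplex: %.3g bases, error %.1e\n",
              x$bulk_depth, x$purity, x$duplex_bases, x$duplex_error))
  cat(sprintf("  biopsies: %d x %d cells\n", x$n_biopsies, x$cells_per_biopsy))
  if (!is.null(x$burden_target)) {
    cat(sprintf("  per-cell burden target: [%g, %g]\n",
                x$burden_target[1], x$burden_target[2]))
  }
  invisible(x)
}

#' Preset simulation configurations
#'
#' Presets are calibrated so that the expected per-cell burden
#' (trunk midpoint + mean branch path below the trunk) hits the midpoint of
#' the stated target range:
#' \describe{
#'   \item{`neonatal_comb`}{infant tumour architecture: trunk of 9-26
#'     mutations, 20 clones, per-cell burden target 65-92.}
#'   \item{`schoolage_sweep`}{school-age tumour: long trunk (150-200) with
#'     three large nested subclones, per-cell burden target 221-248.}
#'   \item{`colorectal_sweep`}{adult-cancer-like sweep: trunk around 500 with
#'     three nested subclones.}
#'   \item{`neonatal_normal_kidney`}{polyclonal normal tissue, near-zero
#'     trunk, per-cell burden target 65-92.}
#'   \item{`schoolage_normal_kidney`}{as above with target 221-248.}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed on to [simulation_config()].
#' @return a `simulation_config`.
#' @export
preset_library <- function(name, ...) {
  presets <- list(
    neonatal_comb = list(
      mode = "comb", trunk_range = c(9L, 26L), n_clones = 20L,
      private_mean = 61, burden_target = c(65, 92)
    ),
    schoolage_sweep = list(
      mode = "sweep", trunk_range = c(150L, 200L),
      clone_fractions = c(0.5, 0.3, 0.2), internal_mean = 30,
      private_mean = 44, burden_target = c(221, 248)
    ),
    colorectal_sweep = list(
      mode = "sweep", trunk_range = c(450L, 550L),
      clone_fractions = c(0.5, 0.3, 0.2), internal_mean = 100,
      private_mean = 50
    ),
    neonatal_normal_kidney = list(
      mode = "comb", trunk_range = c(0L, 5L), n_clones = 50L,
      private_mean = 76, burden_target = c(65, 92)
    ),
    schoolage_normal_kidney = list(
      mode = "comb", trunk_range = c(0L, 5L), n_clones = 50L,
      private_mean = 232, burden_target = c(221, 248)
    )
  )
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(simulation_config, args)
}
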