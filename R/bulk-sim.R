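#' Simulate bulk sequencing observations over a genotype matrix
#'
#' Creates the bulk-WGS observation layer for a set of samples (biopsies,
#' organoids, or a matched normal). Per site and sample, total depth is
#' Poisson around the target depth; mutant reads are binomial with success
#' probability `purity * mutant_cell_fraction * 0.5` (heterozygous diploid);
#' mutant reads are split between forward and reverse strands symmetrically.
#' Alignment-score and clipping annotations are drawn from a clean
#' distribution for genuine records; artefact records (mis-mapping noise)
#' can be injected with noisy annotations and strand-imbalanced counts so
#' every downstream filter has something to remove.
#'
#' @param genotypes numeric matrix (sample x mutation) of mutant cell
#'   fractions in `[0, 1]`, e.g. from [sample_biopsies()]. An attribute
#'   `sites` (data.frame with `chrom`, `pos`, `ref`, `alt`, `id` and
#'   optionally `origin`) supplies site coordinates; without it generic
#'   sites are drawn.
#' @param depth target depth (reads).
#' @param purity tumour purity in `(0, 1]`; scalar or one value per sample.
#' @param seed integer random seed.
#' @param n_artifacts number of artefact records to inject.
#' @param sample_class optional named character vector of sample classes.
#' @param matched_normal optional matched-normal sample name.
#' @param genome genome model used when sites must be drawn.
#' @return a [variant_table()].
#' @export
simulate_bulk_reads <- function(genotypes, depth = 30, purity = 1,
                                seed = 1L, n_artifacts = 0L,
                                sample_class = NULL,
                                matched_normal = NA_character_,
                                genome = default_genome()) {
  if (any(genotypes < 0 | genotypes > 1)) {
    stop("genotype fractions must lie in [0, 1]")
  }
  if (depth < 1) stop("depth must be >= 1")
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  set.seed(seed)

  n_samp <- nrow(genotypes)
  n_mut <- ncol(genotypes)
  samples <- rownames(genotypes)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(n_samp))
  purity <- rep(purity, length.out = n_samp)

  sites <- attr(genotypes, "sites")
  if (is.null(sites)) {
    sites <- sample_sites(n_mut, genome)
    sites$id <- colnames(genotypes)
    if (is.null(sites$id)) sites$id <- sprintf("m%05d", seq_len(n_mut))
  }
  if (is.null(sites$origin)) sites$origin <- "somatic"

  dims <- list(sites$id, samples)
  dp <- matrix(stats::rpois(n_mut * n_samp, depth), n_mut, n_samp,
               dimnames = dims)
  p <- t(genotypes) * rep(purity, each = n_mut) * 0.5
  # germline sites are present in all cells regardless of purity
  germ <- sites$origin == "germline"
  if (any(germ)) p[germ, ] <- t(genotypes)[germ, ] * 0.5
  m <- matrix(stats::rbinom(n_mut * n_samp, as.vector(dp), as.vector(p)),
              n_mut, n_samp, dimnames = dims)
  mf <- matrix(stats::rbinom(n_mut * n_samp, as.vector(m), 0.5),
               n_mut, n_samp, dimnames = dims)
  mr <- m - mf
  # clean mapping annotations for genuine records
  mas <- matrix(sample(140:250, n_mut * n_samp, replace = TRUE),
                n_mut, n_samp, dimnames = dims)
  clip <- matrix(stats::runif(n_mut * n_samp, 0, 0.3), n_mut, n_samp,
                 dimnames = dims)

  variants <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    id = sites$id, origin = sites$origin, stringsAsFactors = FALSE
  )

  if (n_artifacts > 0) {
    art_sites <- sample_sites(n_artifacts, genome)
    art <- data.frame(
      chrom = art_sites$chrom, pos = art_sites$pos,
      ref = art_sites$ref, alt = art_sites$alt,
      id = sprintf("a%05d", seq_len(n_artifacts)),
      origin = "artifact", stringsAsFactors = FALSE
    )
    adp <- matrix(stats::rpois(n_artifacts * n_samp, depth),
                  n_artifacts, n_samp)
    am <- matrix(stats::rbinom(n_artifacts * n_samp, as.vector(adp), 0.15),
                 n_artifacts, n_samp)
    # three mis-mapping flavours: low alignment score, heavy clipping, or
    # clean-looking but strand-imbalanced support
    type <- sample(c("low_as", "clipped", "strand"), n_artifacts,
                   replace = TRUE)
    strand_p <- ifelse(type == "strand", 0.98, 0.5)
    amf <- matrix(stats::rbinom(n_artifacts * n_samp, as.vector(am),
                                rep(strand_p, n_samp)),
                  n_artifacts, n_samp)
    amas <- matrix(ifelse(rep(type == "low_as", n_samp),
                          sample(60:139, n_artifacts * n_samp, replace = TRUE),
                          sample(140:250, n_artifacts * n_samp, replace = TRUE)),
                   n_artifacts, n_samp)
    aclip <- matrix(ifelse(rep(type == "clipped", n_samp),
                           stats::runif(n_artifacts * n_samp, 0.5, 0.9),
                           stats::runif(n_artifacts * n_samp, 0, 0.3)),
                    n_artifacts, n_samp)
    variants <- rbind(variants, art)
    dp <- rbind(dp, adp); m <- rbind(m, am); mf <- rbind(mf, amf)
    mr <- m - mf
    mas <- rbind(mas, amas); clip <- rbind(clip, aclip)
    rownames(dp) <- rownames(m) <- rownames(mf) <- rownames(mr) <-
      rownames(mas) <- rownames(clip) <- variants$id
  }

  variant_table(
    variants = variants,
    depth = dp, mut_fwd = mf, mut_rev = mr, mas = mas, clip = clip,
    sample_class = sample_class,
    matched_normal = matched_normal,
    calling_mode = if (is.na(matched_normal)) "unmatched" else "matched"
  )
}

#' Build the multi-sample genotype matrix for a tumour plus matched normal
#'
#' Stacks biopsy genotypes with a matched-normal row: the normal carries no
#' somatic tumour mutations except the configured embryonic mosaic variants,
#' which sit at low cell fraction in the normal while being clonal in the
#' tumour (they are drawn from the trunk). Optionally appends germline
#' heterozygous sites present in every sample at cell fraction 1.
#'
#' @param tree the generating `clonal_phylogeny`.
#' @param geno biopsy genotype matrix from [sample_biopsies()].
#' @param n_mosaic number of trunk mutations marked as embryonic mosaic.
#' @param mosaic_fraction normal cell fraction of mosaic variants.
#' @param n_germline number of germline heterozygous sites appended.
#' @param normal_name sample name for the matched normal.
#' @param seed integer random seed.
#' @return a genotype matrix with a `sites` attribute, normal row included.
#' @export
add_matched_normal <- function(tree, geno, n_mosaic = 2L,
                               mosaic_fraction = 0.1, n_germline = 100L,
                               normal_name = "NORMAL", seed = 1L) {
  set.seed(seed)
  sites <- attr(geno, "sites")
  normal <- stats::setNames(numeric(ncol(geno)), colnames(geno))
  trunk_branch <- sites$branch[match(colnames(geno), sites$id)]
  trunk_ids <- sites$id[sites$branch == 2L]
  if (n_mosaic > 0 && length(trunk_ids)) {
    pick <- utils::head(trunk_ids, n_mosaic)
    normal[pick] <- mosaic_fraction
    sites$origin <- ifelse(sites$id %in% pick, "mosaic",
                           if (is.null(sites$origin)) "somatic"
                           else sites$origin)
  } else if (is.null(sites$origin)) {
    sites$origin <- "somatic"
  }
  out <- rbind(geno, normal)
  rownames(out)[nrow(out)] <- normal_name

  if (n_germline > 0) {
    gsites <- sample_sites(n_germline, tree$config$genome)
    gsites$id <- sprintf("g%05d", seq_len(n_germline))
    gsites$branch <- NA_integer_
    gsites$origin <- "germline"
    sites <- rbind(
      sites[, c("id", "branch", "chrom", "pos", "ref", "alt", "origin")],
      gsites[, c("id", "branch", "chrom", "pos", "ref", "alt", "origin")]
    )
    gmat <- matrix(1, nrow(out), n_germline,
                   dimnames = list(rownames(out), gsites$id))
    out <- cbind(out, gmat)
  }
  structure(out,
            sites = sites,
            dominant_clone = attr(geno, "dominant_clone"),
            tree_trunk = attr(geno, "tree_trunk"),
            normal_name = normal_name)
}
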