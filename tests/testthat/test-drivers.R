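genes_fixture <- function() {
  read_gene_models(system.file("extdata", "driver_genes_synthetic.tsv",
                               package = "clonarch"))
}

test_that("small-variant rules fire only for hotspot/truncating events", {
  genes <- genes_fixture()
  v <- data.frame(
    chrom = c("chr3", "chr3", "chr11", "chr11", "chr3"),
    pos = c(41010101, 41010555, 32410000, 32410001, 41010120),
    id = paste0("v", 1:5),
    consequence = c("missense", "missense", "truncating", "missense",
                    "inframe"),
    stringsAsFactors = FALSE
  )
  calls <- annotate_small_variants(v, genes)
  # hotspot missense + hotspot inframe in CTNNB1, truncating in WT1;
  # non-hotspot missense and recessive missense are ignored
  expect_equal(nrow(calls), 3L)
  expect_setequal(calls$event_class,
                  c("hotspot_missense", "hotspot_missense", "truncating"))
  expect_setequal(calls$detail[calls$gene == "CTNNB1"], c("v1", "v5"))
  expect_equal(calls$detail[calls$gene == "WT1"], "v3")

  expect_error(annotate_small_variants(v[, 1:3], genes), "consequence")
})

test_that("promoter rescue reinstates filtered records at listed sites", {
  vt <- make_table(
    depth = matrix(30, 3, 1), mut_fwd = matrix(5, 3, 1),
    mut_rev = matrix(5, 3, 1),
    mas = matrix(c(100, 100, 200), 3, 1), clip = matrix(0.1, 3, 1)
  )
  vt$variants$pos <- c(1295113L, 1295300L, 2000L)
  vt$variants$chrom <- "chr5"
  filtered <- qc_filter(vt)          # drops the two low-score records
  expect_equal(nrow(filtered$variants), 1L)

  rescued <- rescue_promoter_sites(
    filtered, data.frame(chrom = "chr5", pos = 1295113)
  )
  expect_equal(nrow(rescued$variants), 2L)
  expect_true(any(rescued$variants$rescued, na.rm = TRUE))

  # empty rescue list and unmatched sites are no-ops
  expect_equal(nrow(rescue_promoter_sites(
    filtered, data.frame(chrom = character(0), pos = integer(0))
  )$variants), 1L)
  expect_equal(nrow(rescue_promoter_sites(
    filtered, data.frame(chrom = "chr9", pos = 1)
  )$variants), 1L)
})

test_that("copy-number rules respect focality and ploidy thresholds", {
  genes <- genes_fixture()
  genome <- default_genome()
  seg_base <- clonarch:::flat_cn_profile("T", genome)$segments

  with_event <- function(chrom, start, end, cn) {
    seg <- seg_base[seg_base$chrom != chrom, ]
    chrlen <- genome$length[match(chrom, genome$chrom)]
    seg <- rbind(seg, data.frame(
      sample = "T", chrom = chrom, start = c(0, start, end),
      end = c(start, end, chrlen), cn = c(2, cn, 2)
    ))
    cn_profile(seg, genome)
  }

  # 0.5 Mb homozygous deletion over TP53: driver
  del <- with_event("chr17", 7.4e6, 7.9e6, 0)
  calls <- annotate_copy_number(del, genes, "diploid")
  expect_equal(calls$event_class, "homozygous_deletion")
  expect_equal(calls$gene, "TP53")

  # 2 Mb deletion: not focal, no call
  wide <- with_event("chr17", 6.5e6, 8.5e6, 0)
  expect_equal(nrow(annotate_copy_number(wide, genes, "diploid")), 0L)

  # CN 5 over MYCN: amplification when diploid...
  amp <- with_event("chr2", 15.9e6, 16.2e6, 5)
  calls <- annotate_copy_number(amp, genes, "diploid")
  expect_equal(calls$event_class, "amplification")
  # ...but in a tetraploid genome only with elevated expression
  expect_equal(nrow(annotate_copy_number(amp, genes, "tetraploid")), 0L)
  calls <- annotate_copy_number(amp, genes, "tetraploid",
                                expression_z = c(MYCN = 5))
  expect_equal(calls$event_class, "sub_amplification_with_expression")
})

test_that("rearrangement rules require expression for regulatory events", {
  genes <- genes_fixture()
  # breakpoint in FOXR2's regulatory domain
  bp <- data.frame(chrom1 = "chr5", pos1 = 54995000,
                   chrom2 = "chr9", pos2 = 1e6)
  expect_equal(nrow(annotate_rearrangements(bp, genes,
                                            expression_z = c(FOXR2 = 0))),
               0L)
  calls <- annotate_rearrangements(bp, genes, expression_z = c(FOXR2 = 5))
  expect_equal(calls$event_class, "regulatory_rearrangement")
  expect_equal(calls$gene, "FOXR2")

  # breakpoint through a recessive gene footprint
  bp2 <- data.frame(chrom1 = "chr11", pos1 = 32450000,
                    chrom2 = "chr2", pos2 = 5e6)
  calls2 <- annotate_rearrangements(bp2, genes)
  expect_equal(calls2$gene, "WT1")
  expect_equal(calls2$event_class, "truncating")

  # whitelisted fusion
  bp3 <- data.frame(chrom1 = "chr1", pos1 = 1, chrom2 = "chr1", pos2 = 2,
                    fusion = "EWSR1-FLI1")
  calls3 <- annotate_rearrangements(bp3, genes,
                                    fusion_whitelist = "EWSR1-FLI1")
  expect_equal(calls3$event_class, "fusion")

  expect_error(annotate_rearrangements(data.frame(x = 1), genes),
               "malformed")
})

test_that("calls are deterministic and each fixture fires exactly one rule", {
  genes <- genes_fixture()
  v <- data.frame(chrom = "chr3", pos = 41010101, id = "v1",
                  consequence = "missense", stringsAsFactors = FALSE)
  c1 <- annotate_small_variants(v, genes)
  c2 <- annotate_small_variants(v, genes)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$rule, "oncogene_hotspot")
})

test_that("an injected truncal driver yields one clonal call and no
           subclonal ones", {
  cfg <- preset_library("neonatal_comb", n_biopsies = 8)
  res <- run_end_to_end(pipeline_config(sim = cfg, seed = 5,
                                        driver_gene = "WT1"))
  expect_equal(nrow(res$drivers), 1L)
  expect_equal(res$drivers$clonality, "clonal")
  expect_equal(sum(res$drivers$clonality == "subclonal", na.rm = TRUE), 0L)
})
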