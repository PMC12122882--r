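germline_fixture <- function(nm, nd, tm, td) {
  # two samples: tumour T and matched normal N
  make_table(
    depth = matrix(c(td, nd), ncol = 2,
                   dimnames = list(NULL, c("T", "N"))),
    mut_fwd = matrix(c(ceiling(tm / 2), ceiling(nm / 2)), ncol = 2),
    mut_rev = matrix(c(floor(tm / 2), floor(nm / 2)), ncol = 2),
    matched_normal = "N"
  )
}

test_that("germline filter removes heterozygous variants and keeps somatic
           and embryonic mosaic ones", {
  # clonal het in normal, no tumour enrichment: removed
  vt <- germline_fixture(nm = 15, nd = 30, tm = 14, td = 30)
  expect_equal(nrow(filter_germline(vt)$variants), 0L)
  # absent from the normal: retained
  vt <- germline_fixture(nm = 0, nd = 30, tm = 12, td = 30)
  expect_equal(nrow(filter_germline(vt)$variants), 1L)
  # embryonic mosaic: low VAF in normal, near-clonal in tumour: retained
  vt <- germline_fixture(nm = 2, nd = 40, tm = 14, td = 30)
  expect_equal(nrow(filter_germline(vt)$variants), 1L)

  expect_error(filter_germline(germline_fixture(1, 2, 3, 4),
                               matched_normal = "missing"),
               "matched normal")
})

test_that("exact test p-values match brute-force enumeration", {
  # clonal-in-normal test: two-sided exact binomial at p = 0.5
  for (n in c(5, 17, 40)) {
    for (x in unique(c(0, 1, floor(n / 3), floor(n / 2), n))) {
      expect_equal(stats::binom.test(x, n, 0.5)$p.value,
                   enum_binom_two_sided(x, n), tolerance = 1e-12)
    }
  }
  # enrichment test: one-sided exact two-proportion (hypergeometric tail)
  cases <- list(c(14, 30, 2, 40), c(10, 30, 15, 30), c(20, 40, 0, 35))
  for (cs in cases) {
    got <- stats::fisher.test(
      matrix(c(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3]), 2),
      alternative = "greater"
    )$p.value
    expect_equal(got, enum_prop_greater(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
})

test_that("strand-imbalance filter uses the exact symmetric binomial test", {
  near <- make_table(depth = matrix(40, 1, 1), mut_fwd = matrix(8, 1, 1),
                     mut_rev = matrix(7, 1, 1))
  expect_equal(nrow(filter_strand_imbalance(near)$variants), 1L)

  skewed <- make_table(depth = matrix(40, 1, 1), mut_fwd = matrix(20, 1, 1),
                       mut_rev = matrix(0, 1, 1))
  # exact p = 2 * 0.5^20, verified by enumeration
  expect_equal(enum_binom_two_sided(20, 20), 2 * 0.5^20)
  expect_equal(nrow(filter_strand_imbalance(skewed, alpha = 0.01)$variants),
               0L)

  tiny <- make_table(depth = matrix(10, 1, 1), mut_fwd = matrix(1, 1, 1),
                     mut_rev = matrix(0, 1, 1))
  expect_equal(nrow(filter_strand_imbalance(tiny)$variants), 1L)
})

test_that("confidence filter needs one sample passing all three criteria", {
  # 4/12 = VAF 0.33 with 2+2 strands: retained
  vt <- make_table(depth = matrix(12, 1, 1), mut_fwd = matrix(2, 1, 1),
                   mut_rev = matrix(2, 1, 1))
  expect_equal(nrow(filter_confident_somewhere(vt)$variants), 1L)
  # 3/10: too few mutant reads
  vt <- make_table(depth = matrix(10, 1, 1), mut_fwd = matrix(2, 1, 1),
                   mut_rev = matrix(1, 1, 1))
  expect_equal(nrow(filter_confident_somewhere(vt)$variants), 0L)
  # 6 mutant reads all forward: fails the both-strands criterion
  vt <- make_table(depth = matrix(12, 1, 1), mut_fwd = matrix(6, 1, 1),
                   mut_rev = matrix(0, 1, 1))
  expect_equal(nrow(filter_confident_somewhere(vt)$variants), 0L)
  # VAF below 0.3 everywhere: removed even with many mutant reads
  vt <- make_table(depth = matrix(40, 1, 1), mut_fwd = matrix(4, 1, 1),
                   mut_rev = matrix(4, 1, 1))
  expect_equal(nrow(filter_confident_somewhere(vt)$variants), 0L)
})

test_that("phylogeny filters commute", {
  set.seed(2)
  cfg <- preset_library("neonatal_comb", n_biopsies = 6)
  sim <- simulate_observations(cfg, seed = 2)
  perms <- list(
    c("g", "s", "c"), c("s", "g", "c"), c("c", "s", "g")
  )
  apply_in_order <- function(order) {
    tab <- sim$table
    for (f in order) {
      tab <- switch(f,
                    g = filter_germline(tab),
                    s = filter_strand_imbalance(tab),
                    c = filter_confident_somewhere(tab))
    }
    sort(tab$variants$id)
  }
  results <- lapply(perms, apply_in_order)
  expect_identical(results[[2]], results[[1]])
  expect_identical(results[[3]], results[[1]])
})

test_that("copy-number discordance exclusion measures the excluded genome", {
  genome <- default_genome()
  vt <- make_table(depth = matrix(30, 2, 2,
                                  dimnames = list(NULL, c("A", "B"))),
                   mut_fwd = matrix(4, 2, 2), mut_rev = matrix(4, 2, 2))
  vt$variants$chrom <- c("chr1", "chr2")
  vt$variants$pos <- c(5e6, 5e6)

  # all diploid: nothing removed
  flat <- clonarch:::flat_cn_profile(c("A", "B"), genome)
  res <- exclude_cn_discordant(vt, flat)
  expect_equal(res$excluded_fraction, 0)
  expect_equal(nrow(res$table$variants), 2L)

  # one sample loses a segment covering ~4% of the genome incl. chr1:5e6
  loss_len <- round(0.04 * sum(genome$length))
  seg <- flat$segments
  seg <- seg[!(seg$sample == "A" & seg$chrom == "chr1"), ]
  seg <- rbind(seg, data.frame(
    sample = "A", chrom = "chr1",
    start = c(0, 1e6, 1e6 + loss_len),
    end = c(1e6, 1e6 + loss_len, genome$length[1]),
    cn = c(2, 1, 2)
  ))
  prof <- cn_profile(seg, genome)
  res <- exclude_cn_discordant(vt, prof)
  expect_equal(res$excluded_fraction, loss_len / sum(genome$length),
               tolerance = 1e-12)
  expect_identical(res$table$variants$chrom, "chr2")

  # deletion-only mode reports the deleted fraction
  res2 <- exclude_cn_discordant(vt, prof, mode = "deletion_only")
  expect_equal(res2$excluded_fraction, loss_len / sum(genome$length),
               tolerance = 1e-12)
})
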