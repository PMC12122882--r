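test_that("mapping QC keeps records at the rule boundary", {
  vt <- make_table(
    depth = matrix(30, 3, 1),
    mut_fwd = matrix(c(8, 8, 8), 3, 1), mut_rev = matrix(7, 3, 1),
    mas = matrix(c(140, 139, 200), 3, 1),
    clip = matrix(c(0.4, 0.1, 0.5), 3, 1)
  )
  out <- qc_filter(vt)
  # score 140 & clip 0.4 retained; score 139 removed; clip 0.5 removed
  expect_identical(out$variants$id, "v00001")
  expect_equal(out$filter_log$qc_mapping, 2L)

  empty <- vt_empty()
  expect_equal(nrow(qc_filter(empty)$variants), 0L)
})

test_that("QC filtering is idempotent", {
  vt <- make_table(
    depth = matrix(30, 5, 2), mut_fwd = matrix(5, 5, 2),
    mut_rev = matrix(4, 5, 2),
    mas = matrix(sample(c(100, 200), 10, TRUE), 5, 2),
    clip = matrix(0.2, 5, 2)
  )
  once <- qc_filter(vt)
  twice <- qc_filter(once)
  expect_identical(twice$variants, once$variants)
})

test_that("organoid VAF filter is strict at 0.3", {
  vt <- make_table(
    depth = matrix(100, 3, 1),
    mut_fwd = matrix(c(16, 15, 25), 3, 1),
    mut_rev = matrix(c(15, 15, 25), 3, 1),   # VAFs 0.31, 0.30, 0.50
    sample_class = c(S01 = "organoid")
  )
  out <- organoid_vaf_filter(vt)
  expect_setequal(out$variants$id, c("v00001", "v00003"))

  # applied to a tissue table: wrong sample class
  vt2 <- make_table(depth = matrix(30, 1, 1), mut_fwd = matrix(5, 1, 1),
                    mut_rev = matrix(5, 1, 1))
  expect_error(organoid_vaf_filter(vt2), "sample class")

  # an all-subclonal table empties out
  sub <- make_table(depth = matrix(100, 4, 1), mut_fwd = matrix(10, 4, 1),
                    mut_rev = matrix(10, 4, 1),
                    sample_class = c(S01 = "organoid"))
  expect_equal(nrow(organoid_vaf_filter(sub)$variants), 0L)
})

test_that("filter order does not change the surviving record set", {
  set.seed(1)
  n <- 40
  vt <- make_table(
    depth = matrix(100, n, 1),
    mut_fwd = matrix(rbinom(n, 50, 0.5), n, 1),
    mut_rev = matrix(rbinom(n, 50, 0.5), n, 1),
    mas = matrix(sample(c(120, 200), n, TRUE), n, 1),
    clip = matrix(runif(n, 0, 0.6), n, 1),
    sample_class = c(S01 = "organoid")
  )
  a <- organoid_vaf_filter(qc_filter(vt))
  b <- qc_filter(organoid_vaf_filter(vt))
  expect_identical(a$variants$id, b$variants$id)
})

test_that("downsampling is hypergeometric with the right mean", {
  vt60 <- make_table(depth = matrix(60, 1, 1), mut_fwd = matrix(15, 1, 1),
                     mut_rev = matrix(15, 1, 1))
  mm <- vapply(1:300, function(s) {
    sum(mutant_reads(downsample_to_depth(vt60, 30, seed = s)))
  }, numeric(1))
  se <- stats::sd(mm) / sqrt(length(mm))
  expect_lte(abs(mean(mm) - 15), 3 * se)
  expect_true(all(vapply(1:20, function(s) {
    all(downsample_to_depth(vt60, 30, seed = s)$depth == 30)
  }, logical(1))))

  # target at current depth: unchanged, independent of the seed
  same1 <- downsample_to_depth(vt60, 60, seed = 1)
  same2 <- downsample_to_depth(vt60, 60, seed = 2)
  expect_identical(same1$depth, vt60$depth)
  expect_identical(same1$mut_fwd, same2$mut_fwd)

  expect_error(downsample_to_depth(vt60, 0), "positive")
  expect_warning(downsample_to_depth(vt60, 90), "below target")
})

test_that("bulk burden counts passing records", {
  n <- 36
  vt <- make_table(depth = matrix(30, n, 1), mut_fwd = matrix(7, n, 1),
                   mut_rev = matrix(8, n, 1))
  expect_equal(bulk_burden(vt)$burden, 36)
  expect_equal(bulk_burden(vt_empty())$burden, 0)

  # detection needs >= 4 mutant reads on both strands
  vt2 <- make_table(depth = matrix(30, 3, 1),
                    mut_fwd = matrix(c(2, 6, 3), 3, 1),
                    mut_rev = matrix(c(1, 0, 2), 3, 1))
  expect_equal(bulk_burden(vt2)$burden, 1)
})

test_that("detection is monotone in depth on simulated data", {
  cfg <- preset_library("neonatal_comb", bulk_depth = 60)
  diffs <- vapply(1:10, function(s) {
    tree <- simulate_phylogeny(cfg, seed = s)
    geno <- bulk_piece_genotypes(tree, 1, seed = s)
    vt60 <- simulate_bulk_reads(geno, depth = 60, seed = s)
    vt30 <- downsample_to_depth(vt60, 30, seed = s + 100)
    bulk_burden(vt60)$burden - bulk_burden(vt30)$burden
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})
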