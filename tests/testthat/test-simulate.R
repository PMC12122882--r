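test_that("comb phylogenies have short trunks and long private branches", {
  cfg <- simulation_config(mode = "comb", trunk_range = c(9, 26),
                           private_mean = 300, n_clones = 20)
  tree <- simulate_phylogeny(cfg, seed = 1)
  expect_true(tree$trunk_mutation_count >= 9 &&
                tree$trunk_mutation_count <= 26)
  leaves <- tree$nodes[tree$nodes$leaf, ]
  depths <- vapply(leaves$clone, function(cl) {
    length(clone_mutations(tree, cl))
  }, numeric(1))
  expect_true(all(depths > 100))
  expect_equal(sum(leaves$fraction), 1, tolerance = 1e-9)
  # every mutation sits on exactly one branch
  expect_equal(anyDuplicated(tree$mutations$id), 0L)
})

test_that("a single clone with no private mutations is a single branch", {
  cfg <- simulation_config(mode = "comb", trunk_range = c(10, 10),
                           private_mean = 0, n_clones = 1)
  tree <- simulate_phylogeny(cfg, seed = 5)
  expect_equal(nrow(tree$nodes), 2L)
  expect_equal(true_per_cell_burden(tree), 10)
})

test_that("sweep clone fractions pass through exactly", {
  cfg <- simulation_config(mode = "sweep", trunk_range = c(500, 500),
                           clone_fractions = c(0.5, 0.3, 0.2),
                           internal_mean = 100, private_mean = 50)
  tree <- simulate_phylogeny(cfg, seed = 7)
  frac <- sort(tree$nodes$fraction[tree$nodes$leaf], decreasing = TRUE)
  expect_identical(frac, c(0.5, 0.3, 0.2))
  expect_equal(tree$trunk_mutation_count, 500L)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_clones = 0), "clones")
  expect_error(simulation_config(trunk_range = c(10, 5)), "empty")
  expect_error(simulation_config(purity = 0), "purity")
  expect_error(preset_library("no_such_preset"), "unknown preset")
})

test_that("presets are calibrated to their stated burden targets", {
  neo <- preset_library("neonatal_comb")
  expect_identical(neo$trunk_range, c(9L, 26L))
  expect_identical(neo$burden_target, c(65, 92))
  expect_lte(abs(mean(neo$trunk_range) + neo$private_mean -
                   mean(neo$burden_target)), 2)
  sch <- preset_library("schoolage_sweep")
  expect_identical(sch$burden_target, c(221, 248))
  burdens <- vapply(1:10, function(s) {
    true_per_cell_burden(simulate_phylogeny(sch, seed = s))
  }, numeric(1))
  expect_gt(mean(burdens), 200)
  expect_lt(mean(burdens), 270)
})

test_that("mean per-cell burden converges to trunk + private mean", {
  cfg <- simulation_config(mode = "comb", trunk_range = c(9, 26),
                           private_mean = 61, private_disp = 10,
                           n_clones = 20)
  burdens <- vapply(1:50, function(s) {
    true_per_cell_burden(simulate_phylogeny(cfg, seed = s))
  }, numeric(1))
  expected <- mean(c(9, 26)) + 61
  se <- stats::sd(burdens) / sqrt(length(burdens))
  expect_lte(abs(mean(burdens) - expected), 3 * se)
})

test_that("simulation output is deterministic under a fixed seed", {
  cfg <- preset_library("neonatal_comb")
  t1 <- simulate_phylogeny(cfg, seed = 11)
  t2 <- simulate_phylogeny(cfg, seed = 11)
  expect_identical(t1, t2)
  b1 <- simulate_duplex_bundles(t1, 1e6, 1e-3, seed = 3)
  b2 <- simulate_duplex_bundles(t2, 1e6, 1e-3, seed = 3)
  expect_identical(b1, b2)
})

test_that("biopsies carry all trunk mutations clonally", {
  tree <- simulate_phylogeny(preset_library("neonatal_comb"), seed = 1)
  geno <- sample_biopsies(tree, 25, 100, seed = 2)
  trunk_ids <- tree$mutations$id[tree$mutations$branch == 2L]
  expect_true(all(geno[, trunk_ids] == 1))
})

test_that("a single biopsy of a single-clone tumour is that clone", {
  cfg <- simulation_config(mode = "comb", trunk_range = c(10, 10),
                           private_mean = 20, n_clones = 1)
  tree <- simulate_phylogeny(cfg, seed = 3)
  geno <- sample_biopsies(tree, 1, 100, seed = 1)
  expect_identical(colnames(geno)[geno[1, ] == 1],
                   clone_mutations(tree, "C1"))
})

test_that("mutations shared by all biopsies recover the trunk", {
  tree <- simulate_phylogeny(preset_library("neonatal_comb"), seed = 4)
  geno <- sample_biopsies(tree, 25, 100, seed = 3)
  shared <- colnames(geno)[apply(geno > 0, 2, all)]
  trunk_ids <- tree$mutations$id[tree$mutations$branch == 2L]
  expect_setequal(shared, trunk_ids)
})

test_that("bulk read counts follow the binomial observation model", {
  # clonal heterozygous diploid site at purity 1, depth 30: mean 15
  geno <- matrix(1, 1, 1, dimnames = list("S", "m1"))
  mm <- vapply(1:200, function(s) {
    vt <- simulate_bulk_reads(geno, depth = 30, purity = 1, seed = s)
    sum(mutant_reads(vt))
  }, numeric(1))
  se <- stats::sd(mm) / sqrt(length(mm))
  expect_lte(abs(mean(mm) - 15), 3 * se)
  # zero-fraction sample never shows mutant reads
  vt0 <- simulate_bulk_reads(matrix(0, 1, 5), depth = 30, seed = 1)
  expect_true(all(mutant_reads(vt0) == 0))
  expect_error(simulate_bulk_reads(matrix(2, 1, 1)), "fractions")
})

test_that("bulk detection matches the closed-form binomial tail", {
  # P(called) for one site with cell fraction f at depth 30, purity 1:
  # depth ~ Pois(30), mutant ~ Bin(depth, f/2), called iff >= 4 mutant
  # reads on both strands; oracle computed by direct summation
  f <- 0.4
  oracle <- local({
    p <- f / 2
    dp <- 0:120
    pd <- stats::dpois(dp, 30)
    p_called_given_dp <- vapply(dp, function(d) {
      if (d < 4) return(0)
      m <- 4:d
      # both strands represented: 1 - 2 * 0.5^m  (m >= 1)
      sum(stats::dbinom(m, d, p) * (1 - 2 * 0.5^m))
    }, numeric(1))
    sum(pd * p_called_given_dp)
  })
  geno <- matrix(f, 1, 200)
  hits <- vapply(1:50, function(s) {
    vt <- simulate_bulk_reads(geno, depth = 30, purity = 1, seed = s)
    mean(clonarch:::bulk_called(vt, "S01"))
  }, numeric(1))
  se <- stats::sd(hits) / sqrt(length(hits))
  expect_lte(abs(mean(hits) - oracle), max(3 * se, 0.005))
})

test_that("duplex bundles carry true variants on both strands at error 0", {
  cfg <- simulation_config(mode = "comb", n_clones = 5, private_mean = 300)
  tree <- simulate_phylogeny(cfg, seed = 2)
  set <- simulate_duplex_bundles(tree, 1e8, error_rate = 0, seed = 2,
                                 meta = duplex_meta_clean())
  expect_gt(nrow(set$bundles), 0)
  reads <- merge(set$reads, set$bundles[, c("bundle_id", "true_alt")])
  expect_true(all(reads$base == reads$true_alt))
})
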