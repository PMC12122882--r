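test_that("consensus calling applies every rule at its stated boundary", {
  # all rules satisfied: 2+2 reads, agreeing alt, qual 30, margin 60,
  # offset 20, 1 mismatch
  expect_equal(consensus_call(make_bundle())$outcome, "variant")
  expect_equal(consensus_call(make_bundle())$alt, "T")

  # one read short on a strand
  r <- consensus_call(make_bundle(n1 = 1, n2 = 2))
  expect_equal(r$outcome, "rejected")
  expect_equal(r$reason, "incomplete_bundle")
  expect_false(r$interrogated)

  # call 5 bp from the read end
  r <- consensus_call(make_bundle(offset = 5))
  expect_equal(r$reason, "read_end")
  # boundary: 8 bp is allowed
  expect_equal(consensus_call(make_bundle(offset = 8))$outcome, "variant")

  # alignment-score margin must exceed 50
  expect_equal(consensus_call(make_bundle(margin = 50))$reason,
               "alignment_margin")
  expect_equal(consensus_call(make_bundle(margin = 51))$outcome, "variant")

  # at most two mismatches per read
  expect_equal(consensus_call(make_bundle(mismatches = 3))$reason,
               "mismatch")
  expect_equal(consensus_call(make_bundle(mismatches = 2))$outcome,
               "variant")

  # consensus quality >= 6; a low-quality rejection is still interrogated
  r <- consensus_call(make_bundle(qual = 5))
  expect_equal(r$reason, "low_quality")
  expect_true(r$interrogated)
  expect_equal(consensus_call(make_bundle(qual = 6))$outcome, "variant")

  # strand disagreement or reference consensus is not a variant
  expect_equal(consensus_call(make_bundle(base2 = "A"))$outcome,
               "reference")
  expect_equal(consensus_call(make_bundle(base1 = "A", base2 = "A",
                                          ref = "A"))$outcome, "reference")
  # within-strand disagreement: no strand consensus
  b <- make_bundle()
  b$reads$base[1] <- "G"
  expect_equal(consensus_call(b)$outcome, "reference")
})

test_that("rule order changes the reason at most, never the outcome", {
  # a bundle failing several rules at once is rejected whichever rule is
  # checked first; the canonical order reports the earliest rule
  b <- make_bundle(n1 = 1, offset = 3, margin = 10, mismatches = 5)
  r <- consensus_call(b)
  expect_equal(r$outcome, "rejected")
  expect_equal(r$reason, "incomplete_bundle")
  # dropping the completeness failure exposes the next rule
  r2 <- consensus_call(make_bundle(offset = 3, margin = 10, mismatches = 5))
  expect_equal(r2$outcome, "rejected")
  expect_equal(r2$reason, "alignment_margin")
})

test_that("vectorised consensus agrees with the single-bundle caller", {
  cfg <- simulation_config(mode = "comb", n_clones = 5, private_mean = 300)
  tree <- simulate_phylogeny(cfg, seed = 3)
  set <- simulate_duplex_bundles(tree, 5e7, error_rate = 1e-3, seed = 4)
  res <- clonarch:::consensus_call_set(set)
  for (i in seq_len(nrow(set$bundles))) {
    bid <- set$bundles$bundle_id[i]
    one <- consensus_call(list(
      ref = set$bundles$ref[i],
      reads = set$reads[set$reads$bundle_id == bid, ]
    ))
    expect_equal(res$outcome[i], one$outcome)
    expect_equal(res$interrogated[i], one$interrogated)
  }
})

test_that("error-free complete bundles give exactly zero false calls", {
  cfg <- simulation_config(mode = "comb", n_clones = 10, private_mean = 100)
  tree <- simulate_phylogeny(cfg, seed = 9)
  set <- simulate_duplex_bundles(tree, 1e6, error_rate = 0, seed = 9,
                                 meta = duplex_meta_clean(),
                                 explicit_background = TRUE)
  res <- clonarch:::consensus_call_set(set)
  truth <- !is.na(set$bundles$true_alt)
  called <- res$outcome == "variant"
  # exhaustive: every interrogated mutant bundle-base is called, and no
  # reference bundle-base ever is
  expect_identical(called[res$interrogated], truth[res$interrogated])
  expect_equal(sum(called & !truth), 0L)
})

test_that("double-strand error rate stays below the analytic bound", {
  # independent per-read errors: both single-read strands showing the
  # same wrong base has probability 3*(e/3)^2 = e^2/3 <= e^2 per base
  cfg <- simulation_config(mode = "comb", trunk_range = c(0, 0),
                           private_mean = 0, n_clones = 2)
  tree <- simulate_phylogeny(cfg, seed = 1)
  e <- 0.05
  set <- simulate_duplex_bundles(tree, 1e6, error_rate = e, seed = 1,
                                 reads_per_strand = 1L,
                                 meta = duplex_meta_clean(),
                                 explicit_background = TRUE)
  s1 <- set$reads[set$reads$strand == 1L, ]
  s2 <- set$reads[set$reads$strand == 2L, ]
  stopifnot(identical(s1$bundle_id, s2$bundle_id))
  ref <- set$bundles$ref[match(s1$bundle_id, set$bundles$bundle_id)]
  fp <- s1$base == s2$base & s1$base != ref
  expect_lte(mean(fp), e^2)
  # and the rate is in the right ballpark, not merely tiny
  expect_gt(mean(fp), e^2 / 3 / 3)
})

test_that("duplex burden is the scaled call rate with a Poisson interval", {
  tree <- simulate_phylogeny(
    simulation_config(mode = "comb", n_clones = 2, private_mean = 10),
    seed = 1
  )
  set <- simulate_duplex_bundles(tree, 1e6, error_rate = 0, seed = 2,
                                 meta = duplex_meta_clean())
  res <- clonarch:::consensus_call_set(set)
  calls <- sum(res$outcome == "variant")
  interrogated <- sum(res$interrogated) + set$n_background_interrogated
  est <- duplex_burden(set, diploid_genome_size = 6.2e9)
  expect_equal(est$burden, calls / interrogated * 6.2e9)
  expect_true(est$ci[1] <= est$burden && est$burden <= est$ci[2])

  # stated example: 10 calls over 1e9 interrogated bases -> 62 per genome
  expect_equal(10 / 1.0e9 * 6.2e9, 62)

  # burden is invariant to shuffling bundle order
  set2 <- set
  set.seed(99)
  perm <- sample(nrow(set2$bundles))
  set2$bundles <- set2$bundles[perm, ]
  set2$reads <- set2$reads[sample(nrow(set2$reads)), ]
  expect_equal(duplex_burden(set2)$burden, duplex_burden(set)$burden)
})

test_that("zero calls give a zero estimate with a positive upper bound", {
  cfg <- simulation_config(mode = "comb", trunk_range = c(0, 0),
                           private_mean = 0, n_clones = 2)
  tree <- simulate_phylogeny(cfg, seed = 1)
  set <- simulate_duplex_bundles(tree, 1e6, error_rate = 0, seed = 1)
  est <- duplex_burden(set)
  expect_equal(est$burden, 0)
  expect_gt(est$ci[2], 0)
})

test_that("contamination adjustment recovers the stated arithmetic", {
  est <- burden_estimate(100, "duplex", 100L, 6.2e9, genome_size = 6.2e9)
  expect_identical(contamination_adjusted_burden(est, 0, 50)$burden, 100)
  adj <- contamination_adjusted_burden(est, 0.2, 50)
  expect_equal(adj$burden, 112.5)
  expect_true(adj$adjusted)
  expect_error(contamination_adjusted_burden(est, 1, 50), "fraction")
})

test_that("contamination-adjusted burden recovers truth under admixture", {
  # tumour at per-cell burden ~111 mixed with 20% normal cells carrying
  # none of the tumour mutations: adjusting the diluted estimate recovers
  # the tumour burden
  cfg <- simulation_config(mode = "comb", trunk_range = c(11, 11),
                           private_mean = 100, n_clones = 20, purity = 0.8)
  ests <- vapply(1:50, function(s) {
    tree <- simulate_phylogeny(cfg, seed = s)
    truthful <- true_per_cell_burden(tree)
    # cells drawn for duplex include the normal fraction: observed burden
    # is (1 - f) * tumour burden; emulate by scaling carrier fractions
    tree$nodes$fraction[tree$nodes$leaf] <-
      tree$nodes$fraction[tree$nodes$leaf] * 0.8
    tree$nodes <- rbind(tree$nodes, data.frame(
      id = max(tree$nodes$id) + 1L, parent = 1L, leaf = TRUE,
      clone = "NORM", fraction = 0.2
    ))
    set <- simulate_duplex_bundles(tree, 2e9, error_rate = 1e-3, seed = s)
    obs <- duplex_burden(set)
    adj <- contamination_adjusted_burden(obs, 0.2, 0)
    adj$burden / truthful
  }, numeric(1))
  expect_lte(abs(mean(ests) - 1), 0.05)
})
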