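test_that("the same seed reproduces the community bit for bit", {
  p <- sim_params(n_species = 4, n_reads = 3000, seed = 99, error_rate = 0.002)
  s1 <- simulate_community(p)
  s2 <- simulate_community(p)
  expect_identical(s1$seqs, s2$seqs)
  expect_identical(s1$truth$haplotypes, s2$truth$haplotypes)
  expect_identical(s1$error_config$conserved_positions,
                   s2$error_config$conserved_positions)
  # a different seed gives a different community
  s3 <- simulate_community(sim_params(n_species = 4, n_reads = 3000, seed = 100,
                                      error_rate = 0.002))
  expect_false(identical(s1$seqs$sequence, s3$seqs$sequence))
})

test_that("a noiseless single-haplotype community is one unique sequence", {
  sim <- simulate_community(sim_params(n_species = 1, haplotypes_per_species = 1,
                                       n_reads = 1000, seed = 3, error_rate = 0))
  expect_equal(nrow(sim$seqs), 1L)
  expect_equal(sim$seqs$count, 1000L)
  expect_false(sim$truth$provenance$is_error)
})

test_that("observed reads always total n_reads and provenance covers every sequence", {
  for (seed in 1:3) {
    sim <- simulate_community(sim_params(n_species = 5, n_reads = 8000, seed = seed,
                                         error_rate = 0.003))
    expect_equal(sum(sim$seqs$count), 8000L)
    expect_setequal(sim$truth$provenance$id, sim$seqs$id)
    # error flags agree with membership in the true haplotype set
    is_true_hap <- sim$seqs$sequence %in% sim$truth$haplotypes$sequence
    expect_equal(!sim$truth$provenance$is_error[match(sim$seqs$id,
                                                      sim$truth$provenance$id)],
                 is_true_hap)
  }
})

test_that("error-free denoise-safe communities are recovered exactly, all modes", {
  sim <- simulate_community(sim_params(n_species = 8, n_reads = 20000, seed = 11,
                                       denoise_safe = TRUE))
  expect_setequal(sim$seqs$sequence, sim$truth$haplotypes$sequence)
  modes <- list(denoise_params(),
                denoise_params(mode = "two_phase", criterion = "distance"),
                denoise_params(entropy_correction = TRUE))
  for (pp in modes) {
    sc <- score_recovery(denoise(sim$seqs, pp), sim$truth)
    expect_equal(sc$recall, 1)
    expect_equal(sc$precision, 1)
  }
})

test_that("clean haplotype pools concentrate entropy in third positions", {
  e2_lt_e3 <- vapply(1:20, function(seed) {
    sim <- simulate_community(sim_params(n_species = 6, haplotypes_per_species = 4,
                                         n_reads = 5000, seed = seed))
    hap <- make_ds(sim$truth$haplotypes$true_count, sim$truth$haplotypes$sequence,
                   sim$truth$haplotypes$hap_id)
    p <- positional_entropy(hap)
    p$e3 > p$e2
  }, logical(1))
  expect_true(all(e2_lt_e3))
})

test_that("uniform errors inflate the entropy ratio of the raw dataset", {
  worse <- vapply(1:20, function(seed) {
    sim <- simulate_community(sim_params(n_species = 5, n_reads = 10000, seed = seed,
                                         error_rate = 0.002))
    hap <- make_ds(sim$truth$haplotypes$true_count, sim$truth$haplotypes$sequence,
                   sim$truth$haplotypes$hap_id)
    entropy_ratio(positional_entropy(sim$seqs)) >
      entropy_ratio(positional_entropy(hap))
  }, logical(1))
  expect_true(all(worse))
})

test_that("entropy correction never hurts haplotype recall on third-position variation", {
  # strong within-species skew puts sibling haplotypes below the merge
  # threshold at d = 1; the correction must rescue third-position variants
  deltas <- vapply(1:20, function(seed) {
    sim <- simulate_community(sim_params(n_species = 10, haplotypes_per_species = 3,
                                         intra_species_substitutions = 1,
                                         within_species_skew = 0.98,
                                         n_reads = 1e5, seed = seed))
    plain <- score_recovery(denoise(sim$seqs, denoise_params(alpha = 5)), sim$truth)
    corr <- score_recovery(denoise(sim$seqs, denoise_params(alpha = 5,
                                                            entropy_correction = TRUE)),
                           sim$truth)
    expect_gte(corr$recall, plain$recall)
    corr$recall - plain$recall
  }, numeric(1))
  expect_gt(mean(deltas), 0)  # the correction must actually rescue variants
})

test_that("recovery scores count verbatim haplotype matches", {
  haps <- data.frame(species_id = 1, hap_id = sprintf("h%d", 1:9),
                     sequence = replicate(9, random_sequence(12)),
                     true_count = 10)
  truth <- list(haplotypes = haps,
                provenance = data.frame(id = haps$hap_id, sequence = haps$sequence,
                                        source_hap = haps$hap_id, species_id = 1,
                                        is_error = FALSE, count = 10))
  perfect <- make_ds(rep(10, 9), haps$sequence, haps$hap_id)
  sc <- score_recovery(perfect, truth)
  expect_equal(sc$recall, 1); expect_equal(sc$precision, 1)
  spurious <- rbind(perfect, data.frame(id = "bad", count = 1L,
                                        sequence = random_sequence(12)))
  expect_equal(score_recovery(spurious, truth)$precision, 0.9)
  none <- make_ds(integer(0), character(0), character(0))
  sc0 <- score_recovery(none, truth)
  expect_equal(sc0$recall, 0)
  expect_true(is.na(sc0$precision))
})

test_that("species-level MOTU recall requires pure single-MOTU species", {
  sim <- simulate_community(sim_params(n_species = 6, n_reads = 10000, seed = 21,
                                       denoise_safe = TRUE))
  ms <- cluster_motus(sim$seqs, d = 13)
  sc <- score_recovery(sim$seqs, sim$truth, motus = ms)
  expect_equal(sc$motu_recall, 1)
  # lumping everything into one MOTU destroys species-level recall
  lumped <- cluster_motus(sim$seqs, d = 313)
  expect_lt(score_recovery(sim$seqs, sim$truth, motus = lumped)$motu_recall, 1)
})

test_that("infeasible divergence is rejected", {
  expect_error(sim_params(fragment_length = 30, inter_species_divergence = 40),
               "infeasible")
})
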