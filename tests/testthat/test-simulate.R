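test_that("generation is bit-identical for a fixed seed", {
  cfg <- sim_config(seed = 1, n_mirna = 50, n_mrna = 80, n_direct = 3,
                    n_indirect = 8, n_early_transient = 4, n_true_pairs = 6,
                    n_decoy = 20, n_background_mrna = 10)
  a <- simulate_timecourse(cfg)
  b <- simulate_timecourse(cfg)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$mrna$detection_p, b$mrna$detection_p)
  expect_identical(a$pairs$pairs, b$pairs$pairs)
  expect_identical(a$truth$true_pairs, b$truth$true_pairs)
  # a different seed changes the data
  c2 <- simulate_timecourse(sim_config(seed = 2, n_mirna = 50, n_mrna = 80,
                                       n_direct = 3, n_indirect = 8,
                                       n_early_transient = 4,
                                       n_true_pairs = 6, n_decoy = 20,
                                       n_background_mrna = 10))
  expect_false(identical(a$mirna$values, c2$mirna$values))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_mirna = 10, n_direct = 8, n_indirect = 8),
               "panel holds")
  expect_error(sim_config(n_mrna = 10, n_true_pairs = 8,
                          n_background_mrna = 8), "panel holds")
  expect_error(sim_config(delta = -1), "non-negative")
  expect_error(sim_config(detection_fail_rate = 1.2), "detection_fail_rate")
})

test_that("emitted matrices are consistent with the declared truth", {
  sim <- simulate_timecourse(sim_config(seed = 4))
  cfg <- sim$truth$config
  expect_equal(length(sim$truth$direct_mirna), cfg$n_direct)
  expect_equal(nrow(sim$truth$true_pairs), cfg$n_true_pairs)
  expect_equal(nrow(sim$pairs$pairs), cfg$n_true_pairs + cfg$n_decoy)
  expect_true(all(sim$truth$true_pairs$miRNA %in% sim$truth$direct_mirna))
  expect_true(all(sim$truth$true_pairs$lag %in% cfg$lag_choices))
  expect_true(all(sim$pairs$pairs$miRNA %in% rownames(sim$mirna$values)))
  expect_equal(sim$truth$spread, sqrt(2) * cfg$noise_sd)
  # low-abundance genes are mostly unauthentic, expressed genes mostly not
  low <- sim$truth$low_expr$miRNA
  expect_gt(mean(sim$mirna$detection_p[low, ] >= 0.01), 0.7)
  other <- setdiff(rownames(sim$mirna$values), low)
  expect_lt(mean(sim$mirna$detection_p[other, ] >= 0.01), 0.02)
})

test_that("null dataset has no planted structure and calibrated call rate", {
  sim <- null_dataset(sim_config(seed = 6))
  expect_length(sim$truth$direct_mirna, 0)
  expect_equal(nrow(sim$truth$true_pairs), 0L)
  expect_equal(nrow(sim$pairs$pairs), 200L)

  # responsive fraction of expressed genes matches the closed-form type-I
  # rate of the discretization: per point, z_k = (N_k - w)/sqrt(2) with a
  # shared baseline draw w, flagged when |z_k| >= 2.576; integrate over w.
  pre_mi <- preprocess_tsm(sim$mirna)$tsm
  pre_m <- preprocess_tsm(sim$mrna)$tsm
  disc_mi <- discretize_profiles(pre_mi, spread = sim$truth$spread)
  disc_m <- discretize_profiles(pre_m, spread = sim$truth$spread)
  obs <- mean(c(disc_mi$responsive, disc_m$responsive))
  thr <- qnorm(1 - 0.01 / 2) * sqrt(2)
  p_resp <- integrate(function(w) {
    q <- pnorm(w - thr) + pnorm(-w - thr)
    dnorm(w) * (1 - (1 - q)^9)
  }, -Inf, Inf)$value
  n_tot <- length(disc_mi$responsive) + length(disc_m$responsive)
  # quantile-mapping jitter and sporadic dropout push the observed rate a
  # little above the i.i.d. oracle; allow binomial noise plus that margin
  tol <- 4 * sqrt(p_resp * (1 - p_resp) / n_tot) + 0.02
  expect_lt(abs(obs - p_resp), tol)
})

test_that("default conditions make the planted structure detectable", {
  sim <- simulate_timecourse(sim_config(seed = 8))
  pre <- preprocess_tsm(sim$mirna)
  disc <- discretize_profiles(pre$tsm, spread = sim$truth$spread)
  # nearly all low-abundance genes are filtered out
  expect_lt(mean(sim$truth$low_expr$miRNA %in% rownames(pre$tsm$values)),
            0.3)
  expect_true(all(sim$truth$direct_mirna %in%
                    disc$gene_ids[disc$responsive]))
  # second burst of the count curve at the planted discriminator
  td <- find_time_discriminator(differential_count_curve(disc))
  expect_equal(td$tau, sim$truth$tau)
  # direct miRNAs out-score the bulk of the late indirect responders
  # (an occasional corrupted-baseline gene can reach a high score, so the
  # comparison is against the indirect median, not the maximum)
  rs <- response_scores(disc)
  rs_direct <- rs$rs[rs$gene_id %in% sim$truth$direct_mirna]
  rs_indirect <- rs$rs[rs$gene_id %in% sim$truth$indirect_mirna]
  expect_gt(min(rs_direct), median(rs_indirect))
})
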