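test_that("odds ratio closed forms, including the degenerate case", {
  expect_equal(contingency_or(10, 10, 10, 10)$or, 1)
  expect_equal(contingency_or(20, 5, 5, 20)$or, 16)
  expect_true(is.na(contingency_or(3, 0, 2, 5)$or))
  # OR is invariant under swapping (a<->d, b<->c)
  set.seed(12)
  for (i in 1:20) {
    n <- sample(1:500, 4)
    expect_equal(contingency_or(n[1], n[2], n[3], n[4])$or,
                 contingency_or(n[4], n[3], n[2], n[1])$or)
  }
})

test_that("global OR counts (pair, time) units against a hand oracle", {
  e_mi <- rbind(m1 = c(1, 1, 0, 0, 0, 0, 0, 0, 0),
                m2 = rep(0L, 9))
  e_m <- rbind(g1 = c(1, 0, 0, 0, 0, 0, 0, 0, 0),
               g2 = c(0, 0, 1, 1, 0, 0, 0, 0, 0))
  disc_mi <- structure(list(e = e_mi, responsive = c(TRUE, FALSE),
                            gene_ids = rownames(e_mi), species = "miRNA",
                            threshold = 20), class = "discretized")
  disc_m <- structure(list(e = e_m, responsive = c(TRUE, TRUE),
                           gene_ids = rownames(e_m), species = "mRNA",
                           threshold = 20), class = "discretized")
  pairs <- data.frame(miRNA = c("m1", "m2"), mRNA = c("g1", "g2"))
  # pair (m1,g1): a=1 (k=1), b=1 (k=2), c=0, d=7
  # pair (m2,g2): a=0, b=0, c=2, d=7
  or <- global_or(pairs, disc_mi, disc_m)
  expect_equal(or$a, 1); expect_equal(or$b, 1)
  expect_equal(or$c, 2); expect_equal(or$d, 14)
  expect_equal(or$total, 2 * 9)
  expect_error(global_or(pairs[0, ], disc_mi, disc_m), "empty")
})

test_that("correspondence weight: closed forms of the lag decomposition", {
  z9 <- rep(0L, 9)
  expect_equal(correspondence_weight(z9, z9)$E, 0)
  all9 <- rep(1L, 9)
  w <- correspondence_weight(all9, -all9, beta = 0.5, lag_max = 3)
  expect_equal(w$E0, 1)
  expect_equal(w$E_lag, c(1, 1, 1))
  expect_equal(w$E, 1.875)
  # miRNA differential only at k=1, mRNA only at k=2
  e_mi <- c(1L, rep(0L, 8)); e_m <- c(0L, -1L, rep(0L, 7))
  w2 <- correspondence_weight(e_mi, e_m, beta = 0.5, lag_max = 3)
  expect_equal(w2$E0, 0)
  expect_equal(w2$E_lag[1], 1 / 8)
  expect_equal(w2$E, 1 / 16)
  expect_error(correspondence_weight(rep(0L, 9), rep(0L, 8)), "length")
})

test_that("modulation score is E * |Fisher z| with the sign kept aside", {
  x <- seq_len(10)
  e <- rep(1L, 9)
  # exactly orthogonal profile: r = 0 so ms = 0 whatever E is
  set.seed(77)
  y0 <- residuals(lm(rnorm(10) ~ x))
  rec0 <- modulation_score(x, y0, e, e)
  expect_equal(rec0$ms, 0)
  # exact closed form at r = tanh(1)
  set.seed(5)
  a <- rnorm(10)
  rec <- modulation_score(a, a, rep(1L, 9), rep(1L, 9), beta = 0)
  expect_equal(rec$E, 1)            # beta 0 kills lag terms, E0 = 1
  expect_equal(rec$ms, abs(atanh(1 - 1e-6)))
  # linear in E for fixed r; sign tracks r
  b <- -2 * a + rnorm(10, sd = 0.01)
  r1 <- modulation_score(a, b, rep(1L, 9), rep(1L, 9), beta = 0)
  r2 <- modulation_score(a, b, rep(1L, 9), rep(1L, 9), beta = 0.5)
  expect_equal(r2$ms / r1$ms, r2$E / r1$E)
  expect_equal(r1$sign, -1)
  expect_warning(modulation_score(rep(1, 10), a, e, e), "zero-variance")
})

test_that("ms is monotone in |r| for fixed E", {
  e <- rep(1L, 9)
  x <- seq_len(10)
  prev <- -1
  for (r in c(0.1, 0.3, 0.6, 0.9, 0.99)) {
    # construct y with exact correlation r against x
    xs <- scale(x)[, 1]
    resid <- scale(residuals(lm(rnorm(10) ~ xs)))[, 1]
    y <- r * xs + sqrt(1 - r^2) * resid
    rec <- modulation_score(x, y, e, e, beta = 0)
    expect_gt(rec$ms, prev)
    prev <- rec$ms
  }
})

test_that("permutation p obeys the add-one rule and granularity", {
  # strongly matched pair: observed ms should beat every null draw
  set.seed(9)
  mi <- c(0, 0, 0, rep(2, 7)) + rnorm(10, sd = 0.05)
  m <- c(0, 0, 0, rep(-2, 7)) + rnorm(10, sd = 0.05)
  e_mi <- c(0L, 0L, rep(1L, 7)); e_m <- c(0L, 0L, rep(-1L, 7))
  p <- permutation_pvalue(mi, m, e_mi, e_m, n_perm = 999)
  expect_true(as.numeric(p) >= 1 / 1000)
  k <- as.numeric(p) * 1000          # add-one rule: p is a multiple of 1/1000
  expect_equal(k, round(k))
  # ms = 0 (zero correspondence weight) can never beat any null: p = 1
  p1 <- permutation_pvalue(rnorm(10), rnorm(10), rep(0L, 9), rep(0L, 9),
                           n_perm = 199)
  expect_equal(as.numeric(p1), 1)
  expect_error(permutation_pvalue(mi, m, e_mi, e_m, n_perm = 10), "100")
})

test_that("permutation p-values are uniform under the null", {
  set.seed(31)
  ps <- replicate(300, {
    x <- rnorm(10); y <- rnorm(10)
    e1 <- sample(c(-1L, 0L, 1L), 9, TRUE)
    e2 <- sample(c(-1L, 0L, 1L), 9, TRUE)
    as.numeric(permutation_pvalue(x, y, e1, e2, n_perm = 400))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("BH q-values match hand computation and the boundary is inclusive", {
  expect_equal(fdr_qvalues(0.03), 0.03)
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_qvalues(rep(1, 5)), rep(1, 5))
  rec <- data.frame(miRNA = c("a", "a", "b"), mRNA = c("x", "y", "z"),
                    q = c(0.1, 0.2, 0.3))
  out <- select_targets(rec, q_max = 0.2)
  expect_identical(out$selected, c(TRUE, TRUE, FALSE))
  tab <- attr(out, "targets_per_mirna")
  expect_equal(unname(tab["a"]), 2L, ignore_attr = TRUE)
  expect_identical(select_targets(rec[0, ], 0.2)$selected, logical(0))
})

test_that("score_pairs gates on joint responsiveness and orders by q", {
  sim <- simulate_timecourse(sim_config(seed = 3, n_mirna = 80, n_mrna = 120,
                                        n_direct = 4, n_indirect = 10,
                                        n_early_transient = 4,
                                        n_true_pairs = 8, n_decoy = 30,
                                        n_background_mrna = 20))
  pre_mi <- preprocess_tsm(sim$mirna)$tsm
  pre_m <- preprocess_tsm(sim$mrna)$tsm
  disc_mi <- discretize_profiles(pre_mi, spread = sim$truth$spread)
  disc_m <- discretize_profiles(pre_m, spread = sim$truth$spread)
  out <- score_pairs(sim$pairs, pre_mi, pre_m, disc_mi, disc_m,
                     n_perm = 500, seed = 3)
  resp_mi <- disc_mi$gene_ids[disc_mi$responsive]
  resp_m <- disc_m$gene_ids[disc_m$responsive]
  expect_true(all(out$miRNA %in% resp_mi))
  expect_true(all(out$mRNA %in% resp_m))
  expect_false(is.unsorted(out$q, na.rm = TRUE))
  expect_true(all(out$p > 0 & out$p <= 1, na.rm = TRUE))
  expect_identical(out$selected, !is.na(out$q) & out$q <= 0.2)
  # identical seed reproduces identical p-values
  out2 <- score_pairs(sim$pairs, pre_mi, pre_m, disc_mi, disc_m,
                      n_perm = 500, seed = 3)
  expect_identical(out$p, out2$p)
})
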