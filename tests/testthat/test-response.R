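test_that("differential-count curve counts non-zero calls per time point", {
  e <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0, 0),
             c(0, 0, -1, 0, 0, 0, 0, 0, 0),
             c(1, 0, -1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(differential_count_curve(e)),
               c(2L, 0L, 2L, rep(0L, 6)))
  expect_equal(unname(differential_count_curve(matrix(0L, 2, 9))),
               rep(0L, 9))
})

test_that("time discriminator sits at the second burst of the count curve", {
  cv <- c(3, 4, 4, 5, 15, 16, 17, 40, 41)
  # forward differences (1,0,1,10,1,1,23,1): strict interior maxima at
  # k = 5 and k = 8, so tau is the second one
  td <- find_time_discriminator(cv)
  expect_equal(td$bursts, c(5L, 8L))
  expect_equal(td$tau, 8L)
  expect_error(find_time_discriminator(c(1, 2, 3, 4, 5, 6, 7, 8, 9)), "tau")
  expect_error(find_time_discriminator(rep(4, 9)), "burst")
})

test_that("Response Score matches the analytic cases", {
  expect_equal(response_score(rep(1L, 9))$rs, 45L)
  expect_equal(response_score(rep(-1L, 9))$rs, 45L)
  expect_equal(response_score(rep(0L, 9))$rs, 0L)
  expect_true(is.na(response_score(rep(0L, 9))$direction))
  # late opposite call: 9 - Int(1/2) = 9
  expect_equal(response_score(c(1, 0, 0, 0, 0, 0, 0, 0, -1))$rs, 9L)
  # immediate alternation: 9 - Int(8/2) = 5
  r <- response_score(c(1, -1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(r$rs, 5L)
  expect_equal(r$direction, "induced")
  expect_equal(r$first_index, 1L)
})

test_that("vectorized Response Score agrees with the brute-force evaluator", {
  set.seed(21)
  e <- matrix(sample(c(-1L, 0L, 1L), 500 * 9, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), 500, 9)
  got <- response_score(e)$rs
  want <- apply(e, 1, rs_brute)
  expect_equal(got, unname(want))
})

test_that("candidate selection takes the top fraction with inclusive ties", {
  rec <- data.frame(gene_id = sprintf("g%02d", 1:10), rs = 10:1,
                    direction = "induced", first_index = 1L)
  sel <- select_candidates(rec, fraction = 0.10)
  expect_equal(sel$threshold, 10L)
  expect_equal(nrow(sel$candidates), 1L)
  # ties at the threshold are all included
  rec$rs <- c(9, 9, 9, 7:1)
  sel2 <- select_candidates(rec, fraction = 0.10)
  expect_equal(sel2$threshold, 9)
  expect_equal(nrow(sel2$candidates), 3L)
  # fraction 1 returns everything
  expect_equal(nrow(select_candidates(rec, 1)$candidates), 10L)
  # empty input
  expect_equal(nrow(select_candidates(rec[0, ], 0.1)$candidates), 0L)
})

test_that("early/late classification respects tau", {
  e <- rep(0L, 9)
  e[1] <- 1L
  expect_equal(classify_early_late(e, 6), "early-only")
  e[7] <- -1L
  expect_equal(classify_early_late(e, 6), "both")
  expect_equal(classify_early_late(c(rep(0L, 7), 1L, 0L), 6), "late-only")
  expect_error(classify_early_late(rep(0L, 9), 6), "responsive")
})

test_that("ARE enrichment comparison: exact mid-p rank sum", {
  # symmetric null: identical groups score one half
  expect_equal(are_enrichment_compare(c(2, 3, 4), c(2, 3, 4)), 0.5)
  expect_equal(are_enrichment_compare(1, 1), 0.5)
  # fully separated small groups: obs is the unique maximum of the 20
  # assignments, mid-p = 0.5/20
  p <- are_enrichment_compare(c(9, 8, 7), c(1, 0, 1))
  expect_equal(p, 0.025)
  expect_lt(p, 0.05)
  expect_error(are_enrichment_compare(numeric(0), 1), "non-empty")
  # large groups fall back to the normal approximation and stay one-sided
  set.seed(1)
  big_hi <- rpois(40, 8)
  big_lo <- rpois(40, 2)
  expect_lt(are_enrichment_compare(big_hi, big_lo), 0.001)
  expect_gt(are_enrichment_compare(big_lo, big_hi), 0.9)
})
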