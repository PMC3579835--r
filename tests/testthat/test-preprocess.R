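test_that("quantile normalization matches the rank/mean oracle", {
  # identical columns are left untouched
  x <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantile_normalize(x), x)
  # columns (1,2) and (3,4) both become (2,3)
  y <- quantile_normalize(cbind(c(1, 2), c(3, 4)))
  expect_equal(unname(y), cbind(c(2, 3), c(2, 3)))
  # within-column ties get the mean of the reference over the tied ranks:
  # ref = (1.5, 2, 4.5) so the tie (1,1) maps to mean(1.5, 2) = 1.75
  z <- quantile_normalize(cbind(c(1, 1, 5), c(2, 3, 4)))
  expect_equal(unname(z), cbind(c(1.75, 1.75, 4.5), c(1.5, 2, 4.5)))
})

test_that("quantile normalization agrees with limma on tie-free data and
           equalizes column distributions", {
  set.seed(42)
  x <- matrix(rnorm(300), 30, 10)
  qn <- quantile_normalize(x)
  # all columns share one sorted multiset, to machine precision
  ref <- sort(qn[, 1])
  for (j in 2:10) expect_equal(sort(qn[, j]), ref)
  # rank order preserved within columns
  for (j in 1:10) expect_identical(order(qn[, j]), order(x[, j]))
  skip_if_not_installed("limma")
  expect_equal(qn, limma::normalizeQuantiles(x, ties = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("quantile normalization rejects non-finite cells", {
  x <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  x[2, 1] <- NaN
  expect_error(quantile_normalize(x), "non-finite")
})

test_that("amendment floors unauthentic cells at the per-array authentic minimum", {
  tsm <- make_tsm(3, seed = 2)
  tsm$values[, 1] <- c(5.3, -12, 150)
  tsm$detection_p[, 1] <- c(0.005, 0.2, 0.2)
  res <- amend_unauthentic(tsm)
  min_au1 <- min(tsm$values[tsm$detection_p[, 1] < 0.01, 1])
  expect_equal(unname(res$report$min_au[1]), min_au1)
  expect_equal(unname(res$tsm$values[1, 1]), 5.3)               # authentic kept
  expect_equal(unname(res$tsm$values[2, 1]), max(-12, min_au1)) # floored
  expect_equal(unname(res$tsm$values[3, 1]), 150)               # above floor
})

test_that("amendment is idempotent and monotone", {
  set.seed(11)
  tsm <- make_tsm(20, seed = 11, noise = 1)
  # ~1/4 of cells unauthentic, the rest clearly authentic
  dp <- ifelse(matrix(runif(200), 20, 10) < 0.25,
               runif(200, 0.01, 1), runif(200, 0, 0.009))
  tsm$detection_p <- matrix(dp, 20, 10, dimnames = dimnames(tsm$detection_p))
  once <- amend_unauthentic(tsm)
  twice <- amend_unauthentic(once$tsm)
  expect_identical(twice$tsm$values, once$tsm$values)
  expect_equal(twice$report$amended_cell_count, 0)
  expect_true(all(once$tsm$values >= tsm$values))
})

test_that("an array with no authentic cell is an error", {
  tsm <- make_tsm(3)
  tsm$detection_p[, 4] <- 0.5
  expect_error(amend_unauthentic(tsm), "min_au")
})

test_that("gene filter boundary: more than 5 unauthentic cells excludes", {
  tsm <- make_tsm(3, seed = 5)
  tsm$detection_p[1, 1:6] <- 0.5   # 6 unauthentic -> removed
  tsm$detection_p[2, 1:5] <- 0.5   # exactly 5 -> retained
  res <- filter_genes(tsm)
  expect_identical(res$report$removed_gene_ids, "g01")
  expect_identical(rownames(res$tsm$values), c("g02", "g03"))
  expect_equal(res$report$n_removed + res$report$n_retained, 3L)
})

test_that("preprocess chain respects stage order and reports consistently", {
  tsm <- make_tsm(10, seed = 9, noise = 0.5)
  tsm$detection_p[1, ] <- 0.5      # fully unauthentic gene, to be removed
  res <- preprocess_tsm(tsm)
  expect_false("g01" %in% rownames(res$tsm$values))
  expect_equal(res$report$n_removed + res$report$n_retained, 10L)
  # normalized output: identical sorted columns
  s1 <- unname(sort(res$tsm$values[, 1]))
  expect_equal(unname(sort(res$tsm$values[, 5])), s1)
  # alternative order runs and yields the same retained set here
  res2 <- preprocess_tsm(tsm, order = c("quantile", "amend", "filter"))
  expect_setequal(rownames(res2$tsm$values), rownames(res$tsm$values))
})
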