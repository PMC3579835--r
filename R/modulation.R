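#' Odds ratio from the four global contingency counts
#'
#' Over every (predicted pair, post-baseline time point) unit: `a` counts
#' units where both the miRNA and the mRNA are differential, `b` miRNA
#' only, `c` mRNA only, `d` neither.  `OR = a d / (b c)`; OR > 1 means the
#' predicted target mRNAs change expression together with their miRNAs
#' more often than expected, i.e. miRNAs globally modulate their predicted
#' targets.
#'
#' @param a,b,c,d Non-negative counts.
#' @return Object of class `"or_counts"`: the counts, `total`, and `or`
#'   (`NA` when `b * c == 0`, in which case the ratio is undefined).
#' @examples
#' contingency_or(12845, 9091, 9625, 10922)$or  # about 1.6
#' @export
contingency_or <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  or <- if (b * c == 0) NA_real_ else (a * d) / (b * c)
  structure(list(a = a, b = b, c = c, d = d, total = a + b + c + d, or = or),
            class = "or_counts")
}

#' @export
print.or_counts <- function(x, ...) {
  cat("Contingency over (pair, time) units: a=", x$a, " b=", x$b,
      " c=", x$c, " d=", x$d, " (total ", x$total, ")\n", sep = "")
  cat("  OR =", if (is.na(x$or)) "undefined (b*c = 0)" else
    format(round(x$or, 3)), "\n")
  invisible(x)
}

#' Global modulation odds ratio over a predicted pair set
#'
#' @param pairs A [predicted_pair_set()] or a data frame with columns
#'   `miRNA` and `mRNA`.
#' @param mirna_disc,mrna_disc [discretize_profiles()] results for the two
#'   panels; pairs whose members are missing from a panel are dropped and
#'   counted in `n_unmatched`.
#' @return An `"or_counts"` object with an extra `n_unmatched` element.
#' @export
global_or <- function(pairs, mirna_disc, mrna_disc) {
  p <- if (inherits(pairs, "pair_set")) pairs$pairs else as.data.frame(pairs)
  if (nrow(p) == 0L) stop("empty pair set")
  ok <- p$miRNA %in% rownames(mirna_disc$e) & p$mRNA %in% rownames(mrna_disc$e)
  n_unmatched <- sum(!ok)
  p <- p[ok, , drop = FALSE]
  if (nrow(p) == 0L) stop("no pair has both members in the panels")
  A <- mirna_disc$e[p$miRNA, , drop = FALSE] != 0L
  B <- mrna_disc$e[p$mRNA, , drop = FALSE] != 0L
  out <- contingency_or(sum(A & B), sum(A & !B), sum(!A & B), sum(!A & !B))
  out$n_unmatched <- n_unmatched
  out
}

#' Lag-decomposed discrete correspondence weight E
#'
#' Measures how often a predicted pair shows differential expression
#' together.  The lag-0 term is the fraction of time points at which both
#' members are differential; the lag-l term pairs the miRNA call at k with
#' the mRNA call at k + l, capturing delayed repression.  Unlike an
#' equal-weight treatment of all lags, longer lags are geometrically
#' down-weighted by `beta^l`, reflecting that a miRNA's effect on its
#' target decays with delay:
#' `E = E_0 + sum_{l=1..L} beta^l E_l`.
#'
#' @param e_mi,e_m Call vectors of equal length N for the miRNA and mRNA.
#' @param beta Geometric down-weighting of longer lags (default 0.5).
#' @param lag_max Largest lag L considered (default 3).
#' @return List with `E0`, `E_lag` (length `lag_max`) and the combined `E`.
#' @export
correspondence_weight <- function(e_mi, e_m, beta = 0.5, lag_max = 3L) {
  if (length(e_mi) != length(e_m))
    stop("'e_mi' and 'e_m' must have the same length")
  N <- length(e_mi)
  a <- e_mi != 0L
  b <- e_m != 0L
  E0 <- mean(a & b)
  E_lag <- vapply(seq_len(lag_max), function(l) {
    if (l >= N) return(0)
    mean(a[1:(N - l)] & b[(1 + l):N])
  }, numeric(1))
  list(E0 = E0, E_lag = E_lag, E = E0 + sum(beta^seq_len(lag_max) * E_lag))
}

#' Modulation Score of one predicted miRNA-mRNA pair
#'
#' `MS = E * |z|` where `z = atanh(r) = (1/2) log((1+r)/(1-r))` is the
#' Fisher transform of the Pearson correlation r between the two continuous
#' expression profiles over all N+1 time points, and E is the
#' lag-decomposed discrete correspondence weight of
#' [correspondence_weight()].  The absolute value makes induced and
#' repressed targets score alike (the interest is whether expression
#' changes track each other, not the direction); the sign of r is kept as
#' metadata.  `|r|` is clipped at `1 - 1e-6` so z stays finite.
#'
#' @param x_mi,x_m Continuous expression vectors of length N+1 (baseline
#'   included).
#' @param e_mi,e_m Call vectors of length N.
#' @inheritParams correspondence_weight
#' @return List with `r`, `z`, `E0`, `E_lag`, `E`, `ms` and `sign`; `NULL`
#'   (with a warning) when either profile has zero variance, since r is
#'   then undefined.
#' @export
modulation_score <- function(x_mi, x_m, e_mi, e_m, beta = 0.5, lag_max = 3L) {
  if (stats::sd(x_mi) == 0 || stats::sd(x_m) == 0) {
    warning("zero-variance profile; correlation undefined, record skipped")
    return(NULL)
  }
  r <- stats::cor(x_mi, x_m)
  rc <- max(min(r, 1 - 1e-6), -1 + 1e-6)
  z <- atanh(rc)
  w <- correspondence_weight(e_mi, e_m, beta = beta, lag_max = lag_max)
  list(r = r, z = z, E0 = w$E0, E_lag = w$E_lag, E = w$E,
       ms = w$E * abs(z), sign = sign(r))
}

# B x N matrix of uniform random permutations of 1..N from the current RNG
# stream (one order() call; no per-row sampling loop).
.rand_perm_matrix <- function(B, N) {
  o <- order(rep(seq_len(B), each = N), stats::runif(B * N))
  matrix((o - 1L) %% N + 1L, B, N, byrow = TRUE)
}

# Null MS draws for one pair: permute the mRNA's post-baseline time order
# (continuous values and discrete calls jointly, baseline fixed).
# perms is a B x N index matrix.  Vectorized over permutations.
.null_ms <- function(x_mi, x_m, e_mi, e_m, perms, beta = 0.5, lag_max = 3L) {
  N <- length(e_m)
  B <- nrow(perms)
  xk <- x_m[-1L]
  Xp <- cbind(x_m[1L], matrix(xk[perms], B, N))
  yc <- x_mi - mean(x_mi)
  sy <- sqrt(sum(yc^2))
  num <- as.vector(Xp %*% yc)
  sx <- sqrt(rowSums(Xp^2) - (N + 1) * rowMeans(Xp)^2)
  r <- num / (sx * sy)
  r[!is.finite(r)] <- 0
  r <- pmax(pmin(r, 1 - 1e-6), -1 + 1e-6)
  a <- as.numeric(e_mi != 0L)
  bm <- matrix(as.numeric(e_m != 0L)[perms], B, N)
  E <- as.vector(bm %*% a) / N
  for (l in seq_len(lag_max)) {
    if (l >= N) break
    E <- E + beta^l *
      as.vector(bm[, (1 + l):N, drop = FALSE] %*% a[1:(N - l)]) / (N - l)
  }
  E * abs(atanh(r))
}

#' Permutation p-value of a Modulation Score
#'
#' The null hypothesis is "no temporal relation between the pair": the
#' mRNA's post-baseline time order is permuted uniformly at random, the
#' same permutation being applied to the continuous profile and the
#' discrete call vector (the baseline stays fixed as the reference), and
#' MS is recomputed.  With B permutations,
#' `p = (1 + #\{null ms >= observed\}) / (B + 1)` (add-one rule), so p is
#' never zero and has granularity `1 / (B + 1)`.
#'
#' @inheritParams modulation_score
#' @param n_perm Number of permutations B (>= 100).
#' @return The p-value, with the observed `ms` as attribute `"ms"`.
#' @export
permutation_pvalue <- function(x_mi, x_m, e_mi, e_m, n_perm = 1e5,
                               beta = 0.5, lag_max = 3L) {
  if (n_perm < 100) stop("'n_perm' must be at least 100")
  rec <- modulation_score(x_mi, x_m, e_mi, e_m, beta, lag_max)
  if (is.null(rec)) return(NA_real_)
  perms <- .rand_perm_matrix(as.integer(n_perm), length(e_m))
  nulls <- .null_ms(x_mi, x_m, e_mi, e_m, perms, beta, lag_max)
  p <- (1 + sum(nulls >= rec$ms)) / (n_perm + 1)
  attr(p, "ms") <- rec$ms
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity
#' (wraps [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Vector of p-values in (0, 1\]; `NA`s are propagated.
#' @return q-values of the same length.
#' @export
fdr_qvalues <- function(p) stats::p.adjust(p, method = "BH")

#' Flag significantly modulated targets
#'
#' @param records Data frame with a `q` column (see [score_pairs()]).
#' @param q_max Significance threshold on the q-value; the boundary is
#'   inclusive (default 0.2).
#' @return `records` with a logical `selected` column, plus per-miRNA
#'   selected-target counts as attribute `"targets_per_mirna"`.
#' @export
select_targets <- function(records, q_max = 0.2) {
  records$selected <- !is.na(records$q) & records$q <= q_max
  sel <- records[records$selected, , drop = FALSE]
  attr(records, "targets_per_mirna") <-
    if (nrow(sel)) table(sel$miRNA) else table(character(0))
  records
}

#' Score every predicted pair: MS, permutation p and q
#'
#' Driver over a predicted pair set.  By default only pairs whose two
#' members are both androgen-responsive are scored (the others carry no
#' usable differential signal); `gate = FALSE` scores every matched pair,
#' which is what null-calibration studies need.  Pairs with a
#' zero-variance profile are reported with `NA` statistics.
#'
#' @inheritParams global_or
#' @param mirna_tsm,mrna_tsm The (pre-processed) expression panels.
#' @param n_perm Permutations per pair.
#' @param beta,lag_max Correspondence-weight parameters.
#' @param q_max Selection threshold on q.
#' @param gate Require both members androgen-responsive (default `TRUE`).
#' @param seed Optional integer seed for the permutation stream.
#' @return Data frame with one row per scored pair: `miRNA, mRNA, r, z,
#'   E0, E1..EL, E, ms, sign, p, q, selected`, ordered by q then ms.
#' @export
score_pairs <- function(pairs, mirna_tsm, mrna_tsm, mirna_disc, mrna_disc,
                        n_perm = 1e5, beta = 0.5, lag_max = 3L,
                        q_max = 0.2, gate = TRUE, seed = NULL) {
  p <- if (inherits(pairs, "pair_set")) pairs$pairs else as.data.frame(pairs)
  if (nrow(p) == 0L) stop("empty pair set")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ok <- p$miRNA %in% rownames(mirna_disc$e) & p$mRNA %in% rownames(mrna_disc$e)
  p <- p[ok, , drop = FALSE]
  if (gate) {
    resp_mi <- mirna_disc$gene_ids[mirna_disc$responsive]
    resp_m <- mrna_disc$gene_ids[mrna_disc$responsive]
    p <- p[p$miRNA %in% resp_mi & p$mRNA %in% resp_m, , drop = FALSE]
  }
  n <- nrow(p)
  lag_cols <- paste0("E", seq_len(lag_max))
  out <- data.frame(miRNA = p$miRNA, mRNA = p$mRNA,
                    r = NA_real_, z = NA_real_, E0 = NA_real_,
                    matrix(NA_real_, n, lag_max,
                           dimnames = list(NULL, lag_cols)),
                    E = NA_real_, ms = NA_real_, sign = NA_real_,
                    p = NA_real_, q = NA_real_,
                    stringsAsFactors = FALSE, check.names = FALSE)
  N <- ncol(mirna_disc$e)
  for (i in seq_len(n)) {
    x_mi <- mirna_tsm$values[p$miRNA[i], ]
    x_m <- mrna_tsm$values[p$mRNA[i], ]
    e_mi <- mirna_disc$e[p$miRNA[i], ]
    e_m <- mrna_disc$e[p$mRNA[i], ]
    rec <- withCallingHandlers(
      modulation_score(x_mi, x_m, e_mi, e_m, beta, lag_max),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(rec)) next
    perms <- .rand_perm_matrix(as.integer(n_perm), N)
    nulls <- .null_ms(x_mi, x_m, e_mi, e_m, perms, beta, lag_max)
    out$r[i] <- rec$r; out$z[i] <- rec$z; out$E0[i] <- rec$E0
    out[i, lag_cols] <- rec$E_lag
    out$E[i] <- rec$E; out$ms[i] <- rec$ms; out$sign[i] <- rec$sign
    out$p[i] <- (1 + sum(nulls >= rec$ms)) / (n_perm + 1)
  }
  if (any(is.na(out$ms)))
    warning(sum(is.na(out$ms)), " pair(s) skipped (zero-variance profile)")
  out$q <- fdr_qvalues(out$p)
  out <- select_targets(out, q_max = q_max)
  o <- order(out$q, -out$ms, out$miRNA, out$mRNA)
  res <- out[o, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "targets_per_mirna") <- attr(out, "targets_per_mirna")
  res
}
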