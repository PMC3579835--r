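#' Surrogate DiffScore for replicate-free time courses
#'
#' When no vendor DiffScore matrix is available, differential expression of
#' time point k against the baseline is scored in the Illumina DiffScore
#' convention, `10 * sign(delta) * (-log10 p)`, with p from a two-sided
#' z-test of `(value_k - value_0) / spread`.  `spread` is the per-gene
#' noise scale of the difference `value_k - value_0` under no change (when
#' both measurements carry independent noise of sd s, that is
#' `sqrt(2) * s`), so the nominal p of the call is calibrated.
#' `|score| >= 20` corresponds to p <= 0.01 and `|score| >= 13` to
#' p <= 0.05.
#'
#' @param value_k,value_0 Numeric vectors (recycled) of post-baseline and
#'   baseline expression.
#' @param spread Positive noise scale of the difference (scalar or
#'   per-gene vector).
#' @return Signed numeric score(s).
#' @export
surrogate_diffscore <- function(value_k, value_0, spread) {
  if (any(!is.finite(spread)) || any(spread <= 0))
    stop("'spread' must be positive and finite")
  d <- value_k - value_0
  p <- 2 * stats::pnorm(-abs(d) / spread)
  p <- pmax(p, 1e-300)
  sign(d) * 10 * (-log10(p))
}

# DiffScore matrix (genes x N) for a panel, from the vendor channel when
# present, otherwise from the surrogate.
diffscore_matrix <- function(tsm, spread = NULL) {
  stopifnot(inherits(tsm, "tsm"))
  if (!is.null(tsm$diffscore)) {
    ds <- tsm$diffscore
    dimnames(ds) <- list(rownames(tsm$values), tsm$axis$labels[-1L])
    return(ds)
  }
  if (is.null(spread)) {
    spread <- estimate_spread(tsm)
    message("no DiffScore channel and no 'spread' supplied; using ",
            "estimated spread ", signif(spread, 3))
  }
  v <- tsm$values
  ds <- surrogate_diffscore(v[, -1L, drop = FALSE], v[, 1L], spread)
  dimnames(ds) <- list(rownames(v), tsm$axis$labels[-1L])
  ds
}

#' Estimate the per-measurement noise scale of a panel
#'
#' Robust fallback for the surrogate DiffScore when the true noise scale is
#' unknown: the median over genes of the per-gene median absolute deviation
#' of the trajectory.  Genes with real expression changes inflate their own
#' MAD but, as long as most genes are flat, the across-gene median is
#' dominated by low-variance genes and tracks the measurement noise.
#'
#' @param tsm A [time_series_matrix()].
#' @return A single positive spread estimate.
#' @export
estimate_spread <- function(tsm) {
  stopifnot(inherits(tsm, "tsm"))
  s <- stats::median(apply(tsm$values, 1L, stats::mad))
  if (!is.finite(s) || s <= 0)
    stop("spread estimate is not positive; supply 'spread' explicitly")
  s
}

#' Discretize one gene's DiffScores into down/none/up calls
#'
#' @param diffscores Numeric vector of length N (post-baseline points).
#' @param threshold Call threshold; the boundary is inclusive, so a score
#'   of exactly `threshold` is an up call.  The default 20 corresponds to
#'   p <= 0.01 in the DiffScore convention.
#' @return Integer vector in `{-1, 0, +1}` of length N.
#' @export
discretize_gene <- function(diffscores, threshold = 20) {
  e <- integer(length(diffscores))
  e[diffscores >= threshold] <- 1L
  e[diffscores <= -threshold] <- -1L
  e
}

#' Discretize a whole panel against the baseline
#'
#' Builds the per-gene call vectors `e` in `{-1, 0, +1}^N` (up, down or no
#' differential expression vs the 0 h baseline) and flags the
#' androgen-responsive genes: those differential at one or more time points.
#'
#' @inheritParams diffscore_matrix
#' @inheritParams discretize_gene
#' @return An object of class `"discretized"`: integer matrix `e`
#'   (genes x N), logical `responsive`, the `species`, `gene_ids`, and the
#'   `threshold` used.
#' @export
discretize_profiles <- function(tsm, threshold = 20, spread = NULL) {
  ds <- diffscore_matrix(tsm, spread)
  e <- matrix(0L, nrow(ds), ncol(ds), dimnames = dimnames(ds))
  e[ds >= threshold] <- 1L
  e[ds <= -threshold] <- -1L
  structure(list(e = e, responsive = rowSums(e != 0L) > 0L,
                 species = tsm$species, gene_ids = rownames(ds),
                 threshold = threshold),
            class = "discretized")
}

#' @export
print.discretized <- function(x, ...) {
  cat("Discretized ", x$species, " profiles: ", nrow(x$e), " genes, ",
      sum(x$responsive), " androgen-responsive (|DiffScore| >= ",
      x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Androgen-responsive gene sets of both panels
#'
#' @param mirna_disc,mrna_disc [discretize_profiles()] results for the
#'   miRNA and mRNA panels (either may be `NULL`).
#' @return List with sorted id vectors `miRNA` and `mRNA` and a `counts`
#'   vector.
#' @export
responsive_set <- function(mirna_disc = NULL, mrna_disc = NULL) {
  pick <- function(d) {
    if (is.null(d)) return(character(0))
    sort(d$gene_ids[d$responsive])
  }
  mi <- pick(mirna_disc)
  m <- pick(mrna_disc)
  list(miRNA = mi, mRNA = m,
       counts = c(miRNA = length(mi), mRNA = length(m)))
}
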