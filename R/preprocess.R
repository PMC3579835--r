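#' Quantile-normalize an expression matrix
#'
#' Forces every array (column) to share the same value distribution: the
#' reference distribution is the row-wise mean of the per-column sorted
#' values, and each cell is replaced by the reference value at its
#' within-column rank.  Entries tied within a column receive the mean of
#' the reference values over their tied rank range, which keeps the
#' procedure deterministic.
#'
#' @param x Numeric matrix (genes x arrays) or a [time_series_matrix()]
#'   whose `values` are normalized in place.
#' @return The same type as `x`, normalized.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "tsm")) {
    x$values <- quantile_normalize(x$values)
    return(x)
  }
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 2L)
    stop("quantile normalization needs >= 1 gene and >= 2 arrays")
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite value at gene ", rownames(x)[bad[1L, 1L]] %||%
           bad[1L, 1L], ", array column ", bad[1L, 2L])
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    sv <- x[o, j]
    runs <- rle(sv)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    norm_sorted <- numeric(length(sv))
    for (g in seq_along(runs$lengths))
      norm_sorted[starts[g]:stops[g]] <- mean(ref[starts[g]:stops[g]])
    out[o, j] <- norm_sorted
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Amend unauthentic signals against the per-array authentic minimum
#'
#' A cell is authentic when its detection p-value is below `alpha`.  For
#' each array the minimum authentic value (`min_au`) is taken as the
#' noise floor on that chip, and every unauthentic cell with original
#' value `a` is replaced by `max(a, min_au)`; authentic cells are never
#' touched.  The amendment is idempotent and monotone (no cell decreases).
#'
#' @param tsm A [time_series_matrix()] carrying detection p-values.
#' @param alpha Authenticity cutoff on the detection p-value (default 0.01).
#' @param per_array Compute the floor per array (default) or once over the
#'   whole panel.
#' @return List with the amended `tsm` and a `report` containing `min_au`
#'   (per array) and `amended_cell_count`.
#' @export
amend_unauthentic <- function(tsm, alpha = 0.01, per_array = TRUE) {
  stopifnot(inherits(tsm, "tsm"))
  auth <- tsm$detection_p < alpha
  v <- tsm$values
  if (per_array) {
    min_au <- rep(NA_real_, ncol(v))
    for (j in seq_len(ncol(v))) {
      if (!any(auth[, j]))
        stop("array ", colnames(v)[j],
             " has no authentic cell; min_au is undefined")
      min_au[j] <- min(v[auth[, j], j])
      up <- !auth[, j]
      v[up, j] <- pmax(v[up, j], min_au[j])
    }
    names(min_au) <- colnames(v)
  } else {
    if (!any(auth)) stop("no authentic cell in the panel")
    floor_all <- min(v[auth])
    v[!auth] <- pmax(v[!auth], floor_all)
    min_au <- stats::setNames(rep(floor_all, ncol(v)), colnames(v))
  }
  amended <- sum(v != tsm$values)
  tsm$values <- v
  list(tsm = tsm,
       report = list(min_au = min_au, amended_cell_count = amended))
}

#' Exclude genes with too many unauthentic signals
#'
#' Genes with more than `max_unauthentic` cells at detection p >= `alpha`
#' (counted before any amendment) are removed from the panel.
#'
#' @inheritParams amend_unauthentic
#' @param max_unauthentic Largest tolerated number of unauthentic cells per
#'   gene; a gene with exactly this many is retained (default 5).
#' @return List with the filtered `tsm` and a `report` listing
#'   `removed_gene_ids`, `n_removed` and `n_retained`.
#' @export
filter_genes <- function(tsm, max_unauthentic = 5L, alpha = 0.01) {
  stopifnot(inherits(tsm, "tsm"))
  n_bad <- rowSums(tsm$detection_p >= alpha)
  drop <- n_bad > max_unauthentic
  out <- tsm_subset(tsm, rownames(tsm$values)[!drop])
  list(tsm = out,
       report = list(removed_gene_ids = rownames(tsm$values)[drop],
                     n_removed = sum(drop), n_retained = sum(!drop)))
}

#' Run the full pre-processing chain on one panel
#'
#' Applies signal amendment, gene filtering and quantile normalization in a
#' configurable order.  The default order is amend, filter, then
#' normalize: authenticity and the noise floor `min_au` refer to the raw
#' scale, and the filter counts raw unauthentic cells.  Normalizing first
#' is available for fidelity experiments via `order`.
#'
#' @inheritParams amend_unauthentic
#' @inheritParams filter_genes
#' @param order Character vector, a permutation of
#'   `c("amend", "filter", "quantile")` (a subset is allowed).
#' @return List with the processed `tsm` and a merged `report` (`min_au`,
#'   `amended_cell_count`, `removed_gene_ids`, `n_removed`, `n_retained`).
#' @export
preprocess_tsm <- function(tsm, order = c("amend", "filter", "quantile"),
                           alpha = 0.01, max_unauthentic = 5L,
                           per_array = TRUE) {
  stopifnot(inherits(tsm, "tsm"))
  order <- match.arg(order, c("amend", "filter", "quantile"),
                     several.ok = TRUE)
  n_input <- nrow(tsm$values)
  report <- list(min_au = NULL, amended_cell_count = 0L,
                 removed_gene_ids = character(0),
                 n_removed = 0L, n_retained = n_input)
  for (stage in order) {
    if (stage == "amend") {
      res <- amend_unauthentic(tsm, alpha = alpha, per_array = per_array)
      tsm <- res$tsm
      report$min_au <- res$report$min_au
      report$amended_cell_count <- res$report$amended_cell_count
    } else if (stage == "filter") {
      res <- filter_genes(tsm, max_unauthentic = max_unauthentic,
                          alpha = alpha)
      tsm <- res$tsm
      report$removed_gene_ids <- res$report$removed_gene_ids
      report$n_removed <- res$report$n_removed
      report$n_retained <- res$report$n_retained
    } else {
      tsm <- quantile_normalize(tsm)
    }
  }
  stopifnot(report$n_removed + report$n_retained == n_input)
  list(tsm = tsm, report = report)
}
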