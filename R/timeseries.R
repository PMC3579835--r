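#' Time axis of the stimulation experiment
#'
#' The sampling design is ten arrays taken at 0 h, 20 min, 40 min, 1 h, 2 h,
#' 4 h, 8 h, 16 h, 24 h and 48 h after androgen (DHT) stimulation.  Index
#' `k = 0` is the pre-stimulation baseline; the `N = 9` post-baseline points
#' are indexed `k = 1..N` throughout the package.
#'
#' @param labels Character vector of time-point labels, baseline first.
#' @param minutes Integer vector of the same length, strictly increasing,
#'   non-negative; minutes after stimulation (baseline 0).
#' @return An object of class `"time_axis"` with elements `labels`,
#'   `minutes` and `n_post` (the number of post-baseline points, `N`).
#' @examples
#' time_axis()
#' @export
time_axis <- function(labels = c("0h", "20min", "40min", "1h", "2h", "4h",
                                 "8h", "16h", "24h", "48h"),
                      minutes = c(0L, 20L, 40L, 60L, 120L, 240L, 480L,
                                  960L, 1440L, 2880L)) {
  minutes <- as.integer(minutes)
  labels <- as.character(labels)
  if (length(labels) != length(minutes))
    stop("'labels' and 'minutes' must have equal length")
  if (length(minutes) < 2L)
    stop("a time axis needs a baseline and at least one later point")
  if (any(minutes < 0L) || is.unsorted(minutes, strictly = TRUE))
    stop("'minutes' must be non-negative and strictly increasing")
  structure(list(labels = labels, minutes = minutes,
                 n_post = length(minutes) - 1L),
            class = "time_axis")
}

#' @export
print.time_axis <- function(x, ...) {
  cat("Time axis:", length(x$minutes), "points (baseline + ",
      x$n_post, " post-stimulation)\n", sep = "")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

# Parse header labels like "0h", "20min", "1h" into minutes.
parse_time_labels <- function(labels) {
  m <- rep(NA_integer_, length(labels))
  is_min <- grepl("^[0-9]+ ?min$", labels)
  is_hr <- grepl("^[0-9.]+ ?h$", labels)
  m[is_min] <- as.integer(sub(" ?min$", "", labels[is_min]))
  m[is_hr] <- as.integer(round(as.numeric(sub(" ?h$", "", labels[is_hr])) * 60))
  if (anyNA(m))
    stop("cannot parse time label(s): ",
         paste(labels[is.na(m)], collapse = ", "),
         " (expected forms like '20min' or '8h')")
  m
}

#' Expression time-series matrix
#'
#' Container for a genes x time-points expression panel with a parallel
#' detection p-value matrix and an optional vendor DiffScore matrix.  Values
#' are expected on a log-intensity scale; the detection p-value of a cell is
#' the probability that the measured signal is background (cells with
#' detection p below the authenticity cutoff are "authentic").
#'
#' @param values Numeric matrix, genes x (N+1) time points, with unique row
#'   names giving the gene identifiers.  Identifiers are opaque strings (the
#'   analysis works at probe level; no symbol mapping is attempted).
#' @param detection_p Numeric matrix of the same shape with entries in
#'   \[0, 1\], or `NULL` for "all cells authentic" (all zeros).
#' @param diffscore Optional numeric matrix, genes x N, of vendor
#'   differential-expression scores against the baseline column.
#' @param species Either `"miRNA"` or `"mRNA"`.
#' @param axis A [time_axis()].
#' @return An object of class `"tsm"`.
#' @export
time_series_matrix <- function(values, detection_p = NULL, diffscore = NULL,
                               species = c("miRNA", "mRNA"),
                               axis = time_axis()) {
  species <- match.arg(species)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (ncol(values) != length(axis$minutes))
    stop("'values' has ", ncol(values), " columns but the time axis has ",
         length(axis$minutes), " points")
  ids <- rownames(values)
  if (is.null(ids)) stop("'values' must have row names (gene identifiers)")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(values)) stop("'values' must not contain missing cells")
  if (is.null(detection_p)) {
    detection_p <- matrix(0, nrow(values), ncol(values),
                          dimnames = dimnames(values))
  } else {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stop("'detection_p' (", nrow(detection_p), "x", ncol(detection_p),
           ") does not match 'values' (", nrow(values), "x", ncol(values), ")")
    if (anyNA(detection_p) || any(detection_p < 0 | detection_p > 1))
      stop("'detection_p' entries must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  if (!is.null(diffscore)) {
    diffscore <- as.matrix(diffscore)
    if (nrow(diffscore) != nrow(values) ||
        ncol(diffscore) != axis$n_post)
      stop("'diffscore' must be genes x ", axis$n_post,
           " (post-baseline points)")
    rownames(diffscore) <- ids
  }
  colnames(values) <- axis$labels
  structure(list(values = values, detection_p = detection_p,
                 diffscore = diffscore, species = species, axis = axis),
            class = "tsm")
}

#' @export
print.tsm <- function(x, ...) {
  cat("Time-series expression matrix (", x$species, "): ",
      nrow(x$values), " genes x ", ncol(x$values), " time points\n", sep = "")
  cat("  time points:", paste(x$axis$labels, collapse = ", "), "\n")
  cat("  vendor DiffScore matrix:",
      if (is.null(x$diffscore)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.tsm <- function(x) dim(x$values)

# Row subset preserving all channels.
tsm_subset <- function(tsm, ids) {
  keep <- rownames(tsm$values) %in% ids
  time_series_matrix(tsm$values[keep, , drop = FALSE],
                     tsm$detection_p[keep, , drop = FALSE],
                     if (!is.null(tsm$diffscore))
                       tsm$diffscore[keep, , drop = FALSE],
                     species = tsm$species, axis = tsm$axis)
}

.read_tsv_matrix <- function(path) {
  dat <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (nrow(dat) == 0L) stop("no data rows in ", path)
  ids <- as.character(dat[[1L]])
  m <- as.matrix(dat[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read an expression panel from tab-separated files
#'
#' The canonical interchange format is a TSV with header
#' `gene_id<TAB>0h<TAB>20min<TAB>...` and one gene per row.  A companion
#' detection-p file (same shape, same gene order) is read alongside; an
#' optional DiffScore file carries the N post-baseline columns only.
#'
#' @param values_path Path to the expression value TSV.
#' @param detection_path Path to the detection p-value TSV, or `NULL` to
#'   mark every cell authentic.
#' @param diffscore_path Optional path to a vendor DiffScore TSV (columns
#'   are the post-baseline time points).
#' @inheritParams time_series_matrix
#' @return A [time_series_matrix()].
#' @export
read_expression_tsv <- function(values_path, detection_path = NULL,
                                diffscore_path = NULL,
                                species = c("miRNA", "mRNA")) {
  species <- match.arg(species)
  values <- .read_tsv_matrix(values_path)
  axis <- time_axis(labels = colnames(values),
                    minutes = parse_time_labels(colnames(values)))
  detection <- NULL
  if (!is.null(detection_path)) {
    detection <- .read_tsv_matrix(detection_path)
    if (!identical(dim(detection), dim(values)))
      stop("detection file shape (", nrow(detection), "x", ncol(detection),
           ") does not match value file shape (",
           nrow(values), "x", ncol(values), ")")
    if (!identical(rownames(detection), rownames(values)))
      stop("detection file gene order differs from value file")
  }
  ds <- NULL
  if (!is.null(diffscore_path)) {
    ds <- .read_tsv_matrix(diffscore_path)
    if (nrow(ds) != nrow(values) || ncol(ds) != axis$n_post)
      stop("diffscore file must be genes x ", axis$n_post, " columns")
  }
  time_series_matrix(values, detection, ds, species = species, axis = axis)
}

#' Write an expression panel to tab-separated files
#'
#' Values are serialized at full double precision (17 significant digits) so
#' a write/read round trip reproduces the matrix bit-identically.
#'
#' @param tsm A [time_series_matrix()].
#' @param values_path,detection_path,diffscore_path Output paths; the
#'   detection and DiffScore channels are written only when a path is given
#'   (and, for DiffScore, when the channel is present).
#' @return Invisibly, `tsm`.
#' @export
write_expression_tsv <- function(tsm, values_path, detection_path = NULL,
                                 diffscore_path = NULL) {
  .write_one <- function(m, cols, path) {
    header <- paste(c("gene_id", cols), collapse = "\t")
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  }
  .write_one(tsm$values, tsm$axis$labels, values_path)
  if (!is.null(detection_path))
    .write_one(tsm$detection_p, tsm$axis$labels, detection_path)
  if (!is.null(diffscore_path) && !is.null(tsm$diffscore))
    .write_one(tsm$diffscore, tsm$axis$labels[-1L], diffscore_path)
  invisible(tsm)
}

#' Read a GEO series-matrix file
#'
#' Parses the `!series_matrix_table_begin` ... `!series_matrix_table_end`
#' block of a Gene Expression Omnibus series-matrix text file.  Series
#' matrices carry no detection p-value channel, so every cell is marked
#' authentic with a warning; supply detection p-values separately when
#' available.
#'
#' @param path Path to the series-matrix text file.
#' @param sample_map Named integer vector mapping every sample accession in
#'   the file to minutes after stimulation, or `NULL` to assume the columns
#'   are already ordered along the default [time_axis()].
#' @inheritParams time_series_matrix
#' @return A [time_series_matrix()].
#' @export
read_geo_series_matrix <- function(path, species = c("miRNA", "mRNA"),
                                   sample_map = NULL) {
  species <- match.arg(species)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("no series-matrix table found in ", path)
  block <- lines[(beg + 1L):(end - 1L)]
  block <- gsub('"', "", block, fixed = TRUE)
  fields <- strsplit(block, "\t", fixed = TRUE)
  samples <- fields[[1L]][-1L]
  if (length(block) < 2L) stop("no data rows in ", path)
  ids <- vapply(fields[-1L], `[`, character(1), 1L)
  values <- do.call(rbind, lapply(fields[-1L], function(f)
    as.numeric(f[-1L])))
  rownames(values) <- ids
  if (!is.null(sample_map)) {
    unmapped <- setdiff(samples, names(sample_map))
    if (length(unmapped))
      stop("sample(s) not covered by 'sample_map': ",
           paste(unmapped, collapse = ", "))
    minutes <- as.integer(sample_map[samples])
    o <- order(minutes)
    values <- values[, o, drop = FALSE]
    minutes <- minutes[o]
    labels <- ifelse(minutes %% 60 == 0, paste0(minutes %/% 60, "h"),
                     paste0(minutes, "min"))
    axis <- time_axis(labels = labels, minutes = minutes)
  } else {
    if (length(samples) != 10L)
      stop("without 'sample_map', expected 10 samples in default time order; ",
           "found ", length(samples))
    axis <- time_axis()
  }
  warning("series matrix has no detection p-value channel; ",
          "marking all cells authentic")
  time_series_matrix(values, NULL, NULL, species = species, axis = axis)
}

#' Sequence-predicted miRNA-mRNA pair set
#'
#' @param pairs Data frame (or two-column object) with columns `miRNA` and
#'   `mRNA`; duplicated pairs are removed.
#' @return An object of class `"pair_set"`: the deduplicated `pairs` data
#'   frame, the number of distinct miRNAs `M`, the per-miRNA predicted
#'   target counts `targets_per_mirna`, and bookkeeping counts `n_input`
#'   and `n_duplicates` (so that retained + rejected equals the input size).
#' @export
predicted_pair_set <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop("'pairs' needs columns miRNA and mRNA")
  pairs <- data.frame(miRNA = as.character(pairs[[1L]]),
                      mRNA = as.character(pairs[[2L]]),
                      stringsAsFactors = FALSE)
  n_input <- nrow(pairs)
  dup <- duplicated(pairs)
  pairs <- pairs[!dup, , drop = FALSE]
  pairs <- pairs[order(pairs$miRNA, pairs$mRNA), , drop = FALSE]
  rownames(pairs) <- NULL
  tab <- table(pairs$miRNA)
  structure(list(pairs = pairs, M = length(tab),
                 targets_per_mirna = as.integer(tab),
                 n_input = n_input, n_duplicates = sum(dup)),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat("Predicted miRNA-mRNA pair set: ", nrow(x$pairs), " unique pairs, ",
      x$M, " miRNAs (", x$n_duplicates, " duplicate input rows removed)\n",
      sep = "")
  invisible(x)
}

#' Read predicted miRNA-mRNA pairs from a two-column TSV
#'
#' Each line is `miRNA_id<TAB>mRNA_id` (miRDB-style); lines starting with
#' `#` are comments.  A line with any other number of fields is a hard
#' error reported with its line number.
#'
#' @param path Path to the pairs TSV.
#' @return A [predicted_pair_set()].
#' @export
read_pairs_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- idx[which(nf != 2L)[1L]]
    stop("malformed pair line ", bad, " in ", path,
         " (expected 2 tab-separated fields, found ", nf[which(nf != 2L)[1L]],
         ")")
  }
  if (!length(fields))
    return(predicted_pair_set(data.frame(miRNA = character(0),
                                         mRNA = character(0))))
  predicted_pair_set(data.frame(miRNA = vapply(fields, `[`, character(1), 1L),
                                mRNA = vapply(fields, `[`, character(1), 2L)))
}
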