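# Small in-code fixtures shared across test files.

# A tiny deterministic panel: n genes x 10 points, optional planted shifts.
make_tsm <- function(n = 5, species = "miRNA", seed = 101, noise = 0.1,
                     detection_p = NULL) {
  set.seed(seed)
  ax <- time_axis()
  v <- matrix(rnorm(n * 10, mean = 7, sd = noise), n, 10,
              dimnames = list(sprintf("g%02d", seq_len(n)), ax$labels))
  if (is.null(detection_p))
    detection_p <- matrix(0.001, n, 10, dimnames = dimnames(v))
  time_series_matrix(v, detection_p, species = species, axis = ax)
}

# Write a tsm to temporary TSV files; returns the paths.
write_tsm_files <- function(tsm, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("tsm")
    dir.create(dir)
  }
  paths <- list(values = file.path(dir, "expression.tsv"),
                detection = file.path(dir, "detection.tsv"))
  write_expression_tsv(tsm, paths$values, paths$detection)
  paths
}

# Independent brute-force Response Score evaluator (plain loop, kept
# deliberately naive and separate from the package's vectorized path).
rs_brute <- function(e) {
  N <- length(e)
  s <- which(e != 0L)[1L]
  if (is.na(s)) return(0L)
  d <- e[s]
  tot <- 0L
  for (k in seq_len(N)) {
    w <- N + 1L - k
    if (e[k] == d) tot <- tot + w
    else if (e[k] == -d) tot <- tot - w %/% 2L
  }
  max(tot, 0L)
}
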