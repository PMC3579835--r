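#' Assemble the miRNA-mediated AR regulatory network
#'
#' Edges are of two kinds: AR -> miRNA for every candidate primary-target
#' miRNA (attribute: its Response Score), and miRNA -> mRNA for every
#' significantly modulated pair (attributes: Modulation Score and q).
#' The edge list is deduplicated and deterministically ordered, so
#' rebuilding from the same inputs is byte-identical.
#'
#' @param candidates Candidate data frame from [select_candidates()]
#'   (`$candidates`), with columns `gene_id` and `rs`.
#' @param selected Scored-pair data frame from [score_pairs()] /
#'   [select_targets()]; only rows with `selected == TRUE` become edges.
#' @return Data frame `source, target, edge_type, rs, ms, q`.
#' @export
build_network <- function(candidates, selected) {
  ar <- data.frame(source = rep("AR", nrow(candidates)),
                   target = candidates$gene_id,
                   edge_type = rep("AR->miRNA", nrow(candidates)),
                   rs = candidates$rs, ms = rep(NA_real_, nrow(candidates)),
                   q = rep(NA_real_, nrow(candidates)),
                   stringsAsFactors = FALSE)
  sel <- selected[selected$selected %in% TRUE, , drop = FALSE]
  mi <- data.frame(source = sel$miRNA, target = sel$mRNA,
                   edge_type = rep("miRNA->mRNA", nrow(sel)),
                   rs = rep(NA_real_, nrow(sel)), ms = sel$ms, q = sel$q,
                   stringsAsFactors = FALSE)
  edges <- rbind(ar, mi)
  edges <- edges[!duplicated(edges[c("source", "target", "edge_type")]), ,
                 drop = FALSE]
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Dominant-modulation histogram
#'
#' For each significantly modulated target mRNA, the number of distinct
#' miRNAs regulating it; the histogram over these counts shows whether
#' most targets are modulated by a single dominant miRNA in the cellular
#' context.
#'
#' @param selected Scored-pair data frame; only `selected` rows count.
#' @return List with `histogram` (data frame `n_regulators, n_targets,
#'   fraction`) and `n_targets`, the number of distinct regulated mRNAs.
#'   Fractions sum to 1 over targets with at least one regulator.
#' @export
dominance_distribution <- function(selected) {
  sel <- selected[selected$selected %in% TRUE, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(list(histogram = data.frame(n_regulators = integer(0),
                                       n_targets = integer(0),
                                       fraction = numeric(0)),
                n_targets = 0L))
  per_target <- table(sel$mRNA)
  h <- table(factor(as.integer(per_target)))
  hist <- data.frame(n_regulators = as.integer(names(h)),
                     n_targets = as.integer(h),
                     fraction = as.numeric(h) / length(per_target))
  list(histogram = hist, n_targets = length(per_target))
}

#' Expression correlation of an intronic miRNA with its host gene
#'
#' Intronic miRNAs are often assumed to be co-transcribed with the host
#' mRNA; this checks the assumption on the continuous time-course
#' profiles.  "Correlated" means Pearson r at or above `r_min`.
#'
#' @param x_mi,x_host Continuous profiles of equal length (baseline
#'   included).
#' @param r_min Correlation threshold (default 0.5).
#' @return List with `r` (`NA` when a profile has zero variance) and
#'   logical `correlated`.
#' @export
host_mirna_correlation <- function(x_mi, x_host, r_min = 0.5) {
  if (stats::sd(x_mi) == 0 || stats::sd(x_host) == 0)
    return(list(r = NA_real_, correlated = NA))
  r <- stats::cor(x_mi, x_host)
  list(r = r, correlated = r >= r_min)
}
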