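# SAM-style moderated two-group statistic used to pre-rank genes for the
# enrichment screen.  Positive scores mean "up in group 2".

#' SAM d-statistic per gene
#'
#' `d_i = (mean2_i - mean1_i) / (s_i + s0)` where `s_i` is the pooled standard
#' error `sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))` and `s0` is the
#' fudge factor guarding low-variance genes.
#'
#' @param expr Gene x sample matrix with dimnames.
#' @param group1,group2 Disjoint sample-id vectors, each of size >= 2;
#'   `group1` is the reference (e.g. primary tumors), so positive `d` means
#'   up-regulation in `group2`.
#' @param s0 Fudge factor (>= 0); use [estimate_s0()] for a data-driven value.
#' @return List with numeric vectors `d`, `s` (pooled SE) and `diff`
#'   (`mean2 - mean1`), named by gene.
#' @export
sam_statistic <- function(expr, group1, group2, s0 = 0) {
  stopifnot(is.matrix(expr))
  if (length(intersect(group1, group2)) > 0L) stop2("groups must be disjoint")
  if (length(group1) < 2L || length(group2) < 2L) stop2("each group needs >= 2 samples")
  missing_s <- setdiff(c(group1, group2), colnames(expr))
  if (length(missing_s) > 0L)
    stop2("samples not in expression matrix: ", paste(missing_s, collapse = ", "))
  if (s0 < 0) stop2("s0 must be >= 0")
  x1 <- expr[, group1, drop = FALSE]
  x2 <- expr[, group2, drop = FALSE]
  n1 <- length(group1); n2 <- length(group2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  if (s0 == 0 && any(s == 0))
    stop2("zero-variance gene with s0 = 0: ",
          paste(utils::head(rownames(expr)[s == 0], 5L), collapse = ", "))
  list(d = (m2 - m1) / (s + s0), s = s, diff = m2 - m1)
}

#' Estimate the SAM fudge factor s0
#'
#' `"median"` returns the median pooled standard error.  `"percentile_search"`
#' follows the original SAM recipe: over candidate s0 values at the 0, 5, ...,
#' 100 percentiles of `s`, pick the one minimizing the coefficient of
#' variation of the window-wise median absolute deviation of `d`, the windows
#' being equal-count bins of genes ordered by `s`.
#'
#' @param s Per-gene pooled standard errors (from [sam_statistic()]).
#' @param method `"median"` or `"percentile_search"`.
#' @param diff Per-gene numerator (`mean2 - mean1`), required for
#'   `"percentile_search"`.
#' @param n_windows Number of equal-count windows (default 10).
#' @return The estimated s0 (scalar).
#' @export
estimate_s0 <- function(s, method = c("median", "percentile_search"),
                        diff = NULL, n_windows = 10) {
  method <- match.arg(method)
  if (length(s) == 0L) stop2("empty standard-error vector")
  if (method == "median") return(stats::median(s))
  if (is.null(diff) || length(diff) != length(s))
    stop2("percentile_search needs the per-gene mean differences")
  cands <- stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE)
  win <- cut(rank(s, ties.method = "first"),
             breaks = n_windows, labels = FALSE)
  cv <- vapply(cands, function(s0) {
    d <- diff / (s + s0)
    mads <- tapply(d, win, stats::mad)
    if (mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, 0)
  cands[which.min(cv)]
}

#' Rank genes by a signed score
#'
#' @param scores Named numeric vector (one score per gene).
#' @return Data frame `gene`, `score` sorted by decreasing score; ties broken
#'   by gene id (lexicographic) for determinism.
#' @export
rank_genes <- function(scores) {
  stopifnot(!is.null(names(scores)), !anyDuplicated(names(scores)))
  ord <- order(-scores, names(scores), method = "radix")
  data.frame(gene = names(scores)[ord], score = unname(scores)[ord],
             stringsAsFactors = FALSE)
}

#' Write a ranked gene list in RNK format (two-column TSV)
#' @param ranked Data frame from [rank_genes()].
#' @param path Output path.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
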