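# Prior-primed weighted co-expression network construction: absolute Pearson
# similarity within one phenotype group, binary prior mask, soft-threshold
# power chosen by scale-free topology fit, and the topological overlap
# measure (TOM) whose dissimilarity 1 - TOM feeds the clustering step.

#' Absolute Pearson correlation similarity within a sample subset
#'
#' The similarity between genes i and j is `|cor(x_i, x_j)|` computed over the
#' given samples (one phenotype group).  Genes with zero variance in the
#' subset cannot be correlated and are dropped with a warning (or raise an
#' error when `drop_zero_variance = FALSE`).
#'
#' @param expr Gene x sample numeric matrix with dimnames.
#' @param sample_subset Character vector of sample ids (>= 3).
#' @param drop_zero_variance Drop constant genes (default) instead of erroring.
#' @return Symmetric similarity matrix in `[0, 1]` with unit diagonal, gene
#'   dimnames preserved in input order.
#' @export
abs_pearson_similarity <- function(expr, sample_subset = colnames(expr),
                                   drop_zero_variance = TRUE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  missing_s <- setdiff(sample_subset, colnames(expr))
  if (length(missing_s) > 0L)
    stop2("samples not in expression matrix: ", paste(missing_s, collapse = ", "))
  if (length(sample_subset) < 3L) stop2("need >= 3 samples to estimate correlations")
  x <- expr[, sample_subset, drop = FALSE]
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    if (!drop_zero_variance)
      stop2("zero-variance gene(s) in subset: ",
            paste(utils::head(rownames(x)[v == 0], 5L), collapse = ", "))
    warn2(sum(v == 0), " zero-variance gene(s) dropped before correlation")
    x <- x[v > 0, , drop = FALSE]
  }
  s <- abs(stats::cor(t(x)))
  s[s > 1] <- 1
  diag(s) <- 1
  s
}

#' Binary prior-relation matrix aligned to a gene order
#'
#' @param network A [relation_network()].
#' @param gene_ids Character vector defining row/column order.
#' @return Symmetric 0/1 matrix with zero diagonal; entry 1 iff the unordered
#'   pair is an edge of `network`.
#' @export
prior_matrix <- function(network, gene_ids) {
  stopifnot(inherits(network, "relation_network"))
  if (anyDuplicated(gene_ids)) stop2("duplicate gene ids")
  n <- length(gene_ids)
  p <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  e <- network$edges
  keep <- e$from %in% gene_ids & e$to %in% gene_ids
  if (any(keep)) {
    i <- match(e$from[keep], gene_ids)
    j <- match(e$to[keep], gene_ids)
    p[cbind(i, j)] <- 1
    p[cbind(j, i)] <- 1
  }
  p
}

#' Prior-primed adjacency: a'_ij = p_ij * s_ij^beta
#'
#' The core integration step: the soft-thresholded co-expression similarity is
#' masked by the binary a priori relation indicator, so only gene pairs with
#' prior evidence (e.g. a PPI) can be connected, with a strength set by the
#' within-group correlation.
#'
#' @param sim Similarity matrix from [abs_pearson_similarity()].
#' @param prior Binary matrix from [prior_matrix()] (same gene order) or a
#'   [relation_network()] to be aligned automatically.
#' @param beta Soft-threshold power (>= 1).
#' @return Adjacency matrix in `[0, 1]` with unit diagonal and attribute
#'   `beta`.  The diagonal is bookkeeping only; connectivity sums exclude it.
#' @export
combined_adjacency <- function(sim, prior, beta) {
  check_square_symmetric(sim, "similarity")
  if (inherits(prior, "relation_network")) prior <- prior_matrix(prior, rownames(sim))
  if (!all(dim(prior) == dim(sim))) stop2("similarity/prior shape mismatch")
  if (!all(prior %in% c(0, 1))) stop2("prior matrix must be binary")
  if (beta < 1) stop2("beta must be >= 1")
  a <- prior * sim^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Connectivity (weighted degree) of an adjacency matrix
#'
#' @param adjacency Square symmetric matrix; the diagonal is excluded.
#' @return Numeric vector of per-gene connectivities k_i.
#' @export
connectivity <- function(adjacency) {
  check_square_symmetric(adjacency, "adjacency")
  rowSums(adjacency) - diag(adjacency)
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `n_bins` equal-width bins and regresses
#' log10(frequency) on log10(mean connectivity) over non-empty bins.  The fit
#' index is R-squared, sign-penalized (negated) when the slope is positive,
#' since scale-free topology requires a decreasing log-log relation.
#'
#' @param k Numeric vector of connectivities, or a square adjacency matrix
#'   (its [connectivity()] is used).
#' @param n_bins Number of bins, between 3 and 10.
#' @return List with `r_squared`, `slope`, `n_bins`, `n_nonempty`,
#'   `mean_connectivity` and the per-bin table `fit_table`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (is.matrix(k)) k <- connectivity(k)
  if (n_bins < 3 || n_bins > 10) stop2("n_bins must be in [3, 10]")
  if (length(unique(k)) == 1L) stop2("degenerate fit: all connectivities equal")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  mean_k <- tapply(k, bin, mean)
  keep <- freq > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 3L) stop2("fewer than 3 non-empty bins: fit undefined")
  lx <- log10(mean_k[keep]); ly <- log10(freq[keep])
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # lm warns on an exact fit
  if (is.na(slope)) stop2("degenerate regression in scale-free fit")
  list(r_squared = if (slope > 0) -r2 else r2,
       slope = slope,
       n_bins = n_bins,
       n_nonempty = sum(keep),
       mean_connectivity = mean(k),
       fit_table = data.frame(mean_k = as.numeric(mean_k[keep]),
                              freq = freq[keep]))
}

# best fit over bin counts 3..10: the largest bin count whose R^2 meets the
# target, else the bin count with the best R^2 (per the S-figure protocol)
best_bin_fit <- function(k, r2_target = 0.8) {
  fits <- list()
  for (nb in 10:3) {
    f <- tryCatch(scale_free_fit(k, nb), error = function(e) NULL)
    if (!is.null(f)) fits[[as.character(nb)]] <- f
  }
  if (length(fits) == 0L) stop2("scale-free fit undefined for all bin counts")
  r2s <- vapply(fits, `[[`, 0, "r_squared")
  ok <- r2s >= r2_target
  if (any(ok)) {
    nb_ok <- max(as.integer(names(fits)[ok]))
    fits[[as.character(nb_ok)]]
  } else {
    fits[[which.max(r2s)]]
  }
}

#' Pick the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power, builds the primed adjacency, evaluates the
#' scale-free fit over bin counts 3..10 (keeping the largest bin count whose
#' R-squared meets the target, else the best-fitting bin count), and returns
#' the smallest power whose kept fit meets the target.  If no power meets it,
#' the power with maximal R-squared is returned with `target_met = FALSE`.
#'
#' @param sim Similarity matrix.
#' @param prior Binary prior matrix or [relation_network()].
#' @param beta_grid Integer candidate powers (default 1:20).
#' @param r2_target Required fit index (default 0.8).
#' @return List with `beta`, `target_met`, and `fits` (per-beta data frame
#'   with beta, r_squared, slope, n_bins, mean_connectivity).
#' @export
pick_soft_threshold <- function(sim, prior, beta_grid = 1:20, r2_target = 0.8) {
  check_square_symmetric(sim, "similarity")
  if (inherits(prior, "relation_network")) prior <- prior_matrix(prior, rownames(sim))
  rows <- list()
  per_beta <- list()
  for (beta in beta_grid) {
    a <- prior * sim^beta       # diagonal-free: connectivity excludes diag anyway
    k <- rowSums(a)
    f <- tryCatch(best_bin_fit(k, r2_target), error = function(e) {
      warn2("beta = ", beta, ": ", conditionMessage(e)); NULL
    })
    if (is.null(f)) next
    per_beta[[as.character(beta)]] <- f
    rows[[length(rows) + 1L]] <- data.frame(
      beta = beta, r_squared = f$r_squared, slope = f$slope,
      n_bins = f$n_bins, mean_connectivity = f$mean_connectivity)
  }
  if (length(rows) == 0L) stop2("scale-free fit failed for every beta")
  fits <- do.call(rbind, rows)
  met <- fits$beta[fits$r_squared >= r2_target]
  if (length(met) > 0L) {
    list(beta = min(met), target_met = TRUE, fits = fits)
  } else {
    list(beta = fits$beta[which.max(fits$r_squared)], target_met = FALSE,
         fits = fits)
  }
}

#' Topological overlap measure
#'
#' For adjacency a' with connectivities `k_i` (diagonal excluded), the TOM is
#' `w_ij = (l_ij + a'_ij) / (min(k_i, k_j) + 1 - a'_ij)` with
#' `l_ij = sum_u a'_iu a'_uj` over third parties `u != i, j`; the diagonal is
#' defined as 1.  `1 - w` is the clustering dissimilarity.
#'
#' @param adjacency Symmetric matrix with values in `[0, 1]` (diagonal
#'   ignored).
#' @return Symmetric TOM matrix in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  check_square_symmetric(adjacency, "adjacency")
  a <- adjacency
  diag(a) <- 0
  if (min(a) < 0 || max(a) > 1) stop2("adjacency values must lie in [0, 1]")
  k <- rowSums(a)
  l <- a %*% a                       # zero diagonal kills u = i and u = j terms
  denom <- outer(k, k, pmin) + 1 - a
  w <- (l + a) / denom
  diag(w) <- 1
  w[w > 1] <- 1
  dimnames(w) <- dimnames(adjacency)
  w
}
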