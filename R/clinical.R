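# Downstream analyses of selected subnetworks: per-sample signature scores
# over leading-edge genes, score differences across tumor groups
# (Mann-Whitney), quartile-based survival splits with Kaplan-Meier curves and
# the log-rank test, and Bonferroni adjustment.

#' Per-sample signature scores over leading-edge genes
#'
#' Each gene is standardized (mean 0, variance 1) across the given samples;
#' the score of a sample is the mean of the standardized values over the
#' leading-edge genes.  Genes with zero variance across the samples are
#' dropped with a warning.
#'
#' @param expr Gene x sample matrix with dimnames.
#' @param leading_edge Nonempty character vector of gene ids present in
#'   `expr`.
#' @param samples Sample ids to score (default all columns).
#' @return Named numeric vector of scores, one per sample.
#' @export
signature_scores <- function(expr, leading_edge, samples = colnames(expr)) {
  if (length(leading_edge) == 0L) stop2("empty leading-edge gene list")
  missing_g <- setdiff(leading_edge, rownames(expr))
  if (length(missing_g) > 0L)
    stop2("genes not in expression matrix: ", paste(missing_g, collapse = ", "))
  x <- expr[leading_edge, samples, drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    if (all(sds == 0)) stop2("all leading-edge genes have zero variance")
    warn2(sum(sds == 0), " zero-variance gene(s) dropped from signature")
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (x - rowMeans(x)) / sds
  colMeans(z)
}

#' Mann-Whitney U test
#'
#' U counts the (A, B) pairs with the A value larger (ties count 1/2), i.e.
#' `U = rank-sum(A) - nA (nA + 1) / 2` with midranks, so complete separation
#' with all A below all B gives U = 0.  The two-sided p-value is exact —
#' computed from the permutation distribution of the rank sum (a
#' shift-algorithm convolution, valid under ties) — whenever
#' `nA * nB <= exact_limit`; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exact_limit Largest `nA * nB` for the exact path (default 400).
#' @return List with `u`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b, exact_limit = 400) {
  if (length(a) == 0L || length(b) == 0L) stop2("both groups must be nonempty")
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))                       # midranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n_a * n_b <= exact_limit) {
    # exact permutation distribution of the rank sum of group A; double the
    # midranks so all values are integers
    r2 <- as.integer(round(2 * r))
    dist <- ranksum_distribution(r2, n_a)
    obs <- as.integer(round(2 * sum(r[seq_len(n_a)])))
    mu <- sum(r2) * n_a / (n_a + n_b)
    dev <- abs(dist$sums - mu)
    p <- sum(dist$counts[dev >= abs(obs - mu) - 1e-9]) / sum(dist$counts)
    list(u = u, p = p, method = "exact")
  } else {
    mu <- n_a * n_b / 2
    n <- n_a + n_b
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) return(list(u = u, p = 1, method = "normal"))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    list(u = u, p = min(1, 2 * stats::pnorm(-max(0, z))), method = "normal")
  }
}

# number of size-m subsets of `values` (integers) attaining each possible sum
ranksum_distribution <- function(values, m) {
  total <- sum(values)
  # counts[s + 1, j]: subsets of size j summing to s, built value by value
  counts <- matrix(0, nrow = total + 1L, ncol = m + 1L)
  counts[1L, 1L] <- 1
  for (v in values) {
    for (j in m:1) {
      nz <- which(counts[, j] > 0)
      if (length(nz) > 0L)
        counts[nz + v, j + 1L] <- counts[nz + v, j + 1L] + counts[nz, j]
    }
  }
  nz <- which(counts[, m + 1L] > 0)
  list(sums = nz - 1L, counts = counts[nz, m + 1L])
}

#' Split samples into two groups by signature-score quartiles
#'
#' @param scores Named numeric vector of signature scores (>= 8 samples).
#' @param scheme One of `"Q1-2_vs_Q3-4"`, `"Q1-3_vs_Q4"`, `"Q1_vs_Q2-4"`; the
#'   part before `_vs_` is the `"low"` group.  Boundary ties go to the low
#'   group.
#' @return Factor with levels `low`, `high`, named by sample.
#' @export
quartile_split <- function(scores, scheme = c("Q1-2_vs_Q3-4", "Q1-3_vs_Q4",
                                              "Q1_vs_Q2-4")) {
  scheme <- match.arg(scheme)
  if (length(scores) < 8L) stop2("need >= 8 samples for a quartile split")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  cut_at <- switch(scheme,
                   "Q1-2_vs_Q3-4" = q[2L],
                   "Q1-3_vs_Q4" = q[3L],
                   "Q1_vs_Q2-4" = q[1L])
  grp <- factor(ifelse(scores <= cut_at, "low", "high"),
                levels = c("low", "high"))
  if (length(unique(grp)) < 2L)
    stop2("degenerate quartiles: all samples fall on one side of the cut")
  names(grp) <- names(scores)
  grp
}

#' Kaplan-Meier curves and the log-rank test between two groups
#'
#' Product-limit estimate per group and the standard log-rank chi-square
#' (observed vs expected events over pooled event times, 1 degree of
#' freedom), via the survival package.
#'
#' @param time Non-negative survival times.
#' @param event Event indicators (1 = disease-specific death).
#' @param group Factor with >= 2 levels.
#' @return List with `chisq`, `p`, `df`, `km` (a [survival::survfit] object)
#'   and `n_events` per group.
#' @export
km_logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop2("need >= 2 groups for the log-rank test")
  if (sum(event) == 0L) stop2("no events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  km <- survival::survfit(survival::Surv(time, event) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       df = df, km = km,
       n_events = tapply(event, group, sum))
}

#' Bonferroni adjustment
#'
#' @param p Numeric vector of p-values.
#' @param m Number of tests (default `length(p)`).
#' @return `min(1, m * p)` element-wise.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' Stage-wise signature-score summary
#'
#' For a set of ordered disease stages, emits per-stage median and quartiles
#' of the signature score plus Mann-Whitney p-values between adjacent stages
#' (the tabular counterpart of a stage boxplot).
#'
#' @param scores Named numeric vector of signature scores.
#' @param stage Factor (or character) of disease stages per sample, in the
#'   desired order of levels.
#' @return Data frame with one row per stage: `stage`, `n`, `q1`, `median`,
#'   `q3`, `p_vs_previous`.
#' @export
stage_score_table <- function(scores, stage) {
  stage <- if (is.factor(stage)) droplevels(stage) else factor(stage, levels = unique(stage))
  stopifnot(length(scores) == length(stage))
  lev <- levels(stage)
  rows <- lapply(seq_along(lev), function(i) {
    x <- scores[stage == lev[i]]
    p_prev <- if (i == 1L) NA_real_ else
      mann_whitney_u(scores[stage == lev[i - 1L]], x)$p
    data.frame(stage = lev[i], n = length(x),
               q1 = stats::quantile(x, 0.25, names = FALSE),
               median = stats::median(x),
               q3 = stats::quantile(x, 0.75, names = FALSE),
               p_vs_previous = p_prev, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
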