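# Independent brute-force oracles used to validate the optimized
# implementations, plus small fixture builders.  These deliberately use the
# most literal formulation of each definition (triple loops, exhaustive
# scans) and share no code with the package internals.

# TOM by literal triple loop over third parties
oracle_tom <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  w <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    w[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(w) <- dimnames(a)
  w
}

# enrichment score by evaluating the running sum explicitly at every position
oracle_es <- function(scores, hit, p = 1) {
  n <- length(scores)
  n_r <- sum(abs(scores[hit])^p)
  n_h <- sum(hit)
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) abs(scores[i])^p / n_r else -1 / (n - n_h)
    run[i] <- cur
  }
  peak <- which.max(abs(run))
  list(es = run[peak], peak = peak)
}

# UPGMA merge heights by direct matrix reduction (size-weighted averages)
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      if (d[active[ii], active[jj]] < bd) {
        bd <- d[active[ii], active[jj]]; best <- c(active[ii], active[jj])
      }
    }
    heights <- c(heights, bd)
    i <- best[1L]; j <- best[2L]
    for (k in setdiff(active, best))
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

# two-group log-rank chi-square by the observed-vs-expected sum over pooled
# event times
oracle_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1L)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1L)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of group-A index
# subsets
oracle_mw_exact_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n_a)])
  mu <- n_a * (n_a + n_b + 1) / 2
  combos <- utils::combn(n_a + n_b, n_a)
  sums <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# block-diagonal dissimilarity with planted tight blocks and loose background
make_block_diss <- function(block_sizes, n_noise = 0, within = 0.1, between = 1,
                            jitter = 0.02, seed = 1) {
  n <- sum(block_sizes) + n_noise
  labels <- c(rep(seq_along(block_sizes), block_sizes), rep(0L, n_noise))
  withr::with_seed(seed, {
    d <- matrix(between, n, n)
    for (b in seq_along(block_sizes)) {
      idx <- which(labels == b)
      d[idx, idx] <- within
    }
    noise <- matrix(stats::runif(n * n, 0, jitter), n, n)
    d <- d + (noise + t(noise)) / 2
    d[d > 1] <- 1
    diag(d) <- 0
    rownames(d) <- colnames(d) <- sprintf("g%03d", seq_len(n))
    list(d = d, labels = stats::setNames(labels, rownames(d)))
  })
}

# small deterministic expression fixture: genes x samples
make_expr <- function(n_genes = 10, n_samples = 8, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * n_samples, mean = 8), n_genes, n_samples)
    dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n_samples)))
    m
  })
}

# adjusted Rand index between two labelings (Hubert & Arabie)
ari <- function(x, y) mclust::adjustedRandIndex(x, y)
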