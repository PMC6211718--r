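# Similarity, primed adjacency, scale-free fit and TOM

test_that("absolute Pearson similarity handles perfect linear relations", {
  expr <- make_expr(4, 6)
  expr[2, ] <- 2 * expr[1, ] + 3      # perfectly correlated
  expr[3, ] <- -expr[1, ]             # perfectly anti-correlated
  s <- abs_pearson_similarity(expr)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], 1)            # absolute value
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(diag(s)), rep(1, 4))
})

test_that("similarity matches the pairwise correlation formula", {
  expr <- make_expr(5, 8, seed = 11)
  s <- abs_pearson_similarity(expr)
  for (i in 1:5) for (j in 1:5) {
    x <- expr[i, ]; y <- expr[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(s[i, j], abs(r), tolerance = 1e-12)
  }
})

test_that("similarity errors on tiny subsets and flags constant genes", {
  expr <- make_expr(4, 6)
  expect_error(abs_pearson_similarity(expr, colnames(expr)[1:2]), ">= 3")
  expr[4, ] <- 7
  expect_warning(s <- abs_pearson_similarity(expr), "zero-variance")
  expect_equal(nrow(s), 3L)
  expect_error(abs_pearson_similarity(expr, drop_zero_variance = FALSE),
               "zero-variance")
})

test_that("primed adjacency is the prior-masked power of the similarity", {
  expr <- make_expr(6, 10, seed = 3)
  s <- abs_pearson_similarity(expr)
  net <- relation_network(data.frame(from = c("g01", "g02", "g03"),
                                     to = c("g02", "g03", "g05")))
  p <- prior_matrix(net, rownames(s))
  a <- combined_adjacency(s, p, beta = 2)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    expect_equal(a[i, j], p[i, j] * s[i, j]^2, tolerance = 1e-12)
  }
  expect_true(all(a[p == 0 & row(p) != col(p)] == 0))
  # trivial arithmetic case
  expect_equal(unname(combined_adjacency(matrix(c(1, .5, .5, 1), 2),
                                         matrix(c(0, 1, 1, 0), 2), 2)[1, 2]),
               0.25)
})

test_that("adjacency is element-wise non-increasing in beta", {
  expr <- make_expr(8, 12, seed = 5)
  s <- abs_pearson_similarity(expr)
  p <- matrix(1, 8, 8) - diag(8)
  dimnames(p) <- dimnames(s)
  a_prev <- combined_adjacency(s, p, 1)
  for (beta in 2:6) {
    a <- combined_adjacency(s, p, beta)
    expect_true(all(a <= a_prev + 1e-15))
    a_prev <- a
  }
})

test_that("increasing a similarity entry never decreases the adjacency", {
  s <- matrix(c(1, .4, .4, 1), 2)
  p <- matrix(c(0, 1, 1, 0), 2)
  a1 <- combined_adjacency(s, p, 3)[1, 2]
  s[1, 2] <- s[2, 1] <- 0.9
  a2 <- combined_adjacency(s, p, 3)[1, 2]
  expect_gt(a2, a1)
})

test_that("exact power-law connectivity data give a perfect scale-free fit", {
  # counts 600/v at v = 10..50 are exactly linear in log-log space
  k <- rep(c(10, 20, 30, 40, 50), times = c(60, 30, 20, 15, 12))
  fit <- scale_free_fit(k, n_bins = 5)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
})

test_that("scale-free fit flags degenerate inputs", {
  expect_error(scale_free_fit(rep(3, 50)), "degenerate")
  expect_error(scale_free_fit(c(1, 2), n_bins = 5), "non-empty bins")
  expect_error(scale_free_fit(1:100, n_bins = 2), "n_bins")
})

test_that("fit index is sign-penalized when frequency increases with degree", {
  # more high-degree than low-degree nodes: slope > 0, r_squared < 0
  k <- rep(c(10, 20, 30, 40, 50), times = c(12, 15, 20, 30, 60))
  fit <- scale_free_fit(k, n_bins = 5)
  expect_gt(fit$slope, 0)
  expect_lt(fit$r_squared, 0)
})

test_that("preferential-attachment degree sequences fit scale-free topology", {
  for (seed in 1:3) {
    g <- withr::with_seed(seed, igraph::sample_pa(2000, m = 2, directed = FALSE))
    fit <- scale_free_fit(igraph::degree(g))
    expect_gte(fit$r_squared, 0.8)
    expect_lt(fit$slope, 0)
  }
})

test_that("soft-threshold search returns the smallest admissible power", {
  # a prior-masked similarity whose masked connectivity is already scale-free
  # at beta = 1: power-law degree graph with near-1 correlations on edges
  g <- withr::with_seed(4, igraph::sample_pa(300, m = 2, directed = FALSE))
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  ids <- sprintf("g%03d", 1:300)
  dimnames(adj) <- list(ids, ids)
  sim <- matrix(0.999, 300, 300, dimnames = dimnames(adj))
  diag(sim) <- 1
  pick <- pick_soft_threshold(sim, adj, beta_grid = 1:5)
  expect_true(pick$target_met)
  expect_equal(pick$beta, 1L)
})

test_that("soft-threshold search flags data where no power meets the target", {
  withr::with_seed(9, {
    sim <- abs(stats::cor(matrix(stats::rnorm(40 * 10), 10)))
  })
  ids <- sprintf("g%02d", 1:40)
  dimnames(sim) <- list(ids, ids)
  p <- matrix(1, 40, 40) - diag(40)
  dimnames(p) <- dimnames(sim)
  pick <- suppressWarnings(pick_soft_threshold(sim, p, beta_grid = 1:3,
                                               r2_target = 0.999))
  expect_false(pick$target_met)
  expect_equal(pick$beta, pick$fits$beta[which.max(pick$fits$r_squared)])
})

test_that("TOM matches its defining formula on canonical cases", {
  # triangle with unit adjacencies: l = 1, k = 2 -> (1 + 1) / (2 + 1 - 1) = 1
  tri <- matrix(1, 3, 3)
  expect_equal(unname(topological_overlap(tri)), matrix(1, 3, 3))
  # isolated non-adjacent pair
  iso <- diag(2)
  expect_equal(topological_overlap(iso)[1, 2], 0)
})

test_that("TOM equals the brute-force triple loop on random instances", {
  for (seed in 1:5) {
    n <- withr::with_seed(seed, sample(20:50, 1))
    a <- withr::with_seed(seed + 100, {
      m <- matrix(stats::runif(n * n), n)
      m <- (m + t(m)) / 2
      m[m < 0.5] <- 0            # sparse, like a masked adjacency
      diag(m) <- 1
      m
    })
    expect_lt(max(abs(topological_overlap(a) - oracle_tom(a))), 1e-10)
  }
})

test_that("TOM commutes with gene reordering", {
  a <- withr::with_seed(2, {
    m <- matrix(stats::runif(100), 10)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(letters[1:10], letters[1:10])
    m
  })
  perm <- withr::with_seed(3, sample(10))
  expect_equal(topological_overlap(a)[perm, perm],
               topological_overlap(a[perm, perm]))
})
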