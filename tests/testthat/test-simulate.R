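# Synthetic-data generator: planted correlation structure, prior network,
# survival linkage, determinism

test_that("within-module correlation tracks the factor-model value rho^2", {
  spec <- synthetic_spec(n_genes = 60, n_samples = c(100, 100),
                         module_sizes = c(30), rho = 0.8,
                         delta = rbind(c(0, 0)))
  ds <- generate_expression(spec, seed = 51)
  members <- names(ds$truth)[ds$truth == 1]
  cors <- stats::cor(t(ds$expr[members, ]))
  mean_cor <- mean(cors[upper.tri(cors)])
  expect_lt(abs(mean_cor - 0.64), 0.05)

  spec0 <- synthetic_spec(n_genes = 60, n_samples = c(100, 100),
                          module_sizes = c(30), rho = 0,
                          delta = rbind(c(0, 0)))
  ds0 <- generate_expression(spec0, seed = 52)
  cors0 <- stats::cor(t(ds0$expr[members, ]))
  expect_lt(max(abs(cors0[upper.tri(cors0)])), 0.35)
  expect_lt(abs(mean(cors0[upper.tri(cors0)])), 0.05)
})

test_that("equal group shifts give a null differential signal", {
  spec <- synthetic_spec(n_genes = 80, n_samples = c(40, 40),
                         module_sizes = c(30), rho = 0.7,
                         delta = rbind(c(0.5, 0.5)))
  ds <- generate_expression(spec, seed = 53)
  g1 <- ds$annotation$sample_id[ds$annotation$group == "groupA"]
  g2 <- ds$annotation$sample_id[ds$annotation$group == "groupB"]
  d <- sam_statistic(ds$expr, g1, g2, s0 = 0.1)$d
  members <- names(ds$truth)[ds$truth == 1]
  expect_lt(abs(mean(d[members])), 0.3)
})

test_that("planted shifts separate the groups in the module genes", {
  spec <- synthetic_spec(n_genes = 80, n_samples = c(40, 40),
                         module_sizes = c(30), rho = 0.8,
                         delta = rbind(c(0, 1)))
  ds <- generate_expression(spec, seed = 54)
  g1 <- ds$annotation$sample_id[ds$annotation$group == "groupA"]
  g2 <- ds$annotation$sample_id[ds$annotation$group == "groupB"]
  d <- sam_statistic(ds$expr, g1, g2, s0 = 0.1)$d
  members <- names(ds$truth)[ds$truth == 1]
  background <- names(ds$truth)[ds$truth == 0]
  expect_gt(mean(d[members]), mean(d[background]) + 0.5)
})

test_that("prior network respects overlap and q_in settings", {
  base <- list(n_genes = 100, n_samples = c(10, 10), module_sizes = c(20, 20),
               rho = 0.8, delta = rbind(c(0, 1), c(0, 0)))
  # no coverage: no within-module prior edges
  spec0 <- do.call(synthetic_spec, c(base, overlap = 0, q_in = 1, pa_m = 0))
  ds <- generate_expression(spec0, seed = 55)
  pr0 <- generate_prior_network(spec0, ds$truth, seed = 56)
  expect_equal(nrow(pr0$network$edges), 0L)
  # full coverage at q_in = 1: covered subgraphs complete
  spec1 <- do.call(synthetic_spec, c(base, overlap = 1, q_in = 1, pa_m = 0))
  pr1 <- generate_prior_network(spec1, ds$truth, seed = 57)
  expect_equal(nrow(pr1$network$edges), 2 * choose(20, 2))
  pm <- prior_matrix(pr1$network, names(ds$truth)[ds$truth == 1])
  expect_true(all(pm[upper.tri(pm)] == 1))
})

test_that("background prior graph has scale-free degree structure", {
  spec <- synthetic_spec(n_genes = 2000, n_samples = c(5, 5),
                         module_sizes = c(10), rho = 0,
                         delta = rbind(c(0, 0)), overlap = 0, pa_m = 2)
  truth <- stats::setNames(c(rep(1L, 10), rep(0L, 1990)),
                           sprintf("g%04d", 1:2000))
  pr <- generate_prior_network(spec, truth, seed = 58)
  pm <- prior_matrix(pr$network, names(truth))
  fit <- scale_free_fit(rowSums(pm))
  expect_gte(fit$r_squared, 0.8)
})

test_that("survival times respond to the module score", {
  spec <- synthetic_spec(n_genes = 50, n_samples = c(100, 100),
                         module_sizes = c(20), rho = 0.8,
                         delta = rbind(c(0, 0)), survival_coef = 1.5)
  ds <- generate_expression(spec, seed = 59)
  su <- generate_survival(spec, ds$module_scores, seed = 60)
  grp <- factor(ifelse(ds$module_scores[, 1] > stats::median(ds$module_scores[, 1]),
                       "high", "low"))
  res <- km_logrank(su$survival_time, su$event, grp)
  expect_lt(res$p, 0.01)

  # zero horizon: everything censored at 0
  spec0 <- spec; spec0$survival_horizon <- 0
  su0 <- generate_survival(spec0, ds$module_scores, seed = 61)
  expect_true(all(su0$survival_time == 0))
  expect_true(all(su0$event == 0))
})

test_that("null-hazard survival keeps the log-rank test near its nominal level", {
  spec <- synthetic_spec(n_genes = 10, n_samples = c(40, 40),
                         module_sizes = c(5), rho = 0.5,
                         delta = rbind(c(0, 0)), survival_coef = 0)
  ds <- generate_expression(spec, seed = 62)
  rejections <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    su <- generate_survival(spec, ds$module_scores, seed = 1000 + r)
    grp <- factor(ifelse(ds$module_scores[, 1] > stats::median(ds$module_scores[, 1]),
                         "high", "low"))
    if (km_logrank(su$survival_time, su$event, grp)$p < 0.05)
      rejections <- rejections + 1L
  }
  # binomial(200, 0.05): mean 10, sd ~3; allow 4 sd
  expect_lt(rejections / n_rep, 0.115)
})

test_that("the generator is deterministic and satisfies reader invariants", {
  spec <- synthetic_spec(n_genes = 120, n_samples = c(15, 15),
                         module_sizes = c(25, 20),
                         delta = rbind(c(0, 1), c(1, 0)))
  d1 <- simulate_dataset(spec, seed = 63)
  d2 <- simulate_dataset(spec, seed = 63)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(spec, seed = 64)
  expect_false(identical(d1$expr, d3$expr))

  # files written from the dataset read back clean, without warnings
  dir <- withr::local_tempdir()
  write_expression_table(d1$expr, file.path(dir, "e.tsv"))
  write_edge_list(d1$prior, file.path(dir, "p.tsv"))
  expect_no_warning(expr <- read_expression_table(file.path(dir, "e.tsv")))
  expect_no_warning(net <- read_edge_list(file.path(dir, "p.tsv")))
  expect_identical(expr, d1$expr)
  expect_identical(net$edges, d1$prior$edges)
})
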