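# Signature scores, Mann-Whitney, quartile splits, KM/log-rank, Bonferroni

test_that("a single-gene signature is that gene's z-score", {
  expr <- make_expr(5, 6, seed = 41)
  sc <- signature_scores(expr, "g01")
  z <- (expr["g01", ] - mean(expr["g01", ])) / stats::sd(expr["g01", ])
  expect_equal(sc, z)
})

test_that("signature scores are invariant to positive affine gene transforms", {
  expr <- make_expr(4, 8, seed = 42)
  genes <- c("g01", "g02", "g03")
  sc <- signature_scores(expr, genes)
  transformed <- expr
  transformed["g02", ] <- 3.7 * expr["g02", ] + 11
  expect_equal(signature_scores(transformed, genes), sc)
})

test_that("signature scores match a hand-computed 3-gene 4-sample case", {
  expr <- rbind(gA = c(1, 2, 3, 4), gB = c(2, 2, 4, 4), gC = c(10, 0, 10, 0))
  colnames(expr) <- paste0("s", 1:4)
  sc <- signature_scores(expr, c("gA", "gB", "gC"))
  hand <- colMeans(rbind((expr["gA", ] - 2.5) / stats::sd(expr["gA", ]),
                         (expr["gB", ] - 3) / stats::sd(expr["gB", ]),
                         (expr["gC", ] - 5) / stats::sd(expr["gC", ])))
  expect_equal(sc, hand, tolerance = 1e-12)
  # order invariance in genes and samples
  expect_equal(signature_scores(expr[c(3, 1, 2), ], c("gC", "gB", "gA")), sc)
  expect_equal(signature_scores(expr[, c(4, 2, 1, 3)], c("gA", "gB", "gC"))[paste0("s", 1:4)],
               sc[paste0("s", 1:4)])
})

test_that("zero-variance signature genes are dropped with a warning", {
  expr <- make_expr(3, 6, seed = 43)
  expr["g02", ] <- 5
  expect_warning(sc <- signature_scores(expr, c("g01", "g02")), "zero-variance")
  expect_equal(sc, signature_scores(expr, "g01"))
  expr["g01", ] <- 2; expr["g03", ] <- 9
  expect_error(suppressWarnings(signature_scores(expr, c("g01", "g02"))), "all")
})

test_that("Mann-Whitney U follows the documented conventions", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # complete separation, A < B
  expect_equal(res$u, 0)
  tied <- mann_whitney_u(rep(1, 4), rep(1, 5))
  expect_equal(tied$u, 4 * 5 / 2)
  expect_equal(tied$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney p equals exhaustive enumeration", {
  withr::with_seed(44, {
    a <- stats::rnorm(4); b <- stats::rnorm(5) + 0.8
  })
  res <- mann_whitney_u(a, b)
  expect_equal(res$method, "exact")
  expect_equal(res$p, oracle_mw_exact_p(a, b), tolerance = 1e-12)
  # with ties present the exact path still matches enumeration
  a2 <- c(1, 2, 2, 3); b2 <- c(2, 3, 3, 4, 5)
  expect_equal(mann_whitney_u(a2, b2)$p, oracle_mw_exact_p(a2, b2),
               tolerance = 1e-12)
})

test_that("tie-free exact p agrees with wilcox.test's exact p", {
  withr::with_seed(45, {
    a <- stats::rnorm(6); b <- stats::rnorm(7)
  })
  expect_equal(mann_whitney_u(a, b)$p,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("large samples switch to the tie-corrected normal approximation", {
  withr::with_seed(46, {
    a <- stats::rnorm(25); b <- stats::rnorm(25) + 1
  })
  res <- mann_whitney_u(a, b)
  expect_equal(res$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(res$p, ref, tolerance = 1e-10)
})

test_that("quartile splits follow the scheme tokens with ties to the low group", {
  sc <- stats::setNames(1:8, paste0("s", 1:8))
  half <- quartile_split(sc, "Q1-2_vs_Q3-4")
  expect_equal(unname(half), factor(rep(c("low", "high"), each = 4),
                                    levels = c("low", "high")))
  top <- quartile_split(sc, "Q1-3_vs_Q4")
  expect_equal(sum(top == "high"), 2L)
  bottom <- quartile_split(sc, "Q1_vs_Q2-4")
  expect_equal(sum(bottom == "low"), 2L)
  expect_error(quartile_split(sc[1:5]), ">= 8")
  expect_error(quartile_split(stats::setNames(rep(1, 10), 1:10)), "degenerate")
})

test_that("log-rank is zero for identical groups and matches the hand oracle", {
  time <- c(5, 8, 12, 20, 30)
  event <- c(1, 1, 0, 1, 0)
  dup <- list(time = rep(time, 2), event = rep(event, 2),
              group = rep(c("x", "y"), each = 5))
  res <- km_logrank(dup$time, dup$event, dup$group)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  toy <- data.frame(time = c(3, 5, 7, 9, 11, 4, 6, 8, 10, 12),
                    event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0),
                    group = rep(c("lo", "hi"), each = 5))
  res2 <- km_logrank(toy$time, toy$event, toy$group)
  expect_equal(res2$chisq, oracle_logrank(toy$time, toy$event, toy$group),
               tolerance = 1e-10)
  expect_error(km_logrank(time, event, rep("x", 5)), ">= 2 groups")
  expect_error(km_logrank(time, rep(0, 5), rep(c("x", "y"), c(2, 3))),
               "no events")
})

test_that("KM curves are non-increasing from 1 and match the empirical survival", {
  time <- c(2, 4, 6, 8, 10, 3, 5, 7, 9, 11)
  event <- rep(1, 10)                    # no censoring
  group <- rep(c("a", "b"), each = 5)
  res <- km_logrank(time, event, group)
  s <- summary(res$km)
  expect_true(all(s$surv <= 1))
  for (g in c("a", "b")) {
    surv_g <- s$surv[grepl(g, as.character(s$strata))]
    expect_true(all(diff(surv_g) < 0))
    expect_equal(surv_g, (4:0) / 5)      # empirical step function
  }
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroni_adjust(0.01, m = 9), 0.09)
  expect_equal(bonferroni_adjust(0.5, m = 9), 1.0)
  expect_equal(bonferroni_adjust(c(0.01, 0.5, 0.001)),
               c(0.03, 1.0, 0.003))
})

test_that("stage table reports quartiles and adjacent-stage comparisons", {
  withr::with_seed(47, {
    scores <- c(stats::rnorm(10), stats::rnorm(10) + 2, stats::rnorm(10) + 4)
  })
  stage <- factor(rep(c("CAH", "G1", "G2"), each = 10),
                  levels = c("CAH", "G1", "G2"))
  names(scores) <- paste0("s", seq_along(scores))
  tab <- stage_score_table(scores, stage)
  expect_equal(tab$stage, c("CAH", "G1", "G2"))
  expect_true(is.na(tab$p_vs_previous[1]))
  expect_true(all(tab$p_vs_previous[-1] < 0.05))
  expect_true(all(diff(tab$median) > 0))
})
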