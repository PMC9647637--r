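# Classical inference: odds ratios, Fisher, Box-Cox, LMM, Spearman,
# Mann-Whitney, t tests.

test_that("Wald odds ratios: published-style cells and inverse symmetry", {
  r <- odds_ratio_wald(18, 7, 1, 4)
  expect_equal(round(r$or, 2), 10.29)
  expect_equal(round(r$lower, 2), 0.97)
  expect_equal(round(r$upper, 2), 108.81)

  expect_equal(round(odds_ratio_wald(11, 10, 8, 1)$or, 2), 0.14)

  r5 <- odds_ratio_wald(5, 5, 5, 5)
  expect_equal(r5$or, 1)
  expect_equal(log(r5$upper), -log(r5$lower), tolerance = 1e-12)

  # OR(a,b,c,d) * OR(b,a,d,c) = 1
  x <- odds_ratio_wald(7, 3, 2, 9); y <- odds_ratio_wald(3, 7, 9, 2)
  expect_equal(x$or * y$or, 1, tolerance = 1e-12)

  # zero cell triggers flagged continuity correction
  z <- odds_ratio_wald(5, 0, 2, 3)
  expect_true(z$corrected)
  expect_true(is.finite(z$upper))
})

test_that("Fisher exact p: enumeration oracle, modal table, transpose symmetry", {
  # margins (2,2): three tables with probs 1/6, 4/6, 1/6 => p(2,0,0,2)=2/6...
  # observed table prob 1/6; sum of probs <= 1/6 is 1/6+1/6 = 1/3
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(7, 2, 3, 8), fisher_exact_2x2(7, 3, 2, 8),
               tolerance = 1e-12)
  # direction agreement: OR > 1 iff a above hypergeometric expectation
  expect_gt(odds_ratio_wald(8, 2, 3, 7)$or, 1)
  expect_gt(8, (8 + 2) * (8 + 3) / 20)
})

test_that("Box-Cox: closed forms and lognormal lambda-hat", {
  y <- c(1, 2, 4, 9)
  expect_equal(boxcox_transform(y, lambda = 1)$values, y - 1)
  expect_equal(boxcox_transform(y, lambda = 0)$values, log(y))
  set.seed(4)
  y <- exp(rnorm(500, 1, 0.4))
  bc <- boxcox_transform(y)
  expect_gte(bc$lambda, -0.2)
  expect_lte(bc$lambda, 0.2)
  # zero counts are shifted, flagged
  bz <- boxcox_transform(c(0, 1, 3), lambda = 0)
  expect_true(bz$shifted)
  expect_equal(bz$values[1], log(0.5))
})

test_that("random-intercept LMM degenerates to OLS and recovers effects", {
  # zero planted group variance; REML lands on the boundary here, so the
  # fit must agree with ordinary least squares (degenerate-limit oracle)
  set.seed(3)
  n <- 240; g <- rep(1:40, each = 6)
  x <- rnorm(n)
  y <- 1 + 0.5 * x + rnorm(n, 0, 1)
  fit <- fit_random_intercept_lmm(y, data.frame(x = x), g)
  ols <- coef(lm(y ~ x))
  expect_equal(fit$var_intercept, 0, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 1e-6)

  # planted random-intercept + fixed effect recovery
  set.seed(11)
  g <- rep(1:200, each = 4)
  b <- rnorm(200, 0, 0.5)[g]
  x <- rbinom(800, 1, 0.5)
  y <- 2 + 0.7 * x + b + rnorm(800, 0, 0.6)
  fit <- fit_random_intercept_lmm(y, data.frame(x = x), g)
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_lt(abs(est - 0.7), 0.15)
  expect_gt(fit$var_intercept, 0.1)

  expect_error(fit_random_intercept_lmm(y, data.frame(x = x, x2 = x), g),
               "collinear")
  expect_error(fit_random_intercept_lmm(y[1:4], data.frame(x = x[1:4]),
                                        rep(1, 4)), "2 groups")
})

test_that("Spearman screen: monotone transforms and null levels", {
  set.seed(5)
  X <- data.frame(a = rnorm(500), b = rnorm(500))
  y <- exp(X$a)                              # monotone in a
  sp <- spearman_matrix(X, y)
  expect_equal(sp$rho["a", "outcome"], 1)
  expect_true(sp$significant["a", "outcome"])
  # independent columns: |rho| small for 95% of pairs
  Xn <- as.data.frame(matrix(rnorm(500 * 8), 500))
  spn <- spearman_matrix(Xn)
  offd <- abs(spn$rho[upper.tri(spn$rho)])
  expect_gte(mean(offd < 0.12), 0.95)
})

test_that("Mann-Whitney: enumeration oracle and symmetry", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  x <- c(1, 5, 7, 8); y <- c(2, 3, 9, 11)
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(y, x)$p,
               tolerance = 1e-12)
  same <- c(1, 2, 3, 4, 5)
  expect_gte(mann_whitney_u(same, same)$p, 0.99)
})

test_that("t test: equal samples, planted-shift power, normality helper", {
  x <- c(1, 2, 3, 4)
  r <- welch_or_student_t(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  set.seed(6)
  hits <- 0
  for (i in 1:50) {
    a <- rnorm(100); b <- rnorm(100, 1)
    if (welch_or_student_t(a, b)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.99 - 1e-9)
  expect_true(all(r$normality_p > 0 | is.na(r$normality_p)))
})
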