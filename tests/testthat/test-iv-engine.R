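test_that("OLS reproduces hand-computed normal equations", {
  fit <- olsFit(c(1, 3, 5), c(0, 1, 2))
  expect_equal(unname(estimate(fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(fit@sigma2, 0, tolerance = 1e-20)
  # exact linear relation with more points: zero residual variance
  x <- seq_len(20)
  fit2 <- olsFit(2 * x, x)
  expect_equal(unname(estimate(fit2)[["x"]]), 2, tolerance = 1e-12)
  expect_lt(fit2@sigma2, 1e-20)
})

test_that("rank-deficient designs are rejected", {
  set.seed(81)
  x <- rnorm(30)
  expect_error(olsFit(rnorm(30), x, covariates = cbind(x, x)),
               "rank-deficient")
})

test_that("logistic fit recovers the 2x2 closed-form odds ratio", {
  y <- c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40))
  x <- c(rep(1, 30), rep(0, 70))
  fit <- logisticFit(y, x, or_scale = TRUE)
  expect_equal(unname(estimate(fit)[["x"]]), (10 * 40) / (20 * 30),
               tolerance = 1e-6)
  expect_error(logisticFit(rep(1, 20), rnorm(20)), "both outcome classes")
  # null association: CI covers OR = 1
  set.seed(82)
  y2 <- rbinom(3000, 1, 0.3)
  f2 <- logisticFit(y2, rnorm(3000), or_scale = TRUE)
  expect_lt(f2@ci_low[["x"]], 1)
  expect_gt(f2@ci_high[["x"]], 1)
})

test_that("perfect separation is detected", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  expect_error(logisticFit(y, x), "separation|non-convergence")
})

test_that("2SLS equals the Wald ratio when just-identified", {
  for (s in 1:5) {
    fx <- makeIvFixture(300, seed = 90 + s)
    iv <- tslsFit(fx$y, fx$x, fx$z)
    expect_equal(estimate(iv), waldRatio(fx$y, fx$x, fx$z),
                 tolerance = 1e-10)
  }
})

test_that("2SLS with instrument = exposure reproduces OLS", {
  fx <- makeIvFixture(500, seed = 96)
  iv <- tslsFit(fx$y, fx$x, fx$x)
  ols <- olsFit(fx$y, fx$x)
  expect_equal(estimate(iv), unname(estimate(ols)[["x"]]), tolerance = 1e-10)
  expect_equal(stdError(iv), unname(stdError(ols)[["x"]]), tolerance = 1e-10)
  # with covariates too
  cv <- rnorm(500)
  iv2 <- tslsFit(fx$y, fx$x, fx$x, covariates = cv)
  ols2 <- olsFit(fx$y, fx$x, covariates = cv)
  expect_equal(estimate(iv2), unname(estimate(ols2)[["x"]]),
               tolerance = 1e-10)
})

test_that("collinear instruments are rejected", {
  fx <- makeIvFixture(100, seed = 97)
  cv <- fx$z
  expect_error(tslsFit(fx$y, fx$x, fx$z, covariates = cv), "collinear")
})

test_that("first-stage F matches an explicit nested-model ANOVA", {
  set.seed(98)
  n <- 100
  z <- rnorm(n); cv <- rnorm(n)
  x <- 0.4 * z + 0.3 * cv + rnorm(n)
  d <- firstStageDiagnostics(x, z, covariates = cv)
  a <- anova(lm(x ~ cv), lm(x ~ cv + z))
  expect_equal(unname(d[["F"]]), a$F[2], tolerance = 1e-8)
  r <- sum(resid(lm(x ~ cv))^2)
  f <- sum(resid(lm(x ~ cv + z))^2)
  expect_equal(unname(d[["partial_r2"]]), (r - f) / r, tolerance = 1e-10)
  # multi-instrument q > 1
  Z <- cbind(z, rnorm(n))
  d2 <- firstStageDiagnostics(x, Z, covariates = cv)
  a2 <- anova(lm(x ~ cv), lm(x ~ cv + Z))
  expect_equal(unname(d2[["F"]]), a2$F[2], tolerance = 1e-8)
})

test_that("orthogonal instruments give F near 1 and tiny partial R2", {
  set.seed(99)
  reps <- replicate(200, {
    x <- rnorm(300); z <- rnorm(300)
    firstStageDiagnostics(x, z)
  })
  expect_lt(abs(mean(reps["F", ]) - 1), 0.35)
  expect_lt(mean(reps["partial_r2", ]), 0.01)
})

test_that("the planted instrument-strength/F relation holds", {
  # partial R2 ~ 0.028 at n = 4,296 implies F around pr2/(1-pr2) * (n-k)
  truth <- TrueParams(score_r2 = 0.028, h2_activity = 0)
  Fs <- vapply(1:5, function(s) {
    sim <- simulateCohort(4296, syntheticBmiPanel(), truth,
                          n_background = 0, seed = 600 + s)
    st <- sim$diagnostics$structural
    firstStageDiagnostics(st$exposure_z, st$score)[["F"]]
  }, numeric(1))
  expect_gt(mean(Fs), 100)
  expect_lt(mean(Fs), 150)
})

test_that("DWH statistic is scale-invariant, non-negative and powerful", {
  fx <- makeIvFixture(2000, seed = 100)
  d1 <- durbinWuHausman(fx$y, fx$x, fx$z)
  d2 <- durbinWuHausman(fx$y * 7.3, fx$x, fx$z)
  expect_equal(d1[["statistic"]], d2[["statistic"]], tolerance = 1e-10)
  expect_gte(d1[["statistic"]], 0)
  # strong confounding, strong instrument: decisive rejection
  fx2 <- makeIvFixture(10000, gamma = 1, conf = 0.8, seed = 101)
  expect_lt(durbinWuHausman(fx2$y, fx2$x, fx2$z)[["p"]], 0.001)
})

test_that("the null DWH statistic follows chi-squared(1)", {
  set.seed(102)
  stats <- replicate(2000, {
    n <- 200
    z <- rnorm(n); x <- 0.4 * z + rnorm(n); y <- 0.2 * x + rnorm(n)
    durbinWuHausman(y, x, z)[["statistic"]]
  })
  ks <- suppressWarnings(ks.test(stats, function(q) pchisq(q, 1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("fitted results serialize to tidy tables", {
  fx <- makeIvFixture(200, seed = 103)
  iv <- tslsFit(fx$y, fx$x, fx$z)
  td <- tidyFit(iv)
  expect_identical(names(td),
                   c("term", "estimate", "se", "ci_low", "ci_high", "p"))
  ols <- olsFit(fx$y, fx$x)
  expect_identical(nrow(tidyFit(ols)), 2L)
})
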