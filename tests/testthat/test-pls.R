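test_that("PLS1 recovers an exact linear dependence with one component", {
  x <- cbind(x1 = seq(0, 10, length.out = 12))
  y <- 2 * x[, 1] + 3
  fit <- pls1_fit(x, y, ncomp = 1)
  expect_equal(unname(coef(fit)), c(3, 2), tolerance = 1e-10)
  expect_equal(predict(fit, x), y, tolerance = 1e-10)
  expect_equal(fit$rmsec, 0, tolerance = 1e-10)
})

test_that("full-component PLS1 equals ordinary least squares", {
  for (seed in c(2, 13, 57)) {
    d <- simulate_pls_data(seed = seed, design = "uniform")
    x <- as.matrix(d[ulva_factors()])
    fit <- pls1_fit(x, d$y, ncomp = 4)
    expect_equal(unname(coef(fit)), unname(ols_coefficients(x, d$y)),
      tolerance = 1e-8
    )
  }
})

test_that("zero-variance predictors are dropped; rank truncation applies", {
  x <- cbind(a = rnorm(10), b = rep(1, 10))
  y <- 2 * x[, "a"]
  expect_warning(fit <- pls1_fit(x, y, ncomp = 2), "zero-variance")
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "b"], 0)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "a"], 2,
    tolerance = 1e-8
  )
})

test_that("percent-yield model puts the largest standardised weight on acid", {
  fit <- pls_outcome(ulva_runs(), "yield", ncomp = 4)
  co <- fit$fit$coefficients
  expect_gt(co$estimate_scaled[co$term == "acid_pct"], 0)
  expect_equal(
    co$term[which.max(abs(co$estimate_scaled))],
    "acid_pct"
  )
})

test_that("cross-validation statistics behave on clean and degenerate data", {
  x <- cbind(x1 = seq(1, 16), x2 = c(seq(8, 1), seq(1, 8)))
  y <- 1.5 * x[, 1] - 0.5 * x[, 2] + 4
  cv <- loo_cv(x, y, ncomp = 2)
  expect_lt(cv$rmsecv, 1e-8)
  expect_equal(cv$band, "excellent") # divergent RPD
  expect_error(loo_cv(x, rep(1, 16), ncomp = 2), "degenerate response")
  expect_error(loo_cv(x[1:2, ], y[1:2]), "at least 3")
})

test_that("RPD times RMSECV equals the response standard deviation", {
  for (seed in c(1, 9)) {
    d <- simulate_pls_data(seed = seed)
    cv <- loo_cv(as.matrix(d[ulva_factors()]), d$y, ncomp = 2)
    expect_equal(cv$rpd * cv$rmsecv, sd(d$y))
  }
})

test_that("RMSECV is invariant to predictor rescaling under autoscaling", {
  d <- simulate_pls_data(seed = 3)
  x <- as.matrix(d[ulva_factors()])
  x_scaled <- sweep(x, 2, c(10, 0.1, 100, 3), "*")
  for (nc in 1:4) {
    expect_equal(
      loo_cv(x, d$y, ncomp = nc)$rmsecv,
      loo_cv(x_scaled, d$y, ncomp = nc)$rmsecv,
      tolerance = 1e-10
    )
  }
})

test_that("RMSECV approximates the planted noise level", {
  # gaussian noise sd 2 at n = 16: the cross-validated error should sit
  # near the noise floor on average
  rms <- vapply(1:50, function(s) {
    d <- simulate_pls_data(seed = 400 + s)
    loo_cv(as.matrix(d[ulva_factors()]), d$y, ncomp = 4)$rmsecv
  }, numeric(1))
  expect_lt(abs(mean(rms) - 2) / 2, 0.3)
})

test_that("RPD bands have left-closed boundaries", {
  expect_equal(rpd_band(2.02), "quantitative prediction possible")
  expect_equal(rpd_band(1.49), "unusable")
  expect_equal(rpd_band(1.5), "distinguish high/low")
  expect_equal(rpd_band(2.0), "quantitative prediction possible")
  expect_equal(rpd_band(2.5), "excellent")
  expect_equal(rpd_band(3.0), "excellent")
  expect_equal(rpd_band(Inf), "excellent")
  expect_error(rpd_band(0), "positive")
})

test_that("Martens uncertainty flags exactly the informative predictor when noiseless", {
  set.seed(8)
  x <- cbind(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  y <- 5 * x[, "c"]
  mut <- martens_uncertainty(x, y, ncomp = 3)
  expect_true(mut$significant[mut$term == "c"])
  expect_false(any(mut$significant[mut$term != "c"]))
})

test_that("Martens uncertainty flags acid for the percent-yield outcome", {
  mut <- martens_uncertainty(
    as.matrix(ulva_runs()[ulva_factors()]),
    ulva_runs()$yield_mean,
    ncomp = 1
  )
  expect_true(mut$significant[mut$term == "acid_pct"])
})

test_that("log10 transform floors zeros and reports them", {
  expect_equal(as.numeric(log10_floor(100)), 2)
  expect_equal(as.numeric(log10_floor(0)), -3)
  expect_true(attr(log10_floor(c(0, 5)), "floored")[1])
  glc <- log10_floor(ulva_runs()$glucose_mean)
  expect_equal(range(glc), c(-3, log10(8137.7)))
  expect_error(log10_floor(1, floor = 0), "positive")
})

test_that("component count is selected by minimum cross-validated error", {
  m <- pls_outcome(ulva_runs(), "glucose")
  rms <- vapply(
    1:4,
    function(a) {
      loo_cv(as.matrix(ulva_runs()[ulva_factors()]), ulva_runs()$glucose_mean,
        ncomp = a
      )$rmsecv
    },
    numeric(1)
  )
  expect_equal(m$ncomp, which.min(rms))
  gl <- glance(m)
  expect_equal(gl$rmsecv, min(rms))
  expect_true(all(c("rmsec", "rpd", "band") %in% names(gl)))
})
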