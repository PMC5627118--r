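test_that("model enumeration has the right combinatorics and order", {
  vars11 <- paste0("v", sprintf("%02d", 1:11))
  expect_length(enumerate_models(vars11, size = 4, exact = TRUE), choose(11, 4))

  both <- enumerate_models(letters[1:3], size = 2, exact = FALSE)
  expect_length(both, 6)
  expect_length(enumerate_models(letters[1:5], size = 2, exact = TRUE), 10)

  # deterministic ordering
  expect_identical(
    enumerate_models(letters[1:4], size = 2),
    enumerate_models(letters[1:4], size = 2)
  )
  expect_error(enumerate_models(character(0)), "empty")
  expect_error(enumerate_models(letters[1:3], size = 4), "exceeds")
})

test_that("the Gompertz fit matches the normal-equations solution", {
  d <- linear_frame(n = 22, noise_sd = 0.3, seed = 61)
  fit <- fit_gompertz(d, c("x1", "x2", "x3"))

  z <- scale(as.matrix(d[c("x1", "x2", "x3")]))
  design <- cbind(1, z)
  beta <- solve(t(design) %*% design, t(design) %*% d$log_area)
  expect_equal(unname(fit$coefficients), unname(beta[-1]), tolerance = 1e-10)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)

  # residuals orthogonal to every included covariate
  expect_lt(max(abs(crossprod(z, fit$residuals))), 1e-8)

  # ML likelihood identity
  rss <- sum(fit$residuals^2)
  expect_equal(
    fit$loglik,
    -(22 / 2) * (log(2 * pi * rss / 22) + 1),
    tolerance = 1e-12
  )

  # noiseless data are interpolated exactly
  d0 <- linear_frame(n = 22, noise_sd = 0, seed = 62)
  fit0 <- fit_gompertz(d0, c("x1", "x2", "x3"))
  expect_equal(
    unname(fit0$coefficients / apply(d0[c("x1", "x2", "x3")], 2, sd)),
    c(-0.5, 0.3, 0),
    tolerance = 1e-8
  )
  expect_equal(fit0$r2, 1, tolerance = 1e-12)
})

test_that("singular designs are flagged and excluded from ranking", {
  d <- linear_frame(n = 22, seed = 63)
  d$x1_copy <- d$x1
  fit <- fit_gompertz(d, c("x1", "x1_copy"))
  expect_true(fit$singular)
  expect_true(is.na(fit$loglik))

  ms <- best_subset_gompertz(d, c("x1", "x1_copy", "x2"), size = 2)
  expect_equal(sum(ms$fits$singular), 1)
  expect_equal(sum(ms$fits$weight), 1, tolerance = 1e-12)
  expect_equal(ms$fits$weight[ms$fits$singular], 0)
})

test_that("BIC, deltas and weights follow their defining formulas", {
  expect_equal(bic_gaussian(0, 0, 1, extra_params = 0), 0)
  expect_equal(bic_gaussian(10, 3, 22), -20 + 5 * log(22))

  w <- model_weights(c(100, 100))
  expect_equal(w$weight, c(0.5, 0.5))
  expect_equal(model_weights(5)$weight, 1)

  mixed <- model_weights(c(10, 12, NA))
  expect_equal(mixed$weight[3], 0)
  expect_equal(sum(mixed$weight), 1, tolerance = 1e-12)
  # weight ratio depends only on the BIC difference
  expect_equal(mixed$weight[2] / mixed$weight[1], exp(-1), tolerance = 1e-12)

  expect_error(model_weights(c(NA, NA)), "finite")
})

test_that("importance, averaging and the confidence set follow the weights", {
  d <- linear_frame(n = 22, betas = c(x1 = -0.8, x2 = 0.4, x3 = 0),
                    noise_sd = 0.25, seed = 67)
  ms <- best_subset_gompertz(d, c("x1", "x2", "x3"), size = 2, exact = FALSE)

  w <- ms$fits$weight
  in_model <- vapply(ms$fits$model, function(m) "x1" %in% m, logical(1))
  expect_equal(
    variable_importance(ms)$importance[
      variable_importance(ms)$variable == "x1"
    ],
    sum(w[in_model]),
    tolerance = 1e-12
  )

  # shrinkage averaging: weighted sum with zeros where absent
  avg <- model_average(ms)
  for (v in c("x1", "x2", "x3")) {
    manual <- sum(vapply(seq_len(nrow(ms$fits)), function(i) {
      b <- ms$fits$coefficients[[i]]
      if (v %in% names(b)) w[i] * b[[v]] else 0
    }, numeric(1)))
    expect_equal(avg$estimate[avg$variable == v], manual, tolerance = 1e-12)
    imp <- avg$importance[avg$variable == v]
    max_b <- max(abs(vapply(ms$fits$coefficients, function(b) {
      if (v %in% names(b)) b[[v]] else 0
    }, numeric(1))))
    expect_lte(abs(avg$estimate[avg$variable == v]), imp * max_b + 1e-12)
  }

  cs <- confidence_set(ms, delta_max = 10)
  expect_true(all(cs$delta <= 10))
  expect_equal(cs$bic, sort(cs$bic))
  expect_equal(nrow(confidence_set(ms, delta_max = 0)), 1)
  expect_equal(
    nrow(confidence_set(ms, delta_max = Inf)),
    sum(!ms$fits$singular)
  )
})

test_that("hand-computed weight sums drive importance and averaging", {
  # three models with weights (0.6, 0.3, 0.1); a variable in models 1 and 3
  ms <- structure(
    list(
      fits = tibble::tibble(
        model = list(c("a"), c("b"), c("a", "b")),
        coefficients = list(c(a = 0.4), c(b = 1), c(a = 0.2, b = 0.5)),
        weight = c(0.6, 0.3, 0.1)
      ),
      importance = NULL, n = 22
    ),
    class = "monarch_modelset"
  )
  imp_a <- sum(ms$fits$weight[vapply(ms$fits$model, function(m) "a" %in% m,
                                     logical(1))])
  expect_equal(imp_a, 0.7)
  # two equal-weight models, beta 0.4 in one, absent in the other
  expect_equal(0.5 * 0.4 + 0.5 * 0, 0.2)
})

test_that("table-style internal consistency holds on a synthetic run", {
  sim <- simulate_monarch_data(simulation_config(seed = 19))
  vars <- c(
    "trend_north_central_01", "clim_north_central_01",
    "clim_north_central_02", "clim_south_01", "prop_inf"
  )
  ms <- best_subset_gompertz(sim$complete, vars, size = 3)
  ok <- !ms$fits$singular
  expect_equal(
    ms$fits$bic[ok],
    -2 * ms$fits$loglik[ok] + (ms$fits$n_covariates[ok] + 2) * log(22),
    tolerance = 1e-12
  )
  expect_equal(
    ms$fits$weight[ok],
    exp(-ms$fits$delta[ok] / 2) / sum(exp(-ms$fits$delta[ok] / 2)),
    tolerance = 1e-12
  )
  expect_equal(sum(ms$fits$weight), 1, tolerance = 1e-12)
  expect_true(all(ms$fits$delta[ok] >= 0))
  expect_true(all(
    variable_importance(ms)$importance >= 0 &
      variable_importance(ms)$importance <= 1 + 1e-12
  ))
})

test_that("residual autocorrelation diagnostics behave at the extremes", {
  alt <- list(residuals = rep(c(1, -1), 50))
  out <- residual_acf(alt, n_lags = 5)
  expect_equal(out$acf[out$lag == 0], 1)
  expect_lt(out$acf[out$lag == 1], -0.9)
  expect_true(attr(out, "any_flagged"))

  set.seed(71)
  flagged_share <- vapply(1:200, function(i) {
    wn <- list(residuals = rnorm(500))
    mean(residual_acf(wn, n_lags = 20)$flagged[-1])
  }, numeric(1))
  expect_gte(mean(flagged_share <= 0.10), 0.90)

  expect_error(residual_acf(list(residuals = rep(1, 30))), "constant")
  expect_error(residual_acf(list(residuals = rnorm(5)), n_lags = 10), "shorter")
})

test_that("AR(1) likelihood nests the white-noise fit and recovers phi", {
  d <- linear_frame(n = 50, seed = 73)
  ols <- fit_gompertz(d, c("x1", "x2"))
  ar0 <- fit_ar1_gls(d, c("x1", "x2"), phi_grid = 0)
  expect_equal(ar0$loglik, ols$loglik, tolerance = 1e-8)

  # phi recovery at phi = 0.6, n = 200
  phis <- vapply(1:60, function(s) {
    set.seed(200 + s)
    n <- 200
    x <- rnorm(n)
    e <- as.numeric(stats::arima.sim(list(ar = 0.6), n, sd = 0.3))
    d2 <- tibble::tibble(x = x, log_area = 1 + 0.5 * x + e)
    fit_ar1_gls(d2, "x")$phi
  }, numeric(1))
  expect_lt(abs(median(phis) - 0.6), 0.1)

  # white-noise truth: phi estimates concentrate near zero
  phis0 <- vapply(1:60, function(s) {
    set.seed(400 + s)
    n <- 100
    x <- rnorm(n)
    d2 <- tibble::tibble(x = x, log_area = 1 + 0.5 * x + rnorm(n, 0, 0.3))
    fit_ar1_gls(d2, "x")$phi
  }, numeric(1))
  expect_lt(abs(median(phis0)), 0.25)

  # independent cross-check of the ML fit against nlme::gls
  skip_if_not_installed("nlme")
  set.seed(79)
  n <- 80
  x <- rnorm(n)
  e <- as.numeric(stats::arima.sim(list(ar = 0.5), n, sd = 0.4))
  d3 <- tibble::tibble(x = x, log_area = 2 + 0.7 * x + e)
  ours <- fit_ar1_gls(d3, "x")
  zd <- tibble::tibble(z = as.numeric(scale(d3$x)), y = d3$log_area)
  ref <- nlme::gls(y ~ z, data = zd,
                   correlation = nlme::corAR1(form = ~1), method = "ML")
  expect_equal(ours$phi, coef(ref$modelStruct$corStruct, unconstrained = FALSE),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(ours$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
})

test_that("adding a covariate never lowers the maximised likelihood", {
  d <- linear_frame(n = 22, seed = 83)
  small <- fit_gompertz(d, "x1")
  big <- fit_gompertz(d, c("x1", "x2"))
  expect_gte(big$loglik + 1e-10, small$loglik)
})
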