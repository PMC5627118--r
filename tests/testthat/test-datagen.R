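test_that("daily growing degree days follow the capped simple-average rule", {
  # single days: plain mean, cap applied to tmax, negative floored at zero
  expect_equal(compute_gdd(make_daily(25, 15))$gdd, (25 + 15) / 2 - 11.5)
  expect_equal(compute_gdd(make_daily(40, 20))$gdd, (36 + 20) / 2 - 11.5)
  expect_equal(compute_gdd(make_daily(10, 5))$gdd, 0)

  # regional value is the unweighted mean over site sums
  two_sites <- dplyr::bind_rows(
    make_daily(c(25, 26), site = "a"),
    make_daily(c(20, 21), site = "b")
  )
  per_site <- c(
    sum((c(25, 26) + c(15, 16)) / 2 - 11.5),
    sum((c(20, 21) + c(10, 11)) / 2 - 11.5)
  )
  expect_equal(compute_gdd(two_sites)$gdd, mean(per_site))
  expect_equal(compute_gdd(two_sites)$n_sites, 2L)

  expect_error(compute_gdd(make_daily(10, tmin = 12)), "tmin")
  expect_error(
    compute_gdd(make_daily(25), start = "2030-01-01"),
    "no daily records"
  )
})

test_that("degree days are nonnegative, additive over windows and monotone", {
  set.seed(31)
  tmax <- runif(30, 5, 42)
  daily <- make_daily(tmax, tmin = tmax - runif(30, 2, 12))

  whole <- compute_gdd(daily)$gdd
  first <- compute_gdd(daily, end = daily$date[14])$gdd
  second <- compute_gdd(daily, start = daily$date[15])$gdd
  expect_gte(whole, 0)
  expect_equal(first + second, whole)

  warmer <- dplyr::mutate(daily, tmin_c = tmin_c + 1)
  expect_gte(compute_gdd(warmer)$gdd, whole)
  hotter <- dplyr::mutate(daily, tmax_c = tmax_c + 1)
  expect_gte(compute_gdd(hotter)$gdd, whole)

  lwhole <- compute_ldd(daily)$ldd
  lfirst <- compute_ldd(daily, end = daily$date[14])$ldd
  lsecond <- compute_ldd(daily, start = daily$date[15])$ldd
  expect_gte(lwhole, 0)
  expect_equal(lfirst + lsecond, lwhole)
})

test_that("lethal degree days accumulate exceedances above the threshold", {
  expect_equal(compute_ldd(make_daily(39))$ldd, 2)
  expect_equal(compute_ldd(make_daily(37.9))$ldd, 0)
  expect_equal(compute_ldd(make_daily(c(38, 40, 36)))$ldd, 1 + 3 + 0)
})

test_that("period totals are annualized evenly and conserve mass", {
  one <- annualize_periods(
    tibble::tibble(start_year = 2001, end_year = 2003, loss = 300)
  )
  expect_equal(one$annual_loss, rep(100, 3))
  expect_equal(one$cumulative_loss, c(100, 200, 300))

  two <- annualize_periods(tibble::tibble(
    start_year = c(2001, 2003), end_year = c(2002, 2006),
    loss = c(50, 200)
  ))
  expect_equal(two$annual_loss, c(25, 25, 50, 50, 50, 50))

  # years before the first period carry zero loss
  padded <- annualize_periods(
    tibble::tibble(start_year = 2001, end_year = 2003, loss = 300),
    years = 1998:2003
  )
  expect_equal(padded$annual_loss[padded$year < 2001], rep(0, 3))

  empty <- annualize_periods(
    tibble::tibble(start_year = double(), end_year = double(), loss = double()),
    years = 1993:2000
  )
  expect_equal(empty$annual_loss, rep(0, 8))

  set.seed(8)
  starts <- c(1993, 1997, 2004)
  ends <- c(1996, 2003, 2010)
  losses <- runif(3, 10, 500)
  rand <- annualize_periods(
    tibble::tibble(start_year = starts, end_year = ends, loss = losses)
  )
  expect_equal(sum(rand$annual_loss), sum(losses))
  expect_equal(max(rand$cumulative_loss), sum(losses))

  expect_error(
    annualize_periods(tibble::tibble(
      start_year = c(2001, 2002), end_year = c(2003, 2004), loss = c(1, 1)
    )),
    "overlap"
  )
  expect_error(
    annualize_periods(
      tibble::tibble(start_year = 2001, end_year = 2002, loss = -5)
    ),
    "negative"
  )
})

test_that("masking hits the requested cells only, deterministically", {
  cfg <- simulation_config(seed = 2, missing_counts = c(prop_inf = 0))
  sim <- simulate_monarch_data(cfg)
  base <- sim$complete

  masked <- apply_missingness(base, c(prop_inf = 7, clim_south_01 = 1), seed = 9)
  expect_equal(sum(is.na(masked$prop_inf)), 7)
  expect_equal(sum(is.na(masked$clim_south_01)), 1)
  expect_equal(sum(is.na(masked)), 8)
  expect_false(anyNA(masked$log_area))

  again <- apply_missingness(base, c(prop_inf = 7, clim_south_01 = 1), seed = 9)
  expect_identical(masked, again)

  tail_mode <- apply_missingness(base, c(prop_inf = 3), seed = 1, mode = "tail")
  expect_true(all(is.na(tail_mode$prop_inf[20:22])))

  expect_error(apply_missingness(base, c(log_area = 1)), "cannot be masked")
  expect_error(apply_missingness(base, c(prop_inf = 22)), "smaller")
  expect_error(apply_missingness(base, c(nope = 1)), "unknown")
})

test_that("the generator collapses to its deterministic skeleton without noise", {
  flat <- simulate_monarch_data(simulation_config(
    true_coefficients = stats::setNames(numeric(0), character(0)),
    noise_sd = 0, milkweed_sd = 0, density_dependence = 0, seed = 4
  ))
  expect_equal(flat$complete$log_area, rep(1.5, 22))

  one <- simulate_monarch_data(simulation_config(
    true_coefficients = c(clim_south_01 = 1),
    noise_sd = 0, milkweed_sd = 0, density_dependence = 0, seed = 4
  ))
  z <- as.numeric(scale(one$complete$clim_south_01))
  expect_equal(one$complete$log_area - 1.5, z, tolerance = 1e-12)
})

test_that("the generated dataset has the advertised structure", {
  cfg <- simulation_config(seed = 10)
  sim <- simulate_monarch_data(cfg)

  expect_identical(sim$data, simulate_monarch_data(cfg)$data)
  expect_equal(nrow(sim$data), 22)
  expect_equal(sim$data$year, 1993:2014)
  # 40 trend + 34 climate + prop_inf + apva_1yr
  expect_equal(ncol(sim$data) - 2L, 76L)
  expect_false(anyNA(sim$data$log_area))

  trend_cols <- grep("^trend_", names(sim$complete), value = TRUE)
  for (v in trend_cols) expect_true(all(diff(sim$complete[[v]]) > 0))

  # trend covariates are near-collinear across regions, as in the real record
  trend_cor <- cor(as.matrix(sim$complete[trend_cols]))
  expect_gt(min(trend_cor), 0.95)

  # masked-cell counts follow the configured map
  counts <- colSums(is.na(sim$data))
  expect_equal(unname(counts[["prop_inf"]]), 7)
  expect_equal(unname(counts[["apva_1yr"]]), 1)
  expect_true(all(counts[trend_cols] == 2))

  # milkweed sits causally downstream of the herbicide driver
  expect_equal(sim$truth$milkweed_driver, "trend_north_central_01")
  expect_lt(cor(sim$path$log_milkweed, sim$path$log_glyphosate_cum), 0)

  expect_error(
    simulation_config(density_dependence = 1),
    "density_dependence"
  )
  expect_error(simulation_config(within_block_correlation = 1), "block")
  expect_error(
    simulate_monarch_data(simulation_config(
      true_coefficients = c(not_a_var = 1)
    )),
    "unknown covariates"
  )
})

test_that("least squares recovers the generating coefficients at large n", {
  truth <- c(
    trend_north_central_01 = -0.5,
    clim_north_central_01 = -0.13,
    clim_north_central_02 = -0.14
  )
  sim <- simulate_monarch_data(simulation_config(
    n_years = 500, true_coefficients = truth, noise_sd = 0.3, seed = 77
  ))
  fit <- fit_gompertz(sim$complete, names(truth))
  expect_equal(unname(fit$coefficients), unname(truth), tolerance = 0.1)
})
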