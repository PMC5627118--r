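#' Configuration for the synthetic annual monarch dataset
#'
#' Bundles and validates the parameters of the generator in
#' [simulate_monarch_data()]. The defaults emulate the structure of the
#' observational record the analysis pipeline is designed for: 22 annual
#' observations (1993-2014) of log overwintering area, 76 candidate
#' covariates organised in regional blocks, a slowly evolving monotone
#' "trend" block (cumulative herbicide and insecticide application, forest
#' loss, set-aside farmland area), a stochastic climate block correlated
#' within region, an infection-proportion survival covariate, the previous
#' year's abundance as an ordinary candidate covariate, and per-variable
#' missing-year counts concentrated in the historically gappy series.
#'
#' Effect sizes in `true_coefficients` act on the standardized covariate
#' (mean 0, sd 1 over the generated years), matching the standardized
#' coefficient scale on which fitted models report. The default truth makes
#' cumulative herbicide in the north-central block dominant (-0.506) with
#' two weaker climate effects (-0.131, -0.139).
#'
#' @param n_years Number of annual observations (>= 4).
#' @param start_year First calendar year.
#' @param n_trend_covariates,n_climate_covariates Number of covariates in the
#'   monotone trend block and the stochastic climate block; both are split
#'   round-robin across `regions`.
#' @param regions Region labels for the covariate blocks.
#' @param true_coefficients Named numeric vector: standardized effect of the
#'   named covariate on the log response. Names must match generated
#'   covariate names (`trend_<region>_<k>`, `clim_<region>_<k>`, `prop_inf`,
#'   `apva_1yr`).
#' @param intercept Intercept `alpha0` of the log response (log hectares).
#' @param density_dependence Autoregressive coefficient `phi` on the previous
#'   log response, in (-1, 1). Zero by default: in this system the monotone
#'   trend covariates absorb the long-term decline, which in the field data
#'   obviated an explicit autoregressive term.
#' @param noise_sd Standard deviation of the annual white-noise innovation
#'   `epsilon_t` (log-hectare units, >= 0).
#' @param within_block_correlation Correlation between climate covariates of
#'   the same regional block, in `[0, 1)`.
#' @param missing_counts Named integer vector: number of years to mask per
#'   covariate (each < `n_years`). `NULL` builds a default map with 2 missing
#'   years for pesticide-style trend series, 7 for the infection proportion,
#'   1 for the lagged abundance and for a third of the climate series.
#' @param missing_mode `"random"` masks uniformly chosen years; `"tail"`
#'   masks the final years of the series, mimicking records that simply stop
#'   before the end of the study window.
#' @param milkweed_gamma,milkweed_sd Slope of the log milkweed resource on
#'   the standardized cumulative herbicide driver, and the sd of its noise.
#' @param milkweed_driver Covariate the milkweed series is downstream of;
#'   when this covariate carries a true coefficient, its effect on the
#'   response is routed entirely through milkweed, so the path-model stage
#'   sees its null structure (no direct herbicide-to-population link). If
#'   the named column does not exist, the first covariate is used.
#' @param seed Integer seed; the same configuration and seed always produce
#'   the same dataset.
#' @return A list of class `monarch_sim_config`.
#' @export
simulation_config <- function(n_years = 22L,
                              start_year = 1993L,
                              n_trend_covariates = 40L,
                              n_climate_covariates = 34L,
                              regions = c("south", "north_central",
                                          "northeast", "overwinter"),
                              true_coefficients = c(
                                trend_north_central_01 = -0.506,
                                clim_north_central_01 = -0.131,
                                clim_north_central_02 = -0.139
                              ),
                              intercept = 1.5,
                              density_dependence = 0,
                              noise_sd = 0.3,
                              within_block_correlation = 0.45,
                              missing_counts = NULL,
                              missing_mode = c("random", "tail"),
                              milkweed_gamma = -0.6,
                              milkweed_sd = 0.25,
                              milkweed_driver = "trend_north_central_01",
                              seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (milkweed_gamma == 0) abort("`milkweed_gamma` must be nonzero")
  if (n_years < 4) abort("`n_years` must be at least 4")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative")
  if (abs(density_dependence) >= 1) {
    abort("`density_dependence` must lie strictly inside (-1, 1)")
  }
  if (within_block_correlation < 0 || within_block_correlation >= 1) {
    abort("`within_block_correlation` must lie in [0, 1)")
  }
  if (!all(is.finite(true_coefficients))) {
    abort("`true_coefficients` must be finite")
  }
  if (length(true_coefficients) > 0 && is.null(names(true_coefficients))) {
    abort("`true_coefficients` must be named")
  }
  cfg <- list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    n_trend_covariates = as.integer(n_trend_covariates),
    n_climate_covariates = as.integer(n_climate_covariates),
    regions = regions, true_coefficients = true_coefficients,
    intercept = intercept, density_dependence = density_dependence,
    noise_sd = noise_sd,
    within_block_correlation = within_block_correlation,
    missing_counts = missing_counts, missing_mode = missing_mode,
    milkweed_gamma = milkweed_gamma, milkweed_sd = milkweed_sd,
    milkweed_driver = milkweed_driver,
    seed = as.integer(seed)
  )
  structure(cfg, class = "monarch_sim_config")
}

block_names <- function(prefix, n, regions) {
  if (n == 0) return(character(0))
  region <- rep(regions, length.out = n)
  idx <- stats::ave(seq_len(n), region, FUN = seq_along)
  stats::setNames(
    sprintf("%s_%s_%02d", prefix, region, idx),
    rep(NULL, n)
  )
}

default_missing_counts <- function(vars, n_climate_missing_idx) {
  counts <- stats::setNames(rep(0L, length(vars)), vars)
  counts[grepl("^trend_", vars)] <- 2L
  counts[vars == "prop_inf"] <- 7L
  counts[vars == "apva_1yr"] <- 1L
  clim <- vars[grepl("^clim_", vars)]
  counts[clim[n_climate_missing_idx(length(clim))]] <- 1L
  counts
}

#' Simulate an annual monarch threat dataset
#'
#' Generates a year-by-variable table with the statistical structure the
#' downstream pipeline assumes. Trend covariates are logistic adoption
#' curves (region-shared timing, small per-variable jitter) accumulated over
#' time, yielding the near-collinear monotone blocks characteristic of
#' cumulative pesticide and land-use records. Climate covariates are AR(1)
#' series sharing a regional factor at the configured within-block
#' correlation. The log response follows the Gompertz-type model
#' `N_t = alpha0 + phi * N_(t-1) + sum_j beta_j z_jt + epsilon_t` with
#' standardized covariates `z` and Gaussian noise. A log milkweed-resource
#' series causally downstream of the cumulative herbicide trend is generated
#' for the path-model stage, and the log response doubles as the population
#' series there.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `monarch_sim`: a list with elements
#'   \describe{
#'     \item{data}{tibble `year`, `log_area`, covariate columns with `NA`
#'       for masked cells.}
#'     \item{complete}{the same tibble before masking.}
#'     \item{meta}{tibble `variable`, `region`, `category`.}
#'     \item{truth}{list `alpha0`, `phi`, `beta`, `sigma`, `milkweed_gamma`.}
#'     \item{path}{tibble `year`, `log_glyphosate_cum`, `log_milkweed`,
#'       `log_population` for the structural path model.}
#'   }
#' @export
simulate_monarch_data <- function(config = simulation_config()) {
  stopifnot(inherits(config, "monarch_sim_config"))
  seed_rng(config$seed)
  n <- config$n_years
  years <- seq(config$start_year, length.out = n)

  trend_vars <- block_names("trend", config$n_trend_covariates, config$regions)
  clim_regions <- setdiff(config$regions, character(0))
  clim_vars <- block_names("clim", config$n_climate_covariates, clim_regions)

  # monotone trend block: logistic adoption, then cumulated
  t_idx <- seq_len(n)
  trend <- vapply(seq_along(trend_vars), function(j) {
    mid <- n / 2 + rnorm(1, 0, 1)
    rate <- 0.5 * exp(rnorm(1, 0, 0.15))
    level <- exp(rnorm(1, 0, 0.5))
    adoption <- level / (1 + exp(-rate * (t_idx - mid)))
    cumsum(adoption)
  }, numeric(n))
  colnames(trend) <- trend_vars

  # stochastic climate block: shared regional AR(1) factor + idiosyncratic AR(1)
  w <- config$within_block_correlation
  clim_region <- rep(clim_regions, length.out = config$n_climate_covariates)
  factors <- lapply(stats::setNames(nm = clim_regions), function(r) ar1_series(n, 0.3))
  clim <- vapply(seq_along(clim_vars), function(j) {
    f <- factors[[clim_region[j]]]
    sqrt(w) * f + sqrt(1 - w) * ar1_series(n, 0.3)
  }, numeric(n))
  colnames(clim) <- clim_vars

  # infection proportion: bounded survival covariate on the logit scale
  prop_inf <- stats::plogis(-2 + ar1_series(n, 0.5))

  covars <- cbind(trend, clim, prop_inf = prop_inf)

  beta <- config$true_coefficients
  lagged_beta <- beta[names(beta) == "apva_1yr"]
  static_beta <- beta[names(beta) != "apva_1yr"]
  unknown <- setdiff(names(static_beta), colnames(covars))
  if (length(unknown) > 0) {
    abort(paste0(
      "true_coefficients name unknown covariates: ",
      paste(unknown, collapse = ", ")
    ))
  }

  z <- scale_columns(covars)
  phi <- config$density_dependence

  # Milkweed resource is causally downstream of the cumulative herbicide
  # driver. When that driver carries a true effect on the response, the
  # effect is routed through milkweed (x -> m -> y with no direct x -> y
  # link), the recursive chain the path-model stage estimates; the total
  # effect of the driver on the response is still its stated coefficient.
  driver <- config$milkweed_driver
  if (!driver %in% colnames(covars)) driver <- colnames(covars)[1]
  gly <- z[, driver]
  log_milkweed <- 5 + config$milkweed_gamma * gly +
    rnorm(n, 0, config$milkweed_sd)
  direct_beta <- static_beta[setdiff(names(static_beta), driver)]
  eta <- as.numeric(z[, names(direct_beta), drop = FALSE] %*% direct_beta)
  if (driver %in% names(static_beta)) {
    eta <- eta +
      (static_beta[[driver]] / config$milkweed_gamma) * (log_milkweed - 5)
  }
  eps <- rnorm(n, 0, config$noise_sd)
  response <- numeric(n)
  prev <- config$intercept / (1 - phi) # stationary mean as pre-sample value
  for (t in t_idx) {
    response[t] <- config$intercept + phi * prev + eta[t] + eps[t] +
      if (length(lagged_beta) == 1) lagged_beta * prev else 0
    prev <- response[t]
  }

  apva_1yr <- c(config$intercept / (1 - phi), response[-n])
  covars <- cbind(covars, apva_1yr = apva_1yr)

  meta <- tibble::tibble(
    variable = colnames(covars),
    region = dplyr::case_when(
      grepl("^trend_", .data$variable) ~
        sub("^trend_(.*)_\\d+$", "\\1", .data$variable),
      grepl("^clim_", .data$variable) ~
        sub("^clim_(.*)_\\d+$", "\\1", .data$variable),
      TRUE ~ "overwinter"
    ),
    category = dplyr::case_when(
      .data$variable == "apva_1yr" ~ "density_dependence",
      .data$variable == "prop_inf" ~ "survival",
      grepl("^trend_.*[048]$", .data$variable) ~ "survival",
      grepl("^trend_", .data$variable) ~ "habitat_availability",
      TRUE ~ "reproduction"
    )
  )

  complete <- tibble::as_tibble(as.data.frame(covars)) |>
    dplyr::mutate(year = as.integer(years), log_area = response, .before = 1)

  counts <- config$missing_counts
  if (is.null(counts)) {
    counts <- default_missing_counts(
      colnames(covars),
      function(k) seq_len(max(0L, k %/% 3L))
    )
  }
  masked <- apply_missingness(
    complete, counts,
    seed = stage_seed(config$seed, "simulate"),
    mode = config$missing_mode
  )

  path <- tibble::tibble(
    year = as.integer(years),
    log_glyphosate_cum = log(covars[, driver]),
    log_milkweed = log_milkweed,
    log_population = response
  )

  structure(
    list(
      data = masked, complete = complete, meta = meta,
      truth = list(
        alpha0 = config$intercept, phi = phi, beta = beta,
        sigma = config$noise_sd, milkweed_gamma = config$milkweed_gamma,
        milkweed_sd = config$milkweed_sd, milkweed_driver = driver
      ),
      path = path, config = config
    ),
    class = "monarch_sim"
  )
}

#' @export
print.monarch_sim <- function(x, ...) {
  nv <- ncol(x$data) - 2L
  cat(
    "<monarch_sim> ", nrow(x$data), " years x ", nv, " covariates; ",
    sum(is.na(x$data)), " masked cells\n",
    sep = ""
  )
  invisible(x)
}

#' Mask covariate cells to emulate historically incomplete records
#'
#' Sets the requested number of cells per covariate column to `NA`. In
#' `"random"` mode the masked years are drawn without replacement within the
#' column; `"tail"` mode masks the final years, mimicking series whose
#' collection stopped before the end of the study window. The response
#' column (`log_area`, when present) and `year` are never masked.
#'
#' @param data A data frame with a `year` column and covariate columns.
#' @param missing_counts Named integer vector, count of years to mask per
#'   column; each count must be smaller than the number of rows. Columns not
#'   named are left untouched.
#' @param seed Integer seed (random mode).
#' @param mode `"random"` or `"tail"`.
#' @return The data frame with `NA` in the masked cells.
#' @export
apply_missingness <- function(data, missing_counts, seed = 1L,
                              mode = c("random", "tail")) {
  mode <- match.arg(mode)
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  protected <- intersect(c("year", "log_area"), names(data))
  bad <- intersect(names(missing_counts), protected)
  if (length(bad) > 0) abort("the year and response columns cannot be masked")
  unknown <- setdiff(names(missing_counts), names(data))
  if (length(unknown) > 0) {
    abort(paste0("unknown columns in missing_counts: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(missing_counts >= n)) {
    abort("missing counts must be smaller than the number of years")
  }
  seed_rng(seed)
  for (v in names(missing_counts)) {
    k <- missing_counts[[v]]
    if (k <= 0) next
    rows <- if (mode == "tail") seq(n - k + 1L, n) else sample.int(n, k)
    data[rows, v] <- NA_real_
  }
  data
}

# AR(1) series with unit marginal variance
ar1_series <- function(n, rho) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (t in seq_len(n)[-1]) x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * rnorm(1)
  x
}

scale_columns <- function(m) {
  ctr <- colMeans(m)
  sds <- apply(m, 2, sd)
  sds[sds == 0] <- 1
  sweep(sweep(m, 2, ctr), 2, sds, "/")
}

# set.seed() scoped to the caller without disturbing the global stream state
# beyond what the draw itself consumes (plain set.seed is fine for a package
# whose entry points all take an explicit seed)
seed_rng <- function(seed) set.seed(as.integer(seed))

#' Simulate series for the three-variable structural path model
#'
#' Draws `x` (log cumulative herbicide, standard normal), a log milkweed
#' resource `m = gamma * x + noise`, and a log population
#' `y = delta * m + noise`: the recursive causal chain the path model
#' estimates, with no direct `x -> y` link (the null structure of the
#' model's single overidentifying restriction). Slopes are raw regression
#' slopes on the log scale; the fitted model reports standardized
#' coefficients, which coincide with these only when the implied marginal
#' variances are 1.
#'
#' @param n Number of years.
#' @param gamma Slope of log milkweed on log cumulative herbicide.
#' @param delta Slope of log population on log milkweed.
#' @param sigma_m,sigma_y Noise standard deviations of the two equations.
#' @param seed Integer seed.
#' @return A tibble with columns `year`, `log_glyphosate_cum`,
#'   `log_milkweed`, `log_population`.
#' @export
simulate_path_data <- function(n = 22L, gamma = -0.178, delta = 1.784,
                               sigma_m = 0.3, sigma_y = 0.3, seed = 1L) {
  if (n < 5) abort("`n` must be at least 5")
  seed_rng(seed)
  x <- rnorm(n)
  m <- gamma * x + rnorm(n, 0, sigma_m)
  y <- delta * m + rnorm(n, 0, sigma_y)
  tibble::tibble(
    year = seq_len(n),
    log_glyphosate_cum = x, log_milkweed = m, log_population = y
  )
}
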