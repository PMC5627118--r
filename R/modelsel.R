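#' Enumerate candidate covariate subsets
#'
#' Builds the model space for the best-subset search: all combinations of
#' the candidate variables of the requested sizes, in deterministic
#' order (combinations are generated in the order the variables are given,
#' sizes ascending). With 11 candidates taken exactly 4 at a time this is
#' choose(11, 4) = 330 models.
#'
#' @param variables Character vector of candidate covariate names.
#' @param size Subset size (the maximum size when `exact = FALSE`).
#' @param exact If `TRUE`, only subsets of exactly `size`; otherwise all
#'   sizes from `min_size` to `size`.
#' @param min_size Smallest subset size when `exact = FALSE`.
#' @return A list of character vectors, one per candidate model.
#' @examples
#' length(enumerate_models(letters[1:11], size = 4)) # 330
#' @export
enumerate_models <- function(variables, size = 4L, exact = TRUE,
                             min_size = 1L) {
  if (length(variables) == 0) abort("`variables` is empty")
  if (size > length(variables)) {
    abort("`size` exceeds the number of candidate variables")
  }
  sizes <- if (exact) size else seq(min_size, size)
  unlist(
    lapply(sizes, function(k) combn(variables, k, simplify = FALSE)),
    recursive = FALSE
  )
}

#' Fit one Gompertz time-series regression
#'
#' Least-squares fit of the log population index on a subset of
#' standardized covariates: `N_t = alpha0 + beta' z_t + epsilon_t`, with
#' `N_t` the natural log of population size and `epsilon_t` Gaussian white
#' noise. When the previous year's log abundance is included among the
#' covariates the model is the classical Gompertz density-dependent form.
#' The Gaussian maximum-likelihood residual variance `RSS/n` gives
#' `logLik = -(n/2) (log(2 pi sigma2) + 1)`.
#'
#' @param data Data frame holding the response and covariate columns (no
#'   missing values; impute first).
#' @param subset Character vector of covariate names.
#' @param response Name of the response column.
#' @return A list of class `monarch_candidate`: `subset`, `coefficients`
#'   (standardized scale), `intercept`, `sigma2_hat`, `loglik`, `r2`,
#'   `n`, `fitted`, `residuals`, `singular` (TRUE when the design was
#'   rank-deficient; such fits carry `NA` likelihoods and are excluded from
#'   ranking).
#' @export
fit_gompertz <- function(data, subset, response = "log_area") {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(response, subset), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  y <- data[[response]]
  n <- length(y)
  if (anyNA(y)) abort("the response contains missing values")
  x <- as.matrix(data[subset])
  if (anyNA(x)) abort("covariates contain missing values; impute first")
  if (n <= length(subset) + 2) abort("too few years for this subset size")
  z <- scale_columns(x)
  design <- cbind(`(Intercept)` = 1, z)
  fit <- lm.fit(design, y)
  singular <- fit$rank < ncol(design)
  if (singular) {
    return(structure(
      list(
        subset = subset, coefficients = stats::setNames(
          rep(NA_real_, length(subset)), subset
        ),
        intercept = NA_real_, sigma2_hat = NA_real_, loglik = NA_real_,
        r2 = NA_real_, n = n, fitted = rep(NA_real_, n),
        residuals = rep(NA_real_, n), singular = TRUE, response = response
      ),
      class = "monarch_candidate"
    ))
  }
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / n
  loglik <- -(n / 2) * (log(2 * pi * sigma2) + 1)
  structure(
    list(
      subset = subset,
      coefficients = fit$coefficients[subset],
      intercept = fit$coefficients[["(Intercept)"]],
      sigma2_hat = sigma2, loglik = loglik, r2 = 1 - rss / tss,
      n = n, fitted = fit$fitted.values, residuals = res,
      singular = FALSE, response = response
    ),
    class = "monarch_candidate"
  )
}

#' Bayesian information criterion for a Gaussian time-series fit
#'
#' `BIC = -2 logLik + k log(n)` with `k = n_covariates + 2`: slopes plus
#' the intercept and the residual variance both count as estimated
#' parameters. This is the parameter-count convention under which published
#' tables of this analysis family are internally consistent at n = 22.
#'
#' @param loglik Gaussian maximum log-likelihood.
#' @param n_covariates Number of slope parameters.
#' @param n_years Number of observations.
#' @param extra_params Parameters beyond the slopes (intercept + residual
#'   variance = 2 by default; AR(1) fits add one more).
#' @return The BIC value.
#' @examples
#' bic_gaussian(10.86, 3, 22) # -6.26 to 2 dp
#' @export
bic_gaussian <- function(loglik, n_covariates, n_years, extra_params = 2L) {
  if (n_years <= 0) abort("`n_years` must be positive")
  if (!is.finite(loglik)) abort("`loglik` must be finite")
  -2 * loglik + (n_covariates + extra_params) * log(n_years)
}

#' BIC differences and model weights
#'
#' `Delta_i = BIC_i - min(BIC)`; the weight of model `i` is
#' `exp(-Delta_i / 2)` normalised over the model set, so the weights sum to
#' one and ratios between any two models depend only on their BIC
#' difference. Non-finite BICs (e.g. singular fits) receive weight 0 and
#' `NA` delta.
#'
#' @param bics Numeric vector of BIC values.
#' @return A tibble with columns `bic`, `delta`, `weight`, aligned with the
#'   input.
#' @export
model_weights <- function(bics) {
  ok <- is.finite(bics)
  if (!any(ok)) abort("no finite BIC values")
  delta <- bics - min(bics[ok])
  raw <- ifelse(ok, exp(-delta / 2), 0)
  tibble::tibble(
    bic = bics,
    delta = ifelse(ok, delta, NA_real_),
    weight = raw / sum(raw)
  )
}

#' Exhaustive best-subset Gompertz regression
#'
#' Fits every enumerated covariate subset, ranks the fits by BIC, and
#' attaches the standard multimodel-inference quantities: BIC differences
#' and weights, the confidence set (models within `delta_max` BIC units of
#' the best), per-variable importance (sum of the weights of the models
#' containing the variable) and shrinkage model-averaged coefficients
#' (weighted average over the full enumerated set with zeros where a
#' variable is absent, which pulls weakly supported effects toward zero).
#' Rank-deficient subsets are excluded from ranking.
#'
#' @inheritParams fit_gompertz
#' @param variables Candidate covariate names.
#' @inheritParams enumerate_models
#' @param delta_max BIC-difference bound of the confidence set.
#' @param average `"all"` averages over the full enumerated set (shrinkage
#'   averaging, the default); `"confidence"` renormalises the weights over
#'   the confidence set only.
#' @return An object of class `monarch_modelset`: `fits` (one row per
#'   model: `model`, `label`, `n_covariates`, `coefficients` list-column,
#'   `r2`, `loglik`, `bic`, `delta`, `weight`, `singular`), `importance`,
#'   `averaged`, `confidence`, plus `n`, `response`, `variables`.
#' @export
best_subset_gompertz <- function(data, variables, response = "log_area",
                                 size = 4L, exact = TRUE, min_size = 1L,
                                 delta_max = 10,
                                 average = c("all", "confidence")) {
  average <- match.arg(average)
  subsets <- enumerate_models(variables, size, exact, min_size)
  fits <- lapply(subsets, fit_gompertz, data = data, response = response)
  n <- fits[[1]]$n
  loglik <- vapply(fits, `[[`, numeric(1), "loglik")
  k_cov <- lengths(subsets)
  bic <- ifelse(
    is.finite(loglik),
    -2 * loglik + (k_cov + 2) * log(n),
    NA_real_
  )
  w <- model_weights(bic)
  tbl <- tibble::tibble(
    model = subsets,
    label = vapply(subsets, paste, character(1), collapse = "+"),
    n_covariates = k_cov,
    coefficients = lapply(fits, `[[`, "coefficients"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    loglik = loglik, bic = bic, delta = w$delta, weight = w$weight,
    singular = vapply(fits, `[[`, logical(1), "singular")
  )

  importance <- vapply(variables, function(v) {
    sum(tbl$weight[vapply(tbl$model, function(m) v %in% m, logical(1))])
  }, numeric(1))

  avg_weights <- tbl$weight
  if (average == "confidence") {
    in_cs <- !is.na(tbl$delta) & tbl$delta <= delta_max
    avg_weights <- ifelse(in_cs, tbl$weight, 0)
    avg_weights <- avg_weights / sum(avg_weights)
  }
  averaged <- vapply(variables, function(v) {
    contrib <- vapply(seq_len(nrow(tbl)), function(i) {
      b <- tbl$coefficients[[i]]
      if (v %in% names(b) && is.finite(b[[v]])) avg_weights[i] * b[[v]] else 0
    }, numeric(1))
    sum(contrib)
  }, numeric(1))

  out <- structure(
    list(
      fits = tbl,
      importance = tibble::tibble(
        variable = variables, importance = unname(importance)
      ) |> dplyr::arrange(dplyr::desc(.data$importance)),
      averaged = tibble::tibble(
        variable = variables, estimate = unname(averaged),
        importance = unname(importance)
      ),
      n = n, response = response, variables = variables,
      delta_max = delta_max, fit_objects = fits
    ),
    class = "monarch_modelset"
  )
  out$confidence <- confidence_set(out, delta_max)
  out
}

#' Confidence set of best-supported models
#'
#' Models within `delta_max` BIC units of the best model, sorted by BIC;
#' ties are broken by fewer covariates, then by the lexicographic subset
#' label, so the ordering is deterministic.
#'
#' @param model_set A [best_subset_gompertz()] result.
#' @param delta_max BIC-difference bound.
#' @return The subset of `model_set$fits` rows in confidence-set order.
#' @export
confidence_set <- function(model_set, delta_max = 10) {
  stopifnot(inherits(model_set, "monarch_modelset"))
  model_set$fits |>
    dplyr::filter(!is.na(.data$delta), .data$delta <= delta_max) |>
    dplyr::arrange(.data$bic, .data$n_covariates, .data$label)
}

#' Per-variable importance as summed model weights
#'
#' @param model_set A [best_subset_gompertz()] result.
#' @return A tibble `variable`, `importance`, sorted decreasing.
#' @export
variable_importance <- function(model_set) {
  stopifnot(inherits(model_set, "monarch_modelset"))
  model_set$importance
}

#' Shrinkage model-averaged coefficients
#'
#' @param model_set A [best_subset_gompertz()] result.
#' @return A tibble `variable`, `estimate`, `importance`.
#' @export
model_average <- function(model_set) {
  stopifnot(inherits(model_set, "monarch_modelset"))
  model_set$averaged
}

#' Residual autocorrelation check
#'
#' Sample autocorrelation function of a fitted model's residuals with the
#' usual large-sample 95% bounds `+/- 1.96 / sqrt(n)`; any lag >= 1 outside
#' the bounds flags residual temporal structure worth an AR(1)-error refit.
#'
#' @param fit A [fit_gompertz()] result (or any object with a `residuals`
#'   element).
#' @param n_lags Number of lags beyond zero.
#' @return A tibble `lag`, `acf`, `lower`, `upper`, `flagged`; the
#'   attribute `"any_flagged"` summarises lags >= 1.
#' @export
residual_acf <- function(fit, n_lags = 10L) {
  res <- fit$residuals
  if (anyNA(res)) abort("fit has no usable residuals")
  if (length(res) <= n_lags) abort("residual series shorter than `n_lags`")
  if (sd(res) == 0) abort("constant residuals have no autocorrelation")
  a <- drop(acf(res, lag.max = n_lags, plot = FALSE, demean = TRUE)$acf)
  bound <- 1.96 / sqrt(length(res))
  out <- tibble::tibble(
    lag = 0:n_lags,
    acf = a,
    lower = -bound, upper = bound,
    flagged = .data$lag >= 1 & abs(.data$acf) > bound
  )
  attr(out, "any_flagged") <- any(out$flagged)
  out
}

#' Gompertz regression with AR(1) errors by exact Gaussian ML
#'
#' Refits a covariate subset allowing the errors to follow
#' `e_t = phi e_(t-1) + u_t`. For fixed `phi` the model is whitened by the
#' stationary AR(1) transform (first row scaled by `sqrt(1 - phi^2)`,
#' subsequent rows quasi-differenced), the regression is solved by least
#' squares, and the exact stationary log-likelihood
#' `-(n/2)(log(2 pi sigma2_u) + 1) + log(1 - phi^2) / 2` is profiled over
#' `phi` by a grid search refined with local optimisation. At `phi = 0` the
#' likelihood equals the white-noise fit's. BIC uses one extra parameter
#' (`k = n_covariates + 3`).
#'
#' @inheritParams fit_gompertz
#' @param phi_grid Grid of AR coefficients searched before refinement.
#' @return A list of class `monarch_ar1_fit`: `phi`, `coefficients`,
#'   `intercept`, `sigma2_u`, `loglik`, `bic`, `ols_loglik`, `ols_bic`,
#'   `delta_bic_vs_ols` (AR(1) BIC minus white-noise BIC; negative favours
#'   the AR(1) errors), `n`.
#' @export
fit_ar1_gls <- function(data, subset, response = "log_area",
                        phi_grid = seq(-0.95, 0.95, by = 0.05)) {
  data <- tibble::as_tibble(data)
  y <- data[[response]]
  n <- length(y)
  x <- as.matrix(data[subset])
  if (anyNA(x) || anyNA(y)) abort("missing values present; impute first")
  z <- scale_columns(x)
  design <- cbind(`(Intercept)` = 1, z)

  profile_ll <- function(phi) {
    r <- sqrt(1 - phi^2)
    yt <- c(r * y[1], y[-1] - phi * y[-n])
    xt <- rbind(r * design[1, ], design[-1, ] - phi * design[-n, ])
    fit <- lm.fit(xt, yt)
    if (fit$rank < ncol(xt)) return(list(ll = -Inf))
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    ll <- -(n / 2) * (log(2 * pi * sigma2) + 1) + 0.5 * log(1 - phi^2)
    list(ll = ll, coef = fit$coefficients, sigma2 = sigma2)
  }

  ll_grid <- vapply(phi_grid, function(p) profile_ll(p)$ll, numeric(1))
  if (!any(is.finite(ll_grid))) {
    warn("AR(1) profile likelihood degenerate; returning white-noise fit")
    ols <- fit_gompertz(data, subset, response)
    return(structure(
      list(
        phi = 0, coefficients = ols$coefficients, intercept = ols$intercept,
        sigma2_u = ols$sigma2_hat, loglik = ols$loglik,
        bic = bic_gaussian(ols$loglik, length(subset), n, 3L),
        ols_loglik = ols$loglik,
        ols_bic = bic_gaussian(ols$loglik, length(subset), n),
        delta_bic_vs_ols = NA_real_, n = n, converged = FALSE
      ),
      class = "monarch_ar1_fit"
    ))
  }
  i_best <- which.max(ll_grid)
  lo <- phi_grid[max(1L, i_best - 1L)]
  hi <- phi_grid[min(length(phi_grid), i_best + 1L)]
  phi_hat <- if (hi - lo > 1e-12) {
    optimise(function(p) profile_ll(p)$ll, c(lo, hi), maximum = TRUE,
             tol = 1e-8)$maximum
  } else {
    phi_grid[i_best]
  }
  best <- profile_ll(phi_hat)

  ols <- fit_gompertz(data, subset, response)
  bic_ar1 <- bic_gaussian(best$ll, length(subset), n, 3L)
  bic_ols <- bic_gaussian(ols$loglik, length(subset), n)
  structure(
    list(
      phi = phi_hat,
      coefficients = best$coef[subset],
      intercept = best$coef[["(Intercept)"]],
      sigma2_u = best$sigma2, loglik = best$ll, bic = bic_ar1,
      ols_loglik = ols$loglik, ols_bic = bic_ols,
      delta_bic_vs_ols = bic_ar1 - bic_ols, n = n, converged = TRUE
    ),
    class = "monarch_ar1_fit"
  )
}

#' @export
print.monarch_modelset <- function(x, ...) {
  ok <- !x$fits$singular
  cat(
    "<monarch_modelset> ", nrow(x$fits), " candidate models (",
    sum(!ok), " singular) over ", length(x$variables),
    " variables, n = ", x$n, "\n",
    sep = ""
  )
  top <- x$confidence[1, ]
  cat(
    "top model: ", top$label, " (R2 ", format(top$r2, digits = 3),
    ", BIC ", format(top$bic, digits = 4),
    ", weight ", format(top$weight, digits = 3), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn best_subset_gompertz Model table in ranked order: one row
#'   per model with one coefficient column per candidate variable (`NA`
#'   where absent), mirroring the standard best-subset report layout.
#' @param x,object A `monarch_modelset` object.
#' @param ... Unused.
#' @export
tidy.monarch_modelset <- function(x, ...) {
  coef_wide <- purrr::map_dfr(x$fits$coefficients, function(b) {
    full <- stats::setNames(rep(NA_real_, length(x$variables)), x$variables)
    full[names(b)] <- b
    tibble::as_tibble(as.list(full))
  })
  dplyr::bind_cols(
    dplyr::select(x$fits, "label", "n_covariates"),
    coef_wide,
    dplyr::select(x$fits, "r2", "loglik", "bic", "delta", "weight")
  ) |>
    dplyr::arrange(.data$bic)
}

#' @describeIn best_subset_gompertz One-row summary: model count, top-model
#'   statistics, confidence-set size and cumulative weight.
#' @export
glance.monarch_modelset <- function(x, ...) {
  top <- x$confidence[1, ]
  tibble::tibble(
    n_models = nrow(x$fits),
    n_singular = sum(x$fits$singular),
    top_label = top$label,
    top_r2 = top$r2, top_loglik = top$loglik, top_bic = top$bic,
    top_weight = top$weight,
    confidence_set_size = nrow(x$confidence),
    confidence_set_weight = sum(x$confidence$weight)
  )
}

#' @describeIn best_subset_gompertz Variable-importance bar chart (summed
#'   model weights per candidate variable).
#' @export
autoplot.monarch_modelset <- function(object, ...) {
  ggplot2::ggplot(
    object$importance,
    ggplot2::aes(
      x = stats::reorder(.data$variable, .data$importance),
      y = .data$importance
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "variable importance (summed model weights)",
      title = "Best-subset variable importance"
    )
}
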