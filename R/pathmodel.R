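#' Fit the recursive three-variable structural path model
#'
#' Estimates the causal chain log(cumulative herbicide) -> log(milkweed
#' resource) -> log(overwinter population): two linear equations,
#' `m = gamma x` and `y = delta m`, with no direct `x -> y` path. For a
#' recursive system with uncorrelated Gaussian errors the maximum-likelihood
#' estimates are the per-equation least-squares slopes, so the standardized
#' `gamma` and `delta` are the simple correlations cor(x, m) and cor(m, y).
#' The single omitted path is the model's one testable restriction: the
#' model-implied covariance matrix equals the sample matrix except in the
#' (x, y) cell, and the likelihood-ratio discrepancy
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - 3` scaled by `n - 1`
#' (Wishart convention; `n` available via `chi2_scale`) gives a chi-square
#' statistic on 1 degree of freedom.
#'
#' Fit indices follow the covariance-structure conventions: RMSEA from the
#' per-df excess of the chi-square over its expectation, CFI against the
#' independence baseline (all covariances zero, variances free, 3 df). Both
#' are computed by [fit_indices()].
#'
#' @param data Data frame holding the three series.
#' @param x,m,y Column names of the upstream driver (log cumulative
#'   herbicide), mediator (log milkweed resource) and response (log
#'   population size).
#' @param chi2_scale Multiplier of the discrepancy: `"nminus1"` (default)
#'   or `"n"`. At the effect sizes this model is used for, the choice does
#'   not move any index at two decimals.
#' @param direct_path If `TRUE`, also frees the direct `x -> y` path: the
#'   model becomes saturated (df = 0, chi-square 0); useful as a
#'   degenerate-case check.
#' @return An object of class `monarch_pathfit` with `gamma`, `delta`
#'   (standardized), `gamma_raw`, `delta_raw` (original-scale slopes),
#'   `gamma_se`, `delta_se` (standardized-scale standard errors),
#'   `r2_milkweed`, `r2_population`, `chi2`, `df`, `p_value`, `rmsea`,
#'   `cfi`, `chi2_baseline`, `df_baseline`, `n`.
#' @export
fit_path_model <- function(data, x = "log_glyphosate_cum",
                           m = "log_milkweed", y = "log_population",
                           chi2_scale = c("nminus1", "n"),
                           direct_path = FALSE) {
  chi2_scale <- match.arg(chi2_scale)
  data <- tibble::as_tibble(data)
  cols <- c(x, m, y)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  mat <- as.matrix(data[cols])
  n <- nrow(mat)
  if (n < 5) abort("at least 5 observations are required")
  if (!all(is.finite(mat))) abort("all series must be finite")
  if (any(apply(mat, 2, sd) == 0)) abort("zero-variance input series")

  s <- stats::cov(mat)
  r <- stats::cov2cor(s)

  gamma <- r[1, 2]
  delta <- r[2, 3]
  gamma_raw <- s[1, 2] / s[1, 1]
  delta_raw <- s[2, 3] / s[2, 2]

  mult <- if (chi2_scale == "nminus1") n - 1 else n
  df <- if (direct_path) 0L else 1L
  singular_s <- det(r) < 1e-12
  if (df == 0L) {
    chi2 <- 0 # saturated: implied covariance reproduces S exactly
  } else if (!singular_s) {
    sigma <- s
    sigma[1, 3] <- sigma[3, 1] <- delta_raw * s[1, 2]
    f_ml <- log(det(sigma)) + sum(diag(s %*% solve(sigma))) - log(det(s)) - 3
    chi2 <- mult * max(f_ml, 0)
  } else {
    # degenerate (collinear) sample moments: the ML discrepancy reduces to
    # -log(1 - partial-cor(x, y | m)^2); with a zero residual variance the
    # omitted path has no evidence against it
    e_x <- stats::residuals(stats::lm(mat[, 1] ~ mat[, 2]))
    e_y <- stats::residuals(stats::lm(mat[, 3] ~ mat[, 2]))
    r_p <- if (sd(e_x) < 1e-10 || sd(e_y) < 1e-10) 0 else cor(e_x, e_y)
    chi2 <- mult * -log(max(1 - r_p^2, .Machine$double.eps))
  }

  det_r <- det(r)
  chi2_baseline <- if (det_r <= 0) Inf else mult * (-log(det_r))
  df_baseline <- 3L

  idx <- if (df > 0) {
    fit_indices(chi2, df, n, chi2_baseline, df_baseline)
  } else {
    tibble::tibble(rmsea = 0, cfi = 1, p_value = NA_real_)
  }

  se_std <- function(rho) sqrt((1 - rho^2) / (n - 2))

  structure(
    list(
      variables = stats::setNames(cols, c("x", "m", "y")),
      gamma = gamma, delta = delta,
      gamma_raw = gamma_raw, delta_raw = delta_raw,
      gamma_se = se_std(gamma), delta_se = se_std(delta),
      r2_milkweed = gamma^2, r2_population = delta^2,
      chi2 = chi2, df = df, p_value = idx$p_value,
      rmsea = idx$rmsea, cfi = idx$cfi,
      chi2_baseline = chi2_baseline, df_baseline = df_baseline,
      n = n, chi2_scale = chi2_scale, sample_cov = s,
      data = tibble::as_tibble(data[cols])
    ),
    class = "monarch_pathfit"
  )
}

#' Covariance-structure fit indices
#'
#' RMSEA is `sqrt(max(chi2 - df, 0) / (df (n - 1)))`: zero whenever the
#' chi-square does not exceed its degrees of freedom. CFI is
#' `1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)` against an
#' independence baseline (all covariances zero; `df_b = 3` for three
#' observed variables): one whenever the model chi-square is within its
#' degrees of freedom. The p-value is the upper tail of the chi-square
#' distribution on `df`.
#'
#' @param chi2 Model chi-square.
#' @param df Model degrees of freedom (> 0).
#' @param n Sample size.
#' @param chi2_baseline,df_baseline Independence-baseline chi-square and
#'   degrees of freedom.
#' @return A one-row tibble `rmsea`, `cfi`, `p_value`.
#' @examples
#' fit_indices(0.019, 1, 22, chi2_baseline = 40, df_baseline = 3)
#' @export
fit_indices <- function(chi2, df, n, chi2_baseline, df_baseline = 3L) {
  if (df <= 0) abort("`df` must be positive")
  if (chi2 < 0) abort("`chi2` must be nonnegative")
  excess <- max(chi2 - df, 0)
  rmsea <- sqrt(excess / (df * (n - 1)))
  denom <- max(chi2_baseline - df_baseline, excess, 0)
  cfi <- if (denom == 0) 1 else 1 - excess / denom
  tibble::tibble(
    rmsea = rmsea,
    cfi = cfi,
    p_value = pchisq(chi2, df, lower.tail = FALSE)
  )
}

#' @export
print.monarch_pathfit <- function(x, ...) {
  cat(
    "<monarch_pathfit> n = ", x$n,
    "; gamma = ", format(x$gamma, digits = 3),
    ", delta = ", format(x$delta, digits = 3), "\n",
    "chi2(", x$df, ") = ", format(x$chi2, digits = 3),
    ", p = ", format(x$p_value, digits = 3),
    "; RMSEA = ", format(x$rmsea, digits = 3),
    ", CFI = ", format(x$cfi, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn fit_path_model One row per path with standardized estimate,
#'   standard error and equation R-squared.
#' @param x,object A `monarch_pathfit` object.
#' @param ... Unused.
#' @export
tidy.monarch_pathfit <- function(x, ...) {
  tibble::tibble(
    path = c(
      paste(x$variables[["x"]], "->", x$variables[["m"]]),
      paste(x$variables[["m"]], "->", x$variables[["y"]])
    ),
    term = c("gamma", "delta"),
    estimate = c(x$gamma, x$delta),
    std.error = c(x$gamma_se, x$delta_se),
    estimate_raw = c(x$gamma_raw, x$delta_raw),
    r.squared = c(x$r2_milkweed, x$r2_population)
  )
}

#' @describeIn fit_path_model One-row fit summary (chi-square, df, p,
#'   RMSEA, CFI, n).
#' @export
glance.monarch_pathfit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2, df = x$df, p_value = x$p_value,
    rmsea = x$rmsea, cfi = x$cfi,
    chi2_baseline = x$chi2_baseline, df_baseline = x$df_baseline,
    n = x$n
  )
}

#' @describeIn fit_path_model Scatter plots of the two fitted equations
#'   with least-squares lines.
#' @export
autoplot.monarch_pathfit <- function(object, ...) {
  v <- object$variables
  d <- object$data
  df <- dplyr::bind_rows(
    tibble::tibble(
      equation = paste(v[["m"]], "~", v[["x"]]),
      predictor = d[[v[["x"]]]], outcome = d[[v[["m"]]]]
    ),
    tibble::tibble(
      equation = paste(v[["y"]], "~", v[["m"]]),
      predictor = d[[v[["m"]]]], outcome = d[[v[["y"]]]]
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predictor, y = .data$outcome)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~equation, scales = "free") +
    ggplot2::labs(title = "Path-model equations")
}
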