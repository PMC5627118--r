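#' Univariate partial least-squares regression (NIPALS PLS1)
#'
#' Extracts latent components from a wide, collinear predictor block that
#' maximise covariance with a single response — the "y-aware" dimension
#' reduction used to screen several dozen candidate threat covariates
#' against a short annual population series. Components are computed by the
#' NIPALS recursion: weight `w` proportional to `X'y` (unit norm), score
#' `t = Xw`, x-loading `p = X't / t't`, y-loading `q = y't / t't`, then
#' deflation `X <- X - t p'` and `y <- y - t q`. Correlation loadings — the
#' correlation of each original (undeflated) predictor, and of the response,
#' with each score vector — are the quantities used for variable selection.
#'
#' Predictors and (by default) the response are standardized to mean 0,
#' sd 1 (n-1 denominator) before fitting; coefficients are reported both on
#' the standardized and the original scale.
#'
#' @param data A data frame containing the response and predictor columns.
#'   Non-numeric columns and a `year` column are ignored as predictors.
#' @param response Name of the response column (character).
#' @param n_components Number of latent components to extract (default 2,
#'   the number used for this analysis family's screening step).
#' @param scale_y Standardize the response as well as the predictors.
#' @return An object of class `monarch_pls` with elements `weights`,
#'   `scores`, `x_loadings`, `y_loadings` (per component),
#'   `correlation_loadings` (variable x component, including the response
#'   row), `explained_y_variance` (percent per component), `coefficients`
#'   (original scale, with intercept), `fitted`, `fitted_r2`, and the
#'   centring/scaling constants.
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
#' fit <- fit_pls1(d, "y", n_components = 1)
#' fit$fitted_r2 # 1
#' @export
fit_pls1 <- function(data, response, n_components = 2L, scale_y = TRUE) {
  prep <- pls_prepare(data, response)
  x0 <- prep$x
  y0 <- prep$y
  n <- nrow(x0)
  if (n_components < 1) abort("`n_components` must be positive")

  x_center <- colMeans(x0)
  x_scale <- apply(x0, 2, sd)
  if (any(x_scale == 0)) {
    abort(paste0(
      "zero-variance predictor(s): ",
      paste(colnames(x0)[x_scale == 0], collapse = ", ")
    ))
  }
  y_center <- mean(y0)
  y_scale <- if (scale_y) sd(y0) else 1
  if (y_scale == 0) abort("the response has zero variance")

  x <- sweep(sweep(x0, 2, x_center), 2, x_scale, "/")
  y <- (y0 - y_center) / y_scale
  tss <- sum(y^2)

  p_vars <- ncol(x)
  a <- n_components
  w_mat <- matrix(0, p_vars, a, dimnames = list(colnames(x0), NULL))
  p_mat <- matrix(0, p_vars, a, dimnames = list(colnames(x0), NULL))
  t_mat <- matrix(0, n, a)
  q_vec <- numeric(a)
  xd <- x
  yd <- y
  for (c in seq_len(a)) {
    w <- drop(crossprod(xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      abort("deflated predictors carry no covariance with the response; reduce `n_components`")
    }
    w <- w / nw
    tt <- drop(xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) abort("degenerate component score; reduce `n_components`")
    p <- drop(crossprod(xd, tt)) / tt2
    q <- sum(yd * tt) / tt2
    xd <- xd - tcrossprod(tt, p)
    yd <- yd - tt * q
    w_mat[, c] <- w
    p_mat[, c] <- p
    t_mat[, c] <- tt
    q_vec[c] <- q
  }

  # correlation loadings against the undeflated variables and the response
  cl <- rbind(cor(x0, t_mat), cor(y0, t_mat))
  rownames(cl) <- c(colnames(x0), response)
  colnames(cl) <- paste0("comp", seq_len(a))

  explained <- 100 * q_vec^2 * colSums(t_mat^2) / tss

  # regression coefficients: standardized scale, then back-transformed
  b_std <- w_mat %*% solve(crossprod(p_mat, w_mat), q_vec)
  b_orig <- drop(b_std) * y_scale / x_scale
  intercept <- y_center - sum(b_orig * x_center)
  fitted <- drop(x0 %*% b_orig) + intercept
  r2 <- 1 - sum((y0 - fitted)^2) / sum((y0 - mean(y0))^2)

  structure(
    list(
      response = response, variables = colnames(x0),
      n_components = as.integer(a),
      x_center = x_center, x_scale = x_scale,
      y_center = y_center, y_scale = y_scale, scale_y = scale_y,
      weights = w_mat, scores = t_mat, x_loadings = p_mat,
      y_loadings = q_vec,
      correlation_loadings = cl,
      explained_y_variance = explained,
      coefficients_std = drop(b_std),
      coefficients = c(`(Intercept)` = intercept, b_orig),
      fitted = fitted, fitted_r2 = r2,
      data = prep$frame
    ),
    class = "monarch_pls"
  )
}

pls_prepare <- function(data, response) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    abort(paste0("response column `", response, "` not found"))
  }
  num <- vapply(data, is.numeric, logical(1))
  keep <- setdiff(names(data)[num], c(response, "year"))
  if (length(keep) == 0) abort("no numeric predictor columns")
  x <- as.matrix(data[keep])
  if (anyNA(x) || anyNA(data[[response]])) {
    abort("missing values present; impute before fitting")
  }
  list(x = x, y = data[[response]], frame = data[c(response, keep)])
}

#' Leave-one-out cross-validation of a PLS1 model
#'
#' Computes the predicted residual error sum of squares
#' `PRESS = sum_i (y_i - yhat_(i/i))^2`, where `yhat_(i/i)` is the
#' prediction of row `i` from a model refit without it (centring and
#' scaling re-estimated inside each fold to avoid leakage), and the
#' cross-validated R-squared `Q2 = 1 - PRESS / TSS`, with TSS taken about
#' the full-sample mean.
#'
#' @inheritParams fit_pls1
#' @return A one-row tibble with columns `press`, `q2`, `tss`.
#' @export
pls_loo <- function(data, response, n_components = 2L, scale_y = TRUE) {
  prep <- pls_prepare(data, response)
  n <- nrow(prep$x)
  if (n < n_components + 2) abort("too few rows for leave-one-out validation")
  preds <- vapply(seq_len(n), function(i) {
    fold <- prep$frame[-i, , drop = FALSE]
    sds <- vapply(fold[, -1, drop = FALSE], sd, numeric(1))
    if (any(sds == 0)) {
      warn("zero-variance predictor inside a fold; dropped for that fold")
      fold <- fold[c(TRUE, sds != 0)]
    }
    fit <- fit_pls1(fold, response, n_components, scale_y)
    newx <- as.numeric(prep$frame[i, fit$variables])
    sum(fit$coefficients[-1] * newx) + fit$coefficients[1]
  }, numeric(1))
  y <- prep$y
  press <- sum((y - preds)^2)
  tss <- sum((y - mean(y))^2)
  tibble::tibble(press = press, q2 = 1 - press / tss, tss = tss)
}

#' Per-component share of response variance
#'
#' @param model A fitted [fit_pls1()] model.
#' @return A tibble with `component`, `explained_y_pct`, `cumulative_pct`.
#' @export
explained_variance_report <- function(model) {
  stopifnot(inherits(model, "monarch_pls"))
  tibble::tibble(
    component = seq_len(model$n_components),
    explained_y_pct = model$explained_y_variance,
    cumulative_pct = cumsum(model$explained_y_variance)
  )
}

#' Select variables by correlation loading
#'
#' Keeps, per component, the variables whose absolute correlation loading
#' meets `threshold`, ranked by absolute loading and truncated at `top_k`
#' (threshold first, cap second). The union across components is the
#' screened candidate set handed to the time-series stage.
#'
#' @param model A fitted [fit_pls1()] model.
#' @param threshold Minimum absolute correlation loading.
#' @param top_k Per-component cap on the number of selected variables.
#' @return A tibble with `component`, `rank`, `variable`,
#'   `correlation_loading`; the attribute `"selected"` carries the deduped
#'   union in first-appearance order.
#' @export
select_by_loadings <- function(model, threshold = 0.15, top_k = 10L) {
  stopifnot(inherits(model, "monarch_pls"))
  cl <- model$correlation_loadings
  cl <- cl[rownames(cl) != model$response, , drop = FALSE]
  per_comp <- purrr::map_dfr(seq_len(ncol(cl)), function(c) {
    v <- cl[, c]
    keep <- which(abs(v) >= threshold)
    keep <- keep[order(-abs(v[keep]))]
    keep <- head(keep, top_k)
    if (length(keep) == 0) {
      return(tibble::tibble(
        component = integer(), rank = integer(),
        variable = character(), correlation_loading = double()
      ))
    }
    tibble::tibble(
      component = c, rank = seq_along(keep),
      variable = names(v)[keep], correlation_loading = unname(v[keep])
    )
  })
  attr(per_comp, "selected") <- unique(per_comp$variable)
  per_comp
}

#' Prune correlated candidates to one representative per cluster
#'
#' Greedy single-linkage grouping of the candidate variables whose pairwise
#' absolute correlation exceeds `r_threshold`; one representative is kept
#' per group, preferring (in order) the highest-priority region, the larger
#' absolute loading, then the lexicographically first name, so the result
#' is deterministic. Mirrors the practice of keeping the north-central
#' variant of a covariate measured redundantly across breeding regions.
#'
#' @param candidates Character vector of candidate variable names.
#' @param data Data frame holding the candidate columns (complete cases
#'   used for the correlations).
#' @param loadings Optional named numeric vector of loadings used for
#'   tie-breaking (e.g. from [select_by_loadings()]).
#' @param meta Optional tibble `variable`, `region` used for the region
#'   preference; variables absent from it get the lowest priority.
#' @param r_threshold Absolute-correlation threshold above which two
#'   variables are considered redundant.
#' @param region_priority Regions in decreasing order of preference.
#' @return A tibble `variable`, `group`, `kept`; kept variables carry
#'   `kept = TRUE`, one per group.
#' @export
correlation_filter <- function(candidates, data, loadings = NULL, meta = NULL,
                               r_threshold = 0.6,
                               region_priority = c("north_central",
                                                   "northeast", "south",
                                                   "overwinter")) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("candidates not in data: ", paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(data[candidates])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0(
      "zero-variance candidate(s): ",
      paste(candidates[sds == 0], collapse = ", ")
    ))
  }
  r <- abs(cor(x))
  p <- length(candidates)
  # single-linkage components of the |r| > threshold graph
  group <- seq_len(p)
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      if (r[i, j] > r_threshold) {
        g <- group %in% c(group[i], group[j])
        group[g] <- min(group[i], group[j])
      }
    }
  }
  region_rank <- function(v) {
    if (is.null(meta)) return(rep(length(region_priority) + 1L, length(v)))
    reg <- meta$region[match(v, meta$variable)]
    rk <- match(reg, region_priority)
    rk[is.na(rk)] <- length(region_priority) + 1L
    rk
  }
  loading_of <- function(v) {
    if (is.null(loadings)) return(rep(0, length(v)))
    l <- abs(loadings[v])
    l[is.na(l)] <- 0
    unname(l)
  }
  out <- tibble::tibble(
    variable = candidates,
    group = match(group, unique(group)),
    region_rank = region_rank(candidates),
    abs_loading = loading_of(candidates)
  ) |>
    dplyr::mutate(
      kept = seq_len(dplyr::n()) ==
        order(.data$region_rank, -.data$abs_loading, .data$variable)[1],
      .by = "group"
    ) |>
    dplyr::select("variable", "group", "kept")
  out
}

#' @export
print.monarch_pls <- function(x, ...) {
  cat(
    "<monarch_pls> ", x$n_components, " component(s), ",
    length(x$variables), " predictors; fitted R2 = ",
    format(x$fitted_r2, digits = 4), "\n",
    sep = ""
  )
  cat(
    "explained response variance (%): ",
    paste(format(x$explained_y_variance, digits = 4), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn fit_pls1 Long table of weights, loadings and correlation
#'   loadings, one row per variable and component.
#' @param x,object A `monarch_pls` object.
#' @param ... Unused.
#' @export
tidy.monarch_pls <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_components), function(c) {
    tibble::tibble(
      component = c,
      variable = x$variables,
      weight = x$weights[, c],
      x_loading = x$x_loadings[, c],
      correlation_loading = x$correlation_loadings[x$variables, c]
    )
  })
}

#' @describeIn fit_pls1 One-row model summary (components, fitted R2,
#'   per-component explained response variance).
#' @export
glance.monarch_pls <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    fitted_r2 = x$fitted_r2,
    explained_y_pct_total = sum(x$explained_y_variance)
  )
}

#' @describeIn fit_pls1 Correlation-loading map for the first two
#'   components (the standard screening display), with unit and 50%
#'   explained-variance circles.
#' @export
autoplot.monarch_pls <- function(object, ...) {
  if (object$n_components < 2) {
    abort("the correlation-loading plot needs at least 2 components")
  }
  cl <- object$correlation_loadings
  df <- tibble::tibble(
    variable = rownames(cl),
    comp1 = cl[, 1], comp2 = cl[, 2],
    role = ifelse(rownames(cl) == object$response, "response", "predictor")
  )
  circle <- function(radius) {
    a <- seq(0, 2 * pi, length.out = 200)
    tibble::tibble(x = radius * cos(a), y = radius * sin(a), r = radius)
  }
  circles <- dplyr::bind_rows(circle(1), circle(sqrt(0.5)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2)) +
    ggplot2::geom_path(
      data = circles,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$r),
      colour = "grey70"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "correlation with component 1",
      y = "correlation with component 2",
      title = "PLS correlation loadings"
    )
}
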