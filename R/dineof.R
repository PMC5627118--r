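#' Select reference cells for imputation cross-validation
#'
#' Draws a set of observed cells to withhold during rank selection: the
#' imputation quality at each candidate rank is judged by the reconstruction
#' error on these known-but-hidden values. Cells are drawn without
#' replacement from the observed cells only, never from the truly missing
#' ones.
#'
#' @param mask Logical matrix, `TRUE` where the value is missing.
#' @param cv_fraction Fraction of observed cells to withhold, in (0, 0.5).
#' @param seed Integer seed.
#' @return An integer matrix with columns `row`, `col`, one withheld cell
#'   per line; at least one cell is always returned.
#' @export
mask_reference_cells <- function(mask, cv_fraction = 0.05, seed = 1L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (cv_fraction <= 0 || cv_fraction >= 0.5) {
    abort("`cv_fraction` must lie in (0, 0.5)")
  }
  observed <- which(!mask)
  if (length(observed) == 0) abort("no observed cells to withhold from")
  n_ref <- max(1L, round(cv_fraction * length(observed)))
  seed_rng(seed)
  cells <- sort(sample(observed, n_ref))
  cbind(
    row = ((cells - 1L) %% nrow(mask)) + 1L,
    col = ((cells - 1L) %/% nrow(mask)) + 1L
  )
}

#' Impute missing cells by iterative truncated SVD (DINEOF)
#'
#' Data-interpolating empirical orthogonal functions: missing cells are
#' initialised at their column means, and for each candidate number of
#' modes `k` the completed matrix is repeatedly standardized (centring and
#' scaling constants re-estimated from the current completion, since the
#' covariates mix units) and replaced by its rank-`k` SVD truncation at the
#' missing and withheld positions, until the re-estimated cells stabilise.
#' A random subset of observed cells is withheld as reference values; the
#' `k` minimising their root-mean-square reconstruction error (in
#' standardized units) is selected and the matrix is refit at that rank
#' using all observed cells. Observed cells are restored exactly in the
#' output.
#'
#' @param data A data frame (a `year` column, if present, is carried through
#'   untouched) or numeric matrix with `NA` for missing cells. Every column
#'   must have at least 2 observed values.
#' @param max_modes Largest candidate rank; defaults to
#'   `min(n_rows, n_cols) - 1`.
#' @param cv_fraction Fraction of observed cells withheld for rank
#'   selection.
#' @param tol Convergence tolerance: iteration stops once the RMS change of
#'   the re-estimated cells falls below `tol` times their magnitude (the
#'   larger of the cell RMS and the RMS column scale).
#' @param max_iter Iteration cap per candidate rank; hitting it flags the
#'   rank as non-converged in the report (a warning is raised only when the
#'   final refit at the selected rank is affected; the best iterate is
#'   still used).
#' @param patience Stop scanning ranks after this many consecutive ranks
#'   without an improvement in the withheld-cell RMSE; ranks beyond a clear
#'   minimum only overfit the reconstruction. Set to `Inf` to scan every
#'   candidate rank.
#' @param seed Integer seed for the withheld-cell draw.
#' @return An object of class `monarch_dineof`: a list with
#'   \describe{
#'     \item{completed}{the input with missing cells filled (same shape and
#'       column order; tibble in, tibble out).}
#'     \item{n_modes}{selected number of modes.}
#'     \item{cv_rmse}{tibble `k`, `rmse`, `iterations`, `converged`.}
#'     \item{n_iterations}{iterations used by the final refit.}
#'     \item{identity}{`TRUE` when the input had no missing cells and was
#'       returned unchanged.}
#'   }
#' @examples
#' x <- outer(1:6, 1:4)
#' x[2, 3] <- NA
#' fit <- dineof_impute(x, seed = 7)
#' fit$completed[2, 3] # close to 2 * 3
#' @export
dineof_impute <- function(data, max_modes = NULL, cv_fraction = 0.05,
                          tol = 1e-8, max_iter = 500L, patience = 3L,
                          seed = 1L) {
  is_df <- is.data.frame(data)
  year_col <- NULL
  if (is_df) {
    df <- tibble::as_tibble(data)
    if ("year" %in% names(df)) {
      year_col <- df$year
      df <- dplyr::select(df, -"year")
    }
    x <- as.matrix(df)
  } else {
    x <- as.matrix(data)
  }
  storage.mode(x) <- "double"
  mask <- is.na(x)

  rebuild <- function(xc, extra) {
    out <- if (is_df) {
      res <- tibble::as_tibble(as.data.frame(xc))
      if (!is.null(year_col)) res <- dplyr::mutate(res, year = year_col, .before = 1)
      res
    } else {
      xc
    }
    structure(c(list(completed = out), extra), class = "monarch_dineof")
  }

  if (!any(mask)) {
    return(rebuild(x, list(
      n_modes = 0L,
      cv_rmse = tibble::tibble(
        k = integer(), rmse = double(),
        iterations = integer(), converged = logical()
      ),
      n_iterations = 0L, identity = TRUE
    )))
  }

  if (any(colSums(!mask) < 2)) {
    abort("every column must have at least 2 observed values")
  }
  if (is.null(max_modes)) max_modes <- min(dim(x)) - 1L
  max_modes <- max(1L, min(max_modes, min(dim(x))))

  obs_mean <- apply(x, 2, mean, na.rm = TRUE)
  col_of <- function(idx) ((idx - 1L) %/% nrow(x)) + 1L

  # EM-style truncated-SVD completion at rank k: the filled cells start at
  # their column means and the centring/scaling constants are re-estimated
  # from the completed matrix at every iteration, so exact low-rank
  # structure stays low-rank on the working scale. Convergence is judged by
  # the RMS change of the re-estimated cells relative to their magnitude.
  run_rank <- function(k, fill_idx, ref_idx = NULL, ref_vals = NULL) {
    xw <- x
    xw[fill_idx] <- obs_mean[col_of(fill_idx)]
    it <- 0L
    converged <- FALSE
    repeat {
      it <- it + 1L
      ctr <- colMeans(xw)
      scl <- apply(xw, 2, sd)
      scl[scl == 0] <- 1
      z <- sweep(sweep(xw, 2, ctr), 2, scl, "/")
      sv <- La.svd(z, nu = k, nv = k)
      recon <- sv$u %*% (sv$d[seq_len(k)] * sv$vt[seq_len(k), , drop = FALSE])
      xr <- sweep(sweep(recon, 2, scl, "*"), 2, ctr, "+")
      new_vals <- xr[fill_idx]
      change <- sqrt(mean((new_vals - xw[fill_idx])^2))
      xw[fill_idx] <- new_vals
      level <- max(sqrt(mean(new_vals^2)), sqrt(mean(scl^2)),
                   .Machine$double.eps)
      if (change <= tol * level) {
        converged <- TRUE
        break
      }
      if (it >= max_iter) break
    }
    rmse <- NA_real_
    if (!is.null(ref_idx)) {
      # withheld-cell error in standardized units, comparable across columns
      scl_f <- apply(xw, 2, sd)
      scl_f[scl_f == 0] <- 1
      rmse <- sqrt(mean(
        ((xw[ref_idx] - ref_vals) / scl_f[col_of(ref_idx)])^2
      ))
    }
    list(x = xw, rmse = rmse, iterations = it, converged = converged)
  }

  ref <- mask_reference_cells(mask, cv_fraction, seed)
  ref_idx <- ref[, "row"] + (ref[, "col"] - 1L) * nrow(x)
  ref_vals <- x[ref_idx]
  fill_idx <- c(which(mask), ref_idx) # missing + withheld cells re-estimated

  runs <- list()
  best_rmse <- Inf
  stalled <- 0L
  for (k in seq_len(max_modes)) {
    runs[[k]] <- run_rank(k, fill_idx, ref_idx, ref_vals)
    if (runs[[k]]$rmse < best_rmse) {
      best_rmse <- runs[[k]]$rmse
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
      if (stalled >= patience) break
    }
  }
  cv <- tibble::tibble(
    k = seq_along(runs),
    rmse = vapply(runs, `[[`, numeric(1), "rmse"),
    iterations = vapply(runs, `[[`, integer(1), "iterations"),
    converged = vapply(runs, `[[`, logical(1), "converged")
  )
  k_best <- cv$k[which.min(cv$rmse)]

  # refit at the chosen rank with all observed cells participating
  final <- run_rank(k_best, which(mask))
  if (!final$converged) {
    warn(paste0(
      "DINEOF refit at the selected rank (", k_best, ") stopped at max_iter ",
      "without meeting tol; best iterate returned"
    ))
  }
  xc <- final$x
  xc[!mask] <- x[!mask] # observed cells restored bit-exactly

  rebuild(xc, list(
    n_modes = as.integer(k_best), cv_rmse = cv,
    n_iterations = final$iterations, identity = FALSE
  ))
}

#' @export
print.monarch_dineof <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<monarch_dineof> no missing cells; input returned unchanged\n")
  } else {
    cat(
      "<monarch_dineof> ", x$n_modes, " mode(s) selected; withheld-cell RMSE ",
      format(min(x$cv_rmse$rmse), digits = 4), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @describeIn dineof_impute Tidy the cross-validation curve: one row per
#'   candidate rank with its withheld-cell RMSE.
#' @param x,object A `monarch_dineof` object.
#' @param ... Unused.
#' @export
tidy.monarch_dineof <- function(x, ...) x$cv_rmse

#' @describeIn dineof_impute One-row summary: selected rank, its RMSE,
#'   iterations, convergence.
#' @export
glance.monarch_dineof <- function(x, ...) {
  if (isTRUE(x$identity)) {
    return(tibble::tibble(
      n_modes = 0L, cv_rmse = NA_real_, n_iterations = 0L,
      converged = TRUE, identity = TRUE
    ))
  }
  tibble::tibble(
    n_modes = x$n_modes,
    cv_rmse = min(x$cv_rmse$rmse),
    n_iterations = x$n_iterations,
    converged = all(x$cv_rmse$converged),
    identity = FALSE
  )
}

#' @describeIn dineof_impute Plot the withheld-cell RMSE against the number
#'   of retained modes, marking the selected rank.
#' @export
autoplot.monarch_dineof <- function(object, ...) {
  if (isTRUE(object$identity)) abort("nothing to plot: input had no missing cells")
  ggplot2::ggplot(object$cv_rmse, ggplot2::aes(x = .data$k, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_modes, linetype = "dashed") +
    ggplot2::labs(
      x = "number of EOF modes",
      y = "withheld-cell RMSE",
      title = "DINEOF rank selection"
    )
}
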