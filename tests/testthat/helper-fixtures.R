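# Small in-code fixtures shared across the suite.

make_daily <- function(tmax, tmin = tmax - 10, site = "s1",
                       region = "north_central",
                       start = as.Date("2001-06-01")) {
  tibble::tibble(
    date = start + seq_along(tmax) - 1,
    site = site, region = region,
    tmax_c = tmax, tmin_c = tmin
  )
}

# rank-1 matrix u v' used by the imputation oracle tests
rank1_matrix <- function(u = c(1, 2, 3, 4, 5, 6), v = c(2, -1, 0.5, 3)) {
  outer(u, v)
}

# deterministic low-rank + noise matrix
lowrank_noisy <- function(n = 30, p = 10, rank = 3, noise_sd = 0.1,
                          seed = 11) {
  set.seed(seed)
  left <- matrix(rnorm(n * rank), n, rank)
  right <- matrix(rnorm(p * rank), p, rank)
  left %*% t(right) + matrix(rnorm(n * p, 0, noise_sd), n, p)
}

# brute-force leave-one-out PRESS: literal loop refit, no shortcuts
press_brute_force <- function(data, response, n_components) {
  n <- nrow(data)
  errs <- vapply(seq_len(n), function(i) {
    fit <- fit_pls1(data[-i, ], response, n_components)
    newx <- as.numeric(data[i, fit$variables])
    pred <- fit$coefficients[1] + sum(fit$coefficients[-1] * newx)
    data[[response]][i] - pred
  }, numeric(1))
  sum(errs^2)
}

# small regression frame with known linear structure
linear_frame <- function(n = 22, betas = c(x1 = -0.5, x2 = 0.3, x3 = 0),
                         noise_sd = 0.2, seed = 5) {
  set.seed(seed)
  x <- matrix(rnorm(n * length(betas)), n,
              dimnames = list(NULL, names(betas)))
  y <- 1 + as.numeric(x %*% betas) + rnorm(n, 0, noise_sd)
  tibble::as_tibble(as.data.frame(x)) |>
    dplyr::mutate(log_area = y, .before = 1)
}
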