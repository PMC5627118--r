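#' Accumulate growing degree days from daily temperature records
#'
#' Monarch larval development accumulates thermal units between a development
#' base of 11.5 degrees C and an upper cap of 36 degrees C. The daily
#' contribution is the simple-average degree-day
#' `max(0, (min(tmax, cap) + tmin) / 2 - base)`: the cap truncates the daily
#' maximum before averaging, and days whose capped mean falls below the base
#' contribute nothing. Daily values are summed over the requested window for
#' each site, and the regional value is the unweighted mean of its site sums
#' (regional series in the field are means over several dozen stations).
#'
#' @param daily A data frame of daily records with columns `date` (Date or
#'   coercible), `site`, `region`, `tmax_c`, `tmin_c`.
#' @param start,end Window bounds (inclusive), coercible to Date. Defaults
#'   span the whole series.
#' @param base Development base temperature, degrees C.
#' @param cap Upper development threshold, degrees C, applied to `tmax_c`.
#' @return A tibble with columns `region`, `n_sites`, `gdd` (mean over sites
#'   of the per-site accumulated degree days).
#' @examples
#' d <- tibble::tibble(
#'   date = as.Date("2001-06-01"), site = "a", region = "north_central",
#'   tmax_c = 25, tmin_c = 15
#' )
#' compute_gdd(d) # (25 + 15)/2 - 11.5 = 8.5
#' @export
compute_gdd <- function(daily, start = NULL, end = NULL, base = 11.5, cap = 36) {
  daily <- check_daily(daily)
  daily <- clip_window(daily, start, end)
  daily |>
    dplyr::mutate(
      dd = pmax(0, (pmin(.data$tmax_c, cap) + .data$tmin_c) / 2 - base)
    ) |>
    dplyr::summarise(dd = sum(.data$dd), .by = c("region", "site")) |>
    dplyr::summarise(
      n_sites = dplyr::n(), gdd = mean(.data$dd), .by = "region"
    )
}

#' Accumulate lethal degree days from daily maxima
#'
#' Days whose maximum reaches the lethal threshold (38 degrees C) contribute
#' `tmax - 37` degree days; cooler days contribute nothing. Site sums are
#' averaged within region, as for [compute_gdd()].
#'
#' @inheritParams compute_gdd
#' @param threshold Daily maximum (degrees C) at which lethal accumulation
#'   begins.
#' @param subtract Reference temperature subtracted from qualifying maxima.
#' @return A tibble with columns `region`, `n_sites`, `ldd`.
#' @export
compute_ldd <- function(daily, start = NULL, end = NULL, threshold = 38,
                        subtract = 37) {
  daily <- check_daily(daily)
  daily <- clip_window(daily, start, end)
  daily |>
    dplyr::mutate(
      dd = ifelse(.data$tmax_c >= threshold, .data$tmax_c - subtract, 0)
    ) |>
    dplyr::summarise(dd = sum(.data$dd), .by = c("region", "site")) |>
    dplyr::summarise(
      n_sites = dplyr::n(), ldd = mean(.data$dd), .by = "region"
    )
}

check_daily <- function(daily) {
  required <- c("date", "site", "region", "tmax_c", "tmin_c")
  missing_cols <- setdiff(required, names(daily))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`daily` is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(daily) == 0) abort("`daily` has no rows")
  if (any(daily$tmin_c > daily$tmax_c)) {
    abort("`daily` contains rows with tmin_c > tmax_c")
  }
  dplyr::mutate(tibble::as_tibble(daily), date = as.Date(.data$date))
}

clip_window <- function(daily, start, end) {
  if (!is.null(start)) daily <- dplyr::filter(daily, .data$date >= as.Date(start))
  if (!is.null(end)) daily <- dplyr::filter(daily, .data$date <= as.Date(end))
  if (nrow(daily) == 0) abort("window contains no daily records")
  daily
}

#' Annualize multi-year habitat-loss period totals
#'
#' Remote-sensing surveys of overwintering forest loss report totals over
#' multi-year periods. Each period's total is divided evenly across its
#' years; years before the first period carry zero loss (no loss is assumed
#' prior to the record). The running sum gives the cumulative-loss covariate
#' used in trend analyses.
#'
#' @param periods A data frame with columns `start_year`, `end_year`,
#'   `loss` (hectares); periods must not overlap and losses must be
#'   nonnegative. Zero rows are allowed.
#' @param years Optional integer vector of years the output should span;
#'   defaults to the range covered by `periods`.
#' @return A tibble with columns `year`, `annual_loss`, `cumulative_loss`.
#' @examples
#' annualize_periods(
#'   tibble::tibble(start_year = 2001, end_year = 2003, loss = 300)
#' )
#' @export
annualize_periods <- function(periods, years = NULL) {
  periods <- tibble::as_tibble(periods)
  if (nrow(periods) > 0) {
    stopifnot(all(c("start_year", "end_year", "loss") %in% names(periods)))
    if (any(periods$loss < 0)) abort("negative period losses are not allowed")
    if (any(periods$end_year < periods$start_year)) {
      abort("period end_year precedes start_year")
    }
    covered <- unlist(Map(seq, periods$start_year, periods$end_year))
    if (anyDuplicated(covered)) abort("periods overlap")
  }
  if (is.null(years)) {
    if (nrow(periods) == 0) abort("`years` required when `periods` is empty")
    years <- seq(min(periods$start_year), max(periods$end_year))
  }
  annual <- stats::setNames(rep(0, length(years)), years)
  for (i in seq_len(nrow(periods))) {
    span <- seq(periods$start_year[i], periods$end_year[i])
    keep <- as.character(intersect(span, years))
    annual[keep] <- annual[keep] + periods$loss[i] / length(span)
  }
  tibble::tibble(
    year = as.integer(years),
    annual_loss = unname(annual),
    cumulative_loss = cumsum(unname(annual))
  )
}
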