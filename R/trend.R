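# Coerce a window spec c(start, end) to Dates and subset a series to it.
window_slice <- function(series, window = NULL) {
  stopifnot(inherits(series, "index_series"))
  if (is.null(window)) return(series)
  window <- as.Date(window)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  series[series$day >= window[1] & series$day <= window[2], , drop = FALSE]
}

#' Centered rolling mean of the index
#'
#' Smooths the daily index with a centered moving average, mainly to damp
#' the weekly posting seasonality of social-media streams (hence the
#' default window of 7 days). Missing days contribute nothing; endpoints
#' use the shrunken window that fits inside the series.
#'
#' @param series an `index_series` tibble.
#' @param window_days odd window width in days (default 7).
#' @return The series with an added `index_smooth` column.
#' @export
rolling_mean <- function(series, window_days = 7L) {
  stopifnot(inherits(series, "index_series"))
  window_days <- as.integer(window_days)
  if (window_days < 1L || window_days %% 2L == 0L) {
    stop("window_days must be a positive odd integer", call. = FALSE)
  }
  if (window_days > nrow(series)) {
    stop("window_days exceeds series length", call. = FALSE)
  }
  half <- window_days %/% 2L
  n <- nrow(series)
  vals <- series$index
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    w <- vals[lo:hi]
    w <- w[!is.na(w)]
    if (length(w) == 0L) NA_real_ else mean(w)
  }, numeric(1))
  series$index_smooth <- out
  series
}

#' Fit a linear trend to the index over a date window
#'
#' Ordinary least squares of I(d) on integer day offset from the window
#' start, solved with the closed-form normal equations. The slope is in
#' index units per day; the intercept is the fitted index at the window's
#' first day, which keeps it interpretable. Missing days are dropped, not
#' interpolated. The 95% confidence interval for the slope uses the
#' residual standard error and the t distribution on n - 2 degrees of
#' freedom.
#'
#' @param series an `index_series` tibble.
#' @param window `c(start, end)` dates, or `NULL` for the whole series.
#' @return A `trend_fit`: list with `window`, `slope`, `intercept`,
#'   `r_squared`, `slope_se`, `slope_ci95` (length-2), `n_days`.
#' @export
#' @examples
#' s <- new_index_series(
#'   as.Date("2020-03-01") + 0:2, c(10L, 10L, 10L), c(0L, 1L, 2L)
#' )
#' fit_linear_trend(s)
fit_linear_trend <- function(series, window = NULL) {
  sub <- window_slice(series, window)
  sub <- sub[!sub$missing, , drop = FALSE]
  n <- nrow(sub)
  if (n < 3L) {
    stop("need at least 3 non-missing days to fit a trend", call. = FALSE)
  }
  x <- as.numeric(sub$day - min(sub$day))
  y <- sub$index
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  resid <- y - (intercept + slope * x)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  se <- sqrt(ss_res / (n - 2L) / sxx)
  tcrit <- stats::qt(0.975, df = n - 2L)
  structure(
    list(
      window = c(min(sub$day), max(sub$day)),
      slope = slope,
      intercept = intercept,
      r_squared = r2,
      slope_se = se,
      slope_ci95 = c(slope - tcrit * se, slope + tcrit * se),
      n_days = n
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> ", format(x$window[1]), " .. ", format(x$window[2]),
      " (", x$n_days, " days)\n", sep = "")
  cat(sprintf("  slope     %.6g per day  [95%% CI %.6g, %.6g]\n",
              x$slope, x$slope_ci95[1], x$slope_ci95[2]))
  cat(sprintf("  intercept %.6g   R^2 %.4f\n", x$intercept, x$r_squared))
  invisible(x)
}

#' Index range and band-inclusion check over a window
#'
#' Reports the extrema of the index in a date window and the fraction of
#' (non-missing) days whose index lies inside a stated band — used to
#' verify plateau behaviour such as "the index stays within [0.15, 0.18]".
#'
#' @param series an `index_series` tibble.
#' @param window `c(start, end)` dates, or `NULL` for the whole series.
#' @param band numeric `c(low, high)` inclusion band (inclusive).
#' @return List with `min`, `max`, `fraction_in_band`, `n_days`.
#' @export
range_check <- function(series, window = NULL, band = c(0.15, 0.18)) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  sub <- window_slice(series, window)
  sub <- sub[!sub$missing, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("window contains no non-missing days", call. = FALSE)
  }
  v <- sub$index
  list(
    min = min(v),
    max = max(v),
    fraction_in_band = mean(v >= band[1] & v <= band[2]),
    n_days = nrow(sub)
  )
}

#' Compare mean index between two date windows
#'
#' Difference of window means with a seeded permutation test: day labels
#' are shuffled across the pooled days and the absolute mean difference
#' recomputed, giving a two-sided p-value under the exchangeability null.
#' Used for contrasts such as pre- vs post-vaccination-campaign windows.
#'
#' @param series an `index_series` tibble.
#' @param window_a,window_b disjoint `c(start, end)` date windows, each
#'   with at least 3 non-missing days.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation draw.
#' @return List with `mean_a`, `mean_b`, `difference` (a minus b),
#'   `p_value`, `n_a`, `n_b`, `n_perm`.
#' @export
compare_windows <- function(series, window_a, window_b,
                            n_perm = 10000L, seed = 1L) {
  window_a <- as.Date(window_a)
  window_b <- as.Date(window_b)
  if (window_a[1] <= window_b[2] && window_b[1] <= window_a[2]) {
    stop("windows must be disjoint", call. = FALSE)
  }
  a <- window_slice(series, window_a)
  a <- a$index[!a$missing]
  b <- window_slice(series, window_b)
  b <- b$index[!b$missing]
  if (length(a) < 3L || length(b) < 3L) {
    stop("each window needs at least 3 non-missing days", call. = FALSE)
  }
  obs <- mean(a) - mean(b)
  pooled <- c(a, b)
  na <- length(a)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), na)
    mean(pooled[idx]) - mean(pooled[-idx])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(
    mean_a = mean(a), mean_b = mean(b), difference = obs,
    p_value = p, n_a = na, n_b = length(b), n_perm = as.integer(n_perm)
  )
}

#' Read an external daily series (deaths, vaccination share, ...)
#'
#' Two-column CSV `date,value` with a header, the layout of common
#' public-health data extracts. Dates must be strictly increasing and
#' values finite.
#'
#' @param path CSV path.
#' @param label short description of the quantity.
#' @return A tibble with columns `date` (Date), `value` (numeric),
#'   carrying attribute `label`.
#' @export
read_external_series <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "value") %in% names(df)))
  out <- tibble::tibble(date = as.Date(df$date), value = as.numeric(df$value))
  out <- out[order(out$date), , drop = FALSE]
  if (anyDuplicated(out$date)) stop("duplicate dates in external series", call. = FALSE)
  if (any(!is.finite(out$value))) stop("non-finite values in external series", call. = FALSE)
  attr(out, "label") <- label
  out
}

#' Forward-fill an external series onto a daily grid
#'
#' Cumulative series reported at a non-daily cadence (e.g. vaccination
#' share) are carried forward up to `max_gap` days; gaps longer than that
#' stay missing. Values are never back-filled. Incidence series such as
#' daily deaths should not be filled at all.
#'
#' @param ext external series tibble (see [read_external_series()]).
#' @param max_gap maximum days to carry a value forward (default 6).
#' @return The series on a contiguous daily grid, `NA` where unfilled.
#' @export
fill_forward <- function(ext, max_gap = 6L) {
  stopifnot(nrow(ext) > 0L)
  grid <- seq(min(ext$date), max(ext$date), by = "day")
  idx <- match(grid, ext$date)
  val <- ext$value[idx]
  last_obs <- cummax(ifelse(is.na(idx), 0L, seq_along(grid)))
  gap <- seq_along(grid) - last_obs
  fill_from <- ifelse(last_obs > 0L & gap <= max_gap, last_obs, NA_integer_)
  out <- tibble::tibble(
    date = grid,
    value = ifelse(is.na(fill_from), NA_real_, val[fill_from])
  )
  # val[fill_from] picks the grid row of the last observation, which holds
  # the observed value there
  attr(out, "label") <- attr(ext, "label")
  out
}

#' Correlate the index with an external daily series
#'
#' Shifts the external series by `lag_days` (positive lag means the
#' external value from `lag_days` earlier is paired with today's index),
#' inner-joins on date, and returns the Pearson correlation over the
#' overlapping days. Missing index days and missing external values are
#' dropped.
#'
#' @param series an `index_series` tibble.
#' @param ext external series tibble (see [read_external_series()]).
#' @param lag_days integer day shift applied to the external dates.
#' @return List with `r` (Pearson correlation), `n` (pairs used),
#'   `lag_days`.
#' @export
align_and_correlate <- function(series, ext, lag_days = 0L) {
  stopifnot(inherits(series, "index_series"))
  shifted <- tibble::tibble(date = ext$date + as.integer(lag_days), value = ext$value)
  joined <- dplyr::inner_join(
    tibble::tibble(date = series$day, index = series$index, missing = series$missing),
    shifted,
    by = "date"
  )
  joined <- joined[!joined$missing & !is.na(joined$value) & !is.na(joined$index), , drop = FALSE]
  if (nrow(joined) < 3L) {
    stop("need at least 3 overlapping dates to correlate", call. = FALSE)
  }
  list(
    r = stats::cor(joined$index, joined$value),
    n = nrow(joined),
    lag_days = as.integer(lag_days)
  )
}
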