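const_series <- function(value, n, t = 1000L, start = "2020-03-01") {
  new_index_series(as.Date(start) + seq_len(n) - 1, rep(t, n),
                   rep(as.integer(round(value * t)), n))
}

test_that("rolling mean: constants pass through, window 1 is identity, linear interiors unchanged", {
  s <- const_series(0.18, 20)
  expect_equal(rolling_mean(s, 7)$index_smooth, rep(0.18, 20))
  expect_identical(rolling_mean(s, 1)$index_smooth, s$index)

  lin <- new_index_series(as.Date("2020-03-01") + 0:19, rep(1000L, 20), 10L * (0:19))
  sm <- rolling_mean(lin, 7)$index_smooth
  # centered mean of a linear sequence equals its centre value
  expect_equal(sm[4:17], lin$index[4:17])

  expect_error(rolling_mean(s, 4), "odd")
  expect_error(rolling_mean(s, 21), "exceeds")
})

test_that("fit_linear_trend recovers exact lines and flat series", {
  s <- new_index_series(as.Date("2020-03-01") + 0:2, rep(1L, 3), 0:2)
  f <- fit_linear_trend(s)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r_squared, 1)

  flat <- const_series(0.17, 10)
  expect_equal(fit_linear_trend(flat)$slope, 0)

  expect_error(fit_linear_trend(const_series(0.1, 2)), "at least 3")
})

test_that("closed-form OLS matches the matrix-algebra oracle on 100 seeded series", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    t_d <- rep(10000L, n)
    n_d <- as.integer(rpois(n, 10000 * runif(1, 0.05, 0.3)))
    s <- new_index_series(as.Date("2020-03-01") + seq_len(n) - 1, t_d, n_d)
    f <- fit_linear_trend(s)
    o <- oracle_ols(as.numeric(s$day - min(s$day)), s$index)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(f$slope_se, o$slope_se, tolerance = 1e-10)
    expect_equal(f$slope_ci95, o$ci, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
  }
})

test_that("lm() cross-check and translation invariance of the slope", {
  set.seed(55)
  n_d <- as.integer(rpois(40, 10000 * 0.17))
  s <- new_index_series(as.Date("2020-03-01") + 0:39, rep(10000L, 40), n_d)
  f <- fit_linear_trend(s)
  lmfit <- lm(index ~ I(as.numeric(day - min(day))), data = s)
  expect_equal(f$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(f$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)

  shifted <- s
  shifted$day <- shifted$day + 365L
  f2 <- fit_linear_trend(shifted)
  expect_equal(f2$slope, f$slope, tolerance = 1e-14)
  expect_equal(f2$intercept, f$intercept, tolerance = 1e-14)
})

test_that("missing days are dropped from fits, not interpolated", {
  s <- new_index_series(as.Date("2020-03-01") + c(0:2, 5:7), rep(10L, 6),
                        as.integer(c(0, 1, 2, 5, 6, 7) * 10))
  f <- fit_linear_trend(s)
  expect_identical(f$n_days, 6L)
  expect_equal(f$slope, 1, tolerance = 1e-12)   # exact line despite the gap
})

test_that("range_check reports extrema and band fractions", {
  s <- const_series(0.16, 10)
  r <- range_check(s, band = c(0.15, 0.18))
  expect_equal(r$fraction_in_band, 1)
  expect_equal(r$min, 0.16)
  expect_equal(range_check(const_series(0.20, 10), band = c(0.15, 0.18))$fraction_in_band, 0)
})

test_that("compare_windows: identical windows give p near 1, separated windows reject", {
  s <- const_series(0.17, 20)
  r <- compare_windows(s, as.Date(c("2020-03-01", "2020-03-10")),
                       as.Date(c("2020-03-11", "2020-03-20")),
                       n_perm = 2000, seed = 4)
  expect_equal(r$difference, 0)
  expect_gt(r$p_value, 0.99)

  set.seed(8)
  hi <- as.integer(round(rnorm(10, 0.17, 1e-4) * 1e6))
  lo <- as.integer(round(rnorm(10, 0.12, 1e-4) * 1e6))
  s2 <- new_index_series(as.Date("2020-03-01") + 0:19, rep(1000000L, 20), c(hi, lo))
  r2 <- compare_windows(s2, as.Date(c("2020-03-01", "2020-03-10")),
                        as.Date(c("2020-03-11", "2020-03-20")),
                        n_perm = 5000, seed = 4)
  expect_lt(r2$p_value, 0.001)
  expect_equal(r2$difference, mean(s2$index[1:10]) - mean(s2$index[11:20]))

  expect_error(
    compare_windows(s, as.Date(c("2020-03-01", "2020-03-12")),
                    as.Date(c("2020-03-10", "2020-03-20"))),
    "disjoint"
  )
  expect_error(
    compare_windows(s, as.Date(c("2020-03-01", "2020-03-10")),
                    as.Date(c("2020-04-01", "2020-04-05"))),
    "at least 3"
  )
})

test_that("tiny-n permutation p-value matches exhaustive enumeration", {
  # 3 + 3 days: all choose(6,3)=20 label assignments enumerated by hand
  vals <- c(0.30, 0.28, 0.29, 0.10, 0.12, 0.11)
  s <- new_index_series(as.Date("2020-03-01") + 0:5, rep(100L, 6),
                        as.integer(vals * 100))
  obs <- mean(vals[1:3]) - mean(vals[4:6])
  combs <- combn(6, 3)
  exact <- mean(apply(combs, 2, function(ix) {
    abs(mean(vals[ix]) - mean(vals[-ix])) >= abs(obs) - 1e-12
  }))
  r <- compare_windows(s, as.Date(c("2020-03-01", "2020-03-03")),
                       as.Date(c("2020-03-04", "2020-03-06")),
                       n_perm = 20000, seed = 2)
  expect_equal(r$p_value, exact, tolerance = 0.1)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(77)
  pvals <- vapply(1:400, function(i) {
    n_d <- as.integer(rpois(12, 1000 * 0.17))
    s <- new_index_series(as.Date("2020-03-01") + 0:11, rep(1000L, 12), n_d)
    compare_windows(s, as.Date(c("2020-03-01", "2020-03-06")),
                    as.Date(c("2020-03-07", "2020-03-12")),
                    n_perm = 400, seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("external series alignment and correlation behave at the extremes", {
  s <- const_series(0.2, 10)
  s$negative_words <- as.integer(seq(100, 190, by = 10))
  s <- new_index_series(s$day, s$total_tweets, s$negative_words)
  ext_same <- tibble::tibble(date = s$day, value = s$index)
  expect_equal(align_and_correlate(s, ext_same)$r, 1)
  ext_neg <- tibble::tibble(date = s$day, value = -s$index)
  expect_equal(align_and_correlate(s, ext_neg)$r, -1)

  lagged <- tibble::tibble(date = s$day - 3, value = s$index)
  r <- align_and_correlate(s, lagged, lag_days = 3)
  expect_equal(r$r, 1)
  expect_identical(r$n, 10L)

  expect_error(
    align_and_correlate(s, tibble::tibble(date = s$day + 100, value = 1:10)),
    "overlapping"
  )
})

test_that("external CSV reading validates and forward-fill respects the gap cap", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("date,value", "2020-11-01,0.01", "2020-11-04,0.02", "2020-11-20,0.10"), p)
  ext <- read_external_series(p, label = "share vaccinated")
  expect_identical(nrow(ext), 3L)
  filled <- fill_forward(ext, max_gap = 6)
  expect_equal(filled$value[filled$date == as.Date("2020-11-03")], 0.01) # gap 2 <= 6
  expect_equal(filled$value[filled$date == as.Date("2020-11-10")], 0.02) # gap 6 <= 6
  expect_true(is.na(filled$value[filled$date == as.Date("2020-11-11")])) # gap 7 > 6
  expect_equal(filled$value[filled$date == as.Date("2020-11-20")], 0.10)

  writeLines(c("date,value", "2020-11-01,1", "2020-11-01,2"), p)
  expect_error(read_external_series(p), "duplicate")
})
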