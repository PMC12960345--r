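daily_tbl <- function(start, n, values) {
  tibble::tibble(date = as.Date(start) + 0:(n - 1), value = values)
}

test_that("monthly statistics summarize available days and flag partial months", {
  x <- daily_tbl("2000-06-01", 30, rep(5, 30))
  m <- monthly_stats(x)
  expect_equal(m$mean, 5)
  expect_equal(m$n_obs, 30)
  expect_false(m$partial)
  expect_true(m$qualifies)

  # 22 of 31 July days: flagged partial, kept, coverage ~0.71
  jul <- daily_tbl("1768-07-01", 22, rnorm(22))
  mj <- monthly_stats(jul)
  expect_true(mj$partial)
  expect_true(mj$qualifies)
  expect_equal(mj$coverage, 22 / 31, tolerance = 1e-12)
  expect_equal(round(mj$coverage, 2), 0.71)

  # below min_coverage: still emitted, but does not qualify
  few <- daily_tbl("1768-07-01", 10, rnorm(10))
  expect_false(monthly_stats(few)$qualifies)

  # empty input: no rows
  expect_equal(nrow(monthly_stats(daily_tbl("2000-01-01", 3, NA_real_))), 0)
})

test_that("monthly mean is order-invariant and min <= mean <= max", {
  set.seed(51)
  x <- daily_tbl("1991-03-01", 31, rnorm(31, -7, 4))
  m1 <- monthly_stats(x)
  m2 <- monthly_stats(x[sample(31), ])
  expect_equal(m1, m2)
  expect_true(m1$min <= m1$mean && m1$mean <= m1$max)
})

test_that("seasonal means weight months equally and need every month", {
  monthly <- dplyr::bind_rows(
    monthly_stats(daily_tbl("1999-12-01", 31, rep(2, 31))),
    monthly_stats(daily_tbl("2000-01-01", 31, rep(2, 31))),
    monthly_stats(daily_tbl("2000-02-01", 29, rep(2, 29)))
  )
  s <- seasonal_stats(monthly, seasons = list("Dec-Feb" = c(12, 1, 2)))
  expect_equal(s$mean, 2)
  expect_equal(s$n_months, 3)
  # wrapping season is assigned to the January year
  expect_equal(s$year, 2000)

  # drop February: no seasonal value
  s2 <- seasonal_stats(monthly[monthly$month != 2, ],
                       seasons = list("Dec-Feb" = c(12, 1, 2)))
  expect_equal(nrow(s2), 0)
})

test_that("seasonal mean equals the unweighted mean of monthly means exactly", {
  set.seed(52)
  monthly <- dplyr::bind_rows(lapply(1:6, function(m) {
    n <- days_in_month <- c(31, 28, 31, 30, 31, 30)[m]
    monthly_stats(daily_tbl(sprintf("2001-%02d-01", m), n, rnorm(n, m, 3)))
  }))
  s <- seasonal_stats(monthly, seasons = list("Jan-Jun" = 1:6))
  expect_equal(s$mean, mean(monthly$mean), tolerance = 1e-12)
})

test_that("normals require two years, handle constants and cover Feb 29", {
  const <- tibble::tibble(date = seq(as.Date("1991-01-01"),
                                     as.Date("1994-12-31"), by = "1 day"),
                          value = 3)
  expect_error(contemporary_normals(const[1:300, ]), "two distinct years")
  nm <- contemporary_normals(const)
  expect_true(all(nm$monthly$sd == 0))
  expect_true(all(nm$daily$sd == 0, na.rm = TRUE))
  expect_equal(nrow(nm$daily), 366)
  feb29 <- nm$daily[nm$daily$month == 2 & nm$daily$day == 29, ]
  expect_false(is.na(feb29$mean)) # pooled from the window across years
  expect_equal(feb29$mean, 3)
})

test_that("anomalies are historical minus normal, zero on self-comparison", {
  set.seed(53)
  x <- tibble::tibble(date = seq(as.Date("1991-01-01"), as.Date("1993-12-31"),
                                 by = "1 day"),
                      value = rnorm(1096, 0, 2))
  nm <- contemporary_normals(x)
  m91 <- monthly_stats(x[format(x$date, "%Y") == "1991", ])
  a <- anomalies(m91, nm)
  expect_equal(nrow(a), 12)
  expect_equal(a$anomaly, a$historical_mean - a$normal_mean, tolerance = 1e-12)

  # a series of exactly the normal values has zero anomaly
  self <- tibble::tibble(date = x$date[1:365],
                         value = nm$monthly$mean[as.integer(format(x$date[1:365], "%m"))])
  a0 <- anomalies(monthly_stats(self), nm)
  expect_equal(a0$anomaly, rep(0, 12), tolerance = 1e-12)

  # months absent from the normals are omitted
  nm2 <- nm
  nm2$monthly <- nm2$monthly[nm2$monthly$month != 1, ]
  expect_equal(nrow(anomalies(m91, nm2)), 11)
})

test_that("the worked January anomaly example evaluates exactly", {
  # historical January monthly mean -18.2 degC vs contemporary normal -7.6
  hist_jan <- monthly_stats(daily_tbl("1791-01-01", 31, rep(-18.2, 31)))
  normals <- structure(
    list(monthly = tibble::tibble(month = 1L, mean = -7.6, sd = 1,
                                  min = -12, max = -2, n = 900),
         daily = tibble::tibble(), reference = "1991-2020",
         n_years = 30, window = 15),
    class = "normals_table"
  )
  a <- anomalies(hist_jan, normals)
  expect_equal(a$anomaly, -10.6, tolerance = 1e-12)
})

test_that("envelope exceedance uses a strict boundary", {
  # unit-normal reference for every day of year
  nm <- structure(
    list(monthly = tibble::tibble(month = 1:12, mean = 0, sd = 1,
                                  min = -4, max = 4, n = 900),
         daily = tibble::tibble(doy = 1:366,
                                month = as.integer(format(as.Date("1999-12-31") + 1:366, "%m")),
                                day = as.integer(format(as.Date("1999-12-31") + 1:366, "%d")),
                                mean = 0, sd = 1, n = 450),
         reference = "unit", n_years = 30, window = 15),
    class = "normals_table"
  )
  d <- as.Date("1993-06-15")
  on_edge <- tibble::tibble(date = d, value = 2)
  expect_equal(envelope_exceedance(on_edge, nm, k = 2)$n_exceed, 0)
  beyond <- tibble::tibble(date = d, value = 2 + 1e-9)
  expect_equal(envelope_exceedance(beyond, nm, k = 2)$n_exceed, 1)
  # k = 0 flags every value that differs from the mean
  expect_equal(envelope_exceedance(tibble::tibble(date = d, value = 0.3),
                                   nm, k = 0)$n_exceed, 1)
  expect_equal(envelope_exceedance(tibble::tibble(date = d, value = 0),
                                   nm, k = 0)$n_exceed, 0)
  # monthly breakdown is consistent with the total
  many <- tibble::tibble(date = as.Date("1993-01-01") + 0:99,
                         value = rep(c(0, 3), 50))
  ex <- envelope_exceedance(many, nm, k = 2)
  expect_equal(sum(ex$by_month$n_exceed), ex$n_exceed)
  expect_equal(ex$n_exceed, 50)
  expect_equal(ex$percent, 50)
})

test_that("percent of days below a threshold uses strict inequality", {
  expect_equal(percent_days_below(c(-1, 0, 1), 0), 100 / 3, tolerance = 1e-9)
  expect_equal(percent_days_below(c(-5, -1), 0), 100)
  expect_equal(percent_days_below(tibble::tibble(date = Sys.Date() + 1:3,
                                                 value = c(-1, NA, 2)), 0), 50)
  expect_error(percent_days_below(c(NA_real_, NA_real_), 0), "undefined")
})

test_that("reports serialize deterministically with a provenance block", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  m <- monthly_stats(daily_tbl("1791-01-01", 31, rep(-18.2, 31)))
  for (o in c(out1, out2)) {
    build_report(o, monthly = m, config = list(a = 1), seed = 7L)
  }
  r1 <- readBin(file.path(out1, "report.json"), "raw", n = 1e6)
  expect_identical(r1, readBin(file.path(out2, "report.json"), "raw", n = 1e6))
  expect_identical(readLines(file.path(out1, "monthly.csv")),
                   readLines(file.path(out2, "monthly.csv")))
  rep <- jsonlite::read_json(file.path(out1, "report.json"))
  expect_equal(rep$provenance$seed, 7)
  expect_true(nzchar(rep$provenance$config_hash))

  # empty report is still valid
  empty <- build_report(withr::local_tempdir(), config = list(), seed = 1L)
  expect_true(is.list(empty))
})
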