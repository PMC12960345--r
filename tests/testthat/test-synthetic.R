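test_that("the generator is deterministic in its seed", {
  cfg <- synthetic_config("contemporary", seed = 42,
                          start = "1991-01-01", end = "1993-12-31")
  s1 <- simulate_contemporary(cfg)
  s2 <- simulate_contemporary(cfg)
  expect_identical(s1$records, s2$records)

  cfg_b <- synthetic_config("contemporary", seed = 43,
                            start = "1991-01-01", end = "1993-12-31")
  s3 <- simulate_contemporary(cfg_b)
  expect_false(identical(s1$records, s3$records))

  h1 <- simulate_historical(synthetic_config("historical_1789", seed = 5,
                                             start = "1790-01-01",
                                             end = "1790-12-31"))
  h2 <- simulate_historical(synthetic_config("historical_1789", seed = 5,
                                             start = "1790-01-01",
                                             end = "1790-12-31"))
  expect_identical(h1$records, h2$records)
})

test_that("with no noise the temperatures equal the seasonal cycle", {
  cfg <- synthetic_config("contemporary", seed = 1, sigma = 0, phi = 0,
                          start = "1991-01-01", end = "1992-12-31")
  s <- simulate_contemporary(cfg)
  cyc <- seasonal_cycle(cfg, s$records$date)
  expect_equal(s$records$temperature, round(cyc, 1), tolerance = 1e-12)
})

test_that("the seasonal cycle preserves the configured monthly means", {
  cfg <- synthetic_config("contemporary", start = "1991-01-01",
                          end = "2000-12-31")
  dates <- seq(cfg$start, cfg$end, by = "1 day")
  cyc <- seasonal_cycle(cfg, dates)
  m <- tapply(cyc, as.integer(format(dates, "%m")), mean)
  expect_equal(as.numeric(m), cfg$temp_monthly, tolerance = 1e-9)
})

test_that("monthly sample means recover the configured targets within 2 SE", {
  cfg <- synthetic_config("contemporary", seed = 99,
                          start = "1991-01-01", end = "2020-12-31")
  s <- simulate_contemporary(cfg)
  rec <- s$records
  mo <- as.integer(format(rec$date, "%m"))
  t_bar <- tapply(rec$temperature, mo, mean)
  n <- tabulate(mo, 12)
  # AR(1) effective sample size: n (1 - phi) / (1 + phi)
  se_t <- (cfg$sigma / sqrt(1 - cfg$phi^2)) /
    sqrt(n * (1 - cfg$phi) / (1 + cfg$phi))
  expect_true(all(abs(t_bar - cfg$temp_monthly) <= 2 * se_t))

  v_bar <- tapply(rec$wind, mo, mean)
  v_sd <- cfg$wind10_monthly / gamma(1.5) *
    sqrt(gamma(2) - gamma(1.5)^2) # Weibull shape-2 SD from the mean
  expect_true(all(abs(v_bar - cfg$wind10_monthly) <= 2 * v_sd / sqrt(n)))
})

test_that("wind discretization is a nearest-code rule with ties to the lower code", {
  sc <- default_wind_scales()
  expect_equal(discretize_wind(0, sc$scale_1767_6pt), 1L)
  expect_equal(discretize_wind(0, sc$scale_1789_5pt), 0L)
  # midpoint between 8.0 and 13.9 goes to the lower code
  expect_equal(discretize_wind((8.0 + 13.9) / 2, sc$scale_1767_6pt), 3L)
  expect_equal(discretize_wind((8.0 + 13.9) / 2 + 1e-9, sc$scale_1767_6pt), 4L)
  expect_error(discretize_wind(-1, sc$scale_1767_6pt), "non-negative")

  set.seed(71)
  v <- runif(10000, 0, 40)
  for (s in sc) {
    expect_equal(discretize_wind(v, s), oracle_nearest_code(v, s))
  }
})

test_that("force -> speed -> force round-trips over all codes of both scales", {
  for (s in default_wind_scales()) {
    expect_identical(discretize_wind(wind_force_to_speed10(s$codes, s), s),
                     s$codes)
  }
})

test_that("generated historical registers pass the full reading contract", {
  cfg <- synthetic_config("historical_1767", seed = 3,
                          start = "1767-09-01", end = "1768-07-22")
  s <- simulate_historical(cfg)
  # twice-daily records, Fahrenheit on the half-degree grid
  expect_equal(nrow(s$records), 2 * as.integer(cfg$end - cfg$start + 1))
  expect_setequal(unique(s$records$hour_lt), c("08:00", "14:00"))
  expect_true(all(s$records$temperature * 2 ==
                    round(s$records$temperature * 2)))

  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yml")
  write_register(s, csv, sidecar = yml)
  s2 <- read_register(csv, yml)
  expect_equal(s2$records, s$records)
  expect_equal(nrow(validate_series(s2)), 0)
  std <- standardize(s2)
  expect_equal(nrow(std), nrow(s$records))
  expect_true(all(!is.na(std$t_c) & !is.na(std$v10)))
})

test_that("missingness is applied as contiguous date blocks", {
  cfg <- synthetic_config("historical_1789", seed = 8, missing_rate = 0.15,
                          start = "1790-01-01", end = "1791-12-31")
  s <- simulate_historical(cfg)
  all_days <- seq(cfg$start, cfg$end, by = "1 day")
  present <- all_days %in% s$records$date
  expect_lt(mean(present), 1)
  gone <- rle(!present)
  block_lengths <- gone$lengths[gone$values]
  expect_gt(length(block_lengths), 0)
  expect_gt(mean(block_lengths), 2) # blocks, not isolated days
  # rate is approximately honoured
  expect_equal(1 - mean(present), 0.15, tolerance = 0.05)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config("contemporary", phi = 1), "phi")
  expect_error(synthetic_config("contemporary", sigma = -1), "non-negative")
  expect_error(synthetic_config("contemporary", missing_rate = 1), "missing_rate")
  expect_error(synthetic_config("contemporary", weibull_shape = 0), "positive")
  expect_error(simulate_contemporary(
    synthetic_config("historical_1767")), "contemporary")
  expect_error(simulate_historical(
    synthetic_config("contemporary")), "historical")
})

test_that("stimulus frequencies of generated data match a direct AR(1) oracle", {
  cfg <- synthetic_config("contemporary", seed = 12,
                          start = "1991-01-01", end = "2020-12-31")
  s <- simulate_contemporary(cfg)
  std <- standardize(s)
  freq <- stimulus_frequencies(interdiurnal_changes(std, "15:00"), by = "period")

  # oracle: interdiurnal |delta| of a pure AR(1) with the config parameters
  # (the seasonal cycle adds a sub-0.5 degC/day drift; tolerance covers it)
  oracle <- withr::with_seed(99, {
    n <- 200000
    a <- stats::filter(rnorm(n, sd = cfg$sigma), cfg$phi, "recursive")
    table(oracle_stimulus(abs(diff(as.numeric(a))))) / (n - 1) * 100
  })
  for (cat in c("neutral", "perceptible", "significant", "severe")) {
    got <- freq$percent[freq$category == cat]
    expect_lt(abs(got - unname(oracle[cat])), 3) # percentage points
  }
})
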