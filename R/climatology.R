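#' Monthly statistics of a dated daily series
#'
#' Arithmetic mean, min and max per (year, month) over the available
#' (non-missing) days. Incomplete months are flagged, never dropped:
#' `partial` marks any month with missing days and `qualifies` marks
#' months whose coverage reaches `min_coverage`, the criterion downstream
#' comparisons use.
#'
#' @param x A tibble with columns `date` (Date) and `value` (numeric);
#'   at most one value per date.
#' @param min_coverage Fraction of the month's days required for the month
#'   to qualify for comparisons (default 0.7).
#' @param variable Optional variable name carried into the output.
#'
#' @return A tibble with columns `variable`, `year`, `month`, `mean`,
#'   `min`, `max`, `n_obs`, `coverage`, `partial`, `qualifies`.
#' @export
monthly_stats <- function(x, min_coverage = 0.7, variable = "value") {
  stopifnot(all(c("date", "value") %in% names(x)))
  x <- x[!is.na(x$value), , drop = FALSE]
  if (nrow(x) == 0L) {
    return(tibble::tibble(variable = character(), year = integer(),
                          month = integer(), mean = numeric(), min = numeric(),
                          max = numeric(), n_obs = integer(),
                          coverage = numeric(), partial = logical(),
                          qualifies = logical()))
  }
  if (anyDuplicated(x$date)) {
    stop("monthly_stats() expects at most one value per date", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  x$year <- as.integer(format(x$date, "%Y"))
  x$month <- as.integer(format(x$date, "%m"))
  out <- dplyr::summarise(
    dplyr::group_by(x, .data$year, .data$month),
    mean = mean(.data$value), min = min(.data$value), max = max(.data$value),
    n_obs = dplyr::n(), .groups = "drop"
  )
  out$coverage <- out$n_obs / mapply(days_in_month, out$year, out$month)
  out$partial <- out$coverage < 1
  out$qualifies <- out$coverage >= min_coverage
  out$variable <- variable
  dplyr::arrange(
    out[, c("variable", "year", "month", "mean", "min", "max", "n_obs",
            "coverage", "partial", "qualifies")],
    .data$year, .data$month
  )
}

#' Default season definitions
#'
#' Climatological seasons plus the half-year block over which historical
#' and contemporary records overlap: Sep-Nov, Dec-Feb, Mar-May, Jun-Aug
#' and Jan-Jun.
#'
#' @return Named list of month-number vectors.
#' @export
default_seasons <- function() {
  list("Sep-Nov" = 9:11, "Dec-Feb" = c(12, 1, 2), "Mar-May" = 3:5,
       "Jun-Aug" = 6:8, "Jan-Jun" = 1:6)
}

#' Seasonal statistics from monthly summaries
#'
#' Season mean = unweighted mean of the constituent monthly means (the
#' mean-of-monthly-means convention of climate normals). A season value is
#' emitted only when every constituent month is present and qualifies.
#' Seasons that wrap the calendar year (e.g. Dec-Feb) are assigned to the
#' year of their January: December belongs to the following season-year.
#'
#' @param monthly Output of [monthly_stats()].
#' @param seasons Named list of month vectors (see [default_seasons()]);
#'   a wrap (descending step) marks months taken from the previous
#'   calendar year.
#'
#' @return A tibble with columns `variable`, `season`, `year`, `mean`,
#'   `n_months`.
#' @export
seasonal_stats <- function(monthly, seasons = default_seasons()) {
  stopifnot(all(c("variable", "year", "month", "mean") %in% names(monthly)))
  rows <- list()
  for (sname in names(seasons)) {
    mv <- seasons[[sname]]
    wrap_at <- which(diff(mv) < 0)
    prev_year_months <- if (length(wrap_at)) mv[seq_len(wrap_at[1L])] else integer()
    m <- monthly[monthly$month %in% mv, , drop = FALSE]
    if (nrow(m) == 0L) next
    m$season_year <- m$year + as.integer(m$month %in% prev_year_months)
    if ("qualifies" %in% names(m)) m <- m[m$qualifies, , drop = FALSE]
    got <- dplyr::summarise(
      dplyr::group_by(m, .data$variable, .data$season_year),
      mean = mean(.data$mean), n_months = dplyr::n(),
      complete = all(mv %in% .data$month), .groups = "drop"
    )
    got <- got[got$complete & got$n_months == length(mv), , drop = FALSE]
    if (nrow(got) == 0L) next
    rows[[sname]] <- tibble::tibble(
      variable = got$variable, season = sname, year = got$season_year,
      mean = got$mean, n_months = got$n_months
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(variable = character(), season = character(),
                          year = integer(), mean = numeric(),
                          n_months = integer()))
  }
  dplyr::bind_rows(rows)
}

# Day-of-year index on a fixed 366-day calendar (Feb 29 = 60), so that
# post-February days share one index across leap and common years.
doy366 <- function(date) {
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  starts <- c(0L, 31L, 60L, 91L, 121L, 152L, 182L, 213L, 244L, 274L, 305L, 335L)
  starts[m] + d
}

#' Contemporary climatological normals
#'
#' Reference statistics from a multi-year contemporary series: per
#' calendar month the mean, SD, min and max over all observations, and per
#' day-of-year (366-day calendar, Feb 29 pooled with its neighbours) the
#' mean and SD over a centered running window of calendar days across all
#' years (default 15 days; `window = 1` disables the smoothing). The
#' day-of-year rows are the basis of the +/- 1 SD and +/- 2 SD envelopes.
#'
#' @param x A tibble with columns `date`, `value`, covering at least two
#'   distinct years.
#' @param window Width (odd integer, days) of the centered pooling window.
#' @param reference Optional label for the reference period; defaults to
#'   the year range of `x`.
#'
#' @return An object of class `normals_table`: a list with elements
#'   `monthly` (12 rows), `daily` (366 rows: `doy`, `month`, `day`,
#'   `mean`, `sd`, `n`), `reference`, `n_years`, `window`.
#' @export
contemporary_normals <- function(x, window = 15, reference = NULL) {
  stopifnot(all(c("date", "value") %in% names(x)))
  x <- x[!is.na(x$value), , drop = FALSE]
  years <- unique(format(x$date, "%Y"))
  if (length(years) < 2L) {
    stop("normals require at least two distinct years of data", call. = FALSE)
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  x$month <- as.integer(format(x$date, "%m"))

  monthly <- dplyr::summarise(
    dplyr::group_by(x, .data$month),
    mean = mean(.data$value), sd = sd(.data$value),
    min = min(.data$value), max = max(.data$value),
    n = dplyr::n(), .groups = "drop"
  )

  doy <- doy366(x$date)
  half <- (window - 1L) %/% 2L
  # values pooled per doy, then each target doy pools its circular window
  vals_by_doy <- split(x$value, factor(doy, levels = 1:366))
  d_mean <- d_sd <- rep(NA_real_, 366)
  d_n <- integer(366)
  for (k in 1:366) {
    win <- ((k - half - 1L):(k + half - 1L)) %% 366L + 1L
    v <- unlist(vals_by_doy[win], use.names = FALSE)
    d_n[k] <- length(v)
    if (length(v) >= 2L) {
      d_mean[k] <- mean(v)
      d_sd[k] <- sd(v)
    } else if (length(v) == 1L) {
      d_mean[k] <- v
    }
  }
  ref_dates <- as.Date("1999-12-31") + 1:366 # doy366 grid of a leap year (2000)
  daily <- tibble::tibble(
    doy = 1:366,
    month = as.integer(format(ref_dates, "%m")),
    day = as.integer(format(ref_dates, "%d")),
    mean = d_mean, sd = d_sd, n = d_n
  )
  structure(
    list(monthly = monthly, daily = daily,
         reference = reference %||% paste(range(as.integer(years)), collapse = "-"),
         n_years = length(years), window = window),
    class = "normals_table"
  )
}

#' @export
print.normals_table <- function(x, ...) {
  cat(sprintf("<normals_table> reference %s (%d years, %d-day window)\n",
              x$reference, x$n_years, x$window))
  print(x$monthly)
  invisible(x)
}

#' Monthly anomalies against contemporary normals
#'
#' Anomaly = historical monthly mean minus the contemporary normal for the
#' same calendar month. Defined only where both sides have a qualifying
#' value; other months are omitted.
#'
#' @param historical_monthly Output of [monthly_stats()] for the
#'   historical series.
#' @param normals A `normals_table` from [contemporary_normals()].
#' @param qualifying_only Use only months with `qualifies = TRUE`
#'   (default).
#'
#' @return A tibble with columns `variable`, `year`, `month`,
#'   `historical_mean`, `normal_mean`, `anomaly`.
#' @export
anomalies <- function(historical_monthly, normals, qualifying_only = TRUE) {
  stopifnot(inherits(normals, "normals_table"))
  h <- historical_monthly
  if (qualifying_only && "qualifies" %in% names(h)) {
    h <- h[h$qualifies, , drop = FALSE]
  }
  nm <- normals$monthly[, c("month", "mean")]
  names(nm) <- c("month", "normal_mean")
  out <- dplyr::inner_join(h, nm, by = "month")
  out <- out[!is.na(out$mean) & !is.na(out$normal_mean), , drop = FALSE]
  tibble::tibble(
    variable = out$variable, year = out$year, month = out$month,
    historical_mean = out$mean, normal_mean = out$normal_mean,
    anomaly = out$mean - out$normal_mean
  )
}

#' Envelope exceedance of daily values against normals
#'
#' Flags each dated value lying strictly outside the mean +/- k SD band of
#' its day-of-year normal (a value exactly on the band edge does not
#' exceed) and summarizes counts per month and overall.
#'
#' @param x A tibble with columns `date`, `value`.
#' @param normals A `normals_table`.
#' @param k SD multiplier (default 2).
#'
#' @return A list with `daily` (per-day tibble: `date`, `value`, `mean`,
#'   `sd`, `exceed`), `by_month` (year, month, n, n_exceed), `n`,
#'   `n_exceed` and `percent`.
#' @export
envelope_exceedance <- function(x, normals, k = 2) {
  stopifnot(inherits(normals, "normals_table"), k >= 0)
  x <- x[!is.na(x$value), , drop = FALSE]
  idx <- doy366(x$date)
  m <- normals$daily$mean[idx]
  s <- normals$daily$sd[idx]
  if (anyNA(m) || anyNA(s)) {
    stop("normals do not cover every day-of-year of the input", call. = FALSE)
  }
  exceed <- abs(x$value - m) > k * s
  daily <- tibble::tibble(date = x$date, value = x$value, mean = m, sd = s,
                          exceed = exceed)
  bm <- tibble::tibble(
    year = as.integer(format(x$date, "%Y")),
    month = as.integer(format(x$date, "%m")),
    exceed = exceed
  )
  by_month <- dplyr::summarise(
    dplyr::group_by(bm, .data$year, .data$month),
    n = dplyr::n(), n_exceed = sum(.data$exceed), .groups = "drop"
  )
  list(daily = daily, by_month = by_month, n = nrow(daily),
       n_exceed = sum(exceed), percent = 100 * mean(exceed))
}

#' Percentage of days strictly below a threshold
#'
#' @param x A tibble with columns `date`, `value`, or a numeric vector.
#' @param threshold Threshold; days with `value < threshold` count
#'   (strict inequality).
#'
#' @return Percentage of non-missing days below the threshold.
#' @export
#' @examples
#' percent_days_below(c(-1, 0, 1), 0) # 33.33: the 0 does not count
percent_days_below <- function(x, threshold) {
  v <- if (is.numeric(x)) x else x$value
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("no non-missing values: percentage undefined", call. = FALSE)
  }
  100 * mean(v < threshold)
}

#' Assemble and serialize a comparison report
#'
#' Gathers the pipeline's tables into one report and writes them as tidy
#' CSVs plus a JSON summary with a provenance block (configuration hash
#' and seed), deterministically: rerunning on identical inputs yields
#' byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param monthly,seasonal,anomaly,stimulus Tibbles from the respective
#'   stages (any may be `NULL`).
#' @param envelope Result of [envelope_exceedance()] (or `NULL`).
#' @param thresholds Named numeric vector of threshold frequencies (e.g.
#'   `c(pct_days_wct_below_0 = 58.1)`), or `NULL`.
#' @param config The run configuration (hashed into provenance).
#' @param seed The seed used for any randomness.
#'
#' @return Invisibly, the report list (also written to `out_dir`).
#' @export
build_report <- function(out_dir, monthly = NULL, seasonal = NULL,
                         anomaly = NULL, stimulus = NULL, envelope = NULL,
                         thresholds = NULL, config = list(), seed = NA_integer_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tbl <- function(tbl, name) {
    if (is.null(tbl)) return(NULL)
    write.csv(as.data.frame(tbl), file.path(out_dir, paste0(name, ".csv")),
              row.names = FALSE, quote = FALSE, eol = "\n")
    name
  }
  files <- c(
    write_tbl(monthly, "monthly"),
    write_tbl(seasonal, "seasonal"),
    write_tbl(anomaly, "anomalies"),
    write_tbl(stimulus, "stimulus_frequencies")
  )
  if (!is.null(envelope)) {
    env_daily <- envelope$daily
    env_daily$lo1 <- env_daily$mean - env_daily$sd
    env_daily$hi1 <- env_daily$mean + env_daily$sd
    env_daily$lo2 <- env_daily$mean - 2 * env_daily$sd
    env_daily$hi2 <- env_daily$mean + 2 * env_daily$sd
    files <- c(files, write_tbl(env_daily, "envelope"))
  }
  report <- list(
    provenance = list(
      package = "histbioclim",
      config_hash = rlang::hash(config),
      seed = seed
    ),
    files = as.list(paste0(files, ".csv")),
    envelope_summary = if (!is.null(envelope)) {
      list(n = envelope$n, n_exceed = envelope$n_exceed,
           percent = envelope$percent)
    },
    thresholds = as.list(thresholds)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}
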