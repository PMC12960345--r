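#' Interdiurnal air-temperature changes
#'
#' Day-to-day change in air temperature between consecutive calendar days
#' at a fixed observation hour (the early-afternoon reading in bioclimate
#' work): `delta_t = |t(day) - t(day - 1)|`, attributed to the later day.
#' Pairs exist only where both days carry a temperature at the stated
#' hour; gaps produce no record.
#'
#' @param std A `std_obs` tibble from [standardize()] (columns `date`,
#'   `hour_lt`, `t_c` suffice).
#' @param hour Observation hour to use, e.g. `"14:00"` (historical) or
#'   `"15:00"` (contemporary).
#'
#' @return A tibble with columns `date` (later day), `delta_t` (degC,
#'   absolute) and `category` (see [stimulus_category()]).
#' @export
interdiurnal_changes <- function(std, hour = "14:00") {
  stopifnot(all(c("date", "hour_lt", "t_c") %in% names(std)))
  x <- std[std$hour_lt == hour & !is.na(std$t_c), c("date", "t_c")]
  x <- dplyr::arrange(tibble::as_tibble(x), .data$date)
  if (nrow(x) < 2L) {
    return(tibble::tibble(date = as.Date(character()), delta_t = numeric(),
                          category = stimulus_category(numeric())))
  }
  consec <- diff(x$date) == 1
  delta <- abs(diff(x$t_c))[consec]
  tibble::tibble(
    date = x$date[-1L][consec],
    delta_t = delta,
    category = stimulus_category(delta)
  )
}

#' Thermal-stimulus category of an interdiurnal change
#'
#' Classifies the absolute day-to-day temperature change into the four
#' stimulus bands: <= 2.0 degC neutral, 2.1-4.0 perceptible, 4.1-6.0
#' significant, >= 6.1 severe. The change is first rounded to 0.1 degC
#' (half away from zero), which makes the printed bands exhaustive (2.04
#' falls to 2.0, neutral; 2.05 rises to 2.1, perceptible).
#'
#' @param delta_t Absolute temperature change(s), degC, non-negative.
#' @return Ordered factor with levels neutral < perceptible < significant
#'   < severe.
#' @export
#' @examples
#' stimulus_category(c(1.0, 2.04, 2.05, 6.1))
stimulus_category <- function(delta_t) {
  if (any(delta_t < 0, na.rm = TRUE)) {
    stop("interdiurnal change must be non-negative", call. = FALSE)
  }
  d <- floor(delta_t * 10 + 0.5) / 10 # round half away from zero (d >= 0)
  lab <- ifelse(d <= 2.0, "neutral",
         ifelse(d <= 4.0, "perceptible",
         ifelse(d <= 6.0, "significant", "severe")))
  factor(lab, levels = c("neutral", "perceptible", "significant", "severe"),
         ordered = TRUE)
}

#' Frequency of stimulus categories
#'
#' Tidy frequency table of stimulus categories per group. Percentages are
#' over the non-missing records of each group and sum to 100; empty groups
#' are simply absent. Categories with zero count are kept (0%) so tables
#' are rectangular.
#'
#' @param records Output of [interdiurnal_changes()].
#' @param by Grouping: `"period"` (one group), `"year"`, `"month"`
#'   (calendar month pooled across years) or `"year_month"`.
#'
#' @return A tibble with columns `group`, `category`, `n`, `percent` and
#'   `n_group` (total classified pairs in the group).
#' @export
stimulus_frequencies <- function(records,
                                 by = c("period", "year", "month", "year_month")) {
  by <- match.arg(by)
  rec <- records[!is.na(records$category), , drop = FALSE]
  grp <- switch(by,
    period = rep("all", nrow(rec)),
    year = format(rec$date, "%Y"),
    month = format(rec$date, "%m"),
    year_month = format(rec$date, "%Y-%m")
  )
  if (nrow(rec) == 0L) {
    return(tibble::tibble(group = character(), category = character(),
                          n = integer(), percent = numeric(),
                          n_group = integer()))
  }
  tab <- table(group = grp, category = rec$category)
  out <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("group", "category", "n")
  out <- dplyr::group_by(out, .data$group)
  out <- dplyr::mutate(out, n_group = sum(.data$n),
                       percent = 100 * .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  out <- out[out$n_group > 0L, ]
  dplyr::arrange(out[, c("group", "category", "n", "percent", "n_group")],
                 .data$group)
}
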