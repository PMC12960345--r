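#' Wind chill temperature (WCT)
#'
#' Apparent temperature combining air temperature and wind to express the
#' cooling of exposed skin:
#' `WCT = 13.12 + 0.6215 t - 11.37 v10^0.16 + 0.3965 t v10^0.16`,
#' with `t` in degC and `v10` the wind speed in m/s at 10 m. At
#' `v10 = 1` the power term is unity and the formula collapses to the
#' affine function `1.75 + 1.018 t`.
#'
#' The index's conventional validity domain is cold, windy conditions;
#' inputs outside it (`t_c > 10` degC or `v10 < 1.34` m/s) still return a
#' value — year-round series are routinely summarized with WCT — and can
#' be flagged via [wct_in_validity()].
#'
#' @param t_c Air temperature(s), degC.
#' @param v10 Wind speed(s) at 10 m, m/s, strictly positive.
#'
#' @return WCT in degC.
#' @export
#' @examples
#' wct(-25.2, adjust_wind_height(6.1, 1.2, 10))
wct <- function(t_c, v10) {
  if (any(v10 <= 0, na.rm = TRUE)) {
    stop("wct() requires v10 > 0", call. = FALSE)
  }
  vp <- v10^0.16
  13.12 + 0.6215 * t_c - 11.37 * vp + 0.3965 * t_c * vp
}

#' @rdname wct
#' @return `wct_in_validity()`: logical, `TRUE` when the inputs are inside
#'   the index's conventional validity domain (`t_c <= 10` degC and
#'   `v10 >= 1.34` m/s).
#' @export
wct_in_validity <- function(t_c, v10) {
  t_c <= 10 & v10 >= 1.34
}

#' Insulation predicted (Iclp)
#'
#' The clothing thermal insulation, in clo (1 clo = 0.155 K m^-2 W^-1),
#' required to keep a person in heat balance at air temperature `t_c`,
#' wind speed `v` and metabolic rate `M`:
#' total required insulation (Burton-Edholm) minus the insulation of the
#' boundary air layer (Fourt-Hollies):
#' `Iclp = 0.082 (91.4 - (1.8 t + 32)) / (0.01724 M) - 1 / (0.61 + (1.9 v)^0.5)`.
#'
#' The wind argument is conventionally the chest-height (1.2 m) speed.
#' `M = 135` W/m^2 corresponds to walking at 4 km/h, `M = 70` to standing.
#'
#' @param t_c Air temperature(s), degC.
#' @param v Wind speed(s), m/s, non-negative (chest height by convention).
#' @param M Metabolic rate, W/m^2, positive.
#'
#' @return Insulation in clo.
#' @export
#' @examples
#' iclp(-25.2, 6.1, M = 135) # person on the move
#' iclp(-25.2, 6.1, M = 70)  # standing person needs roughly twice as much
iclp <- function(t_c, v, M = 135) {
  if (any(M <= 0, na.rm = TRUE)) stop("iclp() requires M > 0", call. = FALSE)
  if (any(v < 0, na.rm = TRUE)) {
    stop("iclp() requires non-negative wind speed", call. = FALSE)
  }
  0.082 * (91.4 - (1.8 * t_c + 32)) / (0.01724 * M) -
    1 / (0.61 + (1.9 * v)^0.5)
}

#' Category schemes: ordered intervals covering the real line
#'
#' A `category_scheme` is an ordered set of disjoint, exhaustive intervals
#' with labels, used for the frostbite-risk and clothing-demand
#' classifications. Interval `i` runs from `breaks[i-1]` to `breaks[i]`;
#' `right_closed[i]` says whether break `i` belongs to the interval below
#' it (`TRUE`) or above it (`FALSE`), so boundary conventions can differ
#' per break (e.g. "<0.5 clo" but "3.0-4.0 clo" inclusive).
#'
#' @param name Scheme name.
#' @param breaks Strictly increasing finite break points (length k-1 for k
#'   labels).
#' @param labels Category labels, ordered from the lowest interval up.
#' @param right_closed Logical, recycled to `length(breaks)`: does each
#'   break belong to the interval below it?
#'
#' @return An object of class `category_scheme`.
#' @export
#' @examples
#' sch <- category_scheme("toy", breaks = c(0, 10), labels = c("lo", "mid", "hi"))
#' classify_value(c(-5, 0, 3, 10.5), sch)
category_scheme <- function(name, breaks, labels, right_closed = TRUE) {
  breaks <- as.numeric(breaks)
  if (length(labels) != length(breaks) + 1L) {
    stop("need exactly one more label than breaks", call. = FALSE)
  }
  if (anyNA(breaks) || any(!is.finite(breaks)) || any(diff(breaks) <= 0)) {
    stop("breaks must be finite and strictly increasing", call. = FALSE)
  }
  right_closed <- rep_len(as.logical(right_closed), length(breaks))
  structure(
    list(name = name, breaks = breaks, labels = as.character(labels),
         right_closed = right_closed),
    class = "category_scheme"
  )
}

#' @export
print.category_scheme <- function(x, ...) {
  b <- c(-Inf, x$breaks, Inf)
  lo_br <- ifelse(c(FALSE, x$right_closed), "(", "[")
  hi_br <- ifelse(c(x$right_closed, FALSE), "]", ")")
  cat("<category_scheme> ", x$name, "\n", sep = "")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %s%g, %g%s  %s\n", lo_br[i], b[i], b[i + 1L], hi_br[i],
                x$labels[i]))
  }
  invisible(x)
}

#' Classify values against a category scheme
#'
#' @param x Numeric values.
#' @param scheme A [category_scheme()].
#' @return An ordered factor of labels; `NA` input yields `NA`.
#' @export
classify_value <- function(x, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  idx <- rep.int(1L, length(x))
  for (i in seq_along(scheme$breaks)) {
    above <- if (scheme$right_closed[i]) x > scheme$breaks[i] else x >= scheme$breaks[i]
    idx[which(above)] <- i + 1L
  }
  idx[is.na(x)] <- NA_integer_
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Frostbite-risk scheme from WCT
#'
#' Default five-level scheme over WCT (degC): above 0 no risk ("lack"),
#' then low, moderate, high and very high with thresholds at 0, -10, -25
#' and -35 degC. `levels = 4` merges "very high" into "high", matching
#' the four-level legend (0 lack, 1 low, 2 moderate, 3 high) used in
#' envelope figures. All thresholds are configurable.
#'
#' @param levels 5 (default) or 4.
#' @param breaks Thresholds, ascending, one fewer than the labels.
#' @param labels Category labels from the most severe up.
#' @return A [category_scheme()].
#' @export
frostbite_scheme <- function(levels = 5,
                             breaks = if (levels == 5) c(-35, -25, -10, 0)
                                      else c(-25, -10, 0),
                             labels = if (levels == 5)
                                        c("very high", "high", "moderate", "low", "lack")
                                      else c("high", "moderate", "low", "lack")) {
  stopifnot(levels %in% c(4, 5))
  # 0 degC belongs to "low" ("lack" is strictly above 0); the colder
  # thresholds belong to the milder side (-10 is still "low", etc.)
  category_scheme("frostbite_risk", breaks = breaks, labels = labels,
                  right_closed = c(rep(FALSE, length(breaks) - 1L), TRUE))
}

#' @rdname frostbite_scheme
#' @param wct_value WCT value(s), degC.
#' @param scheme A [category_scheme()].
#' @export
#' @examples
#' frostbite_category(c(5, -11, -34.8))
frostbite_category <- function(wct_value, scheme = frostbite_scheme()) {
  classify_value(wct_value, scheme)
}

#' Clothing-demand bands from Iclp
#'
#' Seven bands of clothing thermal insulation (clo): <0.5 very light
#' summer; 0.5-1.0 light summer; 1.0-1.5 ordinary summer with accessories;
#' 1.5-2.5 spring/autumn; 2.5-3.0 spring/autumn with increased insulation;
#' 3.0-4.0 normal winter; >4.0 heavy winter ("arctic") clothing. Bands are
#' left-closed except the top one ("> 4.0" is exclusive at 4.0).
#'
#' @return A [category_scheme()].
#' @export
clothing_scheme <- function() {
  category_scheme(
    "clothing_demand",
    breaks = c(0.5, 1.0, 1.5, 2.5, 3.0, 4.0),
    labels = c("very light summer", "light summer",
               "ordinary summer with accessories", "spring/autumn",
               "spring/autumn increased", "normal winter",
               "heavy winter (arctic)"),
    right_closed = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' @rdname clothing_scheme
#' @param clo_value Insulation value(s), clo.
#' @param scheme A [category_scheme()].
#' @export
#' @examples
#' clothing_band(c(0.4, 3.5, 4.5))
clothing_band <- function(clo_value, scheme = clothing_scheme()) {
  classify_value(clo_value, scheme)
}

#' Compute the biometeorological record for a standardized series
#'
#' Applies [wct()] with the 10 m wind and [iclp()] with the 1.2 m
#' chest-height wind (both conventions of the indices), for a person on
#' the move (M = 135 W/m^2) and standing (M = 70 W/m^2), then classifies
#' frostbite risk from WCT and clothing demand from the moving-person
#' Iclp. Missing temperature or wind yields missing indices; nothing is
#' dropped.
#'
#' @param std A `std_obs` tibble from [standardize()].
#' @param frostbite A [category_scheme()] for frostbite risk.
#' @param clothing A [category_scheme()] for clothing demand.
#' @param M Named numeric vector `c(move = 135, stand = 70)`, W/m^2.
#'
#' @return A tibble with columns `date`, `hour_lt`, `wct`, `wct_valid`,
#'   `iclp_move`, `iclp_stand`, `frostbite`, `clothing`.
#' @export
compute_bio_series <- function(std, frostbite = frostbite_scheme(),
                               clothing = clothing_scheme(),
                               M = c(move = 135, stand = 70)) {
  stopifnot(all(c("date", "hour_lt", "t_c", "v10", "v12") %in% names(std)))
  ok_w <- !is.na(std$t_c) & !is.na(std$v10) & std$v10 > 0
  wct_v <- rep(NA_real_, nrow(std))
  wct_v[ok_w] <- wct(std$t_c[ok_w], std$v10[ok_w])
  wct_ok <- rep(NA, nrow(std))
  wct_ok[ok_w] <- wct_in_validity(std$t_c[ok_w], std$v10[ok_w])

  ok_i <- !is.na(std$t_c) & !is.na(std$v12)
  i_move <- i_stand <- rep(NA_real_, nrow(std))
  i_move[ok_i] <- iclp(std$t_c[ok_i], std$v12[ok_i], M = M[["move"]])
  i_stand[ok_i] <- iclp(std$t_c[ok_i], std$v12[ok_i], M = M[["stand"]])

  tibble::tibble(
    date = std$date,
    hour_lt = std$hour_lt,
    wct = wct_v,
    wct_valid = wct_ok,
    iclp_move = i_move,
    iclp_stand = i_stand,
    frostbite = classify_value(wct_v, frostbite),
    clothing = classify_value(i_move, clothing)
  )
}
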