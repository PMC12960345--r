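#' Configuration for a full pipeline run
#'
#' Collects everything a full historical-vs-contemporary comparison needs:
#' where the input series come from (register files with schema sidecars,
#' or the synthetic generator), the index conventions, the category
#' schemes, the season definitions and the output directory. Referenced
#' files are checked at construction; an unknown wind-scale id fails here
#' rather than mid-run.
#'
#' @param out_dir Output directory for the report files.
#' @param seed Integer seed for any randomness (recorded in the report).
#' @param historical Either a list `list(register = <csv>, schema = <yaml>)`
#'   or a [synthetic_config()] in a historical mode.
#' @param contemporary Either a list `list(register = <csv>, schema =
#'   <yaml>)` or a [synthetic_config()] with `mode = "contemporary"`.
#' @param scales Named list of [wind_scale()]s.
#' @param frostbite,clothing [category_scheme()]s for the classifiers.
#' @param seasons Season definitions (see [default_seasons()]).
#' @param hours Named character vector: observation hour used for the
#'   historical and contemporary afternoon comparisons.
#' @param k SD multiplier for the envelope exceedance summary.
#' @param min_coverage Monthly coverage needed to qualify for comparisons.
#'
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       historical = synthetic_config("historical_1789",
                                                     seed = seed,
                                                     start = "1789-01-01",
                                                     end = "1792-06-30"),
                       contemporary = synthetic_config("contemporary",
                                                       seed = seed + 1L),
                       scales = default_wind_scales(),
                       frostbite = frostbite_scheme(),
                       clothing = clothing_scheme(),
                       seasons = default_seasons(),
                       hours = c(historical = "14:00", contemporary = "15:00"),
                       k = 2, min_coverage = 0.7) {
  check_input <- function(x, what) {
    if (inherits(x, "synthetic_config")) return(x)
    if (is.list(x) && !is.null(x$register) && !is.null(x$schema)) {
      for (p in c(x$register, x$schema)) {
        if (!file.exists(p)) stop(what, " input file not found: ", p, call. = FALSE)
      }
      schema <- read_schema(x$schema)
      if (schema$wind_kind == "ordinal_force" &&
          !(schema$scale_id %in% names(scales))) {
        stop(sprintf("config error in `%s`: unknown scale_id '%s'",
                     what, schema$scale_id), call. = FALSE)
      }
      return(x)
    }
    stop("`", what, "` must be a synthetic_config or list(register=, schema=)",
         call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         historical = check_input(historical, "historical"),
         contemporary = check_input(contemporary, "contemporary"),
         scales = scales, frostbite = frostbite, clothing = clothing,
         seasons = seasons, hours = hours, k = k,
         min_coverage = min_coverage),
    class = "run_config"
  )
}

load_series <- function(input, scales) {
  if (inherits(input, "synthetic_config")) {
    if (input$mode == "contemporary") {
      simulate_contemporary(input)
    } else {
      simulate_historical(input, scales = scales)
    }
  } else {
    read_register(input$register, input$schema)
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full comparison pipeline
#'
#' Executes the end-to-end analysis: load or simulate both series,
#' standardize to canonical units, compute the biometeorological indices
#' and category series, classify interdiurnal stimuli, aggregate monthly
#' and seasonal statistics, build contemporary normals, and compare the
#' historical series against them (anomalies, SD-envelope exceedance,
#' threshold frequencies). Results are written to `config$out_dir` as tidy
#' CSVs plus a JSON report with provenance; identical configurations yield
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main intermediate tables and the
#'   serialized report.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hist_series <- stage("load_historical",
                       load_series(config$historical, config$scales))
  cont_series <- stage("load_contemporary",
                       load_series(config$contemporary, config$scales))

  std_h <- stage("standardize", standardize(hist_series, scales = config$scales))
  std_c <- stage("standardize", standardize(cont_series, scales = config$scales))

  bio_h <- stage("bioindices",
                 compute_bio_series(std_h, config$frostbite, config$clothing))
  bio_c <- stage("bioindices",
                 compute_bio_series(std_c, config$frostbite, config$clothing))

  h_hour <- config$hours[["historical"]]
  c_hour <- config$hours[["contemporary"]]
  stim_h <- stage("stimuli", interdiurnal_changes(std_h, hour = h_hour))
  stim_c <- stage("stimuli", interdiurnal_changes(std_c, hour = c_hour))
  stim_freq <- dplyr::bind_rows(
    dplyr::mutate(stimulus_frequencies(stim_h, by = "month"), period = "historical"),
    dplyr::mutate(stimulus_frequencies(stim_c, by = "month"), period = "contemporary")
  )

  afternoon <- function(std, bio, hour) {
    s <- std[std$hour_lt == hour, ]
    b <- bio[bio$hour_lt == hour, ]
    list(t = tibble::tibble(date = s$date, value = s$t_c),
         v12 = tibble::tibble(date = s$date, value = s$v12),
         wct = tibble::tibble(date = b$date, value = b$wct),
         iclp_move = tibble::tibble(date = b$date, value = b$iclp_move))
  }
  aft_h <- afternoon(std_h, bio_h, h_hour)
  aft_c <- afternoon(std_c, bio_c, c_hour)

  monthly <- stage("climatology", dplyr::bind_rows(
    lapply(names(aft_h), function(v) {
      dplyr::mutate(monthly_stats(aft_h[[v]], config$min_coverage, variable = v),
                    period = "historical")
    }),
    lapply(names(aft_c), function(v) {
      dplyr::mutate(monthly_stats(aft_c[[v]], config$min_coverage, variable = v),
                    period = "contemporary")
    })
  ))
  seasonal <- stage("climatology", dplyr::bind_rows(
    dplyr::mutate(seasonal_stats(monthly[monthly$period == "historical", ],
                                 config$seasons), period = "historical"),
    dplyr::mutate(seasonal_stats(monthly[monthly$period == "contemporary", ],
                                 config$seasons), period = "contemporary")
  ))

  normals_t <- stage("normals", contemporary_normals(aft_c$t))
  normals_wct <- stage("normals", contemporary_normals(aft_c$wct))

  anom <- stage("compare", dplyr::bind_rows(
    anomalies(monthly[monthly$period == "historical" &
                        monthly$variable == "t", ], normals_t),
    anomalies(monthly[monthly$period == "historical" &
                        monthly$variable == "wct", ], normals_wct)
  ))
  envel <- stage("compare",
                 envelope_exceedance(aft_h$wct[!is.na(aft_h$wct$value), ],
                                     normals_wct, k = config$k))
  thresholds <- c(
    pct_days_wct_below_0_contemporary =
      percent_days_below(aft_c$wct, 0),
    pct_days_wct_below_0_historical =
      percent_days_below(aft_h$wct, 0)
  )

  report <- stage("report", build_report(
    config$out_dir, monthly = monthly, seasonal = seasonal, anomaly = anom,
    stimulus = stim_freq, envelope = envel, thresholds = thresholds,
    config = config[c("hours", "k", "min_coverage")], seed = config$seed
  ))

  invisible(list(
    historical = hist_series, contemporary = cont_series,
    std_historical = std_h, std_contemporary = std_c,
    bio_historical = bio_h, bio_contemporary = bio_c,
    stimuli = list(historical = stim_h, contemporary = stim_c,
                   frequencies = stim_freq),
    monthly = monthly, seasonal = seasonal,
    normals = list(t = normals_t, wct = normals_wct),
    anomalies = anom, envelope = envel, thresholds = thresholds,
    report = report
  ))
}
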