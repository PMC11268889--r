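#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline — the synthetic-night generator
#' settings, the Boolean classification thresholds, the event-analysis
#' windows and the input unit declaration — into one object that serializes
#' losslessly to YAML.
#'
#' @param night A [night_config()].
#' @param thresholds A [rule_thresholds()].
#' @param prehunt_max_gap Perch-to-strike gap filter for pre-hunt force, s.
#' @param speed_window Look-back window for pre-strike flight speed, s.
#' @param units Acceleration input units: `"g"` (logger native) or `"ms2"`.
#' @return A list of class `owl_pipeline_config`.
#' @export
pipeline_config <- function(night = night_config(),
                            thresholds = rule_thresholds(),
                            prehunt_max_gap = 90,
                            speed_window = 20,
                            units = c("g", "ms2")) {
  units <- match.arg(units)
  structure(list(night = night, thresholds = thresholds,
                 prehunt_max_gap = prehunt_max_gap,
                 speed_window = speed_window, units = units),
            class = c("owl_pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' The YAML round trip is lossless; unknown keys in a file are rejected with
#' an error naming them, so typos cannot silently fall back to defaults.
#'
#' @param config An [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   `owl_pipeline_config`.
#' @export
write_config <- function(config, path) {
  as_plain <- function(x) {
    if (is.list(x)) {
      lapply(unclass(x), as_plain)
    } else if (!is.null(names(x))) {
      as.list(x)  # keep names: YAML maps, not bare sequences
    } else {
      x
    }
  }
  yaml::write_yaml(as_plain(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys <- function(got, want, where) {
    extra <- setdiff(names(got), want)
    if (length(extra)) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
    }
  }
  top_defaults <- pipeline_config()
  check_keys(raw, names(top_defaults), "config")
  check_keys(raw$night, names(formals(night_config)), "night")
  check_keys(raw$thresholds, names(formals(rule_thresholds)), "thresholds")
  night_args <- raw$night
  if (!is.null(night_args$flight_speed_mean)) {
    night_args$flight_speed_mean <- unlist(night_args$flight_speed_mean)
  }
  if (!is.null(night_args$perch_type_mix)) {
    night_args$perch_type_mix <- unlist(night_args$perch_type_mix)
  }
  pipeline_config(
    night = do.call(night_config, night_args),
    thresholds = do.call(rule_thresholds, as.list(raw$thresholds)),
    prehunt_max_gap = raw$prehunt_max_gap %||% 90,
    speed_window = raw$speed_window %||% 20,
    units = raw$units %||% "g"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an accelerometer trace from CSV
#'
#' Expects columns `t` (epoch seconds or ISO-8601 timestamps) and `heave`,
#' `surge`, `sway`. Acceleration declared in m/s^2 is converted to g.
#' Non-monotone or duplicated timestamps and non-uniform sampling are
#' explicit errors.
#'
#' @param path CSV file path.
#' @param units `"g"` or `"ms2"`.
#' @return A validated trace tibble (`t`, `heave`, `surge`, `sway`).
#' @export
read_acceleration_csv <- function(path, units = c("g", "ms2")) {
  units <- match.arg(units)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("t", "timestamp"), names(df))[1]
  if (is.na(tcol) || !all(c("heave", "surge", "sway") %in% names(df))) {
    stop("acceleration CSV needs columns t/timestamp, heave, surge, sway: ",
         path)
  }
  t <- parse_time_column(df[[tcol]], path)
  if (anyDuplicated(t)) stop("duplicated timestamps in ", path)
  if (any(diff(t) <= 0)) stop("non-monotone timestamps in ", path)
  out <- tibble::tibble(t = t, heave = as.numeric(df$heave),
                        surge = as.numeric(df$surge),
                        sway = as.numeric(df$sway))
  if (units == "ms2") {
    out$heave <- out$heave / G0
    out$surge <- out$surge / G0
    out$sway <- out$sway / G0
  }
  validate_trace(out)
  out
}

parse_time_column <- function(x, path) {
  if (is.numeric(x)) return(as.numeric(x))
  tt <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(tt)) stop("unparseable timestamps in ", path)
  as.numeric(tt)
}

#' @rdname read_acceleration_csv
#' @param trace Trace tibble to write.
#' @export
write_acceleration_csv <- function(trace, path) {
  utils::write.csv(trace[, c("t", "heave", "surge", "sway")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write a 1 Hz GPS track CSV
#'
#' Columns `t` (s), `x`, `y` (planar meters; lon/lat inputs are expected to
#' be projected upstream with a declared local equirectangular projection).
#'
#' @param path CSV file path.
#' @return A track tibble.
#' @export
read_gps_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("t", "timestamp"), names(df))[1]
  if (is.na(tcol) || !all(c("x", "y") %in% names(df))) {
    stop("GPS CSV needs columns t/timestamp, x, y: ", path)
  }
  t <- parse_time_column(df[[tcol]], path)
  if (any(diff(t) <= 0)) stop("non-monotone timestamps in ", path)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("non-finite coordinates in ", path)
  }
  tibble::tibble(t = t, x = as.numeric(df$x), y = as.numeric(df$y))
}

#' @rdname read_gps_csv
#' @param track Track tibble to write.
#' @export
write_gps_csv <- function(track, path) {
  utils::write.csv(track[, c("t", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on one synthetic night
#'
#' Self-contained end-to-end run: generates a synthetic night (or reads the
#' trace/track/habitat from `paths`), derives signals, classifies behaviours,
#' builds landing and attempt tables with perch types, segments trips, scores
#' detection against the ground truth (synthetic mode), and computes the
#' descriptive summary table. All intermediate tables can be written to
#' `out_dir` as CSV together with a `results.json` carrying the headline
#' numbers, the seed and a hash of the configuration.
#'
#' @param config An [pipeline_config()].
#' @param meta An [owl_metadata()].
#' @param paths Optional named list `acc`, `gps`, `habitat` of input files;
#'   NULL runs in synthetic mode. A named file that does not exist is an
#'   error naming the path.
#' @param out_dir Optional output directory (created if needed).
#' @return A list: `schedule` (synthetic mode), `classified`, `landings`,
#'   `attempts`, `trips`, `score` (synthetic mode), `summary`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), meta = owl_metadata(),
                         paths = NULL, out_dir = NULL) {
  synthetic <- is.null(paths)
  if (synthetic) {
    night <- generate_night(config$night, meta)
    trace <- night$trace
    gps <- night$gps
    schedule <- night$schedule
    habitat <- generate_habitat_map(schedule, config$night)
  } else {
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    trace <- read_acceleration_csv(paths$acc, units = config$units)
    gps <- read_gps_csv(paths$gps)
    habitat <- if (!is.null(paths$habitat)) {
      read_habitat_geojson(paths$habitat)
    }
    schedule <- NULL
  }

  derived <- derive_signals(trace)
  classified <- classify_night(derived, gps, meta$nest_position,
                               config$thresholds)
  ev <- build_night_events(classified, gps, meta, habitat = habitat,
                           thresholds = config$thresholds,
                           prehunt_max_gap = config$prehunt_max_gap)
  score <- if (synthetic) score_events(classified$events, schedule)
  summary_tbl <- descriptive_tables(ev$attempts, ev$landings,
                                    trips = ev$trips, n_boot = 200,
                                    seed = config$night$seed)
  hash <- rlang::hash(rapply(unclass(config), identity, how = "replace"))

  out <- list(schedule = schedule, classified = classified,
              landings = ev$landings, attempts = ev$attempts,
              trips = ev$trips, score = score, summary = summary_tbl,
              config_hash = hash)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ev$landings, file.path(out_dir, "landings.csv"),
                     row.names = FALSE)
    utils::write.csv(ev$attempts, file.path(out_dir, "attempts.csv"),
                     row.names = FALSE)
    utils::write.csv(ev$trips, file.path(out_dir, "trips.csv"),
                     row.names = FALSE)
    utils::write.csv(classified$timeline, file.path(out_dir, "timeline.csv"),
                     row.names = FALSE)
    if (!is.null(schedule)) {
      utils::write.csv(schedule, file.path(out_dir, "schedule.csv"),
                       row.names = FALSE)
    }
    results <- list(
      config_hash = hash, seed = config$night$seed,
      n_landings = nrow(ev$landings), n_attempts = nrow(ev$attempts),
      n_trips = nrow(ev$trips),
      summary = summary_tbl
    )
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
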