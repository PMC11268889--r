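#' Detect take-offs
#'
#' A take-off is a switch from a standing to a horizontal posture — a pitch
#' drop of at least 10 degrees between consecutive seconds — together with a
#' high-amplitude VeDBA burst (> 1 g) from the wing flapping. Consecutive
#' candidate seconds (within `min_event_separation`) collapse into a single
#' event at the first second.
#'
#' @param features Per-second feature table from [summarize_per_second()].
#' @param thresholds A [rule_thresholds()].
#' @return Numeric vector of take-off event times (second start, s).
#' @export
detect_takeoffs <- function(features, thresholds = rule_thresholds()) {
  cand <- features$dpitch <= thresholds$takeoff_dpitch &
    features$vedba_max > thresholds$takeoff_vedba
  collapse_runs(features$sec[cand], thresholds$min_event_separation)
}

#' Detect travelling flight
#'
#' Travelling flight has smoothed VeDBA above 0.1 g (sustained wingbeat
#' motion) with body pitch below 30 degrees (horizontal posture).
#'
#' @inheritParams detect_takeoffs
#' @return Logical mask, one element per second of `features`.
#' @export
detect_travel <- function(features, thresholds = rule_thresholds()) {
  features$vedba_smooth_max > thresholds$travel_vedba_smoothed &
    features$pitch_mean < thresholds$travel_pitch_max
}

#' Detect landings terminating flights
#'
#' A landing is a change from low to high pitch (delta pitch > +10 degrees)
#' with a final acceleration spike (per-second max VeDBA > 1 g), occurring
#' while a flight is in progress (a take-off has been seen, or the preceding
#' seconds were travelling flight). Candidates within `min_event_separation`
#' of each other merge into one event. For each landing the raw vector-sum
#' peak is extracted in a +/-0.5 s window around the VeDBA spike, and the
#' duration of the preceding flight (landing second minus take-off second, or
#' minus the start of the contiguous travel run when no take-off was seen) is
#' attached for strategy categorization.
#'
#' @inheritParams detect_takeoffs
#' @param derived Per-sample derived signals from [derive_signals()].
#' @param travel Logical travel mask from [detect_travel()]; computed if NULL.
#' @param takeoffs Take-off times from [detect_takeoffs()]; computed if NULL.
#' @return Tibble with one row per landing: `sec`, `peak_g`, `dpitch`,
#'   `dvedba`, `flight_duration` (s).
#' @export
detect_landings <- function(features, derived, thresholds = rule_thresholds(),
                            travel = NULL, takeoffs = NULL) {
  if (is.null(travel)) travel <- detect_travel(features, thresholds)
  if (is.null(takeoffs)) takeoffs <- detect_takeoffs(features, thresholds)
  cand <- features$dpitch > thresholds$landing_dpitch &
    features$vedba_max > thresholds$landing_vedba
  cand_sec <- collapse_runs(features$sec[cand], thresholds$min_event_separation)

  is_takeoff <- features$sec %in% takeoffs
  in_flight <- FALSE
  flight_start <- NA_real_
  keep <- numeric(0)
  dur <- numeric(0)
  cand_set <- features$sec %in% cand_sec
  for (i in seq_len(nrow(features))) {
    s <- features$sec[i]
    if (cand_set[i] && in_flight) {
      keep <- c(keep, s)
      dur <- c(dur, s - flight_start)
      in_flight <- FALSE
      next
    }
    if (is_takeoff[i]) {
      if (!in_flight) flight_start <- s
      in_flight <- TRUE
    } else if (travel[i]) {
      if (!in_flight) flight_start <- s
      in_flight <- TRUE
    }
  }

  rate <- trace_rate(derived)
  t0 <- derived$t[1]
  n_samp <- nrow(derived)
  peak <- vapply(keep, function(s) {
    i0 <- as.integer(round((s - t0) * rate)) + 1L
    i1 <- min(i0 + rate - 1L, n_samp)
    if (i0 < 1L || i0 > n_samp) return(NA_real_)
    spike <- (i0:i1)[which.max(derived$vedba[i0:i1])]
    win <- max(1L, spike - rate %/% 2L):min(n_samp, spike + rate %/% 2L)
    max(derived$vecsum_raw[win])
  }, numeric(1))

  ix <- match(keep, features$sec)
  tibble::tibble(sec = keep, peak_g = peak,
                 dpitch = features$dpitch[ix], dvedba = features$dvedba[ix],
                 flight_duration = dur)
}

#' Classify a landing as perch or hunting strike
#'
#' A landing is a hunting strike when both the rate of pitch change exceeds
#' 6 degrees and the VeDBA amplitude jump exceeds 1.3 g — the impact with the
#' prey/ground is much harder than an ordinary touchdown. Any landing failing
#' either condition is a perching event (a flight termination without a
#' strike).
#'
#' @param landings Tibble from [detect_landings()] (needs `dpitch`, `dvedba`).
#' @param thresholds A [rule_thresholds()].
#' @return Character vector, `"strike"` or `"perch"`, one per landing.
#' @export
classify_landing_type <- function(landings, thresholds = rule_thresholds()) {
  ifelse(landings$dpitch > thresholds$strike_dpitch &
           landings$dvedba > thresholds$strike_dvedba, "strike", "perch")
}

#' Detect self-feeding bouts
#'
#' Self-feeding shows as multiple regular VeDBA peaks (one per swallowing
#' head movement), each between 0.2 and 0.9 g. Peaks are extracted as maximal
#' runs of VeDBA above `feed_peak_min` lasting at least three samples; a run
#' whose maximum reaches `feed_peak_max` is discarded (that amplitude belongs
#' to landings and flight). Peaks separated by at most `feed_max_gap` seconds
#' group into bouts; a bout is kept when it has at least `feed_min_peaks`
#' peaks and the coefficient of variation of its inter-peak intervals is at
#' most `feed_interval_cv` (the "regular" condition).
#'
#' @param derived Per-sample derived signals from [derive_signals()].
#' @param thresholds A [rule_thresholds()].
#' @param exclude_sec Seconds (start times) to exclude from the scan, e.g.
#'   flight, landing and nest-visit seconds.
#' @return Tibble of bouts: `t_start`, `t_end`, `n_peaks`.
#' @export
detect_self_feeding <- function(derived, thresholds = rule_thresholds(),
                                exclude_sec = numeric(0)) {
  v <- derived$vedba
  above <- v > thresholds$feed_peak_min
  if (length(exclude_sec)) {
    above[floor(derived$t) %in% floor(exclude_sec)] <- FALSE
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) {
    return(tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          n_peaks = integer(0)))
  }
  # cluster runs within a 0.5 s refractory gap into one swallowing peak;
  # isolated noise exceedances (< 3 samples in a cluster) are dropped
  run_t0 <- derived$t[starts[runs]]
  run_t1 <- derived$t[ends[runs]]
  cl_id <- cumsum(c(TRUE, run_t0[-1] - run_t1[-length(runs)] > 0.5))
  peak_t <- numeric(0)
  for (g in split(seq_along(runs), cl_id)) {
    seg <- unlist(lapply(runs[g], function(k) starts[k]:ends[k]))
    if (length(seg) < 3L) next
    m <- seg[which.max(v[seg])]
    if (v[m] < thresholds$feed_peak_max) peak_t <- c(peak_t, derived$t[m])
  }
  if (length(peak_t) < thresholds$feed_min_peaks) {
    return(tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          n_peaks = integer(0)))
  }
  peak_t <- sort(peak_t)
  grp <- cumsum(c(TRUE, diff(peak_t) > thresholds$feed_max_gap))
  bouts <- lapply(split(peak_t, grp), function(p) {
    if (length(p) < thresholds$feed_min_peaks) return(NULL)
    gaps <- diff(p)
    cv <- stats::sd(gaps) / mean(gaps)
    if (!is.finite(cv) || cv > thresholds$feed_interval_cv) return(NULL)
    tibble::tibble(t_start = p[1], t_end = p[length(p)],
                   n_peaks = length(p))
  })
  out <- dplyr::bind_rows(bouts)
  if (nrow(out) == 0) {
    out <- tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          n_peaks = integer(0))
  }
  out
}

#' Detect nest-box visits
#'
#' Entering the nest box is a rapid pitch drop (delta pitch < -1.5 degrees)
#' with a VeDBA increase (delta > 0.5 g) as the owl leaps in; leaving is the
#' activity stopping (delta VeDBA < -0.9 g) without a pitch rise (delta pitch
#' < 0.5 degrees). Both transients must occur within `nest_radius` m of the
#' nest position (the GPS check that replaces the study's manual validation).
#' Each entry is paired with the first subsequent exit; an entry with no exit
#' is returned as an open interval (`t_exit` NA) with a warning.
#'
#' Take-off and landing transients at the nest would also satisfy the
#' enter/exit conditions; following the label precedence (landing > takeoff >
#' nest), seconds already claimed by those events are excluded via
#' `exclude_sec`.
#'
#' @inheritParams detect_takeoffs
#' @param gps 1 Hz track (tibble `t`, `x`, `y`).
#' @param nest_position Numeric `c(x, y)` of the nest.
#' @param exclude_sec Seconds claimed by higher-precedence events (take-offs,
#'   landings).
#' @return Tibble of visits: `t_enter`, `t_exit`.
#' @export
detect_nest_visits <- function(features, gps, nest_position,
                               thresholds = rule_thresholds(),
                               exclude_sec = numeric(0)) {
  near <- near_nest_mask(features$sec, gps, nest_position,
                         thresholds$nest_radius)
  free <- !(features$sec %in% exclude_sec)
  enters <- features$sec[features$dpitch < thresholds$nest_enter_dpitch &
                           features$dvedba > thresholds$nest_enter_dvedba &
                           near & free]
  exits <- features$sec[features$dpitch < thresholds$nest_exit_dpitch &
                          features$dvedba < thresholds$nest_exit_dvedba &
                          near & free]
  enters <- collapse_runs(enters, thresholds$min_event_separation)
  if (!length(enters)) {
    return(tibble::tibble(t_enter = numeric(0), t_exit = numeric(0)))
  }
  t_exit <- vapply(enters, function(e) {
    nxt <- exits[exits > e]
    if (length(nxt)) nxt[1] else NA_real_
  }, numeric(1))
  # an exit belongs to the nearest preceding enter only
  for (i in seq_along(enters)[-1]) {
    if (!is.na(t_exit[i - 1]) && !is.na(t_exit[i]) &&
        t_exit[i - 1] >= enters[i]) {
      t_exit[i - 1] <- NA_real_
    }
  }
  if (anyNA(t_exit)) {
    warning("nest visit(s) with an entry but no matching exit (open interval)")
  }
  tibble::tibble(t_enter = enters, t_exit = t_exit)
}

# distance of the nearest-in-time GPS fix (within 1 s) to the nest
near_nest_mask <- function(secs, gps, nest_position, radius) {
  ix <- nearest_fix(secs, gps$t, max_gap = 1)
  d <- sqrt((gps$x[ix] - nest_position[1])^2 +
              (gps$y[ix] - nest_position[2])^2)
  !is.na(d) & d <= radius
}

# index of nearest gps time for each query time; NA beyond max_gap
nearest_fix <- function(times, gps_t, max_gap = 1) {
  ix <- findInterval(times, gps_t)
  ix0 <- pmax(ix, 1L)
  ix1 <- pmin(ix + 1L, length(gps_t))
  d0 <- abs(times - gps_t[ix0])
  d1 <- abs(times - gps_t[ix1])
  best <- ifelse(d1 < d0, ix1, ix0)
  gap <- pmin(d0, d1)
  best[gap > max_gap] <- NA_integer_
  best
}

# collapse candidate seconds separated by <= sep into one event (first second)
collapse_runs <- function(secs, sep = 1) {
  if (!length(secs)) return(numeric(0))
  secs <- sort(secs)
  secs[c(TRUE, diff(secs) > sep)]
}

#' Run the full behavioural classification of one night
#'
#' Applies the Boolean rule set to derived signals: take-offs, travelling
#' flight, landings with perch/strike subtypes and raw-acceleration peaks,
#' self-feeding bouts, and nest-box visits; assembles the one-second
#' behaviour timeline with label precedence landing > takeoff > travel >
#' feeding/nest > stationary, and links each second to the nearest GPS fix
#' within 1 s.
#'
#' @param derived Per-sample derived signals from [derive_signals()].
#' @param gps 1 Hz track (tibble `t`, `x`, `y`).
#' @param nest_position Numeric `c(x, y)` of the nest.
#' @param thresholds A [rule_thresholds()].
#' @return A list: `features` (per-second), `timeline` (tibble `sec`, `label`,
#'   `gps_x`, `gps_y`), `takeoffs`, `landings` (with `subtype`), `feeding`,
#'   `nest_visits`, and `events` (long table of detected events for scoring).
#' @export
classify_night <- function(derived, gps, nest_position,
                           thresholds = rule_thresholds()) {
  features <- summarize_per_second(derived)
  travel <- detect_travel(features, thresholds)
  takeoffs <- detect_takeoffs(features, thresholds)
  landings <- detect_landings(features, derived, thresholds,
                              travel = travel, takeoffs = takeoffs)
  landings$subtype <- classify_landing_type(landings, thresholds)
  nest_visits <- detect_nest_visits(features, gps, nest_position, thresholds,
                                    exclude_sec = c(takeoffs, landings$sec))

  flight_sec <- features$sec[travel]
  nest_sec <- unlist(lapply(seq_len(nrow(nest_visits)), function(i) {
    e <- nest_visits$t_enter[i]
    x <- nest_visits$t_exit[i]
    seq(e, if (is.na(x)) e else x)
  }))
  excl <- c(flight_sec, takeoffs, landings$sec, nest_sec)
  feeding <- detect_self_feeding(derived, thresholds, exclude_sec = excl)

  label <- rep("stationary", nrow(features))
  label[travel] <- "travel"
  for (i in seq_len(nrow(feeding))) {
    label[features$sec >= floor(feeding$t_start[i]) &
            features$sec <= floor(feeding$t_end[i])] <- "feeding"
  }
  if (length(nest_sec)) label[features$sec %in% nest_sec] <- "nest_visit"
  label[features$sec %in% takeoffs] <- "takeoff"
  label[features$sec %in% landings$sec] <- "landing"

  fix <- nearest_fix(features$sec, gps$t, max_gap = 1)
  timeline <- tibble::tibble(
    sec = features$sec, label = label,
    gps_x = ifelse(is.na(fix), NA_real_, gps$x[fix]),
    gps_y = ifelse(is.na(fix), NA_real_, gps$y[fix])
  )

  events <- dplyr::bind_rows(
    tibble::tibble(sec = takeoffs, label = "takeoff", subtype = NA_character_),
    tibble::tibble(sec = landings$sec, label = "landing",
                   subtype = landings$subtype),
    tibble::tibble(sec = feeding$t_start, label = "feeding",
                   subtype = NA_character_),
    tibble::tibble(sec = nest_visits$t_enter, label = "nest_enter",
                   subtype = NA_character_)
  )

  list(features = features, timeline = timeline, takeoffs = takeoffs,
       landings = landings, feeding = feeding, nest_visits = nest_visits,
       events = events)
}
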