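#' Landing force from peak acceleration and body mass
#'
#' The peak vertical ground-reaction force of a landing: the maximum raw
#' acceleration vector sum (in g) times body mass (kg) times standard gravity
#' (9.81 m/s^2), in Newtons.
#'
#' @param peak_g Peak raw vector-sum acceleration, g (>= 0).
#' @param body_mass Body mass, kg (> 0).
#' @return Force in Newtons.
#' @examples
#' compute_landing_force(1, 1)            # 9.81 N
#' compute_landing_force(12.92, 0.322)    # ~40.8 N, a typical female strike
#' @export
compute_landing_force <- function(peak_g, body_mass) {
  if (any(body_mass <= 0)) stop("body_mass must be positive")
  if (any(peak_g < 0, na.rm = TRUE)) stop("peak_g must be non-negative")
  peak_g * G0 * body_mass
}

#' Express a force as a multiple of body weight
#'
#' @param force_N Force in Newtons.
#' @param body_mass Body mass in kg (> 0).
#' @return Dimensionless body-weight multiple `force_N / (body_mass * 9.81)`.
#' @export
bodyweight_multiple <- function(force_N, body_mass) {
  if (any(body_mass <= 0)) stop("body_mass must be positive")
  force_N / (body_mass * G0)
}

#' Categorize the hunting strategy of a strike
#'
#' Sit-and-wait attacks are launched after at most 1 s of flight from the
#' perch; on-the-wing attacks follow at least 5 s of searching flight.
#' Strikes between the two bounds fit neither definition and are marked
#' `excluded` (they are reported, never silently dropped).
#'
#' @param preceding_flight_duration Flight time before the strike, s (>= 0).
#' @return Character: `"sit_and_wait"`, `"on_the_wing"`, or `"excluded"`.
#' @export
categorize_strategy <- function(preceding_flight_duration) {
  out <- rep("excluded", length(preceding_flight_duration))
  out[preceding_flight_duration <= 1] <- "sit_and_wait"
  out[preceding_flight_duration >= 5] <- "on_the_wing"
  out[is.na(preceding_flight_duration)] <- NA_character_
  out
}

#' Infer the outcome of each hunting strike
#'
#' A strike is successful when it is followed by a self-feeding bout (the owl
#' eats the prey on the spot) or by a direct return to the nest box (prey
#' provisioning) before the next landing sequence begins. "Direct return" is
#' operationalized as: no intervening strike or away-from-nest perch landing
#' between the strike and the nest entry; the touchdown on the nest box
#' itself (a landing within `nest_radius` of the nest) is part of the return
#' and does not break the chain.
#'
#' @param strikes Tibble of strikes with column `sec`.
#' @param landings Tibble of all landings: `sec`, `subtype`, and optionally
#'   `x`, `y` for the nest-distance check.
#' @param feeding Tibble of feeding bouts (`t_start`).
#' @param nest_visits Tibble of nest visits (`t_enter`).
#' @param nest_position Numeric `c(x, y)`; used with `nest_radius` to ignore
#'   landings at the nest. If landings carry no coordinates, no landing is
#'   treated as at-nest.
#' @param nest_radius Radius in m.
#' @return Logical vector of inferred success, one per strike.
#' @export
infer_outcome <- function(strikes, landings, feeding, nest_visits,
                          nest_position = c(0, 0), nest_radius = 30) {
  at_nest <- rep(FALSE, nrow(landings))
  if (all(c("x", "y") %in% names(landings))) {
    d <- sqrt((landings$x - nest_position[1])^2 +
                (landings$y - nest_position[2])^2)
    at_nest <- !is.na(d) & d <= nest_radius
  }
  blockers <- sort(c(landings$sec[!at_nest & landings$subtype == "perch"],
                     landings$sec[landings$subtype == "strike"]))
  rewards <- sort(c(feeding$t_start, nest_visits$t_enter))
  vapply(strikes$sec, function(s) {
    nb <- blockers[blockers > s]
    nr <- rewards[rewards > s]
    length(nr) > 0 && (length(nb) == 0 || nr[1] < nb[1])
  }, logical(1))
}

#' Pre-hunt perching context of a strike
#'
#' The force of the most recent perch landing before the strike, kept only
#' when the gap is below `max_gap` (90 s, the lower tercile of the observed
#' perch-to-strike gap distribution); otherwise the force is NA and only the
#' gap is reported.
#'
#' @param strike_sec Strike times (s).
#' @param perches Tibble of perch landings: `sec`, `force_N`.
#' @param max_gap Maximum perch-to-strike gap, s.
#' @return Tibble with `prehunt_perch_force_N` and `prehunt_gap` per strike.
#' @export
prehunt_context <- function(strike_sec, perches, max_gap = 90) {
  ord <- order(perches$sec)
  psec <- perches$sec[ord]
  pforce <- perches$force_N[ord]
  ix <- findInterval(strike_sec - 1e-9, psec)
  gap <- ifelse(ix >= 1, strike_sec - psec[pmax(ix, 1L)], NA_real_)
  force <- ifelse(!is.na(gap) & gap < max_gap, pforce[pmax(ix, 1L)], NA_real_)
  tibble::tibble(prehunt_perch_force_N = force, prehunt_gap = gap)
}

#' Median ground speed over the window before a strike
#'
#' Per-second step speeds from consecutive GPS fixes inside
#' `(strike_t - window, strike_t)`; their median is robust to single outlier
#' fixes. NULL-equivalent (NA) when fewer than two fixes fall in the window.
#'
#' @param track 1 Hz GPS track (tibble `t`, `x`, `y`).
#' @param strike_t Strike time, s.
#' @param window Look-back window, s.
#' @return Median ground speed in m/s, or NA.
#' @export
flight_speed_before_strike <- function(track, strike_t, window = 20) {
  sel <- track$t > strike_t - window & track$t < strike_t
  if (sum(sel) < 2) return(NA_real_)
  xs <- track$x[sel]; ys <- track$y[sel]; ts <- track$t[sel]
  v <- sqrt(diff(xs)^2 + diff(ys)^2) / diff(ts)
  stats::median(v)
}

#' Time from each perching event to the next hunting strike
#'
#' @param perch_sec Perch landing times (s), any order.
#' @param strike_sec Strike times (s), any order.
#' @return Seconds until the next strike per perch; NA when none follows.
#' @export
time_to_next_hunt <- function(perch_sec, strike_sec) {
  ss <- sort(strike_sec)
  ix <- findInterval(perch_sec, ss) + 1L  # first strike strictly after the perch
  ifelse(ix <= length(ss), ss[pmin(ix, length(ss))] - perch_sec, NA_real_)
}

#' Flag perch landings made while loaded with prey
#'
#' Perching events between a successful strike and the terminal event that
#' marks the prey consumed or delivered (the following feeding bout start or
#' nest entry) are made while carrying prey; the extra mass inflates the
#' landing force, so they are excluded from force analyses.
#'
#' @param perch_sec Perch landing times (s).
#' @param strikes Tibble with `sec` and logical `success`.
#' @param feeding Tibble of feeding bouts (`t_start`).
#' @param nest_visits Tibble of nest visits (`t_enter`).
#' @return Logical vector per perch landing.
#' @export
flag_loaded_with_prey <- function(perch_sec, strikes, feeding, nest_visits) {
  loaded <- rep(FALSE, length(perch_sec))
  terminals <- sort(c(feeding$t_start, nest_visits$t_enter))
  for (s in strikes$sec[strikes$success]) {
    term <- terminals[terminals > s]
    if (!length(term)) next
    loaded <- loaded | (perch_sec > s & perch_sec <= term[1])
  }
  loaded
}

#' Segment a night into foraging trips
#'
#' A foraging trip is a maximal interval during which the owl is farther than
#' `nest_radius` from its nest. Attempts falling inside each trip are counted
#' and the sit-and-wait frequency (sit-and-wait attempts over categorized
#' attempts) attached; a trip is `provisioned` when a nest entry follows its
#' end before the next trip starts.
#'
#' @param track 1 Hz GPS track (tibble `t`, `x`, `y`).
#' @param nest_position Numeric `c(x, y)`.
#' @param nest_radius Radius, m.
#' @param attempts Optional tibble of hunting attempts (`t`, `strategy`).
#' @param nest_visits Optional tibble of nest visits (`t_enter`).
#' @return Tibble of trips: `t_start`, `t_end`, `duration` (min),
#'   `n_attempts`, `sw_frequency`, `provisioned`.
#' @export
segment_trips <- function(track, nest_position, nest_radius = 30,
                          attempts = NULL, nest_visits = NULL) {
  away <- sqrt((track$x - nest_position[1])^2 +
                 (track$y - nest_position[2])^2) > nest_radius
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) {
    return(tibble::tibble(t_start = numeric(0), t_end = numeric(0),
                          duration = numeric(0), n_attempts = integer(0),
                          sw_frequency = numeric(0), provisioned = logical(0)))
  }
  t_start <- track$t[starts[keep]]
  t_end <- track$t[ends[keep]] + 1
  n_att <- integer(length(keep))
  swf <- rep(NA_real_, length(keep))
  prov <- rep(FALSE, length(keep))
  for (i in seq_along(keep)) {
    if (!is.null(attempts) && nrow(attempts)) {
      inside <- attempts$t >= t_start[i] & attempts$t < t_end[i]
      n_att[i] <- sum(inside)
      cat_in <- attempts$strategy[inside]
      cat_in <- cat_in[cat_in %in% c("sit_and_wait", "on_the_wing")]
      if (length(cat_in)) swf[i] <- mean(cat_in == "sit_and_wait")
    }
    if (!is.null(nest_visits) && nrow(nest_visits)) {
      nxt_trip <- if (i < length(keep)) t_start[i + 1] else Inf
      prov[i] <- any(nest_visits$t_enter >= t_end[i] &
                       nest_visits$t_enter < nxt_trip)
    }
  }
  tibble::tibble(t_start = t_start, t_end = t_end,
                 duration = (t_end - t_start) / 60,
                 n_attempts = n_att, sw_frequency = swf, provisioned = prov)
}

#' Build the analysis tables of one classified night
#'
#' Turns a night's classification into the two analysis units: landing events
#' (with forces, perch context and prey-load flags) and hunting attempts
#' (with strategy, inferred outcome, pre-hunt context and flight speed), plus
#' the foraging-trip segmentation.
#'
#' @param classified Output of [classify_night()].
#' @param gps 1 Hz GPS track.
#' @param meta An [owl_metadata()].
#' @param habitat Optional habitat map (see [generate_habitat_map()] /
#'   [read_habitat_geojson()]) for perch-type assignment.
#' @param thresholds A [rule_thresholds()] (for `nest_radius`).
#' @param prehunt_max_gap Perch-to-strike gap filter for the pre-hunt force, s.
#' @return A list of tibbles: `landings`, `attempts`, `trips`.
#' @export
build_night_events <- function(classified, gps, meta, habitat = NULL,
                               thresholds = rule_thresholds(),
                               prehunt_max_gap = 90) {
  L <- classified$landings
  takeoffs <- classified$takeoffs
  nest <- meta$nest_position

  fix <- nearest_fix(L$sec, gps$t, max_gap = 1)
  lx <- ifelse(is.na(fix), NA_real_, gps$x[fix])
  ly <- ifelse(is.na(fix), NA_real_, gps$y[fix])

  landings <- tibble::tibble(
    owl_id = meta$owl_id, sec = L$sec, subtype = L$subtype,
    peak_g = L$peak_g,
    force_N = compute_landing_force(L$peak_g, meta$body_mass),
    force_per_kg = compute_landing_force(L$peak_g, meta$body_mass) /
      meta$body_mass,
    flight_duration = L$flight_duration, x = lx, y = ly
  )

  perch <- landings[landings$subtype == "perch", ]
  strike <- landings[landings$subtype == "strike", ]

  landings$perch_type <- "unknown"
  if (!is.null(habitat) && nrow(perch)) {
    pt <- vapply(seq_len(nrow(perch)), function(i) {
      loc <- median_location(perch$sec[i], takeoffs, gps)
      if (anyNA(loc)) return("unknown")
      assign_perch_type(loc, habitat)
    }, character(1))
    landings$perch_type[landings$subtype == "perch"] <- pt
  }

  landings$time_to_next_hunt <- NA_real_
  if (nrow(perch)) {
    landings$time_to_next_hunt[landings$subtype == "perch"] <-
      time_to_next_hunt(perch$sec, strike$sec)
  }

  strikes_tbl <- tibble::tibble(sec = strike$sec)
  success <- if (nrow(strike)) {
    infer_outcome(strikes_tbl, landings, classified$feeding,
                  classified$nest_visits, nest, thresholds$nest_radius)
  } else logical(0)

  landings$loaded_with_prey <- FALSE
  if (nrow(perch) && nrow(strike)) {
    landings$loaded_with_prey[landings$subtype == "perch"] <-
      flag_loaded_with_prey(perch$sec,
                            tibble::tibble(sec = strike$sec, success = success),
                            classified$feeding, classified$nest_visits)
  }

  ph <- prehunt_context(strike$sec, perch[, c("sec", "force_N")],
                        max_gap = prehunt_max_gap)
  speed <- vapply(strike$sec, flight_speed_before_strike, numeric(1),
                  track = gps)
  strategy <- categorize_strategy(strike$flight_duration)
  attempts <- tibble::tibble(
    owl_id = meta$owl_id, sex = meta$sex, t = strike$sec,
    strategy = strategy, success = success,
    strike_force_N = compute_landing_force(strike$peak_g, meta$body_mass),
    preceding_flight_duration = strike$flight_duration,
    flight_speed = ifelse(strategy == "on_the_wing", speed, NA_real_),
    prehunt_perch_force_N = ph$prehunt_perch_force_N,
    prehunt_gap = ph$prehunt_gap
  )

  trips <- segment_trips(gps, nest, thresholds$nest_radius,
                         attempts = attempts,
                         nest_visits = classified$nest_visits)
  list(landings = landings, attempts = attempts, trips = trips)
}
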