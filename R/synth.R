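#' Generate a ground-truthed synthetic owl night
#'
#' Simulates one night of barn-owl foraging as the joint output of a 50 Hz
#' tri-axial accelerometer, a 1 Hz GPS, and the ground-truth event schedule
#' the signals were built from. The night is a sequence of foraging trips;
#' each trip leaves the nest, alternates perch landings, waits and hunting
#' strikes (sit-and-wait pounces or on-the-wing attacks), and returns to the
#' nest, entering the nest box when the final strike provisions prey.
#'
#' Every behaviour carries the accelerometer signature the Boolean classifier
#' keys on: travelling flight is a wingbeat oscillation at `wingbeat_freq`
#' with low pitch; take-off is a posture drop with a flapping burst; a landing
#' is a posture rise plus a 0.1 s acceleration pulse whose raw vector-sum peak
#' equals the scheduled `injected_peak` (about `strike_peak_bw` g for strikes,
#' `perch_peak_bw` g for perch landings, before sensor noise); self-feeding is
#' a regular train of moderate VeDBA peaks; a nest visit is an enter/exit pair
#' of pitch-and-VeDBA transients bracketing sway activity inside the box.
#' Sit-and-wait success odds are modulated by the pre-hunt perch force at
#' `or_per_newton` per Newton, so the success model downstream has a known
#' generating truth.
#'
#' @param config A [night_config()].
#' @param meta An [owl_metadata()].
#' @return A list with elements `trace` (tibble `t`, `heave`, `surge`, `sway`;
#'   g), `gps` (tibble `t`, `x`, `y`; m, 1 Hz), and `schedule` (tibble of
#'   non-overlapping events: `t_start`, `t_end`, `label`, `outcome`,
#'   `perch_type`, `injected_peak`, `x`, `y`, `trip`).
#' @export
generate_night <- function(config = night_config(), meta = owl_metadata()) {
  validate_night_config(config)
  with_preserved_seed(config$seed, {
    schedule <- build_schedule(config, meta)
    trace <- synthesize_trace(schedule, config)
    gps <- synthesize_gps(schedule, config)
    list(trace = trace, gps = gps, schedule = schedule)
  })
}

#' Generate only the ground-truth schedule of a synthetic night
#'
#' The event schedule of [generate_night()] without synthesizing the 50 Hz
#' signals — useful when only the injected ground truth is needed (e.g. for
#' calibration checks over many nights). Uses the same RNG stream, so the
#' schedule equals the one `generate_night` returns for the same config.
#'
#' @inheritParams generate_night
#' @return The schedule tibble (see [generate_night()]).
#' @export
generate_schedule <- function(config = night_config(), meta = owl_metadata()) {
  validate_night_config(config)
  with_preserved_seed(config$seed, build_schedule(config, meta))
}

# run expr under a given seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# log-normal draws with a prescribed arithmetic mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# ---------------------------------------------------------------------------
# schedule construction

build_schedule <- function(cfg, meta) {
  dur <- cfg$night_duration
  speed <- unname(cfg$flight_speed_mean[[meta$sex]])
  nest <- meta$nest_position
  mass <- meta$body_mass
  ref_force <- cfg$perch_peak_bw * mass * G0  # expected perch force, N

  rows <- vector("list", 512L)
  n_rows <- 0L
  t <- 0
  pos <- nest

  add <- function(label, duration, outcome = NA_character_,
                  perch_type = NA_character_, injected_peak = NA_real_,
                  end_pos = pos, trip = 0L) {
    duration <- max(1L, as.integer(round(duration)))
    if (t + duration > dur) {
      stop("synthetic schedule does not fit in night_duration (", dur,
           " s); reduce n_trips/strike_rate or lengthen the night",
           call. = FALSE)
    }
    n_rows <<- n_rows + 1L
    if (n_rows > length(rows)) length(rows) <<- 2L * n_rows
    rows[[n_rows]] <<- list(t_start = t, t_end = t + duration, label = label,
                            outcome = outcome, perch_type = perch_type,
                            injected_peak = injected_peak,
                            x = end_pos[1], y = end_pos[2], trip = trip)
    t <<- t + duration
    pos <<- end_pos
    invisible(NULL)
  }

  draw_perch_type <- function() {
    sample(names(cfg$perch_type_mix), 1L, prob = cfg$perch_type_mix)
  }
  perch_peak <- function() rlnorm_mean_cv(1L, cfg$perch_peak_bw, cfg$perch_peak_cv)
  strike_peak <- function() rlnorm_mean_cv(1L, cfg$strike_peak_bw, cfg$strike_peak_cv)

  # pick a travel heading that keeps the owl away from the nest mid-trip
  travel_leg <- function(duration) {
    for (i in 1:25) {
      theta <- stats::runif(1, 0, 2 * pi)
      cand <- pos + speed * duration * c(cos(theta), sin(theta))
      if (sqrt(sum((cand - nest)^2)) > 2 * cfg$nest_radius) return(cand)
    }
    away <- pos - nest
    away <- away / max(sqrt(sum(away^2)), 1e-9)
    pos + speed * duration * away
  }

  wait_time <- function() {
    min(max(stats::rlnorm(1, cfg$perch_wait_meanlog, cfg$perch_wait_sdlog), 5), 600)
  }

  if (cfg$n_trips == 0) {
    add("stationary", dur)
  } else {
    # the structure under the nest box is one fixed feature all night
    nest_type <- draw_perch_type()
    for (k in seq_len(cfg$n_trips)) {
      add("stationary", stats::runif(1, 60, 180), trip = 0L)

      # outbound leg
      t_out <- round(stats::runif(1, 60, 150))
      theta <- stats::runif(1, 0, 2 * pi)
      out_pos <- nest + speed * t_out * c(cos(theta), sin(theta))
      add("takeoff", 1, trip = k)
      add("travel", t_out, end_pos = out_pos, trip = k)
      add("landing_perch", 1, perch_type = draw_perch_type(),
          injected_peak = perch_peak(), trip = k)
      last_perch_peak <- rows[[n_rows]]$injected_peak

      n_att <- max(1L, stats::rpois(1L, cfg$strike_rate))
      for (j in seq_len(n_att)) {
        add("stationary", wait_time(), trip = k)

        sw <- stats::runif(1) < cfg$p_sitandwait
        if (sw) {
          hop <- stats::runif(1, 0, 2 * pi)
          strike_pos <- pos + speed * c(cos(hop), sin(hop))
          add("takeoff", 1, trip = k)
        } else {
          t_fly <- round(stats::runif(1, 25, 60))
          strike_pos <- travel_leg(t_fly)
          add("takeoff", 1, trip = k)
          add("travel", t_fly, end_pos = strike_pos, trip = k)
        }

        strategy <- if (sw) "sit_and_wait" else "on_the_wing"
        p <- cfg$success_prob[[meta$sex]][[strategy]]
        if (sw) {
          force_n <- last_perch_peak * mass * G0
          p <- stats::plogis(stats::qlogis(p) +
                               log(cfg$or_per_newton) * (force_n - ref_force))
        }
        success <- stats::runif(1) < p
        add("landing_strike", 1, outcome = if (success) "success" else "fail",
            injected_peak = strike_peak(), end_pos = strike_pos, trip = k)

        last_attempt <- j == n_att
        if (success && !last_attempt) {
          add("stationary", stats::runif(1, 5, 12), trip = k)
          n_peaks <- sample(5:15, 1L)
          gap <- round(stats::runif(1, 1, 2) * 50) / 50
          add("feeding", ceiling(n_peaks * gap) + 1, trip = k)
        }
        add("stationary", stats::runif(1, 5, 15), trip = k)

        if (!last_attempt) {
          t_leg <- round(stats::runif(1, 10, 30))
          add("takeoff", 1, trip = k)
          add("travel", t_leg, end_pos = travel_leg(t_leg), trip = k)
          add("landing_perch", 1, perch_type = draw_perch_type(),
              injected_peak = perch_peak(), trip = k)
          last_perch_peak <- rows[[n_rows]]$injected_peak
        }
      }

      # return to the nest; provision if the trip's final strike succeeded
      provisioned <- identical(rows[[n_rows - 1L]]$label, "landing_strike") &&
        identical(rows[[n_rows - 1L]]$outcome, "success")
      dist_home <- sqrt(sum((pos - nest)^2))
      add("takeoff", 1, trip = k)
      add("travel", max(2, round(dist_home / speed)), end_pos = nest, trip = k)
      add("landing_perch", 1, perch_type = nest_type,
          injected_peak = perch_peak(), trip = k)
      if (provisioned) {
        add("stationary", 3)
        add("nest_enter", round(stats::runif(1, 10, 25)))
        add("nest_exit", 1)
        add("stationary", 2)
      }
    }
    if (t < dur) add("stationary", dur - t)
  }

  sched <- dplyr::bind_rows(lapply(rows[seq_len(n_rows)], tibble::as_tibble))
  stopifnot(all(sched$t_start[-1] == sched$t_end[-nrow(sched)]))
  sched
}

# ---------------------------------------------------------------------------
# 50 Hz accelerometer synthesis

PITCH_STAND <- 55   # standing posture, degrees
PITCH_FLIGHT <- 10  # horizontal travelling posture, degrees
PITCH_NEST <- 49    # crouched posture inside the nest box, degrees
SPIKE_DIR <- c(0.85, 0.4, 0.35) / sqrt(sum(c(0.85, 0.4, 0.35)^2))
TAKEOFF_BURST_AMP <- 1.6  # flapping-burst amplitude at take-off, g

synthesize_trace <- function(schedule, cfg) {
  rate <- 50L
  n <- as.integer(cfg$night_duration * rate)
  tt <- (seq_len(n) - 1L) / rate

  idx_of <- function(time) pmin(pmax(as.integer(round(time * rate)) + 1L, 1L), n)
  span <- function(from, to) {
    i0 <- idx_of(from); i1 <- idx_of(to) - 1L
    if (i1 < i0) integer(0) else i0:i1
  }

  pitch <- rep(PITCH_STAND, n)
  dyn_h <- numeric(n); dyn_s <- numeric(n); dyn_w <- numeric(n)

  lab <- schedule$label
  takeoff_rows <- which(lab == "takeoff")
  landing_rows <- which(lab %in% c("landing_perch", "landing_strike"))

  # flight spans: take-off transient to touchdown posture switch
  for (i in takeoff_rows) {
    j <- landing_rows[landing_rows > i][1]
    if (is.na(j)) next
    from <- schedule$t_start[i] + 0.2
    to <- schedule$t_start[j] + 0.3
    ix <- span(from, to)
    pitch[ix] <- PITCH_FLIGHT
    env <- rep(cfg$wingbeat_amp, length(ix))
    env[tt[ix] < schedule$t_end[i]] <- TAKEOFF_BURST_AMP
    ph <- 2 * pi * cfg$wingbeat_freq * tt[ix]
    dyn_h[ix] <- dyn_h[ix] + env * sin(ph)
    dyn_s[ix] <- dyn_s[ix] + 0.25 * env * sin(ph + 1)
    dyn_w[ix] <- dyn_w[ix] + 0.15 * env * cos(ph)
  }

  # landing pulses: 0.1 s half-cosine, raw vector-sum peak = injected_peak
  stand_static <- c(sin(PITCH_STAND * pi / 180), cos(PITCH_STAND * pi / 180), 0)
  su <- sum(stand_static * SPIKE_DIR)
  for (i in landing_rows) {
    centre <- schedule$t_start[i] + 0.5
    peak <- schedule$injected_peak[i]
    amp <- -su + sqrt(su^2 + peak^2 - 1)  # |static + amp * u| = peak
    ix <- span(centre - 0.05, centre + 0.05 + 1e-9)
    pulse <- amp * cos(pi * (tt[ix] - centre) / 0.1)
    pulse[pulse < 0] <- 0
    dyn_h[ix] <- dyn_h[ix] + pulse * SPIKE_DIR[1]
    dyn_s[ix] <- dyn_s[ix] + pulse * SPIKE_DIR[2]
    dyn_w[ix] <- dyn_w[ix] + pulse * SPIKE_DIR[3]
  }

  # self-feeding: regular train of 0.2 s swallowing pulses in surge + heave
  feed_dir <- c(0.7, 0.7, 0.14) / sqrt(sum(c(0.7, 0.7, 0.14)^2))
  for (i in which(lab == "feeding")) {
    t0 <- schedule$t_start[i]
    t1 <- schedule$t_end[i]
    gap <- round(stats::runif(1, 1, 2) * 50) / 50
    centres <- seq(t0 + 0.5, t1 - 0.5, by = gap)
    amps <- stats::runif(length(centres), 0.45, 0.75)
    for (k in seq_along(centres)) {
      ix <- span(centres[k] - 0.1, centres[k] + 0.1 + 1e-9)
      pulse <- amps[k] * cos(pi * (tt[ix] - centres[k]) / 0.2)
      pulse[pulse < 0] <- 0
      dyn_h[ix] <- dyn_h[ix] + pulse * feed_dir[1]
      dyn_s[ix] <- dyn_s[ix] + pulse * feed_dir[2]
      dyn_w[ix] <- dyn_w[ix] + pulse * feed_dir[3]
    }
  }

  # nest visits: crouch + sway activity from entry until the exit second
  enter_rows <- which(lab == "nest_enter")
  exit_rows <- which(lab == "nest_exit")
  for (k in seq_along(enter_rows)) {
    i <- enter_rows[k]
    j <- exit_rows[exit_rows > i][1]
    t_in <- schedule$t_start[i] + 0.3
    t_quiet <- if (is.na(j)) schedule$t_end[i] else schedule$t_start[j]
    t_restore <- (if (is.na(j)) schedule$t_end[i] else schedule$t_end[j]) + 1
    pitch[span(t_in, t_quiet)] <- PITCH_NEST
    # crouch at the hole while hopping out: exit second must not read as a
    # pitch rise
    pitch[span(t_quiet, min(t_restore, cfg$night_duration))] <- PITCH_NEST - 2
    ix <- span(t_in, t_quiet)
    # 4 Hz so the 0.5 s static window spans whole cycles and pitch stays flat
    ph <- 2 * pi * 4 * tt[ix]
    dyn_w[ix] <- dyn_w[ix] + 1.3 * sin(ph)
    dyn_h[ix] <- dyn_h[ix] + 0.15 * sin(ph + 0.8)
  }

  pr <- pitch * pi / 180
  heave <- sin(pr) + dyn_h + stats::rnorm(n, 0, cfg$noise_sd)
  surge <- cos(pr) + dyn_s + stats::rnorm(n, 0, cfg$noise_sd)
  sway <- dyn_w + stats::rnorm(n, 0, cfg$noise_sd)
  tibble::tibble(t = tt, heave = heave, surge = surge, sway = sway)
}

# ---------------------------------------------------------------------------
# 1 Hz GPS synthesis: piecewise-linear kinematics consistent with the schedule

synthesize_gps <- function(schedule, cfg) {
  dur <- as.integer(cfg$night_duration)
  x <- numeric(dur); y <- numeric(dur)
  prev <- c(schedule$x[1], schedule$y[1])
  for (i in seq_len(nrow(schedule))) {
    s0 <- as.integer(schedule$t_start[i]) + 1L
    s1 <- as.integer(schedule$t_end[i])
    if (s1 < s0) next
    end <- c(schedule$x[i], schedule$y[i])
    if (schedule$label[i] == "travel") {
      f <- seq_len(s1 - s0 + 1L) / (s1 - s0 + 1L)
      x[s0:s1] <- prev[1] + f * (end[1] - prev[1])
      y[s0:s1] <- prev[2] + f * (end[2] - prev[2])
    } else {
      x[s0:s1] <- end[1]
      y[s0:s1] <- end[2]
    }
    prev <- end
  }
  tibble::tibble(
    t = as.numeric(seq_len(dur) - 1L),
    x = x + stats::rnorm(dur, 0, cfg$gps_jitter_sd),
    y = y + stats::rnorm(dur, 0, cfg$gps_jitter_sd)
  )
}

#' Build a habitat map consistent with a synthetic night
#'
#' Places one habitat feature at every distinct perch location of the night's
#' ground-truth schedule, typed as the schedule's perch type, so that every
#' synthetic perch has exactly one feature within 2 m by construction. Poles
#' and trees are point features; buildings are 6 m by 6 m square polygons
#' centred on the perch.
#'
#' @param schedule Ground-truth schedule from [generate_night()].
#' @param config The [night_config()] used (for the RNG seed offset).
#' @return A tibble of features: `id`, `perch_type`, `geom_type`
#'   (`point`/`polygon`), and a `coords` list-column of n x 2 matrices.
#' @export
generate_habitat_map <- function(schedule, config = night_config()) {
  perches <- schedule[schedule$label == "landing_perch", , drop = FALSE]
  if (nrow(perches) == 0) {
    return(tibble::tibble(id = integer(), perch_type = character(),
                          geom_type = character(), coords = list()))
  }
  key <- paste(round(perches$x, 1), round(perches$y, 1))
  keep <- !duplicated(key)
  px <- perches$x[keep]; py <- perches$y[keep]
  type <- perches$perch_type[keep]
  coords <- vector("list", length(px))
  geom <- ifelse(type == "building", "polygon", "point")
  for (i in seq_along(px)) {
    coords[[i]] <- if (geom[i] == "polygon") {
      cbind(px[i] + c(-3, 3, 3, -3, -3), py[i] + c(-3, -3, 3, 3, -3))
    } else {
      matrix(c(px[i], py[i]), ncol = 2)
    }
  }
  tibble::tibble(id = seq_along(px), perch_type = type, geom_type = geom,
                 coords = coords)
}

#' Simulate hunting attempts with a known success model
#'
#' Draws hunting attempts directly at the analysis level (no signal
#' synthesis): pre-hunt perch forces are Gaussian, and success is Bernoulli
#' with log-odds shifted by `log(or_per_newton)` per Newton around
#' `force_mean` for sit-and-wait attempts; on-the-wing success is
#' force-independent. Used to verify that the success model recovers its
#' generating odds ratio.
#'
#' @param n Number of attempts.
#' @param p_sitandwait Probability an attempt is sit-and-wait.
#' @param success_prob Baseline success probabilities as in [night_config()].
#' @param or_per_newton Generating odds ratio per Newton (sit-and-wait only).
#' @param force_mean,force_sd Pre-hunt perch force distribution, N.
#' @param sexes Sexes to draw from (uniformly).
#' @param n_owls Number of owl identifiers to spread attempts over.
#' @param seed Optional seed.
#' @return Tibble with `owl_id`, `sex`, `strategy`, `prehunt_perch_force_N`,
#'   `success`.
#' @export
simulate_hunt_attempts <- function(n,
                                   p_sitandwait = 0.5,
                                   success_prob = night_config()$success_prob,
                                   or_per_newton = 0.85,
                                   force_mean = 8.8, force_sd = 2,
                                   sexes = c("F", "M"),
                                   n_owls = 10, seed = NULL) {
  draw <- function() {
    sex <- sample(sexes, n, replace = TRUE)
    strategy <- ifelse(stats::runif(n) < p_sitandwait, "sit_and_wait",
                       "on_the_wing")
    force <- stats::rnorm(n, force_mean, force_sd)
    base <- mapply(function(s, st) success_prob[[s]][[st]], sex, strategy)
    eta <- stats::qlogis(base) +
      ifelse(strategy == "sit_and_wait",
             log(or_per_newton) * (force - force_mean), 0)
    tibble::tibble(
      owl_id = paste0("owl", (seq_len(n) - 1L) %% n_owls + 1L),
      sex = sex, strategy = strategy,
      prehunt_perch_force_N = force,
      success = stats::runif(n) < stats::plogis(eta)
    )
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

#' Score detected events against a ground-truth schedule
#'
#' Matches detected event times to scheduled events of the same kind within a
#' time tolerance (greedy nearest-time, one-to-one) and reports recall and
#' precision per event kind, plus the landing-subtype confusion rate among
#' matched landings.
#'
#' @param events Detected events: tibble with columns `sec` and `label`
#'   (labels `takeoff`, `landing`, `feeding`, `nest_enter`; landings may carry
#'   a `subtype` of `perch`/`strike`).
#' @param schedule Ground-truth schedule from [generate_night()].
#' @param tol Matching tolerance in seconds.
#' @return A list: `summary` (tibble of kind, n_true, n_detected, n_matched,
#'   recall, precision) and `subtype_confusion` (fraction of matched landings
#'   whose perch/strike subtype disagrees with the schedule; NA if no matched
#'   landings carry a subtype).
#' @export
score_events <- function(events, schedule, tol = 1) {
  true_of <- function(labels) schedule$t_start[schedule$label %in% labels]
  match_times <- function(det, truth) {
    used <- rep(FALSE, length(truth))
    hit <- integer(0)
    for (d in sort(det)) {
      cand <- which(!used & abs(truth - d) <= tol)
      if (length(cand)) {
        pick <- cand[which.min(abs(truth[cand] - d))]
        used[pick] <- TRUE
        hit <- c(hit, pick)
      }
    }
    hit
  }
  kinds <- list(
    takeoff = list(det = "takeoff", true = "takeoff"),
    landing = list(det = "landing", true = c("landing_perch", "landing_strike")),
    feeding = list(det = "feeding", true = "feeding"),
    nest_enter = list(det = "nest_enter", true = "nest_enter")
  )
  out <- lapply(names(kinds), function(k) {
    det <- events$sec[events$label == kinds[[k]]$det]
    truth <- true_of(kinds[[k]]$true)
    m <- match_times(det, truth)
    tibble::tibble(kind = k, n_true = length(truth), n_detected = length(det),
                   n_matched = length(m),
                   recall = if (length(truth)) length(m) / length(truth) else NA_real_,
                   precision = if (length(det)) length(m) / length(det) else NA_real_)
  })

  confusion <- NA_real_
  det_land <- events[events$label == "landing", , drop = FALSE]
  if (nrow(det_land) > 0 && "subtype" %in% names(det_land)) {
    truth <- schedule[schedule$label %in% c("landing_perch", "landing_strike"), ]
    n_match <- 0L; n_wrong <- 0L
    used <- rep(FALSE, nrow(truth))
    for (i in order(det_land$sec)) {
      cand <- which(!used & abs(truth$t_start - det_land$sec[i]) <= tol)
      if (length(cand)) {
        pick <- cand[which.min(abs(truth$t_start[cand] - det_land$sec[i]))]
        used[pick] <- TRUE
        n_match <- n_match + 1L
        want <- if (truth$label[pick] == "landing_strike") "strike" else "perch"
        if (!identical(det_land$subtype[i], want)) n_wrong <- n_wrong + 1L
      }
    }
    if (n_match > 0) confusion <- n_wrong / n_match
  }
  list(summary = dplyr::bind_rows(out), subtype_confusion = confusion)
}
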