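th <- rule_thresholds()

# minimal feature-table builder for rule-level tests
feat <- function(pitch, vedba, vsm = NULL, vecsum = NULL) {
  n <- length(pitch)
  tibble::tibble(
    sec = as.numeric(seq_len(n) - 1),
    pitch_mean = pitch, vedba_max = vedba,
    vedba_smooth_max = if (is.null(vsm)) vedba * 0.6 else vsm,
    vecsum_max = if (is.null(vecsum)) vedba + 1 else vecsum,
    dpitch = c(0, diff(pitch)), dvedba = c(0, diff(vedba))
  )
}

test_that("take-off needs both the pitch drop and the VeDBA burst", {
  # constant standing posture: nothing
  expect_length(detect_takeoffs(feat(rep(55, 10), rep(0.05, 10)), th), 0)
  # pitch drop without a burst is not a take-off
  f <- feat(c(55, 55, 40, 10, 10), c(0.05, 0.05, 0.05, 0.05, 0.05))
  expect_length(detect_takeoffs(f, th), 0)
  # burst without pitch drop is not a take-off
  f2 <- feat(rep(55, 5), c(0.05, 0.05, 1.5, 0.05, 0.05))
  expect_length(detect_takeoffs(f2, th), 0)
  # both together fire once
  f3 <- feat(c(55, 55, 30, 10, 10), c(0.05, 0.05, 1.5, 0.6, 0.6))
  expect_equal(detect_takeoffs(f3, th), 2)
})

test_that("travel mask applies the smoothed-VeDBA and pitch thresholds", {
  f <- feat(pitch = c(10, 10, 45, 10), vedba = c(1, 1, 1, 1),
            vsm = c(0.05, 0.5, 0.5, 0.11))
  expect_equal(detect_travel(f, th), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("landing subtype follows the strike thresholds", {
  l <- tibble::tibble(dpitch = c(8, 12, 12, 5), dvedba = c(2.0, 1.0, 2.0, 2.0))
  expect_equal(classify_landing_type(l, th),
               c("strike", "perch", "strike", "perch"))
})

test_that("spikes without a flight to terminate are not landings", {
  fx <- quick_night(seed = 21, duration = 400, n_trips = 0)
  tr <- fx$night$trace
  # inject a hard spike into an all-stationary trace
  ix <- which(abs(tr$t - 200.5) <= 0.05)
  tr$heave[ix] <- tr$heave[ix] + 6 * cos(pi * (tr$t[ix] - 200.5) / 0.1)
  d <- derive_signals(tr)
  f <- summarize_per_second(d)
  expect_equal(nrow(detect_landings(f, d, th)), 0)
})

test_that("candidate seconds within the separation window merge", {
  # two candidate seconds back to back -> one event at the first second
  pitch <- c(10, 10, 10, 25, 40, 55, 55)
  vedba <- c(0.6, 0.6, 0.6, 2.0, 2.0, 0.05, 0.05)
  f <- feat(pitch, vedba, vsm = c(0.5, 0.5, 0.5, 0.5, 0.3, 0.02, 0.02))
  d <- derive_signals(constant_trace(7))  # peaks unused: just needs alignment
  out <- detect_landings(f, d, th)
  expect_equal(nrow(out), 1)
  expect_equal(out$sec, 3)
})

test_that("landings and strikes are recovered near-perfectly on synthetic nights", {
  tot <- c(true = 0, det = 0, match = 0)
  wrong <- 0; matched <- 0
  for (seed in c(101, 102, 103)) {
    fx <- classified_night(seed = seed, duration = 9000, n_trips = 3,
                           strike_rate = 5, sex = if (seed %% 2) "F" else "M")
    sc <- score_events(fx$classified$events, fx$night$schedule)
    s <- sc$summary[sc$summary$kind == "landing", ]
    tot <- tot + c(s$n_true, s$n_detected, s$n_matched)
    if (!is.na(sc$subtype_confusion)) {
      wrong <- wrong + sc$subtype_confusion * s$n_matched
      matched <- matched + s$n_matched
    }
  }
  expect_gte(tot[["match"]] / tot[["true"]], 0.95)  # recall
  expect_gte(tot[["match"]] / tot[["det"]], 0.95)   # precision
  expect_lte(wrong / matched, 0.05)                 # subtype confusion
})

test_that("every scheduled take-off is matched within one second", {
  fx <- classified_night(seed = 104, duration = 9000, n_trips = 3,
                         strike_rate = 5)
  sc <- score_events(fx$classified$events, fx$night$schedule)
  s <- sc$summary[sc$summary$kind == "takeoff", ]
  expect_equal(s$n_matched, s$n_true)
  expect_equal(s$n_detected, s$n_true)
})

test_that("self-feeding bouts require count, amplitude window and regularity", {
  # 5 pulses of ~0.4 g VeDBA at 1.5 s spacing -> one bout
  d <- derive_signals(pulse_train_trace(5, amplitude = 0.5, spacing = 1.5))
  bouts <- detect_self_feeding(d, th)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$n_peaks, 5)

  # pulses above the 0.9 g ceiling are not feeding
  d2 <- derive_signals(pulse_train_trace(5, amplitude = 1.4, spacing = 1.5))
  expect_equal(nrow(detect_self_feeding(d2, th)), 0)

  # two pulses are below the minimum count
  d3 <- derive_signals(pulse_train_trace(2, amplitude = 0.5, spacing = 1.5))
  expect_equal(nrow(detect_self_feeding(d3, th)), 0)

  # irregular spacing (CV > 0.5) is rejected
  tr <- constant_trace(30)
  centres <- c(3, 3.8, 10, 11, 19)
  for (c0 in centres) {
    ix <- which(abs(tr$t - c0) <= 0.1)
    tr$surge[ix] <- tr$surge[ix] + 0.5 * cos(pi * (tr$t[ix] - c0) / 0.2)
  }
  expect_equal(nrow(detect_self_feeding(derive_signals(tr), th)), 0)
})

test_that("nest visits demand transients at the nest location", {
  fx <- classified_night(seed = 106, duration = 12000, n_trips = 4,
                         strike_rate = 3, sex = "M")
  sched <- fx$night$schedule
  enters <- sched$t_start[sched$label == "nest_enter"]
  exits <- sched$t_start[sched$label == "nest_exit"]
  expect_gt(length(enters), 0)  # this night provisions prey
  nv <- fx$classified$nest_visits
  expect_equal(nrow(nv), length(enters))
  expect_true(all(abs(nv$t_enter - enters) <= 1))
  expect_true(all(abs(nv$t_exit - exits) <= 1))

  # identical transients far from the nest are rejected by the radius test
  f <- fx$classified$features
  gps_far <- fx$night$gps
  gps_far$x <- gps_far$x + 500
  nv_far <- detect_nest_visits(f, gps_far, fx$meta$nest_position, th,
                               exclude_sec = c(fx$classified$takeoffs,
                                               fx$classified$landings$sec))
  expect_equal(nrow(nv_far), 0)
})

test_that("timeline labels partition the night and track the schedule", {
  fx <- classified_night(seed = 106, duration = 6000, n_trips = 2,
                         strike_rate = 4)
  tl <- fx$classified$timeline
  expect_equal(nrow(tl), 6000)
  expect_true(all(tl$label %in% c("stationary", "travel", "takeoff",
                                  "landing", "feeding", "nest_visit")))
  # scheduled long travel legs are labelled travel in their interior
  sched <- fx$night$schedule
  tr <- sched[sched$label == "travel" & sched$t_end - sched$t_start >= 10, ]
  for (i in seq_len(nrow(tr))) {
    interior <- tl$label[tl$sec > tr$t_start[i] + 1 & tl$sec < tr$t_end[i] - 1]
    expect_true(all(interior == "travel"))
  }
})

test_that("classification is invariant to a constant timestamp offset", {
  fx <- quick_night(seed = 107, duration = 3000, n_trips = 1, strike_rate = 3)
  d1 <- derive_signals(fx$night$trace)
  cl1 <- classify_night(d1, fx$night$gps, fx$meta$nest_position)

  off <- 7200
  tr2 <- fx$night$trace; tr2$t <- tr2$t + off
  gps2 <- fx$night$gps; gps2$t <- gps2$t + off
  cl2 <- classify_night(derive_signals(tr2), gps2, fx$meta$nest_position)

  expect_equal(cl2$takeoffs, cl1$takeoffs + off)
  expect_equal(cl2$landings$sec, cl1$landings$sec + off)
  expect_equal(cl2$landings$subtype, cl1$landings$subtype)
  expect_equal(cl2$landings$peak_g, cl1$landings$peak_g)
})

test_that("detection degrades monotonically with sensor noise", {
  recall_at <- function(noise) {
    tot <- c(0, 0)
    for (seed in c(108, 109)) {
      fx <- suppressWarnings(  # heavy noise legitimately breaks visit pairing
        classified_night(seed = seed, duration = 9000, n_trips = 2,
                         strike_rate = 5, noise_sd = noise))
      sc <- score_events(fx$classified$events, fx$night$schedule)$summary
      s <- sc[sc$kind == "landing", ]
      tot <- tot + c(s$n_matched, s$n_true)
    }
    tot[1] / tot[2]
  }
  r <- vapply(c(0.05, 0.4, 0.9), recall_at, numeric(1))
  expect_gte(r[1], 0.95)
  expect_true(all(diff(r) <= 1e-9 + 0))  # non-increasing in noise
})
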