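test_that("landing force follows F = peak * g0 * mass and is bilinear", {
  expect_equal(compute_landing_force(1, 1), 9.81)
  expect_equal(compute_landing_force(0, 0.5), 0)
  # printed female strike mean inverts to its peak at the female mean mass
  expect_equal(compute_landing_force(12.92, 0.322), 40.8, tolerance = 1e-3)
  # homogeneity in both arguments
  p <- runif(20, 1, 15); m <- runif(20, 0.2, 0.5)
  expect_equal(compute_landing_force(3 * p, m), 3 * compute_landing_force(p, m))
  expect_equal(compute_landing_force(p, 2 * m), 2 * compute_landing_force(p, m))
  expect_error(compute_landing_force(2, 0), "mass")
})

test_that("body-weight multiples match the published worked values", {
  expect_equal(bodyweight_multiple(9.81, 1), 1)
  expect_equal(bodyweight_multiple(40.8, 0.322), 12.9, tolerance = 1e-2)
  expect_equal(bodyweight_multiple(7.91, 0.281), 2.87, tolerance = 1e-2)
})

test_that("strategy boundaries are closed as published", {
  expect_equal(categorize_strategy(c(0, 1, 1.5, 3, 4.9, 5, 20)),
               c("sit_and_wait", "sit_and_wait", "excluded", "excluded",
                 "excluded", "on_the_wing", "on_the_wing"))
})

test_that("outcome inference follows the direct-return rule", {
  landings <- tibble::tibble(
    sec = c(100, 200, 500, 900, 1000),
    subtype = c("perch", "strike", "strike", "strike", "perch"),
    x = c(400, 410, 500, 600, 0), y = 0)
  feeding <- tibble::tibble(t_start = 240)   # 40 s after first strike
  visits <- tibble::tibble(t_enter = 1005)   # direct return after 3rd strike
  strikes <- tibble::tibble(sec = c(200, 500, 900))
  got <- infer_outcome(strikes, landings, feeding, visits)
  # strike 200: feeding before anything else -> success
  # strike 500: next event is another strike -> failure
  # strike 900: at-nest perch then entry -> success (landing on the box)
  expect_equal(got, c(TRUE, FALSE, TRUE))
})

test_that("outcome inference equals a brute-force event-stream scan", {
  for (seed in c(301, 302)) {
    fx <- classified_night(seed = seed, duration = 9000, n_trips = 3,
                           strike_rate = 5, sex = "M")
    ev <- build_night_events(fx$classified, fx$night$gps, fx$meta)
    strikes <- ev$landings[ev$landings$subtype == "strike", ]
    want <- oracle_outcomes(tibble::tibble(sec = strikes$sec), ev$landings,
                            fx$classified$feeding, fx$classified$nest_visits,
                            fx$meta$nest_position)
    got <- infer_outcome(tibble::tibble(sec = strikes$sec), ev$landings,
                         fx$classified$feeding, fx$classified$nest_visits,
                         fx$meta$nest_position)
    expect_equal(got, unname(want))
  }
})

test_that("inferred outcomes match the schedule when detection is perfect", {
  agree <- 0; total <- 0
  for (seed in c(303, 304, 305)) {
    fx <- classified_night(seed = seed, duration = 10000, n_trips = 3,
                           strike_rate = 6, sex = if (seed %% 2) "F" else "M")
    ev <- build_night_events(fx$classified, fx$night$gps, fx$meta)
    ss <- fx$night$schedule[fx$night$schedule$label == "landing_strike", ]
    att <- ev$attempts
    m <- match(att$t, ss$t_start)
    ok <- !is.na(m)
    total <- total + sum(ok)
    agree <- agree + sum(att$success[ok] == (ss$outcome[m[ok]] == "success"))
  }
  expect_gte(agree / total, 0.98)
})

test_that("pre-hunt context applies the 90 s tercile filter", {
  perches <- tibble::tibble(sec = c(100, 300), force_N = c(8, 10))
  out <- prehunt_context(c(150, 420, 50), perches)
  expect_equal(out$prehunt_gap, c(50, 120, NA))
  expect_equal(out$prehunt_perch_force_N, c(8, NA, NA))
})

test_that("pre-strike flight speed is a robust median of step speeds", {
  tr <- tibble::tibble(t = 0:60, x = 5 * (0:60), y = 0)
  expect_equal(flight_speed_before_strike(tr, 50), 5)
  # a single corrupted fix does not move the median appreciably
  tr2 <- tr; tr2$x[45] <- tr2$x[45] + 400
  expect_equal(flight_speed_before_strike(tr2, 50), 5, tolerance = 1e-6)
  # fewer than two fixes in the window -> NA
  expect_true(is.na(flight_speed_before_strike(tr[tr$t < 31, ], 50)))
})

test_that("time to next hunt is ordered and NA after the last strike", {
  expect_equal(time_to_next_hunt(0, 600), 600)
  expect_true(is.na(time_to_next_hunt(700, 600)))
  tt <- time_to_next_hunt(c(100, 200, 300), 350)
  expect_equal(tt, c(250, 150, 50))
  expect_true(all(diff(tt) < 0))
})

test_that("prey-load flag covers exactly the strike-to-delivery interval", {
  strikes <- tibble::tibble(sec = c(200, 800), success = c(TRUE, FALSE))
  visits <- tibble::tibble(t_enter = 400)
  feeding <- tibble::tibble(t_start = numeric(0))
  flags <- flag_loaded_with_prey(c(100, 250, 380, 450, 900), strikes,
                                 feeding, visits)
  expect_equal(flags, c(FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("trip segmentation recovers scheduled trips and conserves time", {
  fx <- classified_night(seed = 306, duration = 10000, n_trips = 3,
                         strike_rate = 4)
  ev <- build_night_events(fx$classified, fx$night$gps, fx$meta)
  expect_equal(nrow(ev$trips), 3)
  expect_lte(sum(ev$trips$duration) * 60, fx$cfg$night_duration)
  # a night with no trips yields no trips
  fx0 <- quick_night(seed = 307, duration = 300, n_trips = 0)
  expect_equal(nrow(segment_trips(fx0$night$gps, fx0$meta$nest_position)), 0)
  # scheduled sit-and-wait share is recovered per trip
  sched <- fx$night$schedule
  for (k in seq_len(3)) {
    st <- sched[sched$trip == k & sched$label == "landing_strike", ]
    prev <- vapply(st$t_start, function(t0) {
      i <- max(which(sched$t_end <= t0 & sched$label == "takeoff"))
      t0 - sched$t_start[i]
    }, numeric(1))
    true_sw <- mean(prev <= 1)
    expect_equal(ev$trips$sw_frequency[k], true_sw, tolerance = 1e-9)
  }
})

test_that("strategy categories partition the attempts table", {
  fx <- classified_night(seed = 308, duration = 9000, n_trips = 2,
                         strike_rate = 6)
  ev <- build_night_events(fx$classified, fx$night$gps, fx$meta)
  expect_true(all(ev$attempts$strategy %in%
                    c("sit_and_wait", "on_the_wing", "excluded")))
  # on-the-wing attempts carry a speed near the configured mean; sit-and-wait
  # attempts carry none
  otw <- ev$attempts$flight_speed[ev$attempts$strategy == "on_the_wing"]
  expect_true(all(is.finite(otw)))
  expect_equal(mean(otw), unname(fx$cfg$flight_speed_mean["F"]),
               tolerance = 0.1)
  expect_true(all(is.na(
    ev$attempts$flight_speed[ev$attempts$strategy == "sit_and_wait"])))
})
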