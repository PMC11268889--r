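test_that("ratio of means has exact algebraic behaviour", {
  a <- rlnorm(50, 2, 0.3)
  r <- ratio_of_means_log(a, a, n_boot = 50, seed = 1)
  expect_equal(r$ratio, 1)
  r2 <- ratio_of_means_log(a, a / 2, n_boot = 50, seed = 1)
  expect_equal(r2$ratio, 2)
  # symmetry: swapping groups inverts the ratio exactly
  b <- rlnorm(40, 1.8, 0.4)
  expect_equal(ratio_of_means_log(a, b, n_boot = 10, seed = 2)$ratio *
                 ratio_of_means_log(b, a, n_boot = 10, seed = 2)$ratio, 1)
  expect_error(ratio_of_means_log(c(1, -1), a), "positive")
  expect_error(ratio_of_means_log(numeric(0), a), "non-empty")
})

test_that("forces generated at F/M ratio 1.26 are recovered within the CI", {
  set.seed(314)
  inside <- 0
  ests <- numeric(10)
  for (rep in 1:10) {
    f <- rlnorm(400, log(9.94) - 0.045, 0.3)
    m <- rlnorm(400, log(7.91) - 0.045, 0.3)
    r <- ratio_of_means_log(f, m, n_boot = 400, seed = rep)
    ests[rep] <- r$ratio
    inside <- inside + (r$ci_low <= 1.2566 && 1.2566 <= r$ci_high)
  }
  expect_gte(inside, 8)
  expect_equal(mean(ests), 1.2566, tolerance = 0.02)
})

test_that("bootstrap ratio CI coverage is near nominal", {
  set.seed(2718)
  hits <- replicate(200, {
    f <- rlnorm(60, log(10), 0.3)
    m <- rlnorm(60, log(8), 0.3)
    r <- ratio_of_means_log(f, m, n_boot = 300)
    r$ci_low <= 1.25 && 1.25 <= r$ci_high
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})

test_that("the success GLM refuses degenerate outcomes and separation", {
  expect_error(fit_success_glm(tibble::tibble(success = rep(TRUE, 30))),
               "outcome classes")
  # perfectly separating predictor
  att <- tibble::tibble(success = rep(c(TRUE, FALSE), each = 25),
                        prehunt_perch_force_N = c(rnorm(25, 20), rnorm(25, 2)))
  expect_error(fit_success_glm(att), "separation")
})

test_that("a balanced 2x2 design recovers its closed-form odds ratio", {
  # success odds double between strategies: OR = 2 exactly by construction
  n <- 400
  att <- tibble::tibble(
    strategy = rep(c("on_the_wing", "sit_and_wait"), each = n / 2),
    success = c(rep(c(TRUE, FALSE), c(80, 120)),   # odds 2/3
                rep(c(TRUE, FALSE), c(114, 86))))  # odds 4/3
  fit <- fit_success_glm(att)
  sw <- fit$coefficients[fit$coefficients$term == "strategysit_and_wait", ]
  truth <- (114 / 86) / (80 / 120)
  expect_equal(sw$odds_ratio, truth, tolerance = 1e-6)
  expect_true(sw$or_low <= truth && truth <= sw$or_high)
})

test_that("GLM coefficients match a brute-force likelihood grid search", {
  set.seed(7)
  n <- 30
  x <- rnorm(n)
  y <- runif(n) < plogis(-0.4 + 0.9 * x)
  att <- tibble::tibble(success = y, prehunt_perch_force_N = x)
  fit <- fit_success_glm(att)
  est <- fit$coefficients$estimate

  nll <- function(b0, b1) {
    eta <- b0 + b1 * scale(x)[, 1]
    -sum(y * eta - log1p(exp(eta)))
  }
  centre <- c(0, 0); width <- 8
  for (pass in 1:6) {  # successive grid refinement, independent of IRLS
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    grid <- outer(b0s, b1s, Vectorize(nll))
    best <- arrayInd(which.min(grid), dim(grid))
    centre <- c(b0s[best[1]], b1s[best[2]])
    width <- width / 10
  }
  expect_lt(max(abs(est - centre)), 1e-3)
})

test_that("attempts generated at OR 0.85 per Newton are recovered across seeds", {
  inside <- 0
  for (s in 1:10) {
    att <- simulate_hunt_attempts(3000, p_sitandwait = 1, seed = 500 + s)
    sw <- fit_success_glm(att)$or_sitandwait_per_newton
    inside <- inside + (sw$low <= 0.85 && 0.85 <= sw$high)
  }
  expect_gte(inside, 9)
})

test_that("force multiples recover within 5 percent at n = 2000 simulated events", {
  peaks_s <- c(); peaks_p <- c()
  seed <- 0
  while (length(peaks_s) < 2000) {
    seed <- seed + 1
    cfg <- night_config(seed = 600 + seed, night_duration = 30000,
                        n_trips = 5, strike_rate = 10)
    s <- generate_schedule(cfg, owl_metadata())
    peaks_s <- c(peaks_s, s$injected_peak[s$label == "landing_strike"])
    peaks_p <- c(peaks_p, s$injected_peak[s$label == "landing_perch"])
  }
  expect_equal(mean(peaks_s), 13, tolerance = 0.05)
  expect_equal(mean(peaks_p), 3, tolerance = 0.05)
})

test_that("trend detection flags the known change region and only it", {
  set.seed(11)
  n <- 600
  tt <- runif(n, 0, 5400)
  # force declines (toward the hunt) inside the last 30 min only
  force <- ifelse(tt > 1800, 9, 9 - 2.5 * (1800 - tt) / 1800) *
    exp(rnorm(n, 0, 0.1))
  ev <- tibble::tibble(time_to_next_hunt = tt, force_N = force,
                       perch_type = "pole")
  tr <- trend_with_derivative(ev, n_boot = 120, seed = 3)$pole
  expect_true(all(tr$band_low <= tr$fitted & tr$fitted <= tr$band_high))
  expect_gt(mean(tr$significant_decline_mask[tr$grid < 1200]), 0.8)
  expect_equal(mean(tr$significant_decline_mask[tr$grid > 2600]), 0)

  # flat input: no significant change anywhere
  ev0 <- ev; ev0$force_N <- 9 * exp(rnorm(n, 0, 0.1))
  tr0 <- trend_with_derivative(ev0, n_boot = 120, seed = 3)$pole
  expect_false(any(tr0$significant_change_mask))

  # monotone input: derivative positive on the interior grid
  ev1 <- ev; ev1$force_N <- 6 + tt / 1000
  tr1 <- trend_with_derivative(ev1, n_boot = 60, seed = 4)$pole
  interior <- tr1$grid > min(tt) + 200 & tr1$grid < max(tt) - 200
  expect_true(all(tr1$derivative[interior] > 0))

  # too few events: NULL with a warning
  expect_warning(out <- trend_with_derivative(ev[1:20, ], n_boot = 10),
                 "skipped")
  expect_null(out$pole)
})

test_that("descriptive tables reproduce printed-mean ratios and gaps", {
  landings <- tibble::tibble(
    subtype = c("perch", "perch", "strike", "strike"),
    force_N = c(9.94, 7.91, 40.8, 38.41),
    force_per_kg = c(30.9, 28.2, 126.4, 136.2),
    sex = c("F", "M", "F", "M"),
    loaded_with_prey = FALSE)
  attempts <- tibble::tibble(
    sex = c("F", "M"), strategy = "on_the_wing", success = c(TRUE, FALSE),
    flight_speed = c(5.47, 5.24))
  tbl <- descriptive_tables(attempts, landings, n_boot = 20, seed = 1)
  get <- function(measure) tbl$value[tbl$measure == measure][1]
  expect_equal(round(get("perch_force_N_ratio_FM"), 2), 1.26)
  expect_equal(round(get("strike_force_N_ratio_FM"), 2), 1.06)
  expect_equal(get("flight_speed_gap_FM"), 0.23, tolerance = 1e-9)

  # single-owl input: one row per cell with n attached
  one <- descriptive_tables(
    tibble::tibble(sex = "F", strategy = "sit_and_wait", success = TRUE,
                   flight_speed = NA_real_),
    tibble::tibble(subtype = "perch", force_N = 9, force_per_kg = 28,
                   sex = "F", loaded_with_prey = FALSE),
    n_boot = 20, seed = 1)
  expect_equal(one$n[one$measure == "success_rate"], 1)
  expect_true(all(c("success_rate", "perch_force_N") %in% one$measure))
})
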