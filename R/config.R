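#' @name owlstrike-constants
#' @title Physical constants
#' @description `G0` is standard gravitational acceleration, 9.81 m/s^2,
#'   used everywhere a force in Newtons is derived from an acceleration in g.
#' @export
G0 <- 9.81

#' Boolean classification thresholds
#'
#' The full rule set of the behavioural classifier, collected in one block so
#' alternative published values can be swapped in verbatim. Deltas are changes
#' between consecutive one-second summaries.
#'
#' * take-off: pitch drop of at least 10 degrees (`dpitch <= takeoff_dpitch`,
#'   a standing-to-horizontal posture switch) and per-second max VeDBA above
#'   `takeoff_vedba` (1 g);
#' * travelling flight: smoothed VeDBA above `travel_vedba_smoothed` (0.1 g)
#'   and pitch below `travel_pitch_max` (30 degrees);
#' * landing: pitch rise above `landing_dpitch` (+10 degrees) with a VeDBA
#'   spike above `landing_vedba` (1 g), terminating a flight;
#' * strike (landing subtype): `dpitch > strike_dpitch` (6 degrees) and
#'   `dvedba > strike_dvedba` (1.3 g); a landing failing either is a perch;
#' * self-feeding: at least `feed_min_peaks` regular VeDBA peaks, each inside
#'   (`feed_peak_min`, `feed_peak_max`) = (0.2, 0.9) g, inter-peak interval
#'   coefficient of variation at most `feed_interval_cv`;
#' * nest visit: enter when `dpitch < nest_enter_dpitch` (-1.5 degrees) and
#'   `dvedba > nest_enter_dvedba` (0.5 g); exit when
#'   `dpitch < nest_exit_dpitch` (0.5 degrees) and
#'   `dvedba < nest_exit_dvedba` (-0.9 g); the location must additionally lie
#'   within `nest_radius` m of the nest.
#'
#' @param takeoff_dpitch,takeoff_vedba,travel_vedba_smoothed,travel_pitch_max,landing_dpitch,landing_vedba,strike_dpitch,strike_dvedba,feed_peak_min,feed_peak_max,feed_min_peaks,feed_interval_cv,feed_max_gap,nest_enter_dpitch,nest_enter_dvedba,nest_exit_dpitch,nest_exit_dvedba,nest_radius,min_event_separation
#'   See description; defaults are the published in-text values.
#' @return A named list of class `owl_thresholds`.
#' @export
rule_thresholds <- function(takeoff_dpitch = -10,
                            takeoff_vedba = 1.0,
                            travel_vedba_smoothed = 0.1,
                            travel_pitch_max = 30,
                            landing_dpitch = 10,
                            landing_vedba = 1.0,
                            strike_dpitch = 6,
                            strike_dvedba = 1.3,
                            feed_peak_min = 0.2,
                            feed_peak_max = 0.9,
                            feed_min_peaks = 3,
                            feed_interval_cv = 0.5,
                            feed_max_gap = 3,
                            nest_enter_dpitch = -1.5,
                            nest_enter_dvedba = 0.5,
                            nest_exit_dpitch = 0.5,
                            nest_exit_dvedba = -0.9,
                            nest_radius = 30,
                            min_event_separation = 1) {
  th <- as.list(environment())
  stopifnot(th$feed_peak_min < th$feed_peak_max,
            th$takeoff_dpitch < 0, th$landing_dpitch > 0,
            th$min_event_separation >= 0)
  structure(th, class = c("owl_thresholds", "list"))
}

#' Owl deployment metadata
#'
#' @param owl_id Identifier string.
#' @param sex `"F"` or `"M"`.
#' @param body_mass Body mass in kg (> 0). Defaults are the study-population
#'   sex means (0.322 kg females, 0.281 kg males).
#' @param nest_position Numeric `c(x, y)` of the nest box in local planar
#'   meters.
#' @return A named list of class `owl_metadata`.
#' @export
owl_metadata <- function(owl_id = "owl1",
                         sex = c("F", "M"),
                         body_mass = NULL,
                         nest_position = c(0, 0)) {
  sex <- match.arg(sex)
  if (is.null(body_mass)) body_mass <- if (sex == "F") 0.322 else 0.281
  if (!is.numeric(body_mass) || length(body_mass) != 1 || body_mass <= 0) {
    stop("body_mass must be a single positive number (kg)")
  }
  stopifnot(is.numeric(nest_position), length(nest_position) == 2)
  structure(list(owl_id = as.character(owl_id), sex = sex,
                 body_mass = body_mass,
                 nest_position = as.numeric(nest_position)),
            class = c("owl_metadata", "list"))
}

#' Synthetic-night generator configuration
#'
#' Defines the study conditions a synthetic owl night emulates. Defaults are
#' calibrated to the field study this pipeline models: hunting strikes peak at
#' about 13 times body weight and perch landings at about 3, wingbeats run at
#' 4 Hz (two full cycles per 0.5 s), travelling flight averages 5.47 m/s for
#' females and 5.24 m/s for males, and baseline success probabilities per
#' sex x strategy are taken from the study's reported rates (sit-and-wait:
#' M 34.5 % / F 26.8 %; on-the-wing: M 26.1 % / F 19.1 %). For sit-and-wait
#' strikes the success odds are additionally modulated by the pre-hunt perch
#' landing force at `or_per_newton` (default 0.85) per Newton around the
#' expected perch force, so softer pre-hunt landings make success more likely.
#'
#' Perch-to-strike waiting times are log-normal with the default parameters
#' chosen so that 90 s is the lower tercile of the perch-to-strike gap
#' distribution, matching the filter used in the pre-hunt force analysis.
#'
#' @param seed Integer seed; every draw in the generator flows from it.
#' @param night_duration Night length in seconds (default 36000 s = 10 h of
#'   50 Hz data, about 1.8 M samples).
#' @param n_trips Number of foraging trips.
#' @param strike_rate Mean hunting attempts per trip (Poisson, minimum 1).
#' @param p_sitandwait Probability a given attempt uses the sit-and-wait
#'   strategy.
#' @param success_prob Named list `F`/`M`, each with `sit_and_wait` and
#'   `on_the_wing` baseline success probabilities.
#' @param strike_peak_bw,perch_peak_bw Mean injected peak acceleration of
#'   strikes / perch landings, in body-weight multiples (g).
#' @param strike_peak_cv,perch_peak_cv Coefficients of variation of the
#'   log-normal peak distributions.
#' @param wingbeat_freq Wingbeat frequency, Hz.
#' @param wingbeat_amp Heave wingbeat oscillation amplitude in flight, g.
#' @param flight_speed_mean Named numeric `c(F = , M = )`, travelling ground
#'   speed in m/s.
#' @param noise_sd Additive Gaussian sensor noise per axis, g.
#' @param gps_jitter_sd GPS position jitter, m.
#' @param perch_type_mix Named simplex over `pole`, `tree`, `building`.
#' @param perch_wait_meanlog,perch_wait_sdlog Log-normal parameters of the
#'   perched waiting time (s) before a sit-and-wait strike.
#' @param or_per_newton Odds ratio of sit-and-wait success per Newton of
#'   pre-hunt perch force.
#' @param nest_radius Radius (m) within which the owl counts as at the nest.
#' @return A named list of class `owl_night_config`.
#' @export
night_config <- function(seed = 1L,
                         night_duration = 36000,
                         n_trips = 6,
                         strike_rate = 6,
                         p_sitandwait = 0.2,
                         success_prob = list(
                           F = list(sit_and_wait = 0.268, on_the_wing = 0.191),
                           M = list(sit_and_wait = 0.345, on_the_wing = 0.261)
                         ),
                         strike_peak_bw = 13,
                         perch_peak_bw = 3,
                         strike_peak_cv = 0.15,
                         perch_peak_cv = 0.12,
                         wingbeat_freq = 4,
                         wingbeat_amp = 1.0,
                         flight_speed_mean = c(F = 5.47, M = 5.24),
                         noise_sd = 0.05,
                         gps_jitter_sd = 0.5,
                         perch_type_mix = c(pole = 0.5, tree = 0.3,
                                            building = 0.2),
                         perch_wait_meanlog = log(90) - stats::qnorm(1 / 3) * 0.9,
                         perch_wait_sdlog = 0.9,
                         or_per_newton = 0.85,
                         nest_radius = 30) {
  cfg <- as.list(environment())
  validate_night_config(cfg)
  structure(cfg, class = c("owl_night_config", "list"))
}

validate_night_config <- function(cfg) {
  probs <- unlist(cfg$success_prob)
  if (any(probs < 0 | probs > 1) || cfg$p_sitandwait < 0 ||
      cfg$p_sitandwait > 1) {
    stop("night_config: probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$perch_type_mix) - 1) > 1e-8 || any(cfg$perch_type_mix < 0)) {
    stop("night_config: perch_type_mix must be a simplex over pole/tree/building")
  }
  if (!all(c("pole", "tree", "building") %in% names(cfg$perch_type_mix))) {
    stop("night_config: perch_type_mix must name pole, tree and building")
  }
  if (!(cfg$strike_peak_bw > cfg$perch_peak_bw && cfg$perch_peak_bw > 1)) {
    stop("night_config: need strike_peak_bw > perch_peak_bw > 1")
  }
  if (cfg$night_duration <= 0 || cfg$n_trips < 0) {
    stop("night_config: invalid night_duration or n_trips")
  }
  invisible(cfg)
}
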