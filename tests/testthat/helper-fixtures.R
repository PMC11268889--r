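# Shared fixtures: small synthetic nights and constructed traces.

# A short, busy night used by most classifier tests.
quick_night <- function(seed = 1, duration = 10000, n_trips = 3,
                        strike_rate = 5, sex = "F", ...) {
  cfg <- night_config(seed = seed, night_duration = duration,
                      n_trips = n_trips, strike_rate = strike_rate, ...)
  meta <- owl_metadata(paste0("owl", seed), sex)
  night <- generate_night(cfg, meta)
  list(cfg = cfg, meta = meta, night = night)
}

classified_night <- function(seed = 1, ...) {
  fx <- quick_night(seed = seed, ...)
  derived <- derive_signals(fx$night$trace)
  cl <- classify_night(derived, fx$night$gps, fx$meta$nest_position)
  c(fx, list(derived = derived, classified = cl))
}

# Constant-posture trace: standing with gravity on the heave axis.
constant_trace <- function(duration = 10, rate = 50, heave = 1, surge = 0,
                           sway = 0) {
  n <- duration * rate
  tibble::tibble(t = (seq_len(n) - 1) / rate,
                 heave = rep(heave, n), surge = rep(surge, n),
                 sway = rep(sway, n))
}

# Stationary trace with a train of VeDBA pulses (for feeding tests):
# half-cosine pulses of 0.2 s on the surge axis at given amplitude/spacing.
pulse_train_trace <- function(n_pulses = 5, amplitude = 0.5, spacing = 1.5,
                              duration = NULL, rate = 50) {
  if (is.null(duration)) duration <- ceiling(n_pulses * spacing + 6)
  tr <- constant_trace(duration, rate)
  tt <- tr$t
  centres <- 3 + (seq_len(n_pulses) - 1) * spacing
  for (c0 in centres) {
    ix <- which(abs(tt - c0) <= 0.1)
    tr$surge[ix] <- tr$surge[ix] + amplitude * cos(pi * (tt[ix] - c0) / 0.2)
  }
  tr
}
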