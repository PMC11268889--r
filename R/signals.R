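#' Centered moving average with shrinking edges
#'
#' Smooths a series with a centered moving mean. The window, given in seconds,
#' is converted to the nearest odd number of samples so the window is symmetric
#' around each point. At the series edges the window shrinks to the samples
#' actually available, so the output has no phase lag and no NA padding.
#'
#' @param x Numeric series.
#' @param window Window length in seconds.
#' @param rate Sampling rate in Hz.
#' @return Numeric series of the same length as `x`.
#' @examples
#' moving_average(sin(2 * pi * 4 * (0:499) / 50), window = 0.5, rate = 50)
#' @export
moving_average <- function(x, window, rate) {
  if (length(x) == 0L) stop("moving_average(): empty series")
  if (!is.numeric(window) || window * rate < 1) {
    stop("moving_average(): window must cover at least one sample")
  }
  k <- as.integer(round(window * rate))
  if (k %% 2L == 0L) k <- k + 1L     # nearest odd sample count
  if (k <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Derive static/dynamic components, VeDBA, pitch and raw vector sum
#'
#' Decomposes a tri-axial accelerometer trace into its static (gravitational)
#' and dynamic components by smoothing each raw channel over `static_window`
#' seconds and subtracting, then derives the per-sample channels the
#' behavioural classifier consumes:
#'
#' * `vedba` — vectorial dynamic body acceleration, the Euclidean norm of the
#'   three dynamic components (g);
#' * `vedba_smoothed` — VeDBA smoothed over `static_window` seconds;
#' * `pitch` — body pitch in degrees, the arcsine of the static heave
#'   acceleration (clamped to \[-1, 1\] g so sensor noise cannot push the
#'   arcsine out of range), smoothed over `pitch_window` seconds;
#' * `vecsum_raw` — Euclidean norm of the *raw* channels, whose event-window
#'   maximum is the peak used for landing-force estimation.
#'
#' The decomposition is exactly conservative: `raw = static + dynamic` holds to
#' machine precision in every channel.
#'
#' @param trace Accelerometer trace: data frame with columns `t` (s, uniform),
#'   `heave`, `surge`, `sway` (g).
#' @param static_window Smoothing window for the static component, seconds.
#' @param pitch_window Smoothing window applied to pitch, seconds.
#' @return A tibble with the raw channels plus `static_*`, `dyn_*`, `vedba`,
#'   `vedba_smoothed`, `pitch` (degrees), and `vecsum_raw`.
#' @export
derive_signals <- function(trace, static_window = 0.5, pitch_window = 1) {
  validate_trace(trace)
  rate <- trace_rate(trace)
  static_heave <- moving_average(trace$heave, static_window, rate)
  static_surge <- moving_average(trace$surge, static_window, rate)
  static_sway  <- moving_average(trace$sway,  static_window, rate)
  dyn_heave <- trace$heave - static_heave
  dyn_surge <- trace$surge - static_surge
  dyn_sway  <- trace$sway  - static_sway
  vedba <- compute_vedba(dyn_heave, dyn_surge, dyn_sway)
  tibble::tibble(
    t = trace$t,
    heave = trace$heave, surge = trace$surge, sway = trace$sway,
    static_heave = static_heave, static_surge = static_surge,
    static_sway = static_sway,
    dyn_heave = dyn_heave, dyn_surge = dyn_surge, dyn_sway = dyn_sway,
    vedba = vedba,
    vedba_smoothed = moving_average(vedba, static_window, rate),
    pitch = compute_pitch(static_heave, rate, window = pitch_window),
    vecsum_raw = vector_sum_raw(trace)
  )
}

#' Vectorial dynamic body acceleration
#'
#' @param dyn_heave,dyn_surge,dyn_sway Aligned dynamic components (g).
#' @return Per-sample VeDBA (g), non-negative.
#' @export
compute_vedba <- function(dyn_heave, dyn_surge, dyn_sway) {
  stopifnot(length(dyn_heave) == length(dyn_surge),
            length(dyn_heave) == length(dyn_sway))
  sqrt(dyn_heave^2 + dyn_surge^2 + dyn_sway^2)
}

#' Body pitch angle from static heave acceleration
#'
#' Pitch is the arcsine of the static heave acceleration taken directly in g
#' (1 g of static heave means the heave axis points straight up: 90 degrees).
#' The argument is clamped to \[-1, 1\] so that noise in the static estimate
#' cannot produce NaN, and the result is smoothed over `window` seconds.
#'
#' @param static_heave Static heave series (g).
#' @param rate Sampling rate in Hz.
#' @param window Smoothing window in seconds; `NULL` or 0 skips smoothing.
#' @return Pitch in degrees, bounded in \[-90, 90\].
#' @export
compute_pitch <- function(static_heave, rate, window = 1) {
  p <- asin(pmin(pmax(static_heave, -1), 1)) * 180 / pi
  if (!is.null(window) && window > 0) p <- moving_average(p, window, rate)
  p
}

#' Vector sum of the raw acceleration channels
#'
#' The norm of the raw (not gravity-corrected) acceleration; its maximum over a
#' landing spike, multiplied by body mass and g0, is the landing force.
#'
#' @param trace Accelerometer trace (see [derive_signals()]).
#' @return Per-sample vector sum (g), non-negative.
#' @export
vector_sum_raw <- function(trace) {
  sqrt(trace$heave^2 + trace$surge^2 + trace$sway^2)
}

#' Summarize derived signals into one-second features
#'
#' Collapses per-sample derived channels into the per-second feature table the
#' Boolean classifier consumes: mean pitch, max VeDBA, max smoothed VeDBA and
#' max raw vector sum per whole second, plus the change versus the previous
#' second (`dpitch`, `dvedba`; the first second's deltas are 0). Seconds are
#' half-open intervals `[s, s + 1)` counted from the first sample.
#'
#' @param derived Output of [derive_signals()].
#' @return A tibble with one row per whole second: `sec` (the second's start
#'   time, s), `pitch_mean`, `vedba_max`, `vedba_smooth_max`, `vecsum_max`,
#'   `dpitch`, `dvedba`.
#' @export
summarize_per_second <- function(derived) {
  rate <- trace_rate(derived)
  n_sec <- floor(nrow(derived) / rate)
  if (n_sec < 1) stop("summarize_per_second(): need at least 1 s of data")
  n_use <- n_sec * rate
  grp <- function(x, f) {
    m <- matrix(x[seq_len(n_use)], nrow = rate)
    if (identical(f, "mean")) .colMeans(m, rate, n_sec) else colMaxs(m)
  }
  pitch_mean <- grp(derived$pitch, "mean")
  vedba_max <- grp(derived$vedba, "max")
  tibble::tibble(
    sec = derived$t[1] + seq_len(n_sec) - 1,
    pitch_mean = pitch_mean,
    vedba_max = vedba_max,
    vedba_smooth_max = grp(derived$vedba_smoothed, "max"),
    vecsum_max = grp(derived$vecsum_raw, "max"),
    dpitch = c(0, diff(pitch_mean)),
    dvedba = c(0, diff(vedba_max))
  )
}

# column-wise maxima of a matrix without apply() overhead
colMaxs <- function(m) {
  out <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) {
    mi <- m[i, ]
    gt <- mi > out
    if (any(gt)) out[gt] <- mi[gt]
  }
  out
}

# sampling rate from a uniform time axis; errors on non-uniform sampling
trace_rate <- function(trace) {
  t <- trace$t
  if (length(t) < 2L) stop("trace must contain at least two samples")
  dt <- diff(t)
  step <- stats::median(dt)
  if (step <= 0 || any(abs(dt - step) > step * 1e-3)) {
    stop("trace time axis must be strictly increasing and uniformly sampled")
  }
  as.integer(round(1 / step))
}

validate_trace <- function(trace) {
  req <- c("t", "heave", "surge", "sway")
  if (!all(req %in% names(trace))) {
    stop("trace must have columns t, heave, surge, sway")
  }
  if (!all(vapply(trace[req], function(x) all(is.finite(x)), logical(1)))) {
    stop("trace contains non-finite values")
  }
  trace_rate(trace)
  invisible(trace)
}
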