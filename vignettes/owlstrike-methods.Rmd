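---
title: "From raw biologger signals to hunting-success inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw biologger signals to hunting-success inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlstrike)
```

## The problem

Nocturnal raptors such as barn owls hunt either on the wing or from perches
("sit-and-wait"), and the force with which they land — both on the perch and
on the prey — is measurable from a body-mounted accelerometer. owlstrike
implements the full chain from raw 50 Hz tri-axial accelerometry and 1 Hz GPS
to behavioural labels, landing ground-reaction forces, hunting strategies,
inferred strike outcomes, perch types and the study-level statistics, together
with a ground-truthed synthetic-night generator that makes every stage
testable without field data.

## Signal derivation

The accelerometer measures the sum of gravity and body motion on three axes
(heave, surge, sway, in g). The static (gravitational) component of each
channel is estimated by a centred moving average over 0.5 s — two full
wingbeat cycles at the 4 Hz wingbeat frequency, so flapping cancels out of the
static estimate — and the dynamic component is the remainder, making the
decomposition exactly conservative (`raw = static + dynamic` to machine
precision). From these:

* **VeDBA** (vectorial dynamic body acceleration) is the Euclidean norm of
  the three dynamic components; a smoothed version (same 0.5 s window) is
  used for the sustained-motion threshold.
* **Pitch** is the arcsine of the static heave channel taken directly in g,
  clamped to [-1, 1] so sensor noise cannot leave the domain, then smoothed
  over 1 s. 1 g of static heave means the heave axis points straight up
  (90°); a standing owl sits near 55°, a level-flying owl near 10°.
* **The raw vector sum** is the norm of the unprocessed channels; its peak
  over a landing spike, times body mass and g0 = 9.81 m/s², is the landing
  force in Newtons.

The moving average is centred with a shrinking window at the edges; a
trailing window would shift every event time by half the window length.
Deltas ("Δpitch", "ΔVeDBA") are differences between consecutive one-second
summaries, matching the 1 s summarization interval of the classifier; the
first second's deltas are zero.

## Behavioural classification

The classifier is a small set of Boolean threshold rules on the per-second
features, all collected in `rule_thresholds()` so alternative published
values can be swapped in verbatim:

| behaviour | rule |
|---|---|
| take-off | pitch drop ≥ 10° and max VeDBA > 1 g |
| travelling flight | smoothed VeDBA > 0.1 g and pitch < 30° |
| landing | Δpitch > +10°, max VeDBA > 1 g, and a flight in progress |
| hunting strike | a landing with Δpitch > 6° and ΔVeDBA > 1.3 g |
| self-feeding | ≥ 3 regular VeDBA peaks each in (0.2, 0.9) g |
| nest enter | Δpitch < −1.5°, ΔVeDBA > +0.5 g, within 30 m of the nest |
| nest exit | Δpitch < +0.5°, ΔVeDBA < −0.9 g, within 30 m of the nest |

Design choices where the rule set needed interpretation:

* The take-off pitch threshold is implemented as a *decrease* of at least
  10°: the behaviour is a switch from standing to a horizontal posture, so
  the sign convention follows the posture change.
* Labels must partition time, so overlaps resolve by the fixed precedence
  landing > takeoff > travel > feeding/nest > stationary. The same precedence
  excludes take-off and landing seconds from the nest-transient candidates:
  a take-off from the nest box satisfies the enter rule's pitch drop and
  VeDBA jump, and only the precedence keeps the two behaviours apart.
* A landing is only accepted while a flight is in progress (a take-off has
  been seen or the preceding seconds carry the travel mask); an isolated
  spike in stationary data is not a landing.
* Candidate seconds closer than the 1 s minimum event separation merge into
  one event at the first second, so a spike straddling a second boundary is
  not double-counted.
* "Regular" feeding peaks are operationalized as an inter-peak-interval
  coefficient of variation ≤ 0.5; peaks are maximal runs of VeDBA above the
  0.2 g floor, with runs closer than 0.5 s clustered into one peak (a noisy
  pulse otherwise fragments into shoulder runs that wreck the regularity
  statistic) and clusters shorter than 3 samples discarded as noise
  exceedances.
* The nest-radius test (default 30 m, configurable) replaces the original
  study's manual GPS-vs-nest check; GPS linkage generally is
  nearest-fix-in-time within 1 s, farther gaps leave the location missing.

## Events and analysis units

* **Landing force**: `peak_g × 9.81 × body mass` (N); body-weight multiple:
  force / (mass × 9.81). Both are exact algebraic identities, tested for
  bilinearity.
* **Strategy**: flight time before the strike ≤ 1 s → sit-and-wait; ≥ 5 s →
  on-the-wing; both bounds closed; anything between is `excluded` and its
  fraction is reported, never silently dropped.
* **Outcome**: a strike succeeds when the next informative event after it is
  a self-feeding bout or a nest entry ("direct return"). A physical return
  necessarily includes the touchdown on the nest box itself, so landings
  within the nest radius do not break the chain; any other perch landing or
  strike in between means the attempt failed. When several strikes precede
  one feeding bout, the nearest preceding strike gets the credit.
* **Pre-hunt context**: the force of the most recent perch landing, attached
  only when the perch-to-strike gap is under 90 s (the lower tercile of the
  gap distribution, mirrored in the generator's waiting-time calibration).
* **Prey load**: perch landings between a successful strike and the
  subsequent delivery event carry extra mass and are excluded from force
  analyses.
* **Flight speed**: median of per-second GPS step speeds over the 20 s
  before a strike; the median makes single corrupted fixes irrelevant. At
  least two fixes are required, otherwise the speed is missing.
* **Trips**: maximal intervals with nest distance > 30 m; durations in
  minutes; sit-and-wait frequency per trip uses categorized attempts only.

## Perch-type assignment

The perched interval (landing to next take-off) yields a coordinate-wise
median GPS location; the habitat feature nearest to it within 2 m gives the
perch type (point distance for poles and trees, polygon-boundary distance for
buildings, zero inside). Nothing within 2 m gives `unknown`; exact ties break
pole > tree > building, a fixed documented order. Nearest-feature was chosen
over majority-by-area within the radius: with point features for poles and
trees, area majorities are ill-defined, and the tie-break makes the rare
ambiguous case deterministic. Coordinates are planar meters throughout
(lon/lat inputs are expected to be projected with a local equirectangular
projection before entering the pipeline), which keeps every distance exact
and testable.

## The synthetic-night generator

The generator defines the study conditions, not a tuning surface. A night is
a sequence of foraging trips from a nest; each trip alternates perch
landings, log-normal waits, and strikes, ends with a return flight, and
enters the nest box when its final strike provisions prey; mid-trip successes
produce on-the-spot self-feeding bouts. Signal signatures per behaviour:

* travelling flight: 4 Hz heave wingbeat (amplitude 1 g, with smaller
  phase-shifted surge/sway components) at 10° pitch; GPS moves in a straight
  line at the sex-specific mean speed (5.47 m/s females, 5.24 m/s males);
* take-off: posture drop inside one second plus a 1.6 g flapping burst;
* landing: posture rise plus a 0.1 s half-cosine pulse, centred exactly on a
  sample tick, whose raw vector-sum peak equals the scheduled injected peak
  (the pulse amplitude is solved against the standing gravity vector so the
  peak is exact before noise);
* strike peaks are log-normal with mean 13 body weights (CV 0.15), perch
  peaks with mean 3 (CV 0.12); the CVs keep the two spike populations
  separable by the published ΔVeDBA threshold at better than 95 % while
  still overlapping enough to exercise the subtype rule;
* self-feeding: 5–15 pulses of 0.2 s at a constant 1–2 s interval, peak
  VeDBA inside the (0.2, 0.9) g window;
* nest visit: a small pitch drop with the onset of 1.3 g sway activity
  (at 4 Hz, so the static estimate stays flat), ending in a quiet exit
  second with a slight crouch;
* noise: additive Gaussian, 0.05 g per axis (the logger noise floor is not
  published; the value is a declared assumption exposed in the config);
  GPS jitter 0.5 m.

Sit-and-wait strikes launch one second after take-off (about 5.5 m of
flight); on-the-wing strikes follow 25–60 s of searching flight, so the 20 s
speed window lies fully inside the flight. Waiting times are log-normal with
the lower tercile at 90 s, matching the pre-hunt filter. Baseline success
probabilities are the study's per-sex, per-strategy rates; for sit-and-wait
attempts the log-odds shift by log(0.85) per Newton of pre-hunt perch force
around its expectation, giving the downstream success model a known
generating truth. Landings are at least 2 s apart by construction so the
detector's separation rule is well-posed. A schedule that cannot fit the
night raises an explicit error rather than truncating silently.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: aerodynamic or biomechanical realism beyond the
signatures the classifier keys on, terrain, weather, individual posture
calibration, prey behaviour, or any built-in decline of landing force with
time-to-hunt (the trend machinery is therefore validated on constructed
declining inputs, and on the flat generator output it correctly reports no
change). Real signals will be messier in exactly the ways the Boolean rules
are sensitive to; the synthetic suite demonstrates correctness of the
computation, not field-ready classification accuracy.

## Statistics

* **Group force ratios**: `exp(mean(log a) − mean(log b))` with a percentile
  bootstrap CI; with repeated measures per owl the bootstrap resamples whole
  owls (cluster bootstrap), the package's stand-in for the original
  random-intercept structure, which is out of scope.
* **Success model**: fixed-effects logistic regression (binomial IRLS,
  deviance tolerance 1e-8, max 100 iterations) at the final structure
  success ~ force × strategy + sex, continuous predictors z-scored; Wald
  CIs; odds ratios reported per SD and per Newton. All-one-class outcomes
  and post-hoc detected separation (any |z-scale coefficient| > 15) raise
  errors naming the predictor. AICc-based structure selection is not
  reproduced.
* **Force-versus-time-to-hunt trend**: a penalized cubic regression spline
  (9 basis functions) of log force on time-to-next-hunt per perch type, with
  a max-deviation bootstrap simultaneous band: events are resampled, curves
  refitted on a fixed grid, pointwise SDs scaled by the bootstrap quantile
  of the maximal standardized deviation. The first derivative is taken by
  central finite differences on the grid (forward/backward at the ends), and
  grid points whose derivative band excludes zero are flagged; with the grid
  oriented as time-to-hunt, a significantly positive derivative is a force
  *decline* toward the strike. Strata under 50 events yield a NULL trend
  with a warning.
* **Bootstrap sizes**: 1000 resamples for ratio CIs, 200 for the
  simultaneous band, 500 for descriptive-table CIs — enough for stable 95 %
  percentile endpoints at the event counts involved while keeping the whole
  suite inside a half-minute of statistics.

## Problem sizes and reproducibility

The analysis scripts simulate eight owls (four per sex) with 4 h nights of
four trips and about eight attempts each — roughly 500 landings, a study
night in miniature; the acceptance script processes synthetic nights until
2000 strikes have been detected and refits the success model across ten
seeds. A full 10 h night (1.8 M accelerometer samples) runs through the
whole pipeline in a few seconds, and every random draw flows from a single
integer seed: the same seed gives bit-identical traces, schedules and
results.

## Known limitations

* The Boolean thresholds are taken as published constants; no per-individual
  calibration or learning is attempted.
* Outcome inference encodes the direct-return logic only; the original
  study additionally had camera-trap confirmation at the nest.
* The cluster bootstrap approximates, but does not reproduce, mixed-model
  inference; the trend band approximates posterior-simulation bands.
* Force peaks at 50 Hz undersample the true impact peak; estimates are
  lower bounds, a property inherited from the measurement process.
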