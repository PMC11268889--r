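# owlstrike

Hunting-success inference from barn owl biologger signals.

Barn owls (*Tyto alba*) hunt either on the wing or from perches, and a
body-mounted accelerometer records both how hard they land and what they do
next. `owlstrike` is an R package plus analysis workflow that goes from raw
50 Hz tri-axial accelerometry and 1 Hz GPS to:

1. **derived channels** — static/dynamic decomposition, VeDBA (vectorial
   dynamic body acceleration), body pitch (arcsine of static heave), and the
   raw acceleration vector sum;
2. **behavioural labels** — Boolean threshold rules for take-offs,
   travelling flight, landings, self-feeding and nest-box visits, summarized
   at 1 s resolution and linked to GPS;
3. **analysis units** — landing ground-reaction forces
   `F = peak_g x g0 x mass` (in N and body-weight multiples), hunting
   strategies (sit-and-wait: at most 1 s of flight before the strike;
   on-the-wing: at least 5 s), strike outcomes inferred from subsequent
   feeding or nest provisioning, pre-hunt perch forces (gap < 90 s),
   perch types from a habitat map (nearest feature within 2 m), and
   foraging trips;
4. **statistics** — log-scale force ratios with (cluster) bootstrap CIs, a
   logistic success model with the force x strategy interaction (odds
   ratios per Newton), and a penalized-spline force-versus-time-to-hunt
   trend with a derivative-based significant-change mask.

Every stage is exercised against a built-in **synthetic-night generator**
with known ground truth: trips, perch sequences, strikes near 13x body
weight, perch landings near 3x, wingbeat oscillation at 4 Hz, sex-specific
flight speeds and success rates, and a sit-and-wait success model with odds
ratio 0.85 per Newton of pre-hunt perch force.

## Worked example

```r
library(owlstrike)

# a landing peak of 12.92 g by a 322 g female
force <- compute_landing_force(12.92, 0.322)
bodyweight_multiple(force, 0.322)
#> strike force: 40.8 N = 12.9 x body weight

# one self-contained synthetic night through the whole pipeline
cfg <- pipeline_config(night = night_config(seed = 45, night_duration = 7200,
                                            n_trips = 2, strike_rate = 6))
res <- run_pipeline(cfg, owl_metadata("demo", "F"))
res$score$summary
#>   kind       n_true n_detected n_matched recall precision
#> 1 takeoff        26         26        26      1         1
#> 2 landing        26         26        26      1         1
#> 3 feeding         5          5         5      1         1
#> 4 nest_enter      0          0         0     NA        NA
```

The night scheduled 26 take-offs and 26 landings; all were detected at the
right second (recall and precision 1.0), and the five self-feeding bouts that
mark successful strikes were all found. The derived tables report 12 hunting
attempts (5 successful) across 2 foraging trips, and the summary reproduces
the expected magnitudes — perch landings near 9.3 N (~3x body weight for a
322 g female), strikes near 45 N (~14x), on-the-wing flight speed near the
configured 5.47 m/s:

```r
res$summary[res$summary$measure %in%
              c("success_rate", "flight_speed", "perch_force_N",
                "strike_force_N"), ]
#>          measure          group   value  ci_low ci_high  n
#> 1   success_rate  F.on_the_wing  0.3636  0.0909   0.636 11
#> 2   success_rate F.sit_and_wait  1.0000  1.0000   1.000  1
#> 3   flight_speed              F  5.4686  5.4048   5.539 11
#> 4  perch_force_N            all  9.3446  8.7633   9.890 14
#> 5 strike_force_N            all 45.1888 41.5475  50.171 12
```

## Analysis workflow

The numbered scripts under `analysis/` run the study in miniature (eight
owls, four per sex, one 4 h night each) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R   # population, ground truth, GPS, habitat
Rscript analysis/02_classify.R   # signals -> labels -> events, scored vs truth
Rscript analysis/03_events.R     # pooled landing/attempt/trip tables
Rscript analysis/04_stats.R      # ratios, success model, trends, summary
```

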