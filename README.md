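# atcgaze

Eye-tracking analytics for simulated en route air-traffic control: session
level mental-workload (MWL) indices from 30 Hz gaze recordings, and
gaze–action analysis of conflict detection and resolution (CD&R) around
scripted loss-of-separation events.

## The problem

An en route controller watches a radar display (here 61 × 34 cm at 60 cm,
so the central 27.5 × 20.5 cm active sector subtends 25.81° × 19.39°) and
issues altitude/speed clearances to keep every aircraft pair separated by
at least 1,000 ft vertically or 5 NM laterally. Ocular behaviour indexes
both the controller's global workload and where their attention is moment
to moment. `atcgaze` implements the full measurement chain for a 2
(traffic: 6 vs 12 aircraft) × 3 (airspace complexity: low/medium/high)
within-subject simulator study:

- **Event detection** — blinks as simultaneous both-eye data loss lasting
  100–600 ms; fixations by a dispersion-threshold (I-DT) algorithm: any
  gaze remaining within 1° of visual angle (maximum pairwise distance) for
  at least 100 ms.
- **AOI accounting** — fixation time/count over three static regions
  (active sector, out-of-sector airspace, flight-plan sheet) and over
  dynamic per-aircraft rectangles that track each aircraft's projected
  position; 10 s sliding-window attention shares.
- **Workload statistics** — per-session pupil diameter, blink count and
  duration, ISA (mean of eight 1–7 ratings) and NASA-TLX (raw 6–120 sum);
  2 × 3 repeated-measures ANOVAs with Mauchly sphericity checks and
  Huynh-Feldt correction, partial η², Bonferroni pairwise comparisons, and
  Spearman correlations over the six condition means.
- **CD&R analysis** — a separation checker over scripted trajectories with
  clearances applied (altitude changes ramp at 1,500 ft/min), solver /
  non-solver classification, per-conflict cumulative fixation times and
  intervention tallies, Mann–Whitney U tests, and forward-stepwise (score
  entry / Wald removal) binomial logistic regression with McFadden R² and
  VIF.
- **Synthetic cohort generator** — 24 participants × 6 conditions of
  16-min sessions: scripted scenarios (the 12-aircraft high-complexity one
  embeds an Easy two-aircraft conflict violating separation 140 s after
  onset and a Difficult three-aircraft conflict violating at 240 s), a
  renewal-process gaze simulator with condition-dependent pupil, blink and
  attention structure, intervention logs, and subjective scores — so the
  whole pipeline is testable without any recorded data.

## Worked example

```r
library(atcgaze)

# the packaged 12-high scenario with its two scripted conflicts
sc <- generate_scenario(condition(12, "high"))
check_separation(sc, flights = c("POB456", "HYG532"))$time_s
#> [1] 140
check_separation(sc, flights = c("KET456", "REV756", "GPL751"))$time_s
#> [1] 240

# a timely altitude clearance on the climbing aircraft solves the conflict
iv <- data.frame(t_s = 80, flight = "HYG532", kind = "altitude", value = 32000)
classify_solver(sc, iv, flights = c("POB456", "HYG532"))
#> [1] TRUE

# simulate one session and detect its ocular events
p  <- cohort_params()
st <- simulate_gaze(sc, p, solver = list(easy = TRUE, difficult = FALSE),
                    interventions = iv, seed = 43)
detect_blinks(st)
#> <blink_detection> 116 blink(s), 0 track-loss segment(s)
nrow(detect_fixations(st))
#> [1] 2534
round(pupil_mean(st), 2)
#> [1] 3.44
```

The blink count reflects the high-traffic blink rate (~8–10/min over 16
min), the pupil mean sits at the 3.44 mm high-traffic baseline, and the
~2,500 fixations average ≈ 300 ms. A full simulated study
is one call — `run_pipeline(pipeline_config(seed = 1, out_dir = "out"))` —
which writes the session-metric and conflict tables (CSV), the workload
and CD&R statistics (JSON), and a sliding-window attention series.

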