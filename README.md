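# skystrip

Analysis tools for paired **human-observer / drone-imagery
strip-transect surveys** of marine megafauna (dugongs are the motivating
case). When a monitoring programme moves from observers in a light
aircraft to drone imagery, the two platforms must be compared under the
same conditions: how much area does each actually sample, how often does
each miss an available animal, and do counts and group sizes differ once
effort and environment are accounted for? `skystrip` implements that
comparison as a reproducible pipeline, with a synthetic-survey generator
providing known ground truth for every stage.

## What is inside

* **Footprint geometry** — pinhole projection of tilted camera frames
  onto the sea surface; exact overlap, dissolved-coverage and
  minimum-bounding-rectangle width accounting for convex footprints
  (`image_footprint`, `forward_overlap`, `side_overlap`,
  `dissolve_coverage`, `cut_by_segments`, `min_bounding_width`);
  capture-interval scheduling for a prescribed forward-lap and
  altitude-corrected observer strip areas.
* **Sighting resolution** — deduplication of animals seen in several
  overlapping frames, 200 m chain-rule grouping (single-linkage
  connected components), greedy front/back-seat call matching, and
  multi-reviewer capture histories (`deduplicate_imagery`,
  `chain_group`, `match_double_observer`, `build_reviewer_histories`).
* **Perception bias** — Huggins closed-capture conditional likelihood
  with logit-linear structures and covariates, AICc model selection,
  and the combined probability

  $$\hat p_d = 1 - (1-\hat p_1)(1-\hat p_2)$$

  with delta-method errors (`fit_huggins`, `select_model`,
  `combined_probability`, `delta_se_combined`).
* **Minimum-detections simulation** — the full scenario grid
  (7 probabilities per reviewer x 8 detection levels: 392 two-reviewer
  and 2,744 three-reviewer scenarios), conditional history simulation,
  and CV-versus-detections precision curves (`enumerate_scenarios`,
  `simulate_histories`, `run_scenario`, `asymptote_summary`).
* **Count models** — segment-level Tweedie regression (compound
  Poisson-gamma, log-area offsets, flight/transect random intercepts,
  profiled variance power) and zero-truncated Poisson group-size
  models with Wald backwards selection (`fit_tweedie`, `profile_power`,
  `fit_ztp`, `backward_select`, `effect_ratio`).
* **Synthetic surveys and pipeline** — `simulate_survey` writes the
  canonical file set (images, detections, calls, track, cloud, truth);
  `run_all` chains every stage under one config and seed and emits a
  manifest plus coverage/perception/model reports.

## Worked example

```r
library(skystrip)

cfg <- survey_config(n_transects = 2, transect_length = 10000, seed = 7)
sim <- simulate_survey(cfg, density = 4, p_observer = c(0.74, 0.81))

obs <- process_observer_sightings(sim$calls, sim$environment$track, cfg)
sel <- select_model(obs$histories,
                    list(huggins_spec("constant"),
                         huggins_spec("by_occasion")))
print(sel)
#> <perception_selection>
#>        model k  logLik   AICc dAICc
#>     constant 1 -31.151 64.408 0.000
#>  by_occasion 2 -31.106 66.536 2.128
print(sel$fits[[1]])
#> <perception_estimate> constant
#>  occasion  p_hat     se
#>         1 0.8406 0.0475
#>         2 0.8406 0.0475
#> combined p_d = 0.9746 (SE 0.0151)
#> logLik -31.151, k 1, n 40, AICc 64.408
```

The survey simulated 20 km of transect with seat detection
probabilities 0.74 (front) and 0.81 (back). With only 40 matched
double-observer histories, AICc prefers the 1-parameter constant model
(the seat difference is within noise at this sample size); its pooled
estimate 0.84 sits between the two true values, and the combined
team probability 0.97 is within 1.5 SE of the true
1 − 0.26 × 0.19 = 0.9506. At 300+ histories the seat-specific model
recovers each probability within 3 SE (see the test suite).

Coverage accounting from the same run:

```r
coverage_report(sim)
#>   flight_id n_images area_km2 mean_forward_lap mean_width_m side_lap
#> 1         1      548    7.619            0.375       193.47    0.154
```

548 frames at 396 m altitude dissolve to 7.6 km²; the mean on-ground
image width of 193 m and forward-lap near the 40% target match the
nominal geometry of a 50 mm lens and 23.2 mm sensor at that altitude.

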