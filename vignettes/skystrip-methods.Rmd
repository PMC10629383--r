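---
title: "Methods: dual-platform strip-transect survey analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-platform strip-transect survey analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large marine herbivores and cetaceans are monitored by aerial
strip-transect surveys: an aircraft flies parallel transects and counts
animals inside fixed-width strips. Two observation platforms are in use
for dugongs. Human observers in a light aircraft call sightings inside
two ~200 m strips, one on each side, separated by a blind gap under the
fuselage; a fixed-wing drone flying above captures still images with two
obliquely mounted cameras whose combined swath covers roughly the
observers' gap. Comparing counts between the platforms — and estimating
how many available animals each platform misses (perception bias) — is
what this package implements, end to end, as a file-mediated pipeline
with a fully synthetic test world.

`skystrip` has eight parts: a synthetic-survey generator, footprint
geometry, sighting resolution (deduplication, chain-rule grouping,
double-observer matching), transect segmentation with environmental
covariates, Huggins closed-capture perception estimation, a
minimum-detections precision simulation, Tweedie and zero-truncated
Poisson count models, and an orchestrating pipeline.

## Footprint geometry

Each camera is a pinhole with focal length $f$ (default 0.050 m) and
sensor $w_s \times h_s$ = 23.2 x 15.4 mm (6016 x 4000 px), rigidly
tilted $\pm 11.5^\circ$ from vertical about the along-track axis. A
pixel's ray is rotated by mount tilt, then airframe roll, pitch and
azimuth (heading clockwise from north), and intersected with the sea
surface, taken as the plane $z = 0$ — a marine survey needs no terrain
model. The rotation order is the standard aerial photogrammetry
convention; the angles are named in flight telemetry but their
composition order is a package design choice, documented here and fixed
in code.

Useful closed forms used as test oracles: a nadir frame at altitude $H$
covers $H w_s / f \times H h_s / f$ metres ($H^2 w_s h_s / f^2$ m²);
the centre ground-sample distance is $H (w_s / N_{px}) / f$, inflated
by $1/\cos^2\theta$ under tilt $\theta$; a camera tilted $\theta$ spans
across-track from $H\tan(\theta - \phi)$ to $H\tan(\theta + \phi)$ with
half-FOV $\phi = \arctan(w_s / 2f)$.

Footprints are the quadrilaterals of the four projected sensor corners
(no lens distortion; the polarising filter has no geometric effect).
Because they are convex, all area accounting is exact: pairwise overlap
by Sutherland–Hodgman clipping, dissolved coverage (ground covered by at
least one frame counted once) by incremental inclusion–exclusion over
convex intersections, and the on-ground image width as the longer side
of the minimum-area bounding rectangle via rotating calipers over the
convex hull. No GIS dependency is needed; union area is exact rather
than rasterised.

Two conventions worth noting:

* **Side-lap** between the two cameras' dissolved coverages is the
  intersection area divided by the per-camera coverage area; the two
  per-camera areas are equal by design and the implementation divides by
  their mean.
* **Minimum-rectangle width** can flip between exactly tied minimal
  rectangles under rotation; the rectangle *area* is the tie-stable
  invariant and is what the property tests assert for random polygons.

Capture scheduling inverts the forward-lap: the interval is
$H h_s / f \cdot (1 - \text{lap}) / v$. For a tilted camera the true
area forward-overlap of scheduled frames slightly exceeds the nominal
lap (the oblique swath is longer than the nadir swath); this is a real
geometric effect, not an implementation artefact.

The observers' sampled area scales with altitude: segment area =
(mean altitude / 152 m) x segment length x (206 + 203) m. Observer
sightings are mapped at the centre of the called 50 m zone, abeam of the
aircraft position interpolated at the call time, with the lateral offset
scaled by the same altitude fraction.

## Sighting resolution

Animals appear in multiple frames where footprints forward- or
side-lap. Two detections in distinct images are linked as one
individual when their ground positions agree within a tolerance
(default 5 m, about 150 px at a 3.2 cm GSD — a stationary-animal
assumption over the 2–3 s between overlapped frames) *and* both lie in
the frames' overlap region. Links form a forest, so
`unique + links = raw` holds exactly.

Groups are defined by the 200 m chain rule: single-linkage connected
components of the threshold graph (distances exactly at the threshold
link). For imagery the chain runs over individual positions; for
observers — whose group positions are coarse zone-centre points — the
chain runs over plotted centroids and merged sizes are summed, with the
front seat's size kept on conflict (the more experienced observers).
Front- and back-seat calls are matched greedily within a time window
with zone agreement, smallest time difference first, ties by zone
proximity then earlier call; matched pairs become capture history
(1,1), unmatched calls (1,0) or (0,1).

## Perception bias

Capture histories $\omega$ over $T$ occasions (two observer seats, or
three image reviewers) are modelled by the Huggins conditional
likelihood,

$$L = \prod_\omega \frac{\prod_i p_i^{\omega_i}(1-p_i)^{1-\omega_i}}
  {1 - \prod_i (1 - p_i)},$$

which conditions on detection by at least one occasion so abundance
drops out. Probabilities are logit-linear in the model structure
(constant, by occasion, by aircraft side, saturated) plus optional
group-level covariates (size bin 1 / 2–3 / 4+, water visibility, sun
glitter). Fitting is quasi-Newton (BFGS) with multiple starts at logits
−1, 0, 1, analytic gradient, and observed-information standard errors;
boundary fits ($|\hat\eta| > 9$) are flagged, since their information
matrix degenerates. Model selection uses
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with near-ties broken
toward fewer parameters.

The combined probability that at least one occasion detects a group is
$\hat p_d = 1 - \prod_i (1 - \hat p_i)$, with a delta-method standard
error using the full estimated covariance of $\hat p$ (independence is
assumed only when no covariance is available). The two-occasion MLE has
the closed form $\hat p_1 = n_{11}/(n_{01}+n_{11})$,
$\hat p_2 = n_{11}/(n_{10}+n_{11})$, used as an independent oracle.

## Minimum-detections simulation

To ask how many detections are needed for a usable perception estimate,
histories are drawn i.i.d. from the conditional distribution
$P(\omega \mid \ge 1 \text{ detection})$ for every combination of
per-reviewer probabilities on the grid 0.4–1.0 (step 0.1) and a ladder
of detection totals, and the per-occasion model is refitted per
replicate. The grid crosses 7 probabilities per reviewer with 8
detection levels: 392 scenarios for two reviewers, 2,744 for three.
The exact detection ladder is configurable; the default
{5, 25, 65, 125, 205, 300, 400, 500} spans 5–500 with increments
growing from 20 to 100, matching the stated grid sizes.

Precision is summarised as the across-replicate CV (SD/mean) of each
occasion's $\hat p$, reported per occasion and averaged. The "CV stops
improving" point is operationalised as the smallest detection level
whose CV is within 10% of the total decline of the final level's CV —
the source criterion is verbal, so the rule is a package choice. Note
the CV itself scales as $1/\sqrt{n}$ (there is no literal plateau);
"asymptote" refers to the absolute flattening of the curve.

## Count models

The sample unit for platform comparison is the transect segment: a
maximal run of constant water-visibility score along a transect, shared
by both platforms. Each segment carries per-platform areas
(altitude-corrected strips for observers, clipped dissolved coverage
for imagery), mean Beaufort sea state from the 1 Hz GPS track,
per-platform mean sun glitter (imagery glitter from the sun-side camera
only), okta cloud cover and its binary form (any okta > 0 counts as
cloud — the cut is configurable because the source leaves it
unidentifiable), and deduplicated certain-only counts.

Counts per segment are modelled as Tweedie (compound Poisson–gamma,
variance $\phi\mu^p$ with $1 < p < 2$) with log link and log-area
offset — zeros are common and animals arrive in groups, so
extra-Poisson variation is structural. The variance power is profiled
on a grid (default 1.1–1.9 by 0.05) by exact profile likelihood: at
each power the quasi-GLM is refitted and the compound Poisson–gamma
density is maximised over the dispersion. Poisson-like data push the
profile to the lower grid edge and gamma-like data to the upper edge
(both raise a widen-grid warning). Flight, and transect nested in
flight, enter as random intercepts fitted by penalised likelihood
through random-effect smooths (exchangeable within level — compound
symmetry); without random terms the model is a direct IRLS quasi-GLM.

Group sizes (always $\ge 1$) use a zero-truncated Poisson with log link
on the untruncated rate $\lambda$, fitted by ML with analytic gradient;
the fitted mean is $\lambda/(1-e^{-\lambda})$ and the intercept-only
score equation reproduces the sample mean exactly. Random effects are
not available for the truncated family in this stack; where grouping
factors matter they can enter as fixed blocks. Backwards selection
drops the least significant removable term by Wald test at
$\alpha = 0.05$, never removing a main effect while an interaction
containing it remains.

## The synthetic world

The generator is the package's stated world, fixed up front:

* transects 4.6 km apart, due north, in a local planar metric frame;
* group centroids a Poisson process (default 0.5 groups/km²) in a 1 km
  band per transect; sizes zero-truncated negative binomial (size 0.8,
  mean parameter 1.6 — the literal stated default; its zero-truncated
  mean is ≈2.7, on the heavy side of observed dugong group-size means);
  members uniform in a 100 m disc so a 200 m chain rule cannot split a
  generated group;
* detection is one Bernoulli per group per occasion. The per-individual
  phrasing of the forward model is inconsistent with per-occasion
  probability recovery (a group of $k$ would be detected with
  $1-(1-p)^k$), so the group-level reading is implemented: a detecting
  occasion records all covered members;
* attitude noise Normal with 2° SD on pitch/roll, 1° on azimuth (crab),
  3 m on altitude — typical small-UAV jitter;
* visibility piecewise constant with exponential run lengths (mean
  5 km), sea state a slow random walk on the 1 Hz track, glitter runs
  per platform, one okta per transect drawn mostly clear or heavily
  overcast;
* availability is a single Bernoulli per group per platform, default 1,
  so perception estimates can be tested unconfounded.

What a green test does *not* establish: real dugong movement, diving or
clustering behaviour; tides, turbidity physics or depth structure;
observer fatigue or heterogeneity beyond the seat effect; real camera
distortion or georeferencing error. The generator exists to verify the
estimators against known truth, not to imitate Shark Bay.

Two behaviours of the real method surface in the synthetic world and
are deliberate: at high density the 200 m chain rule merges distinct
groups, inflating apparent reviewer probabilities (a merged group
counts as detected if either part was seen); and the platform tally
uses a single reviewer's pass (the full image set is reviewed once in
practice), while all reviewers feed the capture histories on the shared
subset.

## Numerical choices

* Reproducibility: every generator takes a seed; stage seeds derive
  from one master seed by a fixed affine map below $2^{31}$; a rerun
  with identical config and seed reproduces byte-identical files.
* Optimisers: BFGS with relative tolerance $10^{-12}$ (Huggins, ZTP);
  IRLS epsilon $10^{-10}$ (Tweedie); boundary logits flagged at 9; ZTP
  linear predictors clamped at 30 to avoid overflow on divergent
  interim steps.
* Geometry tolerances: intersections below $10^{-9}$ m² are treated as
  empty; point-in-polygon uses an edge tolerance; segment boundaries
  fall midway between the last image of one visibility run and the
  first of the next.
* Missing covariates in short segments are imputed from the nearest
  scored point on the transect, with a message.
* Groups whose centroid falls outside all segments snap to the nearest
  segment, with a message.

## Known limitations

* The Tweedie random-intercept fit is penalised likelihood, not the
  exact marginal likelihood of a dedicated compound-Poisson mixed-model
  package; variance components near zero are reported as such rather
  than tested.
* The ZTP model has no random effects (see above).
* Deduplication is $O(n^2)$ per image set and intended for survey-scale
  detection counts (hundreds), not millions.
* The chain rule is applied per transect; groups straddling two
  transects (4.6 km apart) cannot occur in the stated world.
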