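---
title: "Methods: from raw location fixes to mobility phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw location fixes to mobility phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geopheno)
```

## The problem

Smartphone location traces are irregularly sampled, noisy point streams:
each fix is a timestamp, a WGS84 coordinate, and an accuracy value
conventionally defined as the radius containing the true position with
68% probability. A single fix says nothing about behavior. Behavioral
meaning emerges only after *contextualization*: deciding which runs of
fixes represent staying at a place (stationary states), which represent
travel (non-stationary states), and which stationary states across days
are visits to the same real-world place (recurrent stationary states).
`geopheno` implements this contextualization and the mobility phenotypes
built on it, plus a labelled simulator so every stage can be validated
without access to sensitive real traces.

## Preprocessing model

### Accuracy filter and gap segmentation

Fixes whose confidence radius exceeds `max_confidence_m` (default 200 m)
are dropped before any inference; fixes with *missing* confidence are
kept by default, because silently discarding sparse data would bias
every downstream count. Traces are then split wherever the gap between
consecutive fixes exceeds `max_gap_min` (default 60 min): a gap at least
as long as the stay-point duration threshold cannot be confidently
labelled stationary, so no stay point is allowed to bridge it.

### Stay-point detection (anchor sweep)

Within each gap-free segment the detector sweeps an anchor index *i*:
the window grows over fixes *j* while the haversine distance from the
anchor stays within θ_d; at the first violation (or segment end) the
window *i..j−1* becomes a stay point if its time span is at least θ_t,
and the anchor jumps to *j*; otherwise the anchor advances one fix.
Defaults are θ_t = 60 min and θ_d = 350 m — a stay point is a group of
coordinates remaining stationary for an hour within a 350 m area.

Choices that the algorithm's classic form leaves open are fixed as
follows, because each affects which episodes exist at all:

* **Anchor distance test.** Distances are measured to the window's
  *first* fix, not the pairwise diameter. Pairwise-diameter variants
  exist; the anchor form is kept because it makes the sweep exactly
  reproducible and cheap.
* **Inclusive duration.** The test is span ≥ θ_t, so a dwell lasting
  exactly 60 min qualifies.
* **Trailing windows.** A window truncated by the end of a segment is
  still emitted when its span reaches θ_t; otherwise every dwell
  interrupted by a data gap would vanish.
* **Centroid.** The unweighted arithmetic mean of member coordinates.
  Confidence-weighted centroids are a plausible extension but introduce
  a dependence on the noise model that the rest of the pipeline never
  needs.

All distances use the haversine formula on a sphere of mean radius
6 371 008.8 m; coordinates are never projected.

### Recurrent places (DBSCAN, min_points = 1)

Stay-point centroids are clustered with DBSCAN under the haversine
metric with radius ε (default 150 m). `min_points` defaults to 1: every
stay point is then a core point, clusters are exactly the connected
components of the ε-neighborhood graph, and *no visit is discarded as
noise* — necessary because "unique places visited" must count
single-visit places. Recurrence is instead expressed per cluster as
`is_recurrent = n_visits >= 2`. Cluster ids are canonicalized by each
cluster's earliest arrival, which makes labels invariant to input
permutations.

The known limitation of a fixed ε is inherited: two genuinely distinct
venues closer than ε are merged into one entity, because ε exists to
absorb the positional scatter of repeated visits to one venue.

`tune_epsilon()` supports choosing ε against labelled data: for each
candidate radius it clusters each subject's stay points, scores
agreement with the true place labels by the Adjusted Rand Index, and
reports the across-subject mean with its standard error
(SD/√n subjects). ARI is computed per subject and then averaged — the
alternative (pooling all subjects into one partition) would let
large-trace subjects dominate the curve. The implementation uses the
contingency-table form of ARI and is verified in the test suite against
exhaustive pair counting and against an independent library
implementation.

### Home inference

The home is inferred by a predefined rule: the cluster with the largest
total stay-point dwell overlapping the nightly window, 00:00–06:00 local
time by default, summed over the whole observation period. Ties break
deterministically toward larger total dwell, then earlier first visit.
If no dwell overlaps any night, home is flagged undetermined and the
home-stay phenotypes are emitted as missing rather than guessed. The
window is expressed as fixed offsets from local midnight; windows that
wrap midnight (e.g. 22:00–06:00) are supported.

## Phenotypes

* **Counts.** Places visited (stay points), unique places (distinct
  clusters), trajectories — per local day and as window totals. A visit
  is counted once, on its arrival day; a trajectory on its start day.
* **Home stay.** Hours and percentage at the home cluster per day.
  Unlike counts, *time* is attributed to days proportionally, so a
  dwell spanning midnight contributes its actual hours to each day and
  daily hours can never exceed 24. The percentage denominator is total
  stay-point dwell that day (default): smartphone duty-cycling makes
  elapsed wall-clock time unreliable as a denominator. The alternative
  (`homestay_denominator = "elapsed"`, percent of the 24-h day) is
  provided for sensitivity analyses. Days with zero dwell yield a
  missing percentage.
* **Normalized entropy.** −Σ pᵢ ln pᵢ / ln N over per-place dwell
  proportions, with the single-place case defined as 0 (the natural
  limit: all time at one place is minimal variability). Natural
  logarithms; the normalization makes the measure dimensionless in
  [0, 1] and independent of the log base. Window-level entropy uses the
  window's full dwell distribution; per-day entropy uses each day's
  overlap-apportioned distribution.
* **Diurnal movement.** The stay-point centroid sequence is resampled
  onto a regular grid (default 10 min), carrying the last known place
  through travel and through gaps up to `max_gap_min`, leaving longer
  gaps missing. A least-squares (Lomb) periodogram — appropriate for
  series with missing samples — is computed for the latitude and
  longitude series separately, power is summed over periods in
  23.5–24.5 h, and the score is ln(E_lat + E_lon). Higher scores mean a
  more 24-h-repetitive routine. The scale is internal (degrees-based
  series, natural log): scores are comparable between subjects processed
  with identical settings, not against other implementations with
  different scalings, so the package asserts only ordering and contrast
  properties for this phenotype. Degenerate series (e.g. constant
  location) are floored at ln 10⁻¹², and subjects with fewer than 3 days
  of data yield a missing value.
* **Duration adjustment.** Window-total counts grow mechanically with
  observation length, so `adjust_counts_for_duration()` regresses each
  count on days observed across the cohort and returns residual + grand
  mean; residuals are exactly orthogonal to the duration regressor, and
  the grand-mean shift keeps the adjusted values on the raw scale. When
  all subjects were observed equally long the model degenerates to its
  intercept and the adjustment is the identity (with a warning).

## The simulator: what it emulates, and what it does not

`simulate_subject()` generates a daily routine over a small set of
places with a designated home: overnight home occupancy (probability
`p_home_night`, default 1), a morning departure, 2–4 daytime visits
(dwells of 90–180 min by default) joined by straight-line travel legs
at 8 m/s, and an evening return. Dwell and travel episodes tile the
simulated span exactly, which the ground-truth tables rely on. Sampling
is at a 5-min interval with bursty dropout (two-state Markov chain;
10% long-run loss, 15-min mean bursts). Positional noise is
radial-Gaussian with scale σ = confidence / √(−2 ln 0.32) ≈
confidence/1.5096, so the 68th percentile of the radial error equals
the per-fix confidence — honoring the smartphone accuracy convention.
Per-subject mean confidences are drawn from 25–170 m, matching the
range of per-subject means reported for real smartphone cohorts; places
are at least 600 m apart by default.

The simulator deliberately omits: road networks (travel is
straight-line), multipath/urban-canyon error structure (noise is
isotropic and independent across fixes), device duty-cycling beyond the
Markov dropout, and within-building movement. Passing recovery tests on
this generator therefore demonstrates the pipeline's correctness under
clean dwell/travel structure with realistic noise magnitudes — not its
performance on adversarial real-world traces, where accuracy can only be
established with user-confirmed labels.

## Numerical and degenerate-input conventions

* Timestamps are epoch milliseconds UTC; local-day logic goes through
  one IANA timezone per subject, and a local day is midnight-to-midnight
  (DST days keep their civil length of 23 or 25 h).
* Duplicate timestamps keep the first fix; out-of-bounds coordinates are
  dropped and counted in a load report.
* Segments with fewer than 2 fixes yield no stay points; empty traces
  and empty filter results are legal everywhere downstream.
* ARI's chance-correction denominator vanishes when both partitions are
  all-singletons or both one block; both cases mean identical
  partitions, and 1 is returned.
* Home-stay percentages are clamped to [0, 100] against ulp-level drift
  in the ratio of two overlap sums.
* All randomness in the simulator flows from a single integer seed per
  subject; cohort seeds are derived deterministically from one master
  seed.

## Problem sizes used in validation

The test suite and the acceptance script run entirely on simulated
cohorts chosen to exercise every code path at desk scale: property
checks use segments of up to 50 fixes (where brute-force oracles are
exact), recovery checks use cohorts of 5–20 subjects × 14 days at 5-min
sampling (~4 000 fixes per subject), and ε-tuning uses 4–5 subjects over
a 7-value grid. These sizes were chosen so the full validation runs in
minutes on a single core while keeping every statistical check
well-powered; the pipeline itself is linear in trace length per anchor
sweep and has no practical limit near these sizes.

## Known limitations

* Movement *within* a stationary place (inside a building) is invisible
  to stay-point logic by construction; phenotype interpretation is
  limited to between-place mobility.
* Very precise traces interact unfavorably with a fixed θ_d: when the
  positional scatter is far below θ_d, brief genuine excursions shorter
  than θ_t still reset the anchor rarely, while jittery boundary fixes
  can split dwells on noisy data. Whether θ_d should adapt to per-fix
  confidence is left open; both thresholds are plain configuration.
* The home heuristic assumes the subject predominantly sleeps at one
  place within the night window; shift workers violate this assumption
  and would need a different window (configurable) or rule.
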