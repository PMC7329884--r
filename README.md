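# geopheno

Behavioral phenotypes from smartphone location traces.

Passively collected smartphone GPS data is increasingly used to quantify
human mobility in neuropsychiatric research ("digital phenotyping"), but a
raw location fix carries almost no behavioral meaning on its own.
`geopheno` implements a preprocessing framework that enriches raw traces
with context — stationary states, non-stationary states, and recurrent
stationary states — and derives from them a set of per-subject mobility
phenotypes that are sensitive to clinically relevant behavioral
differences (e.g. time spent at home, number of unique places visited).
It is aimed at researchers who collect longitudinal location data and
need validated, reproducible preprocessing before any group-level
statistics.

## What it computes

**Context enrichment.**

1. *Stay-point detection.* A stay point is a maximal run of fixes that
   remains within a distance threshold θ_d of its anchor fix for at least
   a time threshold θ_t (defaults θ_t = 60 min, θ_d = 350 m; inclusive
   duration test; haversine distances on a sphere of radius
   6 371 008.8 m). Fixes inside stay points are *stationary*; the runs
   between them are *non-stationary* trajectories.
2. *Recurrent-place clustering.* Stay-point centroids are clustered with
   DBSCAN under the haversine metric (default ε = 150 m, min_points = 1),
   so repeated visits to the same real-world place become one entity.
3. *Home inference.* The home is the place cluster with the largest total
   dwell overlapping a nightly window (default 00:00–06:00 local).

**Phenotypes**, per local day and per observation window:

| phenotype | definition |
|---|---|
| places visited | number of stay points |
| unique places | number of distinct place clusters visited |
| trajectories | number of non-stationary runs |
| home stay | hours and % of dwell time at the home cluster |
| normalized entropy | −Σ pᵢ ln pᵢ / ln N over per-place dwell proportions (0 when N = 1) |
| diurnal movement | ln of the Lomb–Scargle spectral energy of the location series in the 23.5–24.5 h period band |

Window-level count phenotypes can be adjusted for unequal observation
length via residuals of a linear model on days observed
(`adjust_counts_for_duration()`).

**Evaluation.** Because every stage can drift silently on real data, the
package ships a deterministic synthetic trace simulator
(`simulate_subject()`, `simulate_cohort()`) that emits ground-truth
labels — per-fix state, per-episode place, home identity — together with
episode-level stay-point accuracy, place-clustering accuracy, Adjusted
Rand Index, and ε-tuning (`tune_epsilon()`) against those labels.
Positional noise honors the smartphone convention that a fix's
"accuracy" is the radius containing the true position with 68%
probability.

## Worked example

```r
library(geopheno)

s  <- simulate_subject(seed = 42, n_days = 14)   # labelled synthetic subject
ph <- derive_phenotypes(s$trace, geopheno_config())
ph$summary
#> # A tibble: 1 × 14
#>   subject_id n_days_observed places_visited unique_places trajectories
#> 1 S1                      15             53             4           30
#>   home_stay_hours home_stay_pct normalized_entropy diurnal_movement
#> 1            16.5          75.9              0.588            -3.90
```

The simulated subject visited 53 places over the window (53 stay points),
of which 4 were distinct real-world places, and made 30 trips. They spent
on average 16.5 h/day (75.9% of accounted dwell time) at the inferred
home cluster; the normalized entropy of 0.588 reflects dwell time
concentrated at home but spread over several daytime places, and the
diurnal-movement score summarizes how 24-h-periodic the movement routine
is (comparable between subjects processed with the same settings).

Because the subject is simulated, every stage can be scored against the
ground truth:

```r
evaluate_cohort(list(s))$summary
#>   n_subjects staypoint_accuracy_mean clustering_accuracy_mean home_accuracy_pct
#> 1          1                     100                      100               100
```

A thin command-line interface over the same functions is installed at
`system.file("cli", "geopheno.R", package = "geopheno")` with subcommands
`simulate`, `detect`, `cluster`, `tune-eps`, `phenotype`, and `run`.

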