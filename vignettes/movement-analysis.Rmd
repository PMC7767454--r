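---
title: "Movement-pattern analysis for paddock-scale GPS herds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-pattern analysis for paddock-scale GPS herds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdmove)
```

`herdmove` describes the movement of GPS-collared cattle confined to a small
paddock and segments their relocations into behavioural states. This
vignette is the package's account of its science: the generative model
behind the synthetic herds, the movement variables, the clustering and
validation machinery, the statistical layer, the numerical conventions, and
the limits of what the package's own tests demonstrate.

## The setting

The design target is a paddock-scale deployment: a cohort of 11-14 weaned
calves in a fenced 105 m × 30 m ryegrass paddock, each wearing a consumer
GPS logger set to a 20-s fix interval with ~4.4 m positional accuracy. Two
device behaviours dominate the data and shape every method choice:

1. **Power saving.** The logger stores on the order of 2,700 points per
   fortnight — two orders of magnitude fewer than a continuous 20-s stream.
   Surviving fixes are therefore irregular, and elapsed time between
   relocations ranges from the nominal 20 s to tens of minutes.
2. **Positional noise.** 4.4 m RMS error is comparable to the distance a
   slow animal moves in 20 s, and noise routinely places fixes outside the
   physical fence.

## The synthetic herd generator

No paddock deployment of this kind is publicly deposited, so the package
ships a generator (`simulate_herd()`) whose defaults are the study
conditions above; it provides per-fix ground truth (latent state, true
position, drawn speed) for calibration and testing.

**Behavioural model.** Each animal follows a three-state first-order Markov
chain at the fix interval over resting (code 1), traveling (2) and foraging
(3). Within a state the animal performs a correlated random walk: the
per-step speed is gamma-distributed with state-specific mean and dispersion
(dispersion = squared coefficient of variation), and the heading change is
wrapped-Cauchy with state-specific concentration ρ (ρ = 0: uniform turns;
ρ → 1: straight-line persistence). This is the standard discrete-time
correlated-random-walk formulation for state-switching movement.

**Defaults and why.** Values the device or deployment fixes: 20-s interval,
4.4 m radial RMS noise (isotropic bivariate Gaussian, per-axis σ = 4.4/√2),
105 × 30 m rectangular paddock centred at 27.5523° S, 152.3335° E, 14-day
duration, 14 collared animals with a 3/14 per-animal logger-failure
probability. Values the biology fixes only loosely, chosen once as
realistic for concentrate-fed weaned calves and then frozen:

| parameter | resting | traveling | foraging | rationale |
|---|---|---|---|---|
| mean speed (m/s) | 0.01 | 1.7 | 0.5 | near-stationary lying/ruminating; brisk walk; slow feeding walk |
| speed dispersion (CV²) | 1 | 0.35 | 0.7 | bursts are more stereotyped than idling |
| turn concentration ρ | 0 | 0.85 | 0.5 | rest has no heading; travel is goal-directed; foraging is tortuous |
| mean dwell | 90 min | 1.5 min | 6 min | lying bouts of an hour-plus; pen crossings take ~1 min |

The 20-s transition matrix (`default_transition_matrix()`) is derived from
those dwell times with exit splits resting → (travel 3/4, forage 1/4),
travel → (rest 3/10, forage 7/10), forage → (rest 7/10, travel 3/10); its
stationary distribution spends roughly 92 / 2 / 6 % of time in
rest/travel/forage, i.e. ~22 h of daily inactivity.

**Diel cycle.** Herds of this kind are most active in the afternoon and
evening and least in the morning. `diel_modulation()` is a raised cosine,
`1 + A·cos(2π(t − 66600)/86400)` (t in seconds of local time), peaking at
18:30 and integrating to exactly 1 over the day; it multiplies the
probability of *leaving* the resting state, so amplitude redistributes
activity across the day without changing its daily total. Default A = 0.8;
A must stay in [0, 1] so the multiplier remains positive.

**Power saving as state-dependent thinning.** The generator models the
logger's duty cycle as independent per-fix dropout with a *state-dependent*
probability, default (0.988, 0.20, 2/3) for rest/travel/forage. This is the
motion-triggered behaviour of real power-saving loggers — the device mostly
sleeps while the animal rests and samples densely while it moves — and it
reproduces two observed signatures at once: a 14-day track emits ≈ 2,668
fixes (the device capacity), and resting is strongly under-represented in
the emitted fixes even though it dominates time. A state-*independent*
thinning tuned to the same capacity would leave mean gaps of ~7.5 min in
every state; over such gaps displacement in a 105 × 30 m pen saturates at
pen scale, which erases the distinction between the two moving states
entirely. State-dependence is therefore a structural requirement, not a
tuning knob.

**Confinement and reflection.** The true path is folded back into the
paddock rectangle (exact multi-fold reflection per axis); for non-rectangular
fences, stray proposals are additionally pulled to the boundary along the
segment towards the polygon centroid by bisection. After reflection the
heading is reset to the realized displacement direction. GPS noise is added
*after* confinement, so true positions are always inside the fence while
observed fixes may leave it — exactly the noise that geofence filtering
removes downstream.

**What the generator does not emulate.** No attraction to feeder, water or
shade (no micro-habitat structure); no social behaviour; no weather or
estrus; no heteroscedastic or autocorrelated GPS error; dropout is
independent given the state rather than scheduled. Tests passing on this
generator therefore demonstrate the pipeline's correctness and its
behaviour under realistic sampling — not that real herds will cluster the
same way.

## Movement variables

- **Step distance** (m): great-circle (haversine) distance between
  successive fixes, sphere radius 6,371,000 m. At paddock scale the choice
  of sphere vs ellipsoid is irrelevant against 4.4 m noise.
- **ROM** (m/s): distance divided by the *actual* elapsed seconds of the
  step — with a power-saving logger the nominal interval would be wrong by
  an order of magnitude.
- **Turning angle** (rad): signed smallest rotation between successive step
  headings, in (−π, π]; headings are measured in a local planar
  (equirectangular) frame, east = 0, counter-clockwise positive, so
  positive angles are left turns. A zero-length step has no heading, and
  any turning angle touching one is missing rather than zero.
- **Linearity ratio** (unitless in [0, 1]): net displacement over path
  length in a sliding window of 30 consecutive steps, assigned to the
  window's central step. A per-step version is identically 1; the window
  makes the ratio measure tortuosity at the ~10-minute scale (at nominal
  sampling) and yields the very small values characteristic of confined
  tortuous movement. 30 steps is a package default, not a law; it is
  configurable everywhere.
- **Geofence filter**: fixes strictly outside the fence polygon dilated by
  a buffer (default 4.4 m, one GPS error) are removed before any feature is
  computed.

Standardization (per-column z-scores) is on by default before clustering:
the four variables span four orders of magnitude, and both clustering
algorithms are scale-sensitive.

## Clustering and validation

`ward_linkage()` implements agglomerative Ward clustering via the
Lance–Williams recurrence on squared Euclidean distances; merge heights
equal twice the increase in total within-cluster sum of squares (the
squared-distance convention; `stats::hclust(d^2, "ward.D")` agrees
exactly, and the test suite verifies both that identity and equality with
a naive minimum-variance oracle that recomputes every cluster variance at
every step). Ties merge the lexicographically smallest index pair, making
trees deterministic. `kmeans_hartigan_wong()` implements Hartigan's
single-point transfer criterion with incremental centroid updates; an
initially empty cluster is re-seeded from the point farthest from its own
centroid, and the best of 25 random restarts (seed-derived) is kept. On
every random instance small enough to enumerate, the returned WCSS equals
the exhaustive-partition optimum.

Internal validation uses plain Euclidean distances on the standardized
features: **connectivity** (Σ over points of 1/j for each j-th nearest
neighbour in a foreign cluster, j ≤ 10; lower better), **mean silhouette
width** ((b−a)/max(a,b); singletons and 0/0 scored 0), and the **Dunn
index** (minimum between-cluster separation over maximum cluster diameter;
all-singleton diameter 0 returns Inf). `select_clustering()` fits every
(method, k) candidate, ranks the three measures (connectivity ascending,
the others descending) and returns the best mean rank, breaking residual
ties towards smaller k. Hierarchical clustering on more than 10,000 rows
works on an animal-stratified subsample (an O(n²) memory guard) with the
remaining rows assigned to the nearest centroid; K-means always uses the
full table.

Raw cluster indices are arbitrary, so `relabel_clusters()` renumbers the
selected k = 3 solution by mean ROM — slowest → 1 (resting), fastest → 2
(traveling), intermediate → 3 (foraging); any other k is numbered 1..k by
ascending mean ROM. All reported cluster numbers follow this convention.

### How many clusters does validation actually choose?

On the default synthetic herds the three-measure rank aggregation
consistently selects **k = 2**, splitting fast traveling from everything
slow, rather than the three generative states. The package's acceptance
test computes this openly. The mechanism is worth understanding:
capacity-limited sampling leaves the resting state observed only over long
gaps (tens of minutes), across which the resting and foraging signatures
overlap in measured distance and ROM; roughly a quarter of moving-state
rows are bout-entry steps whose elapsed time spans a preceding rest, further
filling the valley between the two slow modes; and the signed turning angle
has mean zero in every state (states differ in its *dispersion*), so a
Euclidean clustering sees it as a noise axis. Connectivity is monotone
increasing in k on overlapping data, so the aggregation tips to the
smallest candidate. With well-separated inputs the same machinery picks the
true count (the test suite demonstrates k = 3 recovery on three Gaussian
blobs). The practical lesson the package surfaces: at this duty cycle,
internal validation alone should not be expected to resolve three
behavioural states at paddock scale — a finding to keep in mind when
interpreting three-state analyses of similarly thinned field data.

## Statistical layer

- **Spearman's rho** is the Pearson correlation of mid-ranks, with the
  t-approximation p-value `t = ρ√((n−2)/(1−ρ²))` — standard at thousands of
  relocations. Constant inputs yield a missing value, not an error.
- **Repeated-measures ANOVA**: each movement variable is tested between
  clusters with the animal fitted as the error term, i.e. sequential
  (Type-I) sums of squares entering animal first:
  SS_total = SS_animal + SS_cluster + SS_error,
  F = MS_cluster/MS_error on (k−1, n−k−m+1) df. Degrees of freedom are
  reported from the package's own row counts. A zero-variance response
  returns F = 0, p = 1. The suite verifies the decomposition against
  explicit residual arithmetic and checks type-I calibration: on 1,000 null
  simulations (animal effects present, no cluster effect) the rejection
  rate at α = 0.05 must stay within 5 ± 2 %.
- **Chi-squared homogeneity** of per-cluster relocation counts against an
  equal-expectation null, df = categories − 1.
- No multiple-testing adjustment is applied; raw p-values are reported.
- The **summary table** reports mean (SD) and median (min, max) per
  variable, overall and per cluster, plus per-animal relocation counts.

## Numerical conventions and degenerate inputs

- Duplicate timestamps within an animal: first fix kept (Δt = 0 would make
  ROM undefined); the drop count is reported.
- Timestamps are stored in UTC; diel binning converts to a configured local
  zone (default UTC+10).
- Zero-length steps carry distance 0 and ROM 0 but produce missing turning
  angles; rows missing any variable are excluded from clustering and
  counted.
- Silhouette 0/0 → 0; Dunn with zero diameter → Inf; K-means moves are
  accepted only when they beat the incumbent by more than 1e-12 to keep the
  iteration deterministic under floating-point noise.
- Every stochastic entry point (`simulate_herd`, `kmeans_hartigan_wong`,
  `select_clustering`, `run_pipeline`) is a pure function of its seed and
  restores the caller's RNG state.

## Configuration and outputs

`run_pipeline()` orchestrates simulate/ingest → geofence filter → features
→ clustering and validation → relabelling → statistics, and
`write_bundle()` exports the labelled feature table, score table, summary,
hourly profile, correlation matrix and a JSON stats block; identical
configurations reproduce identical bundles byte for byte. Run
configurations can be written as YAML or JSON files (`read_run_config()`);
YAML/JSON were chosen because R parsers for them are universally available,
and every deployment constant (20-s interval, 4.4 m accuracy, 105 × 30 m
paddock, animal count, duration) appears as an explicit documented default.
GPX 1.1 and the `animal_id,timestamp,lat,lon` CSV dialect are the supported
interchange formats; the CSV layout is this package's canonical dialect
since logger-software exports vary.

## Problem sizes used by the test suite

The suite runs end-to-end on herds scaled to what makes the checks sharp
but quick: two-day, 11-animal herds (≈ 4,000 relocations) for cluster-count
recovery across ten seeds; one-day herds of 3-5 animals for pipeline
determinism and profiles; six-day, 10-animal herds (> 10,000 fixes) for
parameter recovery (per-state mean drawn speed within 15 % of its
configured value); and n ≤ 8 instances for the exhaustive clustering
oracles (100 Ward + 100 K-means + 100 validation labelings). These sizes
are the package's own choices for a fast, reproducible suite.

## Known limitations

- The behavioural model has no spatial preference structure; real herds
  concentrate around feeders, water and shade, which sharpens spatial but
  not necessarily kinematic state contrasts.
- The linearity window is defined in steps, so its time span varies with
  the logger's duty cycle; at heavy thinning it mixes states.
- Internal validation at heavy thinning prefers two clusters (see above);
  forcing `k_range = 3` reproduces a three-state description but then the
  count is assumed, not selected.
- The ANOVA treats relocations as exchangeable within animal × cluster;
  serial autocorrelation along a track is not modelled, so its p-values are
  anti-conservative on dense tracks.
- Coordinates more than ~1° from the paddock origin are rejected rather
  than reprojected; the package is deliberately paddock-scale.
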