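# herdmove

Movement-pattern analysis for GPS-tracked cattle in small paddocks.

Young cattle express their behavioural state through how they move: long
bedded rests, brief fast goal-directed walks to feed or water, and slow
tortuous searching while feeding. `herdmove` turns raw GPS fix streams from
collared animals into a quantitative description of those states. It is
aimed at animal-behaviour and precision-livestock researchers who have (or
want to prototype against) logger exports from a paddock-scale deployment —
fix intervals of tens of seconds, positional error of a few metres, and
loggers that thin their own sampling to save power.

## What it computes

**Per-relocation movement variables.** For each pair of successive fixes of
an animal: elapsed time Δt, great-circle step distance *d*, rate of movement
ROM = *d*/Δt (m/s), the signed turning angle θ ∈ (−π, π] between successive
step headings, and a windowed linearity ratio — straight-line displacement
over a sliding window divided by the path length travelled in it (1 =
perfectly direct, 0 = a closed loop). Fixes falling outside the paddock
fence (dilated by the GPS error) are removed first as positional noise.

**Behavioural segmentation.** Relocations are clustered on the standardized
variables (distance, ROM, linearity, turning angle) with two algorithms,
both implemented in compiled code:

- *Agglomerative Ward clustering*: squared-Euclidean dissimilarities updated
  after every merge with the Lance–Williams recurrence under Ward's
  minimum-variance coefficients,
  d(k, i∪j) = [(nᵢ+nₖ)d(k,i) + (nⱼ+nₖ)d(k,j) − nₖd(i,j)] / (nᵢ+nⱼ+nₖ),
  so each merge height equals twice the increase in within-cluster sum of
  squares.
- *Hartigan–Wong K-means*: single-point transfers accepted whenever the
  size-corrected change n_t/(n_t+1)·‖x−m_t‖² < n_c/(n_c−1)·‖x−m_c‖² lowers
  the total WCSS, run from many random starts.

Every (method, k) candidate is scored with three internal validation
measures — connectivity (lower is better), mean silhouette width and the
Dunn index (higher is better) — and the best mean rank wins. The selected
clusters are then renumbered by mean ROM to the conventional behavioural
codes: 1 = resting (slowest), 2 = traveling (fastest), 3 = foraging
(intermediate).

**Statistics.** Spearman rank correlations among the movement variables;
one-way repeated-measures ANOVA per variable with the animal fitted as the
error term (sequential sums of squares, animal first; F = MS_cluster /
MS_error on (k−1, n−k−m+1) df); a chi-squared test of homogeneity of
relocation counts across clusters; an overall + per-cluster summary table;
and an hourly activity profile in local time.

**Synthetic herds.** Because such deployments are rarely public, the package
includes a generative simulator: a three-state Markov chain at the fix
interval with gamma step lengths, wrapped-Cauchy turning kernels, reflective
confinement to the paddock polygon, a raised-cosine diel cycle that
modulates leaving the resting state (activity peaks in the
afternoon/evening), isotropic GPS noise, motion-triggered fix thinning and
whole-logger failure — with per-fix ground truth for calibration and
testing.

## Worked example

```r
library(herdmove)

cfg <- run_config(
  sim = sim_config(n_animals = 11, logger_failure_prob = 0,
                   duration = 2 * 86400, seed = 1),
  seed = 1
)
res <- run_pipeline(cfg)
print(res)
#> <herd_analysis>
#>   animals: 11 analysed, 0 dropped; 56 fix(es) outside geofence removed
#>   relocations: 3994 (complete feature rows: 3675)
#>   clustering: ward, k = 2
#>   mean ROM per cluster (m/s): 1: 0.285, 2: 1.453
```

Eleven simulated animals are tracked for two days in the default
105 m × 30 m paddock; 56 observed fixes fall outside the fence (GPS noise)
and are removed. The 3,994 relocations yield 3,675 rows complete in all four
variables. The validation table shows why two clusters were selected here:

```r
res$selection$scores[res$selection$scores$method == "ward", ]
#>   method k connectivity silhouette       dunn      wcss mean_rank
#> 1   ward 2     138.7452  0.3910495 0.02126012 10988.487  1.000000
#> 2   ward 3     333.9409  0.2644312 0.01897307  8940.780  3.666667
#> 3   ward 4     497.6726  0.2493898 0.01484267  7114.840  5.000000
#> 4   ward 5     593.7329  0.1984761 0.01259582  6597.829  7.333333
#> 5   ward 6     610.6210  0.2068417 0.01371157  6086.224  7.000000
```

Connectivity rises and silhouette falls with k, so the rank aggregation
prefers the coarse fast-vs-slow split: at this logger's duty cycle the two
slower states blur together (see the methods vignette for the full
analysis). After relabelling, cluster 1 is the slow (resting-like) state at
0.285 m/s and cluster 2 the fast traveling state at 1.453 m/s; the full
summary (`summary(res)`) reports mean (SD) and median (min, max) per
variable, overall and per cluster, with the attached ANOVA and chi-squared
tests, and `write_bundle(res, "out/")` exports everything as CSV/JSON.

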