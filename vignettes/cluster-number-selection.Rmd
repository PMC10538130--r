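---
title: "Selecting the number of posture clusters with SOMs and discriminant-score trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the number of posture clusters with SOMs and discriminant-score trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(somscore)
```

## The problem and the model

A skeleton tracker reduces a moving person to a time series of keypoint
coordinates: here 19 body points × 3 coordinates, a 57-dimensional feature
vector per frame, nominally at 15 fps. A *posture* is a region of that
space — trunk upright vs. leaning, arms extended vs. hanging — inside which
coordinates vary continuously without changing the posture's identity.
Grouping frames into postures without manual labelling is a clustering
problem, and the number of clusters is its critical free parameter: each
output neuron of a self-organizing map is one posture, so the map
architecture itself encodes the answer.

`somscore` trains a **1-D chain SOM**: `M` neurons, each with a weight
vector `w_m` of the data's dimension. Training is online. For each
presented frame `f`, the best matching unit (BMU) `b` is the neuron
minimizing `d(f, w_m)` under the chosen metric (cosine or Euclidean), and
every neuron moves by the additive Kohonen rule

```
w_m <- w_m + alpha(t) * exp(-(m - b)^2 / (2 sigma(t)^2)) * (f - w_m)
```

The chain topology is the smallest one in which neurons and clusters are in
one-to-one correspondence; a 2-D grid would decouple the neuron count from
the cluster count. The metric affects only the winner search: a
cosine-trained map groups frames by the *direction* of the configuration
vector (dominated by trunk inclination for whole-body skeletons), a
Euclidean-trained map by absolute joint positions (trunk *and* hand
placement). The update rule is additive in both cases — the conventional
choice when cosine matching is combined with Kohonen updates.

### Training schedule

All schedule parameters live in `som_config()` and are deliberately
explicit, because reproducibility of an online algorithm demands it:

| parameter | default | meaning |
|---|---|---|
| `epochs` | 50 | passes over the data |
| `lr0` → `lr_final` | 0.5 → 0.01 | learning rate, exponential decay |
| `sigma0` → `sigma_final` | `M/2` → 0.5 | neighbourhood radius (neuron-index units), exponential decay |
| `init` | `"uniform"` | weights i.i.d. on the data's per-dimension range; `"gaussian"` and `"sample"` available |
| `shuffle` | `TRUE` | re-draw presentation order each epoch |

Decay is `alpha(t) = lr0 * (lr_final/lr0)^(t/(T-1))` over the `T = epochs ×
N` presentation steps, so the final step uses exactly `lr_final`. A final
radius of 0.5 makes the neighbourhood essentially the winner alone by the
end, letting neurons specialize; a final learning rate of 0.01 freezes the
map rather than stopping it abruptly. All randomness (initial weights,
shuffles) is drawn from R's RNG before the compiled loop runs, so identical
`(data, config, seed)` give bit-identical weights.

## The validity indices

Five internal scores are computed per candidate `k`, in the specific
variants used in posture work; where a variant departs from the textbook
form this is deliberate and marked in the API.

- **Silhouette** `SC(i) = (b̄_min − ā) / max(ā, b̄_min)`, with `ā` the mean
  distance to co-members and `b̄_min` the best alternative cluster. One
  printed form of this coefficient orders the numerator `ā − b̄_min`, but
  the accompanying semantics (1 = well classified, negative =
  misclassified, range [−1, 1]) force the standard orientation, which is
  what `silhouette_values()` implements. Singletons score 0 by convention.
- **Dunn index, centroid variant**: numerator `min_{m≠m'} d(cc_m, cc_m')`
  over *centroids*, not the classical minimum over point pairs; denominator
  the largest cluster diameter. The centroid numerator makes the index
  cheaper and smoother but less sensitive to boundary overlap — it is kept
  because it is the variant this workflow is defined with, and it is
  labelled "centroid variant" throughout.
- **Davies–Bouldin, sum form**: `davies_bouldin()` defaults to the plain
  sum of per-cluster worst pairings (`variant = "paper_sum"`); the
  classical mean (`variant = "mean"`) is provided because reference
  implementations use it and because oracle tests cross-check against it.
  For fixed `M` the two differ by the constant factor `M` and rank
  clusterings identically.
- **Calinski–Harabasz**: the variance-ratio criterion, always Euclidean by
  definition, regardless of the training metric.
- **Quantization error**: mean squared point-to-BMU distance under the
  model's metric. It is a training diagnostic, not a selection criterion —
  it decreases mechanically as `M` grows.

Empty clusters (dead neurons) are *retained*: indices that cannot include
them skip them and the report carries a degeneracy flag, because a dead
neuron is itself evidence about the candidate `k`.

## The discriminant score

The per-frame membership score is, with `d_m` the distance from frame `f`
to centroid `cc_m`,

```
DS_m = (1/d_m) / sum_m' (1/d_m'),    DS_m = 1 if d_m = 0.
```

One printed form of this score divides the inverse distance by a *sum of
distances*; that reading is not implementable as stated — it exceeds 1 as
any `d_m` shrinks, contradicting the score's defining properties (range
[0, 1], 1 at a centroid, scores comparable across clusters). The
normalized-inverse form above is the unique reading consistent with all of
them, reduces to the zero-distance branch in the limit, and makes each
frame's scores a probability-like vector summing to 1. The tests pin the
limit behaviour explicitly.

Centroids default to the **data means of the SOM assignment** rather than
the raw neuron weights (the score is defined in terms of cluster
centroids); neuron weights are a selectable alternative, and they are also
the automatic fallback for clusters whose data-mean centroid is undefined
because the neuron never won — mirroring real maps, where "unknown" neurons
still carry weight vectors and trace flat, low trajectories.

Tracked over frames the scores form trajectories. The derived quantities
are:

- **winner**: per-frame argmax (ties to the lowest index), smoothed by a
  centered mode filter (`smooth_window = 5` frames by default, i.e. a third
  of a second at 15 fps — long enough to suppress single-frame chatter,
  short enough to displace no transition by more than 2 frames); edges are
  replicated, and mode ties also resolve to the lowest index.
- **transitions**: frames where the smoothed winner changes — the steep
  simultaneous fall/rise visible in the trajectories.
- **peak** per cluster: the maximum score over frames the cluster *wins*
  (0 if it never wins). The maximum over all frames is reported alongside
  (`peak_ds_all`), since a cluster can score moderately on frames it loses;
  the winning-frames version is what the selection rule uses, matching the
  "circled peaks" reading of the trajectories.
- **dwell fraction**: share of frames won.

## The selection rule

`recommend_k()` formalizes what a practitioner reads off the trajectory
plots: a candidate `k` is acceptable when *every* cluster corresponds to a
sustained, well-discriminated posture — minimum peak ≥ `theta_peak` and
minimum dwell ≥ `theta_dwell`. Among acceptable candidates the default rule
takes the **largest** `k` (avoiding the omission of rarer key postures); a
`best_min_peak` alternative takes the candidate whose weakest cluster is
strongest.

`theta_peak = 0.5` is calibrated on the worked peak table shipped as
`pick_place_peaks()`: it is the smallest round threshold that separates
that table's accepted candidates (weakest peaks 0.78 and 0.60) from its
rejected ones (0.44 at k = 5; 0.32 and 0.39 at k = 6), and it has a direct
reading — a cluster whose best frame is more similar to another centroid
than to its own is not a credible posture. `theta_dwell = 0.05` requires a
posture to persist for at least 5% of the recording; at the package's
default activity scripts (dwell 100, transition 10 at 15 fps) a genuine
posture occupies ~25% of frames while transition artefacts occupy ~2%, so
the threshold sits an order of magnitude below the former and safely above
the latter. Both thresholds are exposed in `selection_criteria()`.

The Calinski–Harabasz argmax is computed for every scan and reported with a
`ch_agrees` flag. The two criteria often coincide; when they do not, the
recommendation surfaces the disagreement instead of blending the scores —
there is no principled combination formula, and the audit trail lets the
analyst weigh the evidence.

## The synthetic generator

Real recordings of this kind are not redistributable, so the package ships
a generator whose defaults define the study conditions used throughout the
tests:

- `make_activity_sequence()` plays named archetype poses (five shipped:
  upright walking, leaning pick, leaning place, extended-hands walking,
  squatting; 19 joints in metres, human-scale geometry) with per-segment
  dwells (default 100 frames), linear inter-pose transitions (default 10
  frames), i.i.d. Gaussian keypoint jitter (default sd 0.01 m, typical
  tracker noise), and a sinusoidal forward offset on wrists, knees, ankles
  and feet (default amplitude 0.03 m, period 1 s) standing in for the gait
  cycle. Ground-truth labels switch at the interpolation midpoint, a
  symmetric convention that makes boundary-tolerance checks well defined.
- `make_gaussian_postures()` draws isotropic Gaussian clusters whose
  centres sit on a sphere of radius `separation × sd` about the origin,
  with mutual centre distances rejection-enforced to at least
  `separation × sd`. Placing centres *on a sphere* rather than anywhere in
  space is deliberate: it separates the clusters in direction as well as in
  distance, so the cosine metric — the one the posture maps are trained
  with — sees the same cluster structure the Euclidean metric does, and it
  mirrors real skeleton coordinates, which sit far from the camera origin.

What the generator does *not* model: bone-length constraints, joint-angle
limits, camera projection and occlusion, multi-person scenes, or
inter-subject variation. Passing tests on synthetic data therefore
demonstrate that the algorithms are implemented correctly and behave as
designed under controlled separation and noise — not that any particular
recording will yield four postures.

## Numerical and design choices

- **Indexing**: clusters, neurons and frames are 1-based throughout, the R
  convention; file outputs name score columns `ds_1..ds_M`. A transition
  index is the *first frame of the new regime*.
- **Ties**: every argmin/argmax (BMU search, winner, mode filter) breaks to
  the lowest index, making all pipelines deterministic.
- **Zero-norm vectors** are rejected under the cosine metric (an all-zero
  skeleton frame is corrupt input, not a case to patch), with a tolerance
  of `sqrt(.Machine$double.eps)` on the norm.
- **Euclidean distances** are computed by explicit differencing rather than
  the `||x||² + ||y||² − 2x·y` expansion; the expansion's ~1e-8 relative
  error is visible to the 1e-8-level oracle comparisons the index
  implementations are held to.
- **Degenerate inputs**: silhouette requires two non-empty clusters;
  all-singleton clusterings give Dunn `Inf` with a degeneracy flag;
  coincident centroids flag Davies–Bouldin and error the discriminant score
  (a frame cannot be at distance zero from two distinct centroids);
  `N ≤ M` errors Calinski–Harabasz. `compute_report()` converts component
  errors into `NA`-plus-flag rather than dropping indices silently.
- **Serialization** uses 17 significant digits, the minimum that
  round-trips IEEE doubles exactly; sequence CSVs use `%.17g` for the same
  reason.
- **Scan seeding**: `scan_k()` trains each candidate with
  `seed = base_seed + k`, so per-candidate results are independent yet the
  whole scan is reproducible from one integer.

## Problem sizes used in the shipped studies

The test suite exercises the pipeline at desk scale, chosen so the full
suite runs in about a minute and a half: oracle comparisons on 200 random
datasets (N ≤ 60, D ≤ 8, M ≤ 6); a 1000-dataset stress suite for the
discriminant score's range contract; cluster-count recovery on 4 Gaussian
posture clouds in 57 dimensions (separation 10 × sd, 100 points per
cluster, 50 seeds, candidates 3–6, cosine maps — the metric the posture
workflow trains with); transition tracking on 4-archetype scripts (dwell
100, transition 10, 20 seeds, ±5-frame tolerance); and SOM sanity checks
over 20 seeds. These sizes are the package's study conditions, not limits
of the implementation — the engine is compiled and handles
tens of thousands of frames comfortably.

## Known limitations

- The 1-D chain ties cluster count to neuron count by construction; it
  cannot represent cluster hierarchies or 2-D topographic relations.
- Data-mean centroids inherit any assignment instability of the underlying
  map; a restart mechanism (keeping the lowest-QE run) is not enabled by
  default because single-seed runs are the documented protocol.
- The selection thresholds are calibrated for trajectories of sustained
  activities; continuously morphing movement (dance, free gesture) has no
  dwell plateaus for the rule to find.
- Cosine matching is undefined at the origin, so root-centred preprocessing
  (`preprocess(mode = "center_root")`) should be combined with the
  Euclidean metric if the root joint itself can coincide with the origin of
  every axis.
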