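---
title: "Methods: simulated hierarchical federated learning for three-class nodule classification"
author: "fedlung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated hierarchical federated learning for three-class nodule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedlung)
```

## The problem and the model

`fedlung` is a desk-scale, fully deterministic simulator of a hierarchical
federated-learning (FL) pipeline for three-way lung nodule classification:
slices are labeled **normal** (no positive region of interest, RoI),
**benign** (a positive RoI with a smooth, non-expanding boundary) or
**malignant** (a positive RoI with active, irregular growth). Instead of
real CT volumes, the package generates synthetic grayscale slices whose
three classes reproduce the qualitative structure of that labeling, so the
entire pipeline — feature extraction, local training, client thresholding,
two-stage aggregation, evaluation — can be exercised and verified on a
single CPU in minutes.

The federation is two-tiered: client nodes $S_i$ hold data shards and
train local models; routing servers $SR_k$ each aggregate a disjoint
subset of clients; a central server $SX$ aggregates the router summaries.
Aggregation at both tiers is federated averaging — the weighted mean of
flat parameter vectors, with weights proportional to shard sizes:

$$\theta \leftarrow \frac{\sum_i w_i\,\theta_i}{\sum_i w_i}.$$

Because the weighted mean is associative, the two-stage aggregate is
mathematically identical to the flat weighted mean over all admitted
clients; the test suite asserts this to $10^{-10}$ on random topologies.
The hierarchy matters only when combined with **distributed network
thresholding (DNT)**: before aggregation, each client's freshly trained
model is scored on a calibration set held at the central server, and
clients whose score fails the admission rule are dropped from the round.

## Synthetic slices and the Pa/Pd feature vector

Each slice is a 64×64 matrix of intensities in $[0,1]$ with 1.25 mm slice
thickness carried as metadata. The background is Gaussian noise (mean
0.2, sd 0.05, clipped). Nodules are rasterized from a polar boundary

$$r(\theta) = r_0\bigl(1 + a \textstyle\sum_k \sin(k\theta + \varphi_k)\bigr),$$

clamped below at half a pixel, and softened with a Gaussian blur of
$\sigma = 1$ px before compositing. Class settings (package defaults):

| class     | radius $r_0$ (px) | core intensity | spiculation $a$ | harmonics $k$ |
|-----------|-------------------|----------------|------------------|---------------|
| normal    | — (no nodule)     | —              | —                | —             |
| benign    | U(3, 6)           | 0.6            | 0                | —             |
| malignant | U(5, 9)           | 0.8            | 0.35             | 3, 5, 7       |

The foreground threshold for RoI detection is fixed at 0.45 — five
background standard deviations above the background mean — so a normal
slice's RoI is empty with overwhelming probability, which realizes the
"no positive RoI" definition of the normal class operationally. The RoI
is the largest connected component above the threshold.

The classifier does not see pixels; it sees an 8-dimensional feature
vector, the concatenation of a *physical* attribute group Pa and a
*digital* group Pd (the concatenation order is fixed and declared):

* **Pa** — `density` (mean RoI intensity), `mass` (density × RoI area),
  `orientation` (principal-axis angle from central second moments,
  defined as 0 for degenerate/rotationally symmetric masks),
  `weight` (RoI area fraction × density);
* **Pd** — `pixel_ratio` (RoI area / image area), `growth_pattern`
  (boundary irregularity $P^2 / 4\pi A$), `pixel_intensity` (max RoI
  intensity), `expansion_density` (mean absolute radial intensity
  gradient over the one-pixel boundary band).

An empty RoI yields the all-zero vector, so normal cases sit at the
origin of feature space by construction.

**Perimeter estimation.** `growth_pattern` needs a digital perimeter. We
count exposed pixel edges ("crack length") and apply the Cauchy–Crofton
correction factor $\pi/4$, which is unbiased for isotropically oriented
boundaries and nearly exact for digitized disks. For strongly anisotropic
shapes (an axis-aligned square) the estimator can dip below the disk
bound $P^2/4\pi A = 1$, so the ratio is floored at 1 for non-empty RoIs;
the floor encodes the geometric fact that no shape is more compact than a
disk. At the default radii a rasterized benign disk lands in
$[1.0, 1.15]$ and the spiculated malignant boundary typically lands in
$[1.8, 3.6]$, which is what makes `growth_pattern` the discriminative
feature between the two nodule classes.

## Local model and training

The per-client model is a multilayer perceptron on the 8 features: one
hidden layer of 16 rectifier units, a softmax head over the three classes
(195 parameters), held as a single flat vector so that averaging is a
vector operation. Training is plain mini-batch gradient descent on
softmax cross-entropy with an L2 weight penalty — no momentum or adaptive
steps, so a run is bit-for-bit reproducible from its seeds. Defaults:
60 local epochs per round, learning rate 0.1, batch size 16 (shards
smaller than one batch train full-batch), $\ell_2 = 10^{-4}$.

Feature standardization statistics (per-feature mean/sd) are computed
once on the pooled client training pool and broadcast; this avoids
per-client scale drift at the cost of a mild deviation from strict data
locality, and it is applied identically in the centralized arm so the
comparison is like for like.

Two reproducibility conventions matter:

* the per-round training seed is shared by all clients
  (`train_seed + round`), so clients holding identical shards follow
  identical trajectories;
* each shard presents its rows in cohort order, not partition-shuffle
  order, so a one-client federation with admission off is *bit-identical*
  to centralized training with the same seeds (the collapse identity the
  tests assert).

## DNT: validation scoring and admission

After local training in each round, every client model is scored on a
fixed calibration set — a stratified 20 % carve-out of the training
split, held at the central server and identical across rounds (the
pipeline's validation data source is a design choice; nothing else in the
setup supplies one). The score separates the attribute groups:
$v_{Pa}$ is the calibration accuracy with the Pd coordinates zero-masked
(zero on the standardized scale is mean-imputation), $v_{Pd}$ symmetric,
and $v = (v_{Pa} + v_{Pd})/2$ exactly. Scores accumulate in the
append-only validation matrix $R$ (rounds × clients; a non-participating
client is a missing entry, not a zero).

Admission policies on the combined score $v$, with an inclusive boundary:

* `off` — admit everyone (vanilla federated averaging, exactly);
* `absolute` — admit $\{i : v_i \ge \tau\}$; the admitted set is monotone
  non-increasing in $\tau$;
* `robust` — admit $\{i : v_i \ge \mathrm{median}(v) - z\,\mathrm{MAD}(v)\}$
  with the unscaled median absolute deviation; when MAD $= 0$ the band
  collapses to $\{v \ge \mathrm{median}\}$, so equal scores admit everyone.

If a rule would admit no one, the single best-scoring client is admitted
and the round is flagged — a keep-best fallback rather than keep-previous
global, chosen so every round makes progress while the anomaly stays
visible in the round log.

With defaults (5 clients, one of them trained on label-shuffled data,
`robust` with $z = 2$), one local-training round separates the corrupted
client's near-chance score ($\approx 1/3$) from the intact clients'
scores far enough that the corrupted client is excluded in essentially
every seeded replicate; the acceptance checks require at least 80 % of 20.

## Experiments

**Centralized vs decentralized.** One synthetic cohort (default 300
cases, equal class mix) is split 60/40 into train/test, stratified by
class. The decentralized arm runs the federation (default 5 clients,
IID partition, 30 rounds, admission off); the centralized arm trains a
single model on the pooled client training pool with the same
initialization and per-round seeds. Both are evaluated on the shared test
split. Under the default generator the classes are cleanly separable, so
both arms reach test accuracy near 1 and the gap is near 0 — the
comparison exercises the machinery and the collapse/equivalence
identities rather than hunting a performance difference.

**Node scaling.** The participating-node ladder doubles from 5 to 160.
Federating a fixed 50-case cohort across 160 nodes is degenerate (most
shards would be empty), so the cohort is scaled with the ladder: 12 cases
per node, 60 % of them training. Routers follow the square-root rule
$\lceil\sqrt{n}\rceil$. Each rung is one federated run of 10 rounds,
seeded per rung; the result is one row of accuracy / macro-sensitivity /
macro-specificity per count.

**Published-table fixtures.** The package ships, as a plain-CSV fixture,
the 3×3 training and testing confusion tables reported for a centralized
and a federated arm on a 50-case low-dose CT cohort (rows = true class,
columns = predicted). The metric engine computes accuracy as
trace / grand total, per-class sensitivity TP/(TP+FN), and one-vs-rest
specificity TN/(TN+FP), macro-averaged with zero-denominator classes
flagged and excluded. Two documented discrepancies in the source tables
are preserved rather than repaired: the testing-phase cell arithmetic
yields 52/90 ≈ 57.8 % (federated) and 29/65 ≈ 44.6 % (centralized),
irreconcilable with the 89.63 %/94.31 % headline figures reported
alongside them; and the federated testing table's printed first column
total (19) disagrees with its own cells (34 — the 19 duplicates the
normal row total). The loader validates row and grand totals and attaches
the printed column totals so both facts stay checkable.

## Numerical choices and edge cases

* Largest-remainder rounding for class counts and per-class allocations;
  ties break in label order (normal, benign, malignant).
* `weighted_average` normalizes weights before the matrix product, so a
  single admitted model passes through bit-exactly.
* Softmax is computed with the row-max shift; prediction ties break
  toward the earlier label, so the all-zero model predicts `normal`.
* Orientation of a rotationally symmetric RoI is defined as 0 (the
  principal axes are degenerate).
* Constant features receive sd 1 in the standardization statistics.
* An empty shard after partitioning is repaired by moving one case from
  the largest shard; an impossible repair is an error.
* All randomness flows through explicit component seeds (cohort, split,
  partition/calibration, initialization, training); there is no
  wall-clock seeding anywhere.

## What the synthetic cohort does and does not show

The generator reproduces the *decision structure* of the task — an
absent-RoI class, a smooth-boundary class and a spiculated
higher-intensity class — with class-conditional feature distributions
that are separable but noisy at the margins (rasterization, blur,
background noise). It does not emulate real CT physics: no Hounsfield
calibration, no anatomy, no 3-D context, no scanner artifacts, no
inter-reader label noise. Passing tests therefore demonstrate that the
federated pipeline is correct and that its identities (collapse,
hierarchy–flat equivalence, DNT monotonicity) hold — not that the
default MLP would reach any particular accuracy on clinical data. The
near-perfect synthetic accuracies should be read as "the task is
learnable and the machinery learns it", and the published-table fixtures
are the package's only contact with real-data performance numbers.

## Problem sizes

Default experiment sizes are chosen so a full verification run — the
whole test suite plus the acceptance script — completes on one CPU in a
few minutes: 300-case cohorts for the comparison arm, 150-case cohorts
for the 20 thresholding replicates, 12 cases per node (60–1920 cases) on
the scaling ladder, 10 rounds per scaling rung and 30 rounds for the
comparison. All sizes are arguments, not constants.
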