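---
title: "Swarm learning for weakly supervised tile classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm learning for weakly supervised tile classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Molecular biomarkers of solid tumors — microsatellite instability (MSI/dMMR)
or *BRAF* mutational status in colorectal cancer, for example — can be
predicted directly from routine H&E histopathology. The models that do this
are data hungry, and the data live in different hospitals that cannot pool
patient images on one server. Swarm learning (SL) addresses this: several
peers train the same network on their own data and periodically exchange and
average *parameters* rather than images, with merge leadership rotating
among the peers instead of resting with a fixed coordinator.

`histoswarm` implements the full pipeline in process: slide tessellation and
tile quality control, stain normalization, pluggable tile feature
extraction, a weakly supervised tile classifier, a deterministic multi-peer
swarm trainer with both merge schedules, a replicate evaluation harness, and
model-examination outputs. A synthetic multi-cohort generator with known
ground truth makes every stage testable without any clinical data.

## The model

Each patient $i$ is a *bag* of tiles with a single binary label $y_i$; every
tile inherits its patient's label (weak supervision), and no tile-level
cleaning is attempted. Tiles are mapped to $d$-dimensional feature vectors
($d = 512$ by default) and scored by a four-layer fully connected network
($d{\times}256$, $256{\times}256$, $256{\times}128$, $128{\times}2$, ReLU
activations, softmax output; 230,274 parameters at $d = 512$). The patient
score is the arithmetic mean of its tile class-1 probabilities, and models
are compared by patient-level AUROC (Mann–Whitney form, ties half-credited).

Training minimizes the mean tile-level cross-entropy by mini-batch SGD.
Before training, each training set is class-balanced by random
undersampling; each swarm peer balances its own tiles, because balancing is
a per-training-set preprocessing step and each peer owns one training set.

## The swarm protocol

Peers run in lockstep rounds. In a round, each active peer performs $S$
local optimizer steps (the *sync interval*, default 4), then all
participants' parameters are merged by an elected peer:

$$\theta \leftarrow \sum_{i \in \text{active}} w_i\, \theta_i,
  \qquad \sum_i w_i = 1,$$

and the merged $\theta$ is broadcast. Leader election is simulated as a
deterministic round-robin; because a weighted average does not depend on who
computes it, the elected merger affects only the audit log. Every merge is
recorded as a sync event (round, participants, weights, parameter digest),
and event logs replay exactly under the same seed.

Two schedules are provided, for peers with tile counts $N_i$ and base epoch
count $E$ (default 5):

* **basic** — every peer trains $E$ epochs with equal weights
  $w_i = 1/P$. Small peers finish first: when the smallest finishes, the
  post-merge model is checkpointed (`b_chkpt1`); when the second-smallest
  finishes the run stops — at least two partners are required — and the
  final merge is `b_chkpt2`.
* **weighted** — small peers train more epochs,
  $e_i = \max(1, \mathrm{round}(E \cdot \max_j N_j / N_i))$, so all peers
  finish at (nearly) the same round, and merge weights are strictly
  proportional to tile counts, $w_i = N_i / \sum_j N_j$. One terminal
  checkpoint (`w_chkpt`) results.

Design choices that the protocol description leaves open, decided here and
encoded in the implementation:

* **Checkpoint content** is the post-merge global model at the triggering
  round, not the triggering peer's local weights — the swarm's shared state
  is what is deployed and evaluated.
* **Epoch rounding** in weighted mode uses `round()` with a floor of one
  epoch; any residual step mismatch is resolved by letting early-finished
  peers idle with their weight withheld, the remaining weights renormalized.
* **Weights use post-balancing tile counts** — the tiles actually trained
  on — rather than raw counts.
* **Epoch reshuffling** derives its permutation from (run seed, epoch), not
  from the peer index. Peers with different data still see independent
  batch orders (their data differ), while peers holding identical data make
  identical updates — which gives the protocol its cleanest invariant:
  a swarm of identical peers is exactly one local run.

Two exact equivalences anchor the implementation and are asserted in the
test suite: (1) with $S = 1$, plain SGD, equal per-peer batch sizes and
batch-proportional weights, each swarm round equals one centralized SGD
step on the concatenated batch (the merge is linear in the per-peer
updates); (2) identical peers at any $S$ reproduce a single local run to
floating-point accuracy.

## Preprocessing choices

* **Tessellation** cuts a non-overlapping grid anchored at the top-left
  corner; partial edge tiles are discarded. Tile size is a parameter
  everywhere (512 px is the conventional production value; the synthetic
  slides use 64 px and tests mostly 16–32 px).
* **Tile QC** converts to grayscale (luminance weights 0.299/0.587/0.114),
  computes a Canny edge map (3×3 Sobel, L1 magnitude, non-maximum
  suppression, double-threshold hysteresis; edge pixels 255) and scores the
  tile by the mean of the map. Tiles *below* threshold 4 are removed; a
  score exactly at the threshold is kept. The hysteresis thresholds are not
  fixed by convention, so defaults (low 40, high 100 on the 0–255 scale)
  are exposed as arguments.
* **Stain normalization** defaults to Macenko stain-vector normalization
  against a packaged standard H&E target (stain matrix and 99th-percentile
  concentrations), with `"none"` available. Near-white tiles with too few
  stained pixels pass through unchanged with a `no_stain` flag rather than
  being distorted. The method is pluggable via the `reference` argument.
* **Per-patient sampling** takes up to `n` tiles (150 is the conventional
  budget) without replacement, deterministically under a seed; patients
  with fewer tiles keep all of them, and empty patients are flagged with a
  warning instead of an error.

## Feature extraction

The default backbone is a handcrafted multi-scale texture descriptor
(intensity and gradient statistics plus gradient-orientation histograms at
three scales, with channel moments) projected to `feature_dim` dimensions
by a fixed matrix. It is deterministic, CPU-cheap, needs no pretrained
weights, and cleanly separates the generator's two texture families. A
seeded random-projection backbone is included, and any function
`tile -> numeric(feature_dim)` can be plugged in, which is the adapter seam
for a pretrained CNN. Features are not re-standardized after extraction by
default. Tiles are processed independently, so extraction commutes with
reordering and batching.

## The synthetic generator

`generate_feature_cohorts()` emulates the statistical structure of a
multi-site weak-label study without emulating histology itself:

* background tiles are isotropic Gaussian noise in feature space;
* in positive patients, a `witness_rate` fraction of tiles (default 0.5) is
  shifted by `effect_size` (default 2.0, in noise s.d. units) along one
  hidden unit direction — only some tiles of a positive patient carry
  signal, as in real slides;
* every tile of a cohort receives a cohort-specific offset of magnitude
  `site_shift` (default 1.5) drawn orthogonal to the signal direction — a
  site effect (scanner, staining, population) that moves cohorts apart
  without moving class means apart;
* default cohort sizes are 100/300/150 patients (smallest/largest/middle,
  echoing the unequal three-site setting), prevalence 0.3 per cohort,
  32 tiles per patient.

Each patient bag is generated under its own derived seed, so output is a
pure function of the configuration. `effect_size` was fixed at 2.0 so that
tile-level signal is weak but five epochs of training reach a stable
plateau — the regime in which comparing schedules is informative.
`generate_tile_images()` renders the same bag structure as textured RGB
mosaics (blob vs stripe families, H&E-tinted as true two-stain optical
density mixtures) with a configurable fraction of constant-color blank
tiles for the QC filter to remove.

What this generator deliberately does not model: realistic tissue
morphology, stain chemistry, label noise in the ground truth, spatial
correlation between neighboring tiles, and site effects that interact with
the class signal. Passing tests therefore demonstrate correctness of the
protocol and pipeline mechanics and the *direction* of the multi-site
effects, not clinical performance.

## Training defaults

Default hyperparameters are mini-batches of 32 tiles, learning rate 0.03,
plain SGD, five epochs. Plain SGD is the default because it keeps the
merge operation exactly linear in the per-peer updates, which is what makes
the swarm/centralized equivalence exact; an Adam-style adaptive optimizer
is available behind `optimizer = "adaptive"`. The rate/batch combination
was chosen once, on the synthetic defaults, so that all model families
reach their performance plateau within the fixed five-epoch budget; at
desk scale, much smaller rates leave every model near chance and every
comparison vacuous. All tunables are recorded in the returned objects.

## Evaluation harness

Experiments are repeated over seeds (default five replicates; three for the
sync sweep); the seed drives initialization, subsampling, balancing and
shuffling. Replicate AUROC lists are compared with a classical two-sided
unpaired $t$-test (equal variances pooled; Welch behind a flag; no
multiple-testing correction), with a flagged convention for degenerate
zero-variance inputs ($p = 1$ on equal means). Replicate summaries report
the sample (n−1) standard deviation. Stratified subsampling uses
largest-remainder rounding of class quotas — floors first, remaining slots
to the largest fractional parts — which is deterministic and exact whenever
the quotas are integral.

The experiment grid trains, per seed and subset size: one local model per
cohort, a merged model on the concatenated cohorts (balanced as one set),
and the three swarm checkpoints; both basic checkpoints come from a single
swarm session. All models are evaluated on a held-out external cohort
generated with its own site offset; train/test patient overlap is rejected.

Problem sizes used by the shipped experiments (chosen as the package's
desk-scale study conditions): the headline comparison uses the default
100/300/150-patient cohorts plus a 200-patient external test cohort and
five seeds; the data-efficiency curve uses 420/630/480-patient cohorts
subsampled to 100/200/400 patients per cohort with three seeds; the sync
sweep uses intervals 1/4/16/64 at 200 patients per cohort with three
seeds.

## Model examination

Whole-slide heatmaps place tile class-1 probabilities at tile centers on
the tile lattice, fill QC-removed cells by linear interpolation along rows
and columns (averaged where both exist), fill cells outside the scored span
with the nearest scored value, and upscale bilinearly — so the raster is
exact at every scored tile center and resolution-independent.
`top_tiles()` exports the $N$ highest-scoring tiles of the $M$
highest-scoring patients (5 × 5 by convention) with ties broken
lexicographically by patient and tile coordinates, making the selection a
total order that is invariant to input permutation. For examination of a
replicate family, use the seed whose AUROC is the median of the replicate
list (unique with five seeds).

## Known limitations

* Peers are simulated in one process in strict lockstep; real deployments
  add network transport, identity management and failure handling, none of
  which changes the learning dynamics simulated here.
* The adaptive optimizer's moment state is local to each training call and
  is not exchanged at sync events; only parameters are merged.
* Stain normalization assumes two dominant stains; it passes through, with
  a flag, tiles where that assumption fails.
* Pyramidal whole-slide formats are out of scope; the pipeline starts from
  RGB rasters (an adapter can feed decoded regions to `tessellate()`).
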