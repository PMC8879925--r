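---
title: "Methods: dose-response phenotyping of zebrafish Y-maze behaviour"
author: "ymazer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response phenotyping of zebrafish Y-maze behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model system

`ymazer` is an analysis pipeline for neurotoxicological phenotyping of
adult zebrafish (*Danio rerio*) exposed to a dopaminergic toxin such as
MPTP (1-methyl-4-phenyl-1,2,3,6-tetrahydropyridine), the standard
chemical model of Parkinson's disease. The pipeline covers four branches
that in a wet-lab study would be fed by EthoVision-style positional
exports, a mortality census and inhibitory-avoidance latencies:

1. **Y-maze behaviour** — spontaneous alternation (SAB) and locomotor
   endpoints from positional tracks;
2. **acute toxicity** — LD50 by the Miller–Tainter probit regression;
3. **AI branch** — 30-s track segments rasterized to grayscale images, a
   small residual CNN classifying day-by-dose labels, a permutation
   significance baseline, and Louvain clustering of the confusion
   matrix viewed as a class-similarity graph;
4. **conventional statistics** — normality-gated t-tests, Pearson
   correlation, paired analysis of avoidance latencies.

Because raw in-vivo tracks for this design are not publicly deposited,
the package ships a first-class synthetic-data module whose planted
parameters are the ground truth against which every downstream stage is
tested.

# The synthetic world

## Trajectory model

A fish is simulated as a discrete-time path follower inside the maze
polygons (three rectangular arms of default 25 × 8 cm joined by an
equilateral junction triangle, arms at bearings 90°/210°/330°,
maze-local cm coordinates with the origin at the junction centroid):

* **Speed process.** Per-sample speed is Gaussian
  (`mean_speed`, `speed_sd`, clipped at 0). Freezing is a Poisson
  process of `freeze_rate` bouts/min, each forcing speed 0 for
  `freeze_duration` s. A frozen or stationary fish holds its position
  exactly — this makes the stationary-fish and freeze-recovery
  contracts sharp.
* **Route.** The fish shuttles between the junction centroid and arm
  way-points at 90% of the arm length. Cumulative swum distance is
  mapped onto this way-point path, so planned kinematics and realized
  geometry stay consistent.
* **Arm choice** at each junction crossing implements the alternation
  propensity `p_alternate`: with two distinct previously visited arms
  the fish picks the arm different from both with probability
  `p_alternate` and otherwise returns to the previous arm; with fewer
  than two distinct previous arms it picks uniformly between the two
  arms other than the current one. Consecutive entries therefore always
  differ, and each sliding window of three entries alternates with
  probability exactly `p_alternate`, giving `E[SAB%] = 100·p_alternate`.
  (The two-choice chance level is 1/2, i.e. SAB ≈ 50%.) A literal
  "uniform over remaining options" fallback would instead give
  `p + (1-p)/2` and break the chance-level anchor, so the rule above is
  the package's declared convention.
* **Lateral wobble.** An AR(1) offset (innovations only while moving)
  perpendicular to the current leg, clamped to the local corridor
  half-width (narrowing to 2/3 of the mouth width at the junction
  centroid), keeps every sample inside the maze polygons by
  construction; a point-in-polygon sweep over every generated sample is
  a standing test.

Defaults mirror the modelled study design: 600-s trials, three dose
groups (`control`, `100ug`, `200ug` per ~1-g fish) × two test days,
10 fish per group. The positional sampling rate is not stated by
tracking-software conventions alone; the package defaults to 25 Hz and
exposes it, and the test suite deliberately runs at 5–10 Hz to fit CPU
budgets (the estimators are rate-invariant well above ~2 Hz).

The planted group structure of the demonstration configuration
(`demo_config()`): control and 100-ug groups share all parameters
(speed 6 ± 2 cm/s, 0.5 freezes/min, `p_alternate` 0.70); the 200-ug
group is markedly parkinsonian-like (2.5 ± 1.2 cm/s, 4 freezes/min of
5 s, `p_alternate` 0.50). This is the world in which the pipeline's
headline property — the 200-ug classes clustering away from everything
else regardless of day — is expected to hold. Day has no planted
effect.

What the generator does **not** emulate: wall-following and thigmotaxis,
burst-glide swimming, body posture, inter-individual personality
variance beyond the seeded streams, and tracking artifacts (pixel
noise, identity swaps, reflections). A green end-to-end test therefore
establishes that the pipeline recovers planted effects of realistic
magnitude from geometrically valid trajectories — not that it would
survive every pathology of real video tracking.

## Mortality and avoidance

Mortality composes a probit dose–lethality curve (slope in probit units
per log10 dose) with a baseline control lethality as independent risks,
`p = c + (1-c)·Φ(b·(log10 d - log10 LD50))`, so the Abbott correction
used downstream inverts the composition exactly in expectation. Doses
are ug per ~1-g fish, numerically equal to mg/kg. Inhibitory-avoidance
records are paired latencies `test = train + learned_delta + noise`
(clipped at 0) with a planted fraction of non-avoiders whose training
latency exceeds the 180-s cutoff.

# Scoring conventions

* **Arm entry**: the fish must remain in one arm ≥ `min_dwell` (default
  0.5 s) after arriving from the junction or another arm; consecutive
  duplicates collapse. The dwell hysteresis suppresses junction jitter;
  the value is a declared convention, not an inferred one.
* **SAB**: overlapping windows of three consecutive entries, alternation
  = pairwise distinct window, `SAB% = 100·alternations/(entries - 2)`
  (the continuous-SAB convention). Fewer than three entries gives an
  undefined (NA, flagged) score — a value, not an error — and such fish
  are excluded from group statistics with a logged count.
* **Freezing**: speed < 0.5 cm/s sustained ≥ 2 s (literature-typical
  defaults; both configurable).

# LD50 (Miller–Tainter)

Treated-group mortality is Abbott-corrected for control lethality
(`p' = (p - p0)/(1 - p0)`, clipped to [0,1]; mortality below control
clips to 0 and is flagged), 0%/100% are replaced by the Miller–Tainter
endpoint corrections `100·0.25/n` and `100·(n-0.25)/n`, and probits
`5 + Φ⁻¹(p'/100)` are regressed on log10 dose by unweighted least
squares — the "graphical" variant of the method, chosen over iteratively
reweighted probit ML to match the cited procedure. LD50 is the dose at
fitted probit 5. On noiseless probit-linear tables the chain is exact to
machine precision (a standing test); an optional nonparametric bootstrap
over fish provides a percentile CI, since the source method reports
none.

# The AI branch

## Rasterization

Tracks are cut into non-overlapping 30-s windows (trailing partial
window dropped by default). Each window is drawn on a fixed `size x
size` grid (default 64) by mapping the maze bounding box with preserved
aspect, joining consecutive samples with integer (Bresenham-style DDA)
lines — no anti-aliasing, for cross-platform determinism — and grading
intensity linearly in time from 0.2 (oldest) to 1.0 (newest), so
direction and recency survive rasterization; `binary = TRUE` restores
plain occupancy. Because the mapping is anchored to the maze and not to
the data, identical paths give identical images.

## Classifier

No deep-learning framework is available in the target environment, so
the reduced residual CNN is implemented in the package itself: a 3×3
convolution stem (1→8 channels), three identity-skip residual blocks
with 2×2 mean-pooling between stages, global average pooling and a
dense softmax head; 3×3 convolution forward/backward kernels are
compiled C++ (single-threaded, deterministic), the optimizer is Adam on
a class-weighted cross-entropy (weights inverse to class frequency —
dose groups of 12–41 fish are the realistic regime). Defaults: 15
epochs, batch 16, learning rate 3e-3, seeded init/shuffling, no
augmentation. This is the desk-scale stand-in for a full ResNet34,
which the architecture deliberately does not attempt on CPU budgets.

Dataset assembly is **by fish**, not by segment: all windows of one fish
land on one side of the holdout split, because segments of the same
trajectory are strongly autocorrelated and a segment-level split
inflates validation accuracy. Cross-day designs (train Day 1 → test
Day 2 and the reverse) put whole days on each side instead.

Five canonical experiment designs are built in: E1 (all six day×dose
classes, within-class holdout), E2A/E2B (one day only), E3A/E3B
(cross-day). In cross-day designs the train and test label sets are
disjoint by construction, so literal label-match accuracy is
identically zero; accuracy and its permutation baseline are therefore
scored on the dose component of the label, while the confusion matrix
and the similarity graph keep the full rectangular day-by-dose label
sets.

## Permutation baseline

True labels are shuffled against the *fixed* predictions (no
retraining, matching the described procedure; retraining per
permutation would be the conservative variant) `reps` times; the
significance threshold is the empirical (1-α) quantile (type-1, i.e. an
order statistic) of the permuted accuracies, and the observed accuracy
is significant iff it strictly exceeds the threshold. Discreteness
makes the test slightly conservative, which the 20-run null-calibration
acceptance check confirms.

## Similarity graph and Louvain

The confusion matrix (column-normalized: cell *i,j* = fraction of true
class *j* predicted as class *i*) becomes an undirected weighted graph:
weight(i,j) = (cm[i,j] + cm[j,i])/2 for i ≠ j, the diagonal
(self-recognition) discarded so that edges measure inter-class
confusability only; rectangular matrices are first embedded on the
union of row/column labels. Symmetrization by arithmetic mean is a
declared choice — the source procedure does not specify one.

Louvain is the standard two-phase greedy modularity optimization
(seeded node-visiting order; modularity-gain ties broken toward the
smallest community id for determinism; default 10 restarts keeping the
best recomputed Q on the *original* graph, which doubles as a
self-consistency check). Modularity follows
`Q = Σ_c [W_c/W - γ·(S_c/2W)²]`. An edgeless graph returns the flagged
singleton partition with Q = 0. No edge thresholding is applied before
clustering by default. On all graphs small enough to enumerate, the
implementation is tested against a brute-force scan of every set
partition.

# Statistics

Group contrasts use a Shapiro–Wilk gate at α = 0.05 per sample: both
normal → pooled-variance unpaired t (df = n₁+n₂-2), otherwise
Mann–Whitney, with the chosen test recorded. Paired latencies use the
dependent-samples t (df = n-1) with an explicit zero-variance guard
(all-zero differences report t = 0, p = 1; constant nonzero differences
report a flag rather than ±∞). Pearson r carries df = n-2. All tests
are two-sided (sidedness is not specified by the source conventions).
One-way ANOVA with Fisher's LSD post-hoc ships for >2-group contrasts,
but the pipeline's reported comparisons are pairwise. Non-avoiders
(latency > 180 s, training phase by default) are excluded with a
reported count before the paired analysis.

# Numerical and reproducibility choices

* One master seed fans out to named substreams (synth / split / train /
  permute / louvain / mortality / iat) via a deterministic integer
  hash; per-fish streams derive from the fish index so growing a cohort
  never reshuffles existing fish.
* `run_study()` reports a deterministic hash over every numerical
  outcome; two runs of the same config+seed are hash-identical (an
  acceptance criterion). Stage reuse is compositional: a precomputed
  image set can be passed back into `run_study()` and reproduces the
  classifier branch exactly; no persistent on-disk cache is kept.
* Fractional death counts are accepted in mortality tables so that
  exact probit-linear validation tables can be constructed; simulated
  and real tables are integer.
* The Miller–Tainter endpoint correction keeps probits finite for any
  n ≥ 1 but is non-monotone against interior percentages at n = 1 — a
  degenerate group size that cannot arise with real percent mortality.

# Known limitations

* The trajectory model plants kinematic and mnemonic group differences
  but not subtler signatures (turn chirality, wall distance), so
  classifier accuracies here say nothing about the ceiling on real
  video data.
* The reduced CNN is a deliberately small stand-in; no transfer
  learning, augmentation or hyperparameter search is attempted.
* Louvain is run on graphs of ≤ 6 nodes in this pipeline, where it is
  exhaustively verifiable; its scalability properties are untested here.
* Bootstrap LD50 intervals resample at the observed rates
  (parametric-in-p binomial resampling of individual fish), which is
  slightly narrower than a full case bootstrap for tiny groups.
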