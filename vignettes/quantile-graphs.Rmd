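---
title: "Quantile-graph analysis of EEG time series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-graph analysis of EEG time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The method

A quantile graph (QG) maps a univariate time series $X = \{x(t)\}_{t=1}^T$
into a weighted directed network.  The sample is partitioned into $Q$
quantile intervals; each interval is a node.  For a lag $k$, an arc
$i \to j$ receives one unit of weight each time $x(t)$ falls in quantile
$i$ and $x(t+k)$ falls in quantile $j$.  The count matrix $A_k$ therefore
has total weight exactly $T-k$; row-normalizing it gives a Markov
transition matrix $W_k$ whose row $i$ is the empirical distribution of the
quantile $k$ steps after quantile $i$.  Periodicity, persistence and
randomness of the signal become topological features of the family
$\{W_k\}$, which is summarized by five metrics and swept over
$k = 1, \dots, k_{cap}$ (default 25).

The number of quantiles follows the cube-root rule
$Q \approx 2T^{1/3}$, rounded half-up (`default_num_quantiles()`); for the
1024-sample, 128 Hz EEG segments this package targets, $Q = 20$.  The
method is only weakly sensitive to this choice.

## Partition convention

Two decisions are not fixed by the method's definition and matter for
reproducibility:

* **Boundaries.** `fit_partition()` places boundaries at the empirical
  quantiles of probabilities $i/Q$ with linear interpolation between order
  statistics (R's type-7 convention), with the outer boundaries at the
  sample minimum and maximum.  We chose interpolated rather than
  inverse-ECDF (type-1) boundaries because only the former guarantees the
  defining property of a quantile partition — with distinct values every
  interval holds between $\lfloor T/Q \rfloor$ and $\lceil T/Q \rceil$
  samples.  With boundaries placed exactly on order statistics, the
  boundary sample itself tips one interval over and the occupancies can
  drift to $\{T/Q - 1, \dots, T/Q + 1\}$.
* **Ties and closure.** Intervals are half-open on the right,
  $[b_{i-1}, b_i)$, with the last interval closed; a sample equal to an
  interior boundary belongs to the upper interval.  When a partition
  fitted on one segment is reused on another (not done by the default
  pipeline, which refits per segment), out-of-range values are clamped to
  the end bins with a warning rather than dropped.

Matrix orientation is rows = source quantile (time $t$), columns =
destination (time $t+k$), and node ids are 1-based everywhere, including
file exports.

## Group aggregation

Group-level curves use the *transition matrix of medians*: the
element-wise median of the group's count matrices $A_k$ is taken first and
the median matrix is then row-normalized (`median_transition_matrix()`).
Aggregating counts before normalizing (rather than taking medians of
$W_k$) keeps the aggregate interpretable as a transition structure
estimated from typical counts, and an all-zero median row stays an
honestly unsupported row.  Unsupported rows are never filled with
fabricated uniform mass; every metric tolerates them.

## The five metrics

All five consume the Markov weights $W_k$ (entries in $[0,1]$); with
row-stochastic weights the Laplacian spectrum stays $O(1)$ per node, which
is what keeps the Laplacian Estrada index near $Q e^{\bar\mu}$ rather than
overflowing as a binary-adjacency Laplacian would.

* **Clustering coefficient (CC).**  Weighted directed clustering
  $CC_i = \frac{1}{s_i(d_i-1)} \sum_{j,d} \frac{w_{ij}+w_{id}}{2}
  a_{ij}a_{jd}a_{id}$, averaged over nodes.  The weighted-clustering
  literature is ambiguous for digraphs; we take $d_i$ as the number of
  distinct neighbours over the union of in/out arcs and $s_i$ as the
  out-strength, exclude self-loops, and let degenerate nodes
  ($d_i \le 1$ or $s_i = 0$) contribute 0.
* **Mean jump length (MJL / $\Delta$).**  $\Delta = \frac{1}{Q}
  \mathrm{tr}(P W^\top)$ with $p_{ij} = |i-j|$.  It is 0 iff all supported
  mass sits on the diagonal and approaches $(Q^2-1)/(3Q)$ (6.65 at
  $Q=20$) for independent noise.  A Monte-Carlo random-walk estimator
  (`mean_jump_length_walk()`) is provided; dead-end rows restart the walk
  uniformly over supported rows and restart jumps are not counted, so the
  walk and trace formulas agree on doubly-stochastic matrices.  Note that
  $\Delta$ is intentionally *not* invariant under node relabelling — it
  uses the quantile ordering.
* **Betweenness centrality (BC).**  Hop-count shortest-path betweenness on
  the directed graph of positive-weight arcs, self-loops ignored, each
  node divided by $(Q-1)(Q-2)$ and averaged.  The method's definition
  gives no edge-length rule; unweighted hops are the parsimonious reading
  and the normalization makes per-node values comparable across $Q$.
  Computation is delegated to igraph and cross-checked in the tests
  against an exhaustive path-enumeration oracle.
* **Modularity (MO).**  $M(P) = \sum_i [e_i/E - (d_i/2E)^2]$ on the
  symmetrized weighted graph ($w'_{ij} = (w_{ij}+w_{ji})/2$, self-loops
  dropped).  Partitions come from deterministic greedy modularity
  maximization (igraph's agglomerative scheme), so MO is reproducible
  without a seed; the score itself is computed by `modularity_score()`
  and verified against an independent implementation.  An edgeless graph
  yields the single-module partition with $M = 0$ by convention; asking
  for the score of an edgeless graph directly is an error ($E = 0$).
* **Laplacian Estrada index (LEE).**  $LEE = \sum_i e^{\mu_i}$ over the
  eigenvalues of $L = D - A$ of the symmetrized, loop-free weighted graph.
  Computed by dense symmetric eigendecomposition; the tests check it
  against the trace of the matrix exponential.

## Discrimination pipeline

For each channel and metric, one curve per group is built over
$k = 1..k_{cap}$.  The separation between the healthy cluster (groups A,
B) and the patient cluster (C, D) at lag $k$ is the *worst-case* gap: the
minimum over cluster pairs of $|$curve difference$|$.  $k_{max}$ is the
smallest lag attaining the maximal separation.  The worst-case definition
was chosen over the gap between cluster means because it only declares
separation when the clusters are actually disjoint, which is what the
curve families of well-separated cohorts show.

At $k_{max}$ the metric is evaluated per segment (no aggregation) and the
groups are compared by:

* a **two-level ANOVA** (healthy vs patient, equivalent to the pooled
  t test; $F = t^2$) with a 95% CI of the mean difference — two levels,
  not four, because the clinical question is controls vs AD;
* a **Mann–Whitney ROC area**, oriented as $\max(A, 1-A)$ so the reported
  discrimination does not depend on whether disease raises or lowers a
  metric;
* per channel, $\hat A_{ROC}$: the average ROC area over the four
  healthy-vs-AD pairs (A,C), (B,D), (A,D), (B,C).  Within-condition pairs
  (A,B) and (C,D) are excluded — they compare eye states, not health.

No multiple-testing correction is applied, matching the analysis the
pipeline reproduces.

## Classification

`crossval_classify()` runs stratified 10-fold cross-validation of a
support vector machine on the five metric features.  The kernel defaults
to linear: with 5 features, ~48 subjects and strong class separation, the
simplest max-margin classifier is the honest choice, and anything more
flexible invites overfitting the folds.  Features are z-scored with
means/scales fitted on each training fold only; fold assignment is seeded
and stratified (class counts per fold differ by at most one).  ACC, SEN
and SPE come from the pooled confusion matrix with AD as the positive
class; AUC from pooled decision values.

## Frequency bands

`decompose_bands()` splits a segment into delta (1–4 Hz), theta (4–8 Hz),
alpha (8–13 Hz) and beta (13–30 Hz) series plus a residual that completes
the identity.  The default scheme is a 5-level periodized orthogonal DWT
with the 8-tap Daubechies filter (db4): at 128 Hz the dyadic components
map to delta = A5+D5 (0–4 Hz), theta = D4 (4–8 Hz), alpha = D3 (8–16 Hz,
approximating 8–13) and beta = D2 (16–32 Hz, approximating 13–30).  The
dyadic alpha/beta edges are honest approximations, so a zero-phase
4th-order Butterworth band-pass scheme at the exact printed cut-offs is
provided as `scheme = "bandpass"` and works at any sampling rate; the DWT
scheme requires 128 Hz and a length divisible by $2^5$ (the periodized
transform needs even lengths at every level).  The transform is
implemented as an orthonormal analysis/adjoint-synthesis pair and
reconstructs to $10^{-10}$ relative error (checked in the tests).

`band_qg_analysis()` refits quantile partitions on each band series (a
band has its own amplitude distribution) and compares two groups band by
band.  The comparison lag defaults to **half the band-centre period**
(delta → capped at $k_{cap}$, theta 11, alpha 6, beta 3 at 128 Hz), i.e.
each band is probed at its own timescale.  We deliberately do not default
to the lag of maximum observed curve separation: choosing the most
separated lag and then testing group means at that same lag is a
selection effect that inflates the type-I error on bands with no true
difference, which we verified empirically on null cohorts.

## The synthetic cohort generator

`generate_cohort()` emulates the study design — four groups (A: controls
eyes open, B: controls eyes closed, C: AD eyes open, D: AD eyes closed),
24 subjects per group, the 19 channels of the 10-20 system, 1024 samples
at 128 Hz — and the qualitative contrast between groups: controls
alpha-dominant, AD "slowed" toward delta/theta, alpha amplitude boosted
with eyes closed and over posterior channels.

Each segment is the sum of:

1. a broadband $1/f$ background limited to 1–30 Hz with fixed,
   group-independent variance (1.0) — real band-limited EEG has rhythmic
   peaks riding on such a background, and this term is what lets a
   band-power change alter the *dynamics* inside a band (a quantile
   partition absorbs pure amplitude scaling, so a band consisting only of
   scaled band-noise would be invisible to the method);
2. per-band rhythms: Gaussian noise with a narrow spectral peak at the
   band centre (width one sixth of the band), scaled to the group's
   band-power profile — defaults: controls $\delta$ 1.0, $\theta$ 0.8,
   $\alpha$ 1.6, $\beta$ 0.6; AD 2.6 / 2.0 / 0.7 / 0.45 (variance units);
3. a 10 Hz AR(2) oscillator ($r = 0.97$) with variance 0.4 (A), 1.4 (B),
   0.15 (C) and 0.5 (D) — the eyes-closed groups get the boost — scaled
   by a channel map (posterior 1.3, frontal 0.8);
4. white sensor noise (sd 0.3).

Per-subject lognormal factors (log-sd 0.15) vary band powers coherently
across a subject's channels.  A per-channel `contrast` factor in $[0,1]$
scales each group's departure from the reference profile, so test
cohorts can carry informative and uninformative channels.  Everything is
deterministic in (seed, group, channel, subject).

What the generator does **not** emulate: eye-blink/EMG artifacts (the
emulated recordings were curated free of them), cross-channel spatial
correlation, non-stationarity within a segment, and any biophysical
cortical model.  Passing recovery tests on this generator therefore shows
the pipeline recovers planted spectral contrasts of realistic size — not
that it diagnoses real patients.

## Numerical choices and degenerate inputs

* Constant series cannot be partitioned and raise an explicit
  degenerate-partition error; `Q > T` and `k >= T` are rejected.
* Supported rows of every transition matrix sum to 1 within $10^{-12}$.
* Lag ties in `select_kmax()` resolve to the smallest lag; community
  detection is deterministic, so the whole pipeline is bit-reproducible
  given the cohort and seed.
* Zero-variance ANOVA inputs use the conventions $p = 1$ (equal means)
  and $p = 0$ (unequal means) rather than erroring mid-pipeline.
* Test problem sizes: the study-shaped runs use 12 subjects per group
  (which makes the three published graph-count totals 1,200 / 22,800 /
  2,400 exact); recovery checks use the full 24 per group on one or two
  channels.

## Limitations

Betweenness normalization and the exact clustering variant for digraphs
are documented package choices among defensible alternatives, not
assertions about the original analysis; both are isolated behind
`betweenness_centrality()` and `clustering_coefficient()`.  The
reproduction of published per-dataset numbers (specific $k_{max}$ values,
ANOVA tables, ROC tables) requires the original EEG recordings, which
this package does not ship; with a user-supplied cohort in the long-TSV
layout the same pipeline applies unchanged.
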