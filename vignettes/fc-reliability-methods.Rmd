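---
title: "Estimating functional-connectome reliability across scan durations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating functional-connectome reliability across scan durations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcreliab)
```

# The measurement model

A subject's functional connectome is estimated as the Fisher-z
transformed Pearson correlation matrix of parcellated BOLD time series,
computed over post-censored volumes. Two quantities summarize how trustworthy
that estimate is at a given scan duration:

* **FC-TRC** (test–retest correlation): the Pearson correlation between
  the upper-triangle edge vectors of two connectomes built from
  independent splits of one subject's data. It measures within-subject
  stability of the whole connectome.
* **ICC(2,1)**: the two-way random-effects, absolute-agreement,
  single-measure intraclass correlation across subjects' paired
  split-half measurements. With MSR, MSC, and MSE the between-subject,
  between-measurement, and residual mean squares of the n × k table,

  $$\mathrm{ICC} = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)}.$$

  It measures whether between-subject differences exceed within-subject
  measurement noise — the quantity that matters for individual-difference
  research.

Both rise asymptotically with the amount of data entering each split,
because the sampling variance of a correlation-based edge estimate falls
roughly as $1/T$. The practical output is the *time-to-threshold*: the
post-censored duration at which a subject's FC-TRC curve first reaches
0.8, linearly interpolated between grid points.

## Split-session and iterative curves

The split-session estimator partitions the four sessions into halves
({1,4} vs {2,3}, {1,2} vs {3,4}, {1,3} vs {2,4}), concatenates each
half's censored volumes in acquisition order, truncates both halves to
the first T post-censored minutes, and averages the three resulting
edge-vector correlations. Truncation to the *first* T minutes mirrors
what a shorter acquisition would have collected; an evenly-spaced-chunk
alternative was considered and rejected as less faithful to a truncated
scan. A duration is reported only when every half of every pairing can
supply it, so curves from different splits are always built from matched
data quantities.

The iterative estimator tiles the full censored concatenation into
1-minute chunks (the trailing partial chunk is dropped — the alignment
is deterministic given the mask), samples chunks without replacement into
a 60-minute "true" reference, and correlates the reference connectome
with connectomes built from T minutes of the remaining chunks, averaging
over iterations. Chunks may span run boundaries, since the data are
concatenated before chunking. Because the residual subsets ignore
temporal ordering, within-session autocorrelation inflates the iterative
estimate relative to the split-session one on real data; on this
package's synthetic data (temporally independent volumes) the two agree
when the information on both sides is matched, which is how the
method-agreement check is constructed: split-session TRC at 10 minutes is
compared with an iterative TRC using a 10-minute reference at a 10-minute
residual duration. With a longer reference the iterative value at
duration T estimates $\sqrt{R_{\mathrm{ref}}\,R_T}$ rather than $R_T$,
so matching reference and evaluation duration is the fair comparison.

## Motion handling

The FD formula is the Power convention: sum of absolute backward
differences of the six rigid-body parameters, rotations converted to arc
length on a 50 mm sphere, FD of the first volume defined as 0. "Above
threshold" is read strictly: FD > 0.15 mm is censored, FD = 0.15 mm is
retained. Before FD computation, high-frequency pseudo-motion (chiefly
respiration aliased into the phase-encoding direction) can be removed
with a zero-phase order-4 Butterworth low-pass at 0.1 Hz, applied by
default only to the anterior–posterior translation; censoring operates on
the filtered FD by default, with a flag for raw FD, since the two
orderings are both defensible and the choice is not settled by
convention. Rotations are assumed to be in radians; a degree converter is
provided. No pre-/post-contamination extension of the censor mask is
applied by default.

## Motion-group classification

Subjects are grouped by how much data survives censoring. Normal
densities are fitted to each age group's post-censored volume counts
(mean and SD — a two-parameter family is the minimal choice that makes
"intersection" well defined from summary statistics; a kernel-density
alternative is available), and the threshold is the equal-density root
between the two means. Counts *below* the threshold mean more data lost
to motion, so those subjects form the high-motion group; ties go to low
motion. A pre-classification filter excludes subjects with under 40
minutes of usable data.

# The synthetic cohort generator

The generator is the package's test surface: it emulates a parent–child
precision-fMRI design — 24 pairs, 4 sessions, 3 passive-viewing
conditions × 2 runs × 205 volumes at TR = 2 s — with known ground truth
at every level. It does **not** model hemodynamics, spatial geometry,
autocorrelation, or respiration physics; volumes are i.i.d. multivariate
normal draws. Consequences: passing tests demonstrate correct
bookkeeping, estimator behavior, and parameter recovery under the
stated model, not robustness to autocorrelated or non-Gaussian noise.

* **Latent connectomes.** Each group has a block-structured correlation
  template (within-network r = 0.35 by default). A subject's connectome
  adds symmetric Gaussian noise (SD 0.1) to the Fisher-z of the
  template's off-diagonal entries, transforms back, and projects to the
  nearest correlation matrix — keeping entries in (−1, 1) and the matrix
  PSD while making the deviation scale interpretable in z units.
* **Signal.** A run is `sd_multiplier * sqrt(latent) %*% Z` plus
  i.i.d. observation noise (SD 0.5 by default). The noise level was fixed
  once so that default whole-connectome reliability curves cross 0.8
  within roughly 15–20 post-censored minutes — the regime the method is
  designed to interrogate; it is a generator constant, not a fitted
  quantity. Per-condition SD multipliers and burst-rate multipliers are
  the two condition-effect mechanisms; no evoked responses are modeled.
  An optional session-specific Fisher-z offset (default 0) emulates
  day-to-day state variance and bounds the TRC asymptote below 1.
* **Motion.** FD is a two-state process: a constant per-subject baseline
  floor (the generator's deterministic stand-in for the tight FD floor of
  low-motion scans, which also keeps the censoring rate analytic:
  `P(FD > t) = p_burst * P(baseline + M > t)` with lognormal M), plus
  lognormal bursts with per-volume probability. Burst magnitudes center
  near the 0.15 mm threshold (meanlog log 0.15, sdlog 1), so roughly a
  third of bursts survive censoring — the mechanism by which motion
  degrades reliability *after* censoring. Burst indicators are drawn from
  a per-volume uniform stream, so under a fixed seed the burst set at
  probability p is nested in the set at 2p: doubling the burst rate
  strictly increases censoring for every subject by construction.
* **Artifact.** During spikes, a rank-one artifact
  (`scale * w %o% max(FD - baseline, 0)`, w redrawn per run, scale 15)
  contaminates the signal with amplitude comparable to the signal SD at
  FD ≈ 0.1 mm — the realistic regime in which sub-threshold motion
  visibly corrupts FC. Because w varies across runs, the artifact
  decorrelates split halves rather than canceling.
* **Heterogeneity.** Adults draw burst rates from a low range
  (0.005–0.05); children split into lower- (0.02–0.10) and higher-motion
  (0.15–0.45) subsets at the 14/24 ratio, giving the adult-low /
  child-mixed structure that the grouping stage is meant to recover.
* **Behavior.** Surveys are simulated with condition-dependent recall
  and drowsiness probabilities (more drowsiness, less recall for
  low-engagement clips) purely so the scoring stage has end-to-end
  input.

## Network-structured subject differences

For the pre- vs post-averaging ICC comparison, the edge-level simulation
gives subject deviations a network-block-shared component in addition to
an edge-level one. This is deliberate: individual connectome differences
are network-structured in real data, and it is exactly this structure
that block-averaging preserves while canceling edge-level noise. Without
it (subject deviations independent across edges), averaging would dilute
the between-subject signal as fast as the noise and pre-averaging would
*lose* — the property being tested is a claim about data with
network-level individual differences, not about arbitrary noise.

# Numerical choices and degenerate inputs

* Fisher z at |r| = 1 (possible on tiny inputs) clips to ±(1 − 1e−7)
  with a warning instead of erroring, so toy examples run.
* tSD uses the sample (n − 1) SD.
* The published ICC category bins leave (0.59, 0.6) unmapped; the
  implemented bins are contiguous — poor (≤ 0.4, including negatives),
  fair (0.4, 0.6), good [0.6, 0.75), excellent [0.75, ∞) — and cover
  [−1, 1] exactly. Negative ICCs are retained in matrices and floored
  only at binning.
* Template-matching similarity is the Pearson correlation between a
  node's FC profile (self-connection removed) and each network's binary
  membership vector, with eta² as an alternative metric; ties break to
  the first network in canonical order with a warning. This operates at
  parcel resolution — a desk-scale stand-in for the vertex-level
  procedure, a change of resolution rather than of method.
* Edge-wise ICC operates on Fisher-z edges for consistency with the TRC
  stages.
* Time-to-threshold interpolates linearly between bracketing grid
  points; reported off-grid values imply some interpolation was used and
  linear is the minimal assumption.
* The equal-density threshold solves the normal equal-density quadratic
  and takes the root between the means; with equal SDs it is the
  midpoint, and a midpoint fallback is available for pathological SDs.
* Seeds derive from a single master seed through an exact-in-doubles
  linear congruential mix, keeping every derived seed below 2^31.

# Problem sizes

Simulation-based tests run at reduced scale chosen to keep the full
suite fast while preserving the tested property: reliability-curve
properties use 20-subject cohorts with 100 nodes and 115-volume runs
(each split half then supports the 5–40-minute grid after censoring);
motion-effect checks use 8 subjects at 50 nodes with the full 205-volume
design; averaging-order checks simulate edges directly for 30 subjects
over 6 networks; the demo pipeline uses 8 subjects, 40 nodes, and
75-volume runs. The generator itself defaults to the full study-shaped
design (48 subjects, 1,152 runs).

# Known limitations

* No temporal autocorrelation: the split-session vs iterative inflation
  seen on real data is directional only, not reproduced quantitatively.
* No vertex-level geometry; template matching and consensus maps work on
  parcels.
* Inferential statistics around the descriptive outputs (mixed-effects
  models on time-to-threshold, ANOVAs on retention or behavior) are out
  of scope; the pipeline exports the per-subject tables those models
  would consume.
* The behavioral simulator is plumbing for the scoring code, not a model
  of attention or drowsiness.
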