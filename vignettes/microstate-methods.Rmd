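---
title: "Resting-state EEG microstate analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The scientific problem

Spontaneous multichannel EEG does not wander continuously through
topography space: the scalp potential field stays quasi-stable for roughly
80–120 ms and then switches abruptly to a different configuration. These
quasi-stable periods — *microstates* — tile the recording, and in
resting-state data four archetypal classes (labeled A–D) recur across
studies: A with a right-frontal / left-occipital diagonal axis, B with the
mirrored diagonal, C with an anterior–posterior axis, and D with a
fronto-central maximum. Their temporal statistics (how long each class
dwells, how often it recurs, what share of time it occupies) are
interpretable proxies for large-scale network dynamics, and group
comparisons of those statistics — for example between autistic and
typically developing children recorded with eyes closed and eyes open —
are the typical study design this package serves.

`microstatr` implements the complete chain: preprocessing of continuous
EEG, polarity-invariant topographic clustering (T-AAHC), template sorting,
backfitting, parameter extraction, and the two-group × two-condition
mixed-design ANOVA, plus a synthetic-cohort generator so that every stage
can be validated by parameter recovery against a known ground truth —
something impossible with real resting-state data, where the true state
sequence is unobservable.

## The measurement model

**Global field power.** At each time point the average-referenced frame
$v(t) \in \mathbb{R}^{N}$ is summarized by its population standard
deviation across the $N$ electrodes,
$\mathrm{GFP}(t) = \sqrt{\tfrac1N \sum_i (v_i(t) - \bar v(t))^2}$,
a reference-free measure of momentary field strength. Topographies are
sampled at the local maxima of the GFP curve, where the signal-to-noise
ratio of the field configuration is highest.

**T-AAHC clustering.** The peak maps are clustered bottom-up: every map
starts as its own cluster; at each step the cluster contributing the least
global explained variance, $\sum_{t \in c} (\mathrm{GFP}(t)\,
r(v(t), \mu_c))^2$, is *atomized* and its members are re-assigned to the
surviving cluster with the highest absolute spatial Pearson correlation,
until `K = 4` clusters remain. Similarity always uses $|r|$: for
spontaneous EEG a map and its polarity reversal are the same state.
Cluster centroids are the first principal component of the member maps,
re-centered to zero mean and unit norm — unlike a sign-aligned mean this
is invariant to the order in which members arrive. Ties at the atomization
step are broken deterministically (fewer members, then lower index), and a
GFP-peak plateau contributes one map, at its first sample.

**Two-level maps and sorting.** Individual template sets are pooled (each
map rescaled to unit GFP so participants weigh equally) and re-clustered
into group-level maps per group × condition. Group maps are matched to the
canonical A–D set by exhaustive evaluation of all $K! = 24$ label
assignments, maximizing total $|r|$, with polarities flipped so the
correlation to the matched canonical map is positive. Individual sets can
be ordered the same way against their group maps.

**Backfitting and parameters.** Every sample of the cleaned, epoched,
average-referenced data — not only GFP peaks — is labeled with the class
whose template it matches best by $|r|$, with no temporal smoothing and no
minimum-correlation rejection. From the label sequence we compute, per
class: global explained variance
$\mathrm{GEV}_k = \sum_{t: L(t)=k} (\mathrm{GFP}(t) r_t)^2 /
\sum_t \mathrm{GFP}(t)^2$; mean duration (ms) of the contiguous runs;
frequency (run onsets per second); coverage (time share); mean GFP during
the state; and the zero-diagonal transition probability matrix
(within-epoch transitions only).

Runs touching an epoch boundary are excluded from duration and frequency
by default: a 2 s epoch truncates roughly two runs, and counting the cut
fragments biases the mean downward. Coverage always uses every sample — it
is a time share, not a run statistic. Both conventions are exposed
(`include_truncated`), and in the all-runs mode the identity
$\mathrm{coverage}_k = \mathrm{frequency}_k \times \mathrm{duration}_k$
holds to machine precision, which the tests assert.

## Preprocessing

The preprocessing chain mirrors a standard resting-state protocol, in this
order: down-sample to 125 Hz, zero-phase band-pass 2–20 Hz with a 60 Hz
notch, cut into 2 s epochs with per-channel baseline correction, flag
artifact epochs, keep the first 10 artifact-free epochs (20 s of analyzed
data per condition), interpolate bad channels, and re-reference to the
common average.

Numerical choices worth stating:

* **Anti-alias filter.** Decimation is preceded by a linear-phase
  windowed-sinc FIR (cutoff $0.4 f_s^{\text{new}}$, Hamming window,
  transition width $0.07 f_s^{\text{new}}$) applied by centered
  convolution, which is exactly zero-phase by symmetry. A low-order
  two-pass IIR cannot reach the required stopband attenuation that close
  to the new Nyquist frequency: a tone at $0.88\times$ Nyquist must leave
  less than 5% residual, which the FIR achieves with margin.
* **Band-pass and notch.** Forward–backward Butterworth (two-pass order
  4) for the band; an RBJ biquad notch with quality factor 30 at the mains
  frequency, also run forward–backward. Zero phase matters because
  microstate boundaries are timing claims.
* **Artifact flagging.** Interactive artifact screening is not
  reproducible, so a deterministic rule stands in: a channel is bad within
  an epoch if its peak-to-peak amplitude exceeds 200 µV or falls below
  0.5 µV (flat); an epoch is rejected when more than 10% of channels
  exceed the amplitude bound (or ≥ 25% of channels are bad, making
  interpolation unreliable). The flag set grows monotonically as the
  amplitude threshold is lowered.
* **Spherical-spline interpolation.** Perrin-style splines with stiffness
  $m = 4$, 50 Legendre terms and ridge regularization $10^{-8}$. The
  constrained system (coefficients sum to zero, plus a constant term) is
  solved on the good channels only; good channels pass through
  bit-for-bit. Reconstruction of a held-out channel of a smooth low-order
  field on 32 channels errs by well under 2% of the field RMS; fields in
  the spline's own span are reproduced to numerical precision.

The online acquisition filter (a wide 0.1–100 Hz hardware band) is not
modeled: the offline 2–20 Hz band is strictly inside it and dominates the
response.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated.

* **Geometry.** Electrodes are a Fibonacci lattice on the spherical cap
  $z \ge -0.2$ (scalp coverage to just below the equator). The default is
  32 channels — template recovery and backfit accuracy were verified to be
  insensitive to montage density (32 vs 128) because both signal and noise
  are spatially smooth — with 128 available by argument.
* **Templates.** The four canonical maps are built analytically from the
  montage axes: A $\propto x + y$, B $\propto -x + y$, C $\propto y$, D a
  radial fronto-central Gaussian bump; each average-referenced and
  unit-normalized. Note these analytic maps are *mutually correlated* (C
  shares its anterior–posterior axis with both diagonals,
  $|r(A,C)| \approx 0.7$) — as real canonical maps are — which matters for
  identifiability below.
* **State dynamics.** A hidden semi-Markov process: run lengths are gamma
  (shape 4 — right-skewed, strictly positive, matching 80–120 ms
  quasi-stability without heavy tails) with class-specific means, rounded
  to ≥ 1 sample; the next class is drawn from a zero-diagonal transition
  matrix (uniform by default). The sequence is generated continuously and
  then cut into epochs, so boundary-truncated runs occur exactly as in
  real segmented data.
* **Signal and noise.** Each sample is the active template scaled by
  $|N(1, 0.2^2)| \times$ a 10 µV GFP scale (Table-typical resting GFP
  values are 5–12 µV), plus additive noise that is temporally pink (1/f
  power) per channel and spatially mixed by a Gaussian kernel of width
  0.6 rad over inter-electrode great-circle distances, scaled to a given
  signal-to-noise ratio (clean RMS over noise RMS; the study default
  is 2). Smooth, autocorrelated noise is deliberately hard: it defeats
  per-channel thresholds and mimics EEG background.
* **Cohort structure.** Two groups (13 + 13 by default) × two conditions
  (EC, EO), 10 × 2 s epochs per condition at 125 Hz. Each participant
  receives a jittered copy of the templates (additive perturbation with sd
  0.25, keeping $|r| > 0.9$ to canon — the literature does not quantify
  inter-participant topographic variability, so this is a modeling choice)
  and a lognormal multiplier (sdlog 0.1) on all duration means. Programmed
  effects multiply one class's mean duration in chosen group × condition
  cells. Covariates (age, IQ, two symptom scales) are drawn from
  group-specific normal models with realistic separations, truncated at
  zero.
* **Generation polarity.** Frames are always emitted with positive
  template polarity; polarity invariance is exercised downstream by
  explicit sign-flip tests, keeping the ground truth unambiguous.

What the generator does **not** emulate: eye-blink/EMG artifact
morphology (artifact tests inject amplitude spikes), alpha-band
oscillatory structure in the amplitude envelope, volume-conduction
forward models, and non-stationarity across the recording. Passing
recovery tests therefore demonstrates correctness of the algorithms under
the stated generative assumptions, not performance on any particular real
dataset.

## What recovery tests show — and a known limitation

With noise-free data the chain is exactly identifiable: T-AAHC centroids
match the generating maps to $|r| \ge 0.999$, backfit labels agree with
the ground truth at ≥ 99% of samples, and total GEV is 1. Coverage is
extremely robust: at SNR 2 the cohort-level class coverages recover the
programmed stationary shares within ±0.015.

Durations are different, and the bias is worth understanding rather than
hiding. At SNR 2, per-sample backfit accuracy is about 94%: the noise is
spatially smooth and therefore lives in the same low-dimensional subspace
as the (mutually correlated) templates, so occasional frames correlate
better with a neighbouring class — most often C's neighbours A and B. A
mislabeled sample splits a run in two, so with ~10-sample runs the
*recovered* mean durations shrink by tens of percent, and class C (the
most confusable) shrinks the most, which can even reorder the class means.
At SNR 4 the same pipeline recovers durations within ±7% with the correct
rank order. Because backfitting deliberately applies no temporal smoothing
(matching the analysis protocol being reproduced), this attenuation is an
inherent property of sample-wise labeling at low SNR — it is the same
reason empirical microstate duration estimates depend on preprocessing
choices. The acceptance suite asserts the ±15% recovery band at SNR 2 as
specified and documents its failure rather than relaxing the band or
quietly raising the SNR; treat recovered durations at low SNR as
attenuated estimates, ordinally meaningful only when classes are well
separated.

For the same reason, the Monte-Carlo power analysis of the group ×
condition interaction (`interaction_power_sim()`) defaults to measuring
durations on the generator's ground-truth label sequences: it answers the
design question — can a 2 × 2 mixed design with 13 participants per group
detect a +20% duration change in one cell? (yes: power ≈ 1.0 at the
default geometry) — without conflating it with backfit attenuation. The
`measure = "backfit"` route exposes the conflated version, whose power at
SNR 2 drops to roughly a third.

## Statistics

Each parameter × class is tested with the classical two-group ×
two-condition mixed-design decomposition: the group effect against
subjects-within-groups, condition and interaction against the
condition × subject residual; partial
$\eta^2 = SS_{\text{effect}} / (SS_{\text{effect}} + SS_{\text{error}})$.
The implementation is closed-form on cell and subject means and is
verified in the tests against both `stats::aov` with an `Error` stratum
and an independent brute-force sums-of-squares oracle (agreement to
$10^{-8}$ relative). Complete cases only: a participant missing a
condition is dropped with a warning, never imputed.

*Observed power* follows the retrospective convention of mainstream
statistics packages: noncentrality $\lambda = F \cdot df_1$, power
$= P(F'(df_1, df_2, \lambda) > F_{\text{crit}}(\alpha))$. Retrospective
power is a deterministic transform of the observed F and should be read
as descriptive, not as a replication probability. Significant interactions
are decomposed into four simple effects — paired t within each group
across conditions, pooled-variance two-sample t within each condition
across groups (Welch by flag) — at the Bonferroni-corrected threshold
$0.05 / 4 = 0.0125$. Degenerate cells (zero variance) are handled
explicitly: a certain zero difference gives $t = 0$, a certain nonzero
difference $|t| = \infty$.

Covariate correlations transform the (skewed, non-negative) covariate as
$\log(x+1)$ and report Pearson's r with a two-sided p, Bonferroni-adjusted
over the declared family — by default the class-C frequency in the first
condition against four covariates, i.e. a family of four at 0.0125. The
type-I error of both the interaction test and the correlation test is
verified by null simulation (1000 and 500 replicates respectively,
nominal 0.05 within Monte-Carlo bounds).

The per-analysis sample-size variations seen in published tables (error
dfs of 21–24 for the same cohort) imply undocumented per-analysis
exclusions; this implementation analyzes complete cases uniformly, so all
error dfs equal $N - 2$.

## Problem sizes and degenerate inputs

The shipped validation uses desk-scale problem sizes chosen once: 32
channels, 26 participants × 2 conditions × 10 × 2 s epochs at 125 Hz for
cohort recovery; 200 replicates for the power curve and 1000 for null
calibration; single-recording property tests use 2–100 epochs as the
property demands. Degenerate inputs are defined, not accidental: a
constant frame inherits the previous label (class 1 at an epoch start) and
is counted; a class absent from a segmentation reports `NA` duration and
GFP (never 0) and an all-zero transition row; an all-zero GFP curve makes
GEV an error; clustering refuses `K` larger than the number of maps;
interpolation refuses ≥ 25% bad channels and duplicate electrode sites.

## Using the pipeline

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(seed = 1, simulate = list(
  groups = c(TD = 13L, ASD = 13L),
  effects = list(list(group = "ASD", condition = "EC",
                      class = "C", factor = 1.2)))))
head(res$parameters)     # tidy: participant, group, condition, class, parameter, value
res$anova                # F, p, partial eta squared, observed power per effect
res$posthoc              # Bonferroni-corrected simple effects at 0.0125
res$correlations         # log(x+1) Pearson family
```

Every result bundle carries the configuration hash and a per-stage log,
and identical seed + configuration reproduce the parameter table
bit-for-bit. EDF export/import (`write_cohort()`, `read_edf()`) allows the
same pipeline to run from files on disk via a manifest CSV.
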