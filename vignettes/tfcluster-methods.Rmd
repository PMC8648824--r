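---
title: "Methods: factor coding, time-frequency estimation and cluster permutation inference in tfcluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factor coding, time-frequency estimation and cluster permutation inference in tfcluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcluster)
```

## The experimental model

The package analyses EEG from cue-stimulus experiments in which a
probabilistic cue announces the modality and intensity of an upcoming
affective stimulus. Cues predict the modality correctly in 70% of trials and
the intensity in 60%, with the remaining intensity mass split equally
between the two wrong levels; the two contingencies are treated as
independent, so each of the six cue types distributes its trials over
stimulus outcomes as 0.42/0.14/0.14 (congruent modality) and
0.18/0.06/0.06 (incongruent). `build_trial_schedule()` realises these
proportions *exactly*, which requires the per-cue trial count to be a
multiple of 50; a 126-trial block design can only approximate them, so the
generator takes `n_per_cue` and enforces integrality instead of replicating
a fixed block length. Pseudorandomisation is a uniform seeded shuffle with
no run-length constraints. Catch trials (cue only, response probe, no
stimulus) are appended per block and carry no stimulus fields.

Each modality-congruent picture condition is coded by three within-subject
factors over the 3 x 3 cue-by-stimulus grid:

* **INT** — stimulus intensity, linear code -1/0/1 for low/medium/high;
* **EXP** — expectation, the same linear code applied to the cued intensity;
* **PE** — absolute prediction error, `|EXP - INT|`, taking values 0/1/2
  with 3/4/2 cells per level.

Under equal cell weighting PE is orthogonal to both linear factors
(`sum(INT * PE) = sum(EXP * PE) = 0`), which is what makes the three
one-way tests on cell averages well defined.

## Synthetic EEG generator

`simulate_subject_eeg()` produces stimulus-locked epochs for the analysed
(picture-cued, picture-stimulus) trials as

* per-channel independent 1/f background noise (spectrally shaped white
  noise, exponent 1, normalised to a configurable standard deviation), plus
* three band-limited oscillations — alpha (10 +- 2 Hz), beta (20 +- 3 Hz)
  and gamma (55 +- 10 Hz) — with per-trial uniform random phase and
  frequency jitter, weighted over channels by smooth Gaussian-bump
  topographies.

Oscillations are amplitude-modulated sinusoids; random per-trial phase
makes the activity induced (non-phase-locked), matching the
event-related-desynchronisation phenomenology. Evoked (phase-locked)
components are deliberately not modelled. Within 0-2000 ms post-stimulus
the alpha and beta amplitudes are multiplied by
`1 + g_pe_low*PE - g_int*INT - g_exp*EXP` and the gamma amplitude by
`1 + g_pe_gamma*PE`; the window has 100 ms cosine ramps to avoid spectral
splatter, and the 0-2000 ms extent mirrors the two-second stimulus
presentation. Because modulation is multiplicative on amplitude, band power
scales as `(1 + m)^2`, which the tests use as a closed-form oracle.

No published effect magnitudes exist in raw-signal units, so the default
amplitudes and gains (`amp_alpha = 10`, `amp_beta = 7`, `amp_gamma = 5`
against `noise_scale = 10`; `g_int = g_exp = 0.3`, `g_pe_low = 0.12`,
`g_pe_gamma = 0.45`) were fixed once, by a small calibration at the desk
scale, to give reliable recovery of all three injected effects with twelve
subjects; they are not tuned to any real signal-to-noise ratio. The
positivity constraint `|m| < 1` over all nine cells is validated at
construction.

Ratings follow a latent-variable model: `u = beta0 + beta_int*INT +
beta_pe*PE + N(0, sigma)`, rounded half-up and clipped to the 1-4 scale.
EXP carries no latent effect. The default intercept is `beta0 = 2.2`: with
`beta_pe = 0.3` and mean PE of 1 this centres the effective latent mean at
2.5, the midpoint of the rating scale. Centring matters because clipping is
nonlinear and the mean PE per EXP level is unbalanced (1, 2/3, 1 across the
three EXP levels); an off-centre scale lets floor/ceiling saturation leak a
spurious linear EXP trend into the cell means. At `beta0 = 2.2` the exact
clipping-induced EXP slope bias is zero.

What the generator does **not** emulate: volume-conducted forward models
(topographies are arbitrary smooth maps, not dipole projections), eye/muscle
artifacts, between-subject variability in effect size (all subjects share
one effect spec; subject differences arise only from sampling noise), pain
trials (scheduled but given no EEG), and evoked potentials. Passing
recovery tests therefore demonstrates correctness of the inference
machinery under the assumed generative model, not robustness to artifacts
or realistic inter-subject heterogeneity.

## Preprocessing and time-frequency estimation

Epochs are centred and linearly detrended per trial and channel, band-pass
filtered at 1-100 Hz with a 4th-order Butterworth, and re-referenced to the
common average. The filter applies the squared Butterworth magnitude
response (the forward-backward, zero-phase response) multiplicatively in
the frequency domain, with traces zero-padded to a 2-3-5-smooth FFT length;
this is transient-free and exactly zero phase, and it matches
`signal::filtfilt`'s steady-state amplitude to within 1% in the tests.
Cue-locked and stimulus-locked datasets are produced by integer-sample
re-alignment using each trial's cue-stimulus onset asynchrony (1500-1900
ms), cropped to the time range common to all trials.

Low frequencies (1-30 Hz, 1 Hz steps) use a sliding 300 ms Hanning window;
high frequencies (31-100 Hz) use a sliding 200 ms multitaper window with
15 Hz spectral smoothing. The time-bandwidth product is 0.2 s x 15 Hz = 3,
and the taper count follows the standard rule `K = floor(2*T*W) - 1 = 5`;
the Slepian sequences are computed from the symmetric tridiagonal
eigenproblem and verified orthonormal and spectrally concentrated in the
tests. Power at each requested frequency is the squared magnitude of the
tapered segment's projection onto a complex exponential at *exactly* that
frequency, not the nearest padded-FFT bin, so the 1 Hz stepping is
independent of window length. Window centres advance in 50 ms steps;
windows that would need samples outside the epoch are dropped (no padding).
A `center_windows` argument restricts computation to the window centres an
analysis actually uses (baseline plus test window).

Spectral estimates are averaged per subject within each of the nine
condition cells (trial counts recorded), then z-baselined: for every
channel-frequency combination the baseline mean and standard deviation are
estimated from the *all-trial* average (cells pooled with trial-count
weights) over the baseline window, and every value is transformed to
`(x - mean)/SD`. The SD uses the sample (N-1) convention over baseline time
points. Pooling over all conditions (rather than per condition) was chosen
because a condition-specific baseline would absorb genuine condition
effects into the normalisation; with this convention the all-trial-average
baseline is exactly mean 0, SD 1, which the tests check to 1e-10. The
cue-locked baseline is (-650, -150) ms — ending 150 ms before cue onset
because of the 150 ms half-taper length — and the stimulus-locked baseline
is the same physical window shifted by the maximal 1900 ms cue-stimulus
interval: (-2550, -2050) ms.

## Statistics

The per-sample statistic is a single-degree-of-freedom repeated-measures
linear trend: the nine cells are first collapsed (unweighted) to the three
factor-level means, each subject's level means are regressed on the level
codes, and the per-subject slopes are tested against zero with a one-sample
t; `F = t^2` with df `(1, n-1)`. This reading — rather than an omnibus
two-df ANOVA — follows from the reported single-df form of the group
statistic and from summarising each factor by its average subject slope;
the omnibus variant is deliberately not implemented. The statistic is
invariant to affine recoding of the levels.

Cluster inference follows the nonparametric max-statistic scheme:

* supra-threshold samples (`F > threshold`, strictly — a sample exactly at
  threshold is excluded) are split by the sign of the group-mean slope, so
  every cluster is sign-pure;
* each sign's mask passes a spatial restriction: a sample survives only if
  at least one neighbouring channel is also supra-threshold at the same
  frequency and time;
* connected components are formed under orthogonal adjacency — adjacent
  time steps, +-1 frequency step, and montage-neighbour channels — and each
  cluster's value is its summed F.

The default cluster-forming threshold is the parametric upper-5% critical
value `f_critical(1, n-1, 0.05)`; with 29 subjects this is F(1,28) = 4.196.
The permutation null relabels, independently per subject and permutation, the
assignment of the three level means to the level codes (uniform over the six
permutations, seeded), recomputes the full map-threshold-filter-cluster
chain, and records the maximum positive and negative cluster values. A
cluster's tail probability is the plain proportion of same-sign permutation
maxima at or above its value (it can be 0; an `add_one` option gives
`(b+1)/(n+1)`).

Two-sided control: the test is applied two-sided over negative and positive
clusters. Comparing each tail to the full alpha would double the family
error rate to ~0.10, so the default reports the doubled tail probability
(capped at 1) and declares significance at `p < alpha`, giving an overall
two-tailed level of alpha; `tail = "per-tail"` provides the uncorrected
variant. The type-I simulation in the acceptance suite checks the default's
realised error rate against the nominal 0.05.

Post-hoc tests average the z-values over all channel-frequency-time samples
of a significant cluster per subject and factor level, compare the three
level pairs with paired t-tests, and Bonferroni-correct by 3. Identical
level values yield t = 0, p = 1; a constant nonzero difference with zero
variance is reported as a degenerate error. Ratings are tested with the same
linear-trend statistic on the subject-by-9-cell mean table, with parametric
F(1, n-1) p-values.

The pipeline's test matrix mirrors the factorial design: stimulus-locked
data are tested for INT, EXP and PE in both frequency bands (six analyses)
and cue-locked data for EXP in both bands (two analyses); test windows are
0-2000 ms post-stimulus and 0-1500 ms post-cue, clipping TFR samples by
window-centre timestamp within the closed interval.

## Validation problem sizes

The desk-scale configuration used throughout the simulation studies is 12
subjects, a 4 x 4 grid montage (16 channels, 4-connected neighbours),
250 Hz, and 27 trials per condition cell. The probabilistic design cannot
produce equal cell counts (intensity-congruent cells receive three times
the off-diagonal mass), so simulation studies of the inference machinery
use `build_balanced_schedule()`, while design-level tests and the pipeline
demonstration use the probabilistic `build_trial_schedule()` with
`n_per_cue = 50` (21/7 trials per cell). Monte-Carlo studies use reduced
spectral grids (2 Hz steps in the low band, 3 Hz steps in the high band;
8-18 Hz and 3 trials/cell for the 200-dataset type-I study) and 200
permutations; these sizes were chosen to keep each study at the scale of
minutes while preserving the inference problem. Oracle equivalences
(clustering vs brute-force flood fill; the trend statistic vs per-subject
regression plus a one-sample t) run on 500 and 100 random instances
respectively.

## Known limitations

* The 20 ms-step multitaper variant used in some artifact-inspection
  workflows is not implemented; artifact handling (ICA, trial rejection,
  EOG/EMG) is out of scope because the synthetic data are clean.
* Cluster statistics other than the summed F (max-size, TFCE) and
  between-subject designs are not supported.
* The Hanning window's 300 ms length maps delta/theta frequencies poorly;
  estimates at 1-3 Hz are dominated by spectral leakage, as expected for
  this window choice.
* With only 200 permutations the smallest attainable nonzero two-sided p is
  0.01; studies needing finer resolution should raise `n_perm` (the
  pipeline default is 1000).
* The plain-proportion p-value is slightly anti-conservative relative to
  the `(b+1)/(n+1)` convention; the latter is available via `add_one`.
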