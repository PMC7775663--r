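---
title: "Sensorimotor connectivity and simulated BCI performance: methods"
author: "smrconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensorimotor connectivity and simulated BCI performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrconn)
```

## The scientific question

Motor-imagery brain-computer interfaces (BCIs) decode which movement a user
imagines from the amplitude modulation of sensorimotor rhythms — chiefly the
mu rhythm (9–14 Hz) — yet roughly a fifth of users never gain reliable
control. A candidate neurophysiological explanation is that successful
imagery requires functional coupling between the motor (precentral) and
somatosensory (postcentral) cortices: imagining a movement engages both the
efferent command and the anticipated proprioceptive consequence, and their
integration needs a functioning pathway. If so, the strength of
motor–somatosensory coupling measured during a calibration recording should
predict the accuracy a user later achieves in closed-loop feedback, over and
above what the sheer amplitude (signal-to-noise ratio, SNR) of the rhythms
explains.

`smrconn` implements that entire analysis as a tested pipeline and — because
the original multi-subject recordings are not bundled — exercises it on a
synthetic cohort whose causal structure is planted and therefore known:
coupling strength → imagery quality (ERD depth) → online accuracy. The
pipeline must recover the planted association from raw simulated EEG, and
must *not* find one when the link is severed.

## The generative model

`make_lead_field()` builds the forward model: electrodes on the upper half
of a spherical head, mirror-symmetric across the sagittal plane, and current
dipole sources inside it. Gains are quasi-static homogeneous-medium dipole
potentials, `q·(r_e − r_0) / (4πσ|r_e − r_0|³)`. This is deliberately
simpler than a multi-shell or realistic (BEM/FEM) head: it is smooth,
analytic, exactly mirror-symmetric (which makes the left/right symmetry of
the ROI placement testable to machine precision) and sufficient for the
inverse-modeling properties that matter here, foremost eLORETA's exact
localization of point sources. Four regions of interest — left/right pre-
and post-central — are placed around canonical sensorimotor coordinates;
their size is configurable up to atlas-like sizes (125/112 sources).

Each simulated subject (`simulate_subject()`) is parameterized by a
`subject_ground_truth()`:

* **Oscillation model.** Each hemisphere carries a mu oscillation modeled as
  narrowband Gaussian noise (white noise shaped to the subject's mu band by
  a squared fourth-order Butterworth response), not a sinusoid — real
  sensorimotor rhythms have finite bandwidth, and only a stochastic
  narrowband process exercises the spectral estimators non-trivially
  (coherency below 1 under noise).
* **Coupling.** The postcentral source receives the precentral signal with
  its analytic signal rotated by `coupling_lag` radians, mixed with an
  independent narrowband component weighted `(1 − coupling_strength)`. A
  fixed phase rotation yields a controllable analytic target for the
  imaginary part of coherency; a zero lag with positive coupling is refused
  unless explicitly requested, because zero-lag coupling is invisible to
  that measure.
* **ERD.** During imagery the contralateral hemisphere's amplitude (both
  hemispheres for feet) is scaled by `1 − erd_depth·g(t)`, with `g` a
  raised-cosine ramp from 0.5 s to 1.5 s after the cue. In feedback trials
  the gate is referenced to an arrow cue shown 1 s before cursor onset, as
  in the online protocol being emulated, so the modulation is established
  when scoring starts.
* **Noise.** Background sources carry 1/f ("pink") noise; sensors receive a
  spatially mixed 1/f noise floor at a configurable SNR (default 0 dB).
  Noise spectra are drawn directly in the frequency domain (the real and
  imaginary parts of one complex inverse FFT are two independent
  realizations), which is distributionally identical to filtering white
  noise at half the cost.
* **Subject constancy.** Source orientations, ROI loading vectors, the
  sensor-noise mixing matrix and the noise scale are drawn once per subject
  and shared between the calibration and feedback runs. They are anatomy,
  not noise; re-drawing them per run would make the two recordings
  non-exchangeable and destroy classifier transfer.

`simulate_cohort()` draws per-subject parameters from one seeded generator:
coupling strengths on an even grid over [0.1, 0.9], lags uniform in
[π/3, 2π/3], subject-specific mu bands, and log-normal oscillation power,
optionally confounded with coupling. The default coupling→ERD link is
`erd_depth = 0.05 + 0.35·coupling` (9–37% amplitude suppression), chosen
once so that simulated accuracies span a graded 0.5–1.0 range rather than
saturating; `link = "constant"` severs the causal path and serves as the
negative control. Per-subject seeds derive from the cohort seed by a fixed
affine rule, so cohorts are bitwise reproducible; subject EEG is
materialized on demand (`cohort_subject_data()`) because a full-scale
cohort does not fit in memory at once.

What the generator does **not** emulate: realistic anatomy and volume
conduction, eye/muscle artifacts, non-stationary learning across runs, and
trial-to-trial autocorrelation beyond what the stationary processes imply.
Passing tests therefore certify the *analysis machinery* — filters,
classifiers, inverse solution, spectral statistics, inference — under a
known truth, not the biology of any particular dataset.

## Calibration and simulated feedback

The calibration chain follows the standard sensorimotor-BCI recipe:

1. **Band selection** (`signed_r2_spectrum()`, `select_band()`): per-trial
   Welch band power (1 s Hann segments, 50% overlap, 1 Hz bins, 5–35 Hz,
   post-stimulus samples), the signed point-biserial `r²` between power and
   class per channel and bin, smoothed over 3 Hz; the band grows outward
   from the most discriminative bin while the channel-maximum `|signed r²|`
   stays above one third of the seed value. The growth uses the channel-max
   profile and ignores sign consistency — the simplest reading of the
   one-third rule. A degenerate all-zero map falls back to the canonical mu
   band (9, 14) Hz with a warning.
2. **Interval selection** (`erd_curve()`, `select_interval()`): zero-phase
   band-pass (fourth-order Butterworth magnitude applied in the frequency
   domain, i.e. the exact amplitude response of forward–backward filtering,
   vectorized over channels and trials; a literal `signal::filtfilt` path
   is available), Hilbert envelopes, class-averaged ERD in percent relative
   to the (−0.5, 0) s baseline. The selected window (within 0.75–4 s, at
   least 1 s long) maximizes the time-averaged maximal pairwise class
   contrast; ties resolve to the earliest start and then the *longest*
   window, so a flat contrast yields the full search window, and a
   vanishing contrast yields the canonical (1.5, 3.0) s with a warning.
3. **CSP + LDA** (`fit_csp()`, `logvar_features()`, `fit_lda()`):
   trial-averaged trace-normalized class covariances with analytic
   identity-target shrinkage, generalized eigendecomposition via pooled
   whitening, three filters per spectral end by default (the
   subject-specific count in the emulated study is not specified), log
   variance features, and pooled-covariance LDA with Ledoit–Wolf-style
   shrinkage.
4. **Pair selection** (`chronological_cv()`): five contiguous,
   chronologically ordered folds (remainder trials to the last fold); the
   *entire* chain — band, interval, CSP, LDA — is refit inside every
   training fold; the best of the three class pairs is chosen, ties going
   to the fixed order left/right, left/feet, right/feet.
5. **Feedback** (`simulate_feedback()`): a trailing 750 ms window advanced
   every 40 ms over the 4 s task period (so `1 + ⌊(4 − 0.75)/0.04⌋ = 82`
   classifier outputs, the first when the first full window is available);
   each output is added to an unbounded cursor (no gain or bias adaptation
   — none is described for the emulated system); the trial is a hit if the
   final cursor sign matches the target side, with an exact zero counted as
   a miss. Accuracy is hits over trials; the binomial chance threshold
   (`chance_threshold()`) gives 54.67% for 300 trials at α = 0.05.

Accuracy is an *emergent* quantity — the trained classifier really runs on
held-out simulated trials; nothing maps ground-truth parameters to accuracy
by formula.

## Source connectivity

`eloreta_inverse()` iterates the eLORETA weight equations (per-source 3×3
blocks, `W_s = (L_s' M L_s)^{1/2}` with `M` the regularized pseudoinverse of
the weighted model covariance) to a fixed point; regularization defaults to
5% of mean sensor-space model power. The implementation is validated by the
defining property: a noiseless point source is localized exactly as the
regularization vanishes.

`extract_roi_components()` projects the pre-stimulus (−1, 0) s or
post-stimulus (1.5, 3.0) s interval to source space, normalizes every
source-orientation series to unit variance over the concatenated trials,
and keeps the three leading SVD components per ROI (signs fixed by making
the largest loading positive). Trials of all three classes enter one SVD;
spectra are then computed per class. `cross_spectrum()` treats trials as
realizations: one Hann-tapered, zero-padded FFT per trial and segment,
averaged across trials — the 1 s pre-stimulus segment at 100 Hz leaves no
room for within-trial Welch splitting, so cross-trial averaging is used for
both intervals. The nominal FFT length is 128; a segment longer than that
(the 150-sample post-stimulus interval) doubles it to the next power of
two, keeping zero-padding well defined. `icoh()` is
`|Im(S_ij/√(S_ii·S_jj))|`: nonzero only for stable non-zero phase lags,
insensitive to instantaneous mixing, bounded by one.

`aggregate_icoh()` averages over the 3×3 component pairs of each region
pair, all classes, and the frequency bins whose centers fall in the band
(the canonical mu band and the subject's selected feedback band). The
*within*-hemisphere scheme averages the two intra-hemispheric
motor–sensory pairs; the *across* scheme the four inter-hemispheric pairs
(sensory–motor both ways, motor–motor, sensory–sensory). Pooling all three
calibration classes (rather than only the feedback pair) is one admissible
reading of the emulated analysis; it is fixed here and noted as a choice.

## SNR estimation

`fit_psd_model()` fits, in decibels, a noise baseline `k + a·f^(−b)` and up
to two Gaussian bumps, minimizing the L2 distance between model and PSD.
The baseline is fitted by linear least squares over a deterministic
exponent grid, refit once after masking bins more than one residual SD
above the curve (presumed peaks), then polished with bounded
Levenberg–Marquardt; peaks are initialized on a deterministic
(center, width) grid with linearly solved heights and polished the same
way. No random restarts — fits are reproducible by construction. The dB
scale stabilizes the objective across the 1/f range and makes the SNR
(`snr_from_fit()`: the maximal height of the fitted peak curve above the
fitted noise curve) invariant to rescaling the raw signal. Bumps below
0.5 dB are not retained, so a featureless spectrum reports SNR 0.
`subject_snr()` averages component-level SNRs over ROIs, components and
(optionally) classes for each interval.

The exact parametric forms of the two curves in the emulated analysis are
not published; the forms here are documented substitutes sharing the same
SNR definition (maximal peak-above-noise difference).

## Statistical validation

`spearman_cor()` (Pearson on average ranks, two-sided t-approximation
p-value), `partial_spearman()` (rank residualization on the covariate,
equivalent to the recursion formula; p on n − 3 degrees of freedom),
`fdr_correct()` (Benjamini–Yekutieli by default, Benjamini–Hochberg as an
option) and `permutation_test()` (1,000 subject shuffles, one-sided
comparison of the observed correlation against the 95th percentile of the
null, with a permutation p-value reported alongside) compose
`build_result_table()`: 16 correlations (within/across × post/pre ×
mu/feedback band × raw/SNR-partialled), FDR-corrected jointly across the
table by default (per-column available), each with its permutation flag.
The parametric p-values are two-sided while the permutation rule is
one-sided — the two serve different roles and both are reported.

## Problem sizes and reproducibility

`run_config()` defaults encode the emulated study's constants: 80 subjects,
75 calibration trials per class, 300 feedback trials of the chosen pair,
100 Hz sampling of 0.5–45 Hz band-limited signals, intervals (−1, 0) and
(1.5, 3.0) s, mu band (9, 14) Hz, 1,000 permutations. The package's own
Monte-Carlo validation uses `reduced_run_config()` — 40 subjects, a
10-channel lead field with 3 sources per ROI, 9 calibration and 10 feedback
trials per class, pooled-class grid-only PSD fits — sizes chosen so that a
full 40-subject cohort runs in under half a minute while every
methodological setting stays identical. Under those conditions the planted
link is recovered (positive, permutation-passing within-hemisphere
post-stimulus mu-band correlation that survives SNR partialling) in the
overwhelming majority of seeds, and the severed-link control stays null.

Every stochastic step flows from explicit integer seeds through
self-contained Mersenne-Twister streams that never touch the caller's
global RNG state; identical configurations reproduce results bitwise.

## Known limitations

* The spherical homogeneous forward model and small ROI counts understate
  real volume-conduction complexity; absolute iCOH levels are not
  comparable to those from a realistic head model.
* The online system is replayed without bias/gain adaptation or cursor
  saturation; real closed-loop dynamics (and user learning) are out of
  scope.
* The band-growth rule ignores the sign of `r²` across bins and operates on
  the channel-maximum profile; other readings of the heuristic exist.
* Welch band power for band selection uses post-stimulus samples only;
  small-Laplacian channel derivations are not applied (the pipeline
  operates on the provided channels).
* SNR peak shapes are Gaussian in log-power; knee-type aperiodic models are
  out of scope.
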