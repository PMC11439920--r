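---
title: "Methods: MCCA spatial filtering, cross-validated intersubject correlation, and the pre/post contrast layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MCCA alignment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mccalign)
```

# The problem

When several people process the same continuous stimulus — here, spoken
narratives recorded during MEG — part of their sensor-level activity is
driven by the shared stimulus and part is idiosyncratic. *Neural alignment*
is the degree to which the stimulus-driven component is shared: it is
measured as the intersubject correlation (ISC) of a common signal extracted
from each subject's recording. `mccalign` implements the full chain from
multi-subject sensor matrices to group-level pre/post-intervention
contrasts:

1. deterministic preprocessing (zero-phase band-pass, resampling,
   zero-padding of rejected segments, PCA reduction);
2. MAXVAR multiset canonical correlation analysis (MCCA) to learn, per
   subject, spatial filters whose outputs are maximally correlated across
   subjects;
3. cross-validated ISC of the top canonical component with a circular-shift
   bootstrap null;
4. paired pre/post contrasts on per-subject ISC values with effect sizes,
   a sensitivity power analysis, and FDR correction.

Because raw recordings of such a study are rarely publicly
deposited, the package ships a first-class synthetic-data generator that
emulates the design — two groups (intervention/control), two sessions
(pre/post), two counterbalanced stimulus versions, and four narrative
conditions (political/nonpolitical × congruent/incongruent) — with known
ground truth, so that every stage is testable end to end.

# The model

## Spatial filtering by MAXVAR MCCA

Subject $m$ contributes a data matrix $Z^m$ ($D \times t$). A spatial
filter row $w$ produces a canonical variate $y = w Z^m$. MCCA chooses one
filter matrix $W^m$ per subject so that corresponding variates are
maximally correlated *across* subjects while mutually uncorrelated *within*
a subject.

`fit_maxvar()` solves the MAXVAR criterion in closed form:

* each subject's centred data are sphered by an eigenvalue whitening of its
  covariance (relative eigenvalue floor $10^{-10}$, so rank-deficient
  inputs are handled without explicit regularisation);
* the whitened matrices are stacked and the joint correlation matrix
  $C$ is formed; the top eigenvector of $C$, split into per-subject blocks
  and block-normalised, gives the stage-1 weights — this maximises the
  largest eigenvalue of the correlation matrix of the variates, which is
  the MAXVAR objective;
* each subject's block of $C$ is then deflated by the projector onto the
  orthogonal complement of its weight, and the eigen-step repeats. The
  deflation is what guarantees *exact* within-subject decorrelation of the
  training variates (the test suite checks $|r| < 10^{-6}$); a single joint
  SVD would not, because blocks of different eigenvectors of $C$ are not
  mutually orthogonal within a subject.

At $M = 2$ this construction reduces exactly to classic two-set CCA, which
the test suite uses as an independent oracle (`cancor`, agreement to
$10^{-6}$).

Two sign conventions make the fit deterministic: the global eigenvector
sign is fixed by its largest-magnitude element, and each component's sign
per subject is flipped so that its training variate correlates
non-negatively with the across-subject mean variate. Components are
ordered by the (non-increasing) deflated eigenvalues, i.e. by
across-subject consistency on the training data.

## Activation patterns

Filter weights are not physiologically interpretable; the forward-model
*activation pattern* $A = \Sigma_z W' \Sigma_y$ is. For a single component
`activation_pattern()` uses only that component's variance,
$a_k = \mathrm{Cov}(z, y_k)\,\mathrm{Var}(y_k)$, which is robust when the
full variate covariance is singular, and optionally back-projects through
the PCA loadings to the original channel space. In single-source
simulations the pattern recovers the true mixing vector (cosine $> 0.95$
at snr 2) and is invariant up to scale under invertible re-mixing of a
subject's sensors.

## Cross-validated ISC and the circular-shift null

`crossval_alignment()` splits the recording into $k = 3$ contiguous folds.
Per fold it fits PCA (per subject, on the training portion only, so that no held-out
sample can leak into the reduction) and the MCCA model on the
training folds, projects the held-out fold, computes all
$M(M-1)/2$ pairwise Pearson correlations of each component, pools them by
the Fisher transform $z = \operatorname{arctanh}(r)$ (with $|r|$ clipped
to $1 - 10^{-12}$), and selects the component with the strongest pooled
test-set correlation, ties broken by lowest index. Folds are combined by
the mean of absolute values.

`circular_null()` re-draws the statistic under the null that subjects are
temporally misaligned: every subject's held-out variates are circularly
shifted by an independent uniform lag in $[1, t_{test}-1]$ (lag 0
excluded), and the *entire* observed statistic — including the per-fold
top-component selection — is recomputed, folds combined identically.
Re-running the selection per draw is essential: the observed value is a
maximum over components, and a null that shifted only the selected
component would not be exchangeable with it, destroying calibration. Two
design choices here were genuinely open:

* the null shifts the held-out *variates* rather than the raw sensor data
  with a full refit; refitting $5{,}000\times$ per cell is computationally
  prohibitive, and under the shift the projection is equivariant, so the
  variate-level shift is the same operation at far lower cost;
* lags are drawn independently per subject per draw.

The implementation precomputes circular cross-correlation tables by FFT,
so the per-draw cost is an index lookup; 5,000 draws at study scale or 200
draws in simulation cost essentially the same as the observed statistic.

`p_from_null()` applies the add-one exceedance rule
$p = (1 + \#\{z_{null} \ge z_{obs}\})/(1 + B)$, one-sided because the
mean-absolute statistic has a folded null. Cell p-values across the
analysis family are adjusted by Benjamini–Hochberg (`fdr_adjust()`).

Under a pure-noise cell the statistic is a fixed function of jointly
shifted series that are circularly exchangeable, so p-values are uniform;
the test suite verifies calibration empirically (type-I error within
[0.035, 0.065] at $\alpha = 0.05$ over 1,000 simulated cells, 200 draws
each).

## The contrast layer

`subject_isc()` reduces an alignment result to one scalar per subject (the
Fisher-z mean of that subject's $M-1$ pairwise correlations, folds
combined by mean absolute value). `build_contrast_table()` averages these
across the two stimulus versions and runs a *paired* t-test on post − pre
differences per (group × condition), with $d = t/\sqrt{n}$ and BH-adjusted
p-values. The paired form (df $= n - 1$) is the natural test for the
within-subject design: each subject is their own control. Between-group tests on MCCA values
are deliberately not offered: values from different MCCA models are not
comparable across groups, so only the within-group pre/post path is
exposed. `welch_t()` and `cohens_d_pooled()` operate on summary statistics
for the self-report measures, and `sensitivity_power()` inverts the exact
noncentral-t power function (uniroot, tolerance $10^{-6}$) to give the
minimal detectable effect size of the paired design — $d = 0.47$ at
$n = 37$, $\alpha = 0.05$ two-sided, power 0.80.

# The synthetic-data generator

`synthesize_study()` builds one recording per
(group, session, version, condition, subject):

```
recording = snr_realised * mixing %o% latent + noise
```

* **Latent signals** (`make_latent_signal()`): Gaussian white noise
  band-passed to 0.5–10 Hz by the same zero-phase FIR used in
  preprocessing, then standardised. One latent per
  (session, version, condition) stimulus cell, shared by both groups (both
  groups hear the same stimuli), a different one per cell. Modelling the
  whole 1.5-min condition as one latent (rather than one per sentence)
  matches the analysis, which treats the concatenated condition as a
  single series.
* **Forward models**: one unit-norm Gaussian mixing vector per subject,
  fixed across sessions and conditions. Unit norm makes `snr` the
  *aggregate* shared-to-noise amplitude ratio, so the ideal-filter ISC is
  $\mathrm{snr}^2/(1+\mathrm{snr}^2)$ independent of channel count
  (`base_snr = 0.5` gives $r \approx 0.2$, a typical magnitude for MEG
  ISC).
* **Noise**: white Gaussian, unit variance, independent per channel and
  subject — the simplest model under which the circular-shift null is
  exactly exchangeable.
* **Alignment-strength heterogeneity** (`snr_subject_sdlog = 0.6`): each
  recording's realised snr is its cell value times a log-normal factor
  (about 65% coefficient of variation). Real ISC data show wide
  subject-to-subject and session-to-session spread in alignment strength,
  and this term is the error the paired pre/post contrast rests on —
  with perfectly homogeneous subjects the per-subject ISC values within a
  cell differ only through shared sampling error and the paired t-test's
  denominator degenerates.
* **Intervention effect** (`delta_post`): added to the snr of
  intervention-group political conditions in the post session only; all
  other cells are distributionally identical across sessions.
* **Seeds**: one master seed; per-latent, per-mixing and per-noise seeds
  derive from it through a documented counter hash, so any subset of the
  study regenerates identically.
* **Bad segments** (`mark_bad_segments()`): optional random non-overlapping
  intervals totalling a target fraction of samples, to exercise the
  zero-padding contract.

What the generator does **not** emulate: realistic MEG forward fields
(head models, dipole geometry), 1/f or spatially correlated sensor noise,
eye-blink/cardiac artifacts, or sensor dropout. Passing tests therefore
demonstrate the correctness and operating characteristics of the
*analysis*, not robustness to every physiological artifact of real
recordings; the ICA-based artifact rejection and reference-coil noise
suppression of a real pipeline are out of scope here.

# Preprocessing choices

* **Filter**: FIR windowed-sinc band-pass (Hamming), order
  $\approx 3.3\, f_s / \text{transition}$, applied forward–backward, so
  phase is exactly zero and stop-band attenuation doubles. Given the band
  (0.5–10 Hz) and the 0.5 Hz transition width, the filter family itself is
  a design choice; FIR is chosen for stable zero-phase behaviour at a
  0.5 Hz edge. Edges are handled by odd
  reflection padding.
* **Resampling**: Fourier-domain truncation (downsampling only), which
  preserves pass-band content without phase distortion for arbitrary
  rate ratios such as 1,017 → 400 Hz.
* **Zero-padding**: rejected segments are replaced by zeros *before* the
  analysis band-pass (the chain runs resample → zero-pad → filter). Filtering
  necessarily spreads energy into the padded region; padded samples are
  kept (not re-zeroed, not excluded from correlations); keeping them
  preserves the equal-length contract MCCA requires, and the choice is
  documented here so users can trim pads themselves if preferred.
* **PCA**: channels are mean-centred (standard covariance PCA) and
  reduced to `D = 50` by default at full scale; in cross-validation the
  reduction is fitted on training samples only.

# Numerical conventions

* Correlations are clipped to $|r| \le 1 - 10^{-12}$ before
  $\operatorname{arctanh}$ (duplicate subjects thus give a large finite
  statistic rather than infinity).
* Whitening uses a relative eigenvalue floor of $10^{-10}$; no other
  regularisation is applied.
* Component ties in the per-fold selection break to the lowest index.
* Constant held-out variates (e.g. an all-zero test segment) produce
  undefined correlations; the affected pairs are excluded and counted,
  with a logged message.
* `make_folds()` gives contiguous folds whose lengths differ by at most
  one sample, remainder to the earliest folds.

# Problem sizes used by the test suite

Simulation-based tests run at desk scale, chosen to keep the full suite in
minutes while leaving every statistical property measurable: 8–16
channels, 30–90 s at 100 Hz, 4–20 subjects, 99–200 null draws, 1,000
cells for the calibration study, and 20 independent study replicates
(M = 12 per group, 60 s, PCA to 10) for the contrast-recovery study. The
printed-statistic reproductions (p-values, effect sizes, the $d = 0.47$
sensitivity bound) are exact closed-form computations and run in
milliseconds.

# Known limitations

* **Per-subject ISC values are not independent.** Subject $m$'s value is
  the mean of its pairwise correlations with all other subjects, so all
  $M$ values in a cell are coupled (each pair is shared by two subjects,
  and every value moves with the cell's average alignment quality). A
  paired t-test across subjects treats them as independent and is
  therefore somewhat anticonservative at the cell level; at $M = 12$ the
  coupling inflates the null spread of the paired t by roughly 1.5×
  irrespective of recording length or heterogeneity scale. This is a
  structural property of subject-averaged pairwise ISC statistics, not of
  this implementation; the contrast-recovery test in the suite documents
  it quantitatively (true effects are detected in every replicate, while
  null cells exceed the nominal FDR rate). Group-level inference that must
  control error rates exactly should rely on the circular-shift null of
  the *cell-level* statistic, which is exchangeable by construction and
  empirically calibrated.
* The circular-shift null shifts held-out variates without refitting the
  MCCA model per draw (see above); a full-refit null is conceptually
  cleaner but computationally prohibitive, and the difference is
  documented as a deviation risk.
* MAXVAR is the only MCCA cost implemented (no SUMCOR/GENVAR), and
  upsampling is not supported in `resample_to()`.
* The on-disk study container stores matrices as full-precision text CSV;
  round trips are exact to about $10^{-15}$ relative, not bit-identical.
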