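---
title: "Models and methods behind rtnf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rtnf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rtnf` re-creates, at desk scale and on fully synthetic data, the
computational chain of a posterior-cingulate-cortex (PCC) targeted
real-time fMRI neurofeedback experiment with a block-design mindfulness
paradigm: ground-truth BOLD simulation, per-volume real-time noise
regression, the feedback bar rule, offline GLM and PPI analysis, and the
group statistical battery. This vignette explains the models, the
parameters that matter, and the design choices made where the design was
genuinely open.

## The paradigm

A task run lasts 426 s on a 2-s TR grid (213 retained volumes after 3
dummy volumes): a 66-s rest lead-in followed by three cycles of
Describe (20 s), Rest (30 s), Focus-on-Breath (70 s). The cycle order
keeps a 30-s rest immediately before every Focus block — the feedback
baseline rule requires it, since the baseline is the mean of the
preceding rest block excluding its first two volumes (which still carry
the delayed hemodynamic response of the preceding Describe block). The
published run length of 6 min 56 s (416 s) cannot be reconciled exactly
with a 66-s lead-in plus whole 120-s cycles; `rtnf` derives the run
length from the configured schedule (426 s by default) and keeps every
block duration configurable through `nf_timing()` rather than silently
adjusting any block. Neurofeedback target levels are −0.5, −0.75 and
−1.0 percent for runs NF1–NF3; OBS and TRS show no bar.

## Hemodynamic model

`hrf_kernel()` is a double-gamma kernel parameterized by the *mode* of
each gamma component (`shape = 1 + delay/dispersion`), so the impulse
response peaks exactly at the configured peak delay (default 6 s) and
the undershoot bottoms near 16 s. The kernel itself is normalized to
unit peak. `hrf_convolve()` rescales the TR-sampled kernel to unit
*sum* before convolving: a sustained block then plateaus exactly at the
input amplitude, which is what makes task betas read directly in
percent-signal-change (PSC) units end to end. With unit-peak sampling a
70-s block would plateau at roughly 2.6 times the nominal amplitude and
no stage of the pipeline would be in interpretable units.

## The synthetic world

`default_geometry()` builds an isotropic 2-mm grid (24³ by default,
minimum 20³) with labelled compartments: the 7-mm target sphere centred
on MNI (−5, −55, 23) — 179 voxels by voxel-center inclusion, placed via
a stored affine so ROI code exercises world-to-voxel math — a
white-matter slab, a small ventricle box, and gray matter elsewhere.

The signal model is multiplicative on the percent scale:

    x_v(t) = baseline_v × (1 + s_v(t) / 100)

where `s_v(t)` sums the HRF-convolved task effects (ROI: −0.5% Focus,
+0.2% Describe by default), Legendre drift, RETROICOR-basis
physiological fluctuation built from the generated cardiac/respiratory
waveforms (25-ms clock), motion-coupled signal from a bounded random
walk (with optional transient spikes to exercise the 0.3-mm framewise
displacement censoring), compartment-specific slow fluctuations, and
white thermal noise (1% per voxel by default). PSC therefore has exact
ground truth, and every percent-scale output is invariant to the
baseline intensity.

Two deliberate departures from a literal miniature brain:

* **The task effect region extends one smoothing FWHM (6 mm) beyond the
  measurement sphere.** Real mindfulness-related deactivation covers far
  more than the 7-mm target; on a sphere only 3.5 voxels across, 6-mm
  smoothing would otherwise dilute the ROI mean by roughly 40% and no
  feedback rule could recover the nominal amplitude.
* **Motion enters as signal coupling, not geometric resampling** —
  registration is out of scope, and coupling is what the motion
  regressors can actually remove.

What the generator does *not* emulate: anatomy, EPI artifacts,
susceptibility dropout, heart-rate-variability response functions,
non-white noise spectra, or true head displacement. Passing tests
therefore demonstrate correctness of the *computational chain*, not
performance on real scanner data.

## Real-time processing

Per volume the chain is: masked separable Gaussian smoothing (6-mm
FWHM; normalized convolution `smooth(x·m)/smooth(m)` so constants are
preserved inside the mask), percent scaling against the frozen mean of
the first 19 TRs (inside the rest lead-in; counted after dummy
removal), then a streaming regression of the scaled ROI mean on the
design accumulated so far: six motion parameters, eight RETROICOR
regressors (cardiac and respiratory phase harmonics, computed causally
from physiology observed up to the volume time), white-matter and
ventricle means, and Legendre drift terms (order 3 by default; the
real-time order is not constrained by the offline choice). Export
starts once the sample count exceeds the regressor count by 5.

Three numerical choices matter here:

* **Recursive least squares via Givens QR updating.** The engine
  maintains the triangular QR factor of the accumulated design with one
  O(k²) rotation pass per volume. This is genuinely incremental yet
  agrees with refitting the full OLS from scratch at every TR to
  ~1e-12 — the normal-equations alternative loses six or more digits on
  the ill-conditioned pairing of random-walk motion with polynomial
  drift. Rank deficiency is detected on the triangular diagonal; the
  offending columns are pinned to zero and logged.
* **The task model is protected, not regressed away.** The
  HRF-convolved Focus and Describe regressors join the fit so that the
  nuisance betas are estimated free of task variance, but their fitted
  contribution stays in the exported signal. Over a growing window a
  cubic drift basis is flexible enough to absorb a block design almost
  entirely early in the run; without protection the feedback signal is
  flat even on noise-free data.
* **Tissue nuisance means come from unsmoothed data.** At desk scale
  the compartments sit within one smoothing kernel of the task effect
  region, so smoothed tissue means inherit the task profile and a
  regression on them cancels it. Using unsmoothed compartment means is
  the desk-scale equivalent of the eroded tissue masks used on real
  data (and of local-average schemes like ANATICOR, whose 30-mm
  neighbourhoods do not fit on this grid).

## The feedback rule

The feedback value at Focus volume `v` (0-based within the block,
starting at `v = 2` to ride out the hemodynamic delay) is the exported
ROI value minus the preceding rest baseline — a subtraction, not a
ratio, because the signal is already percent-scaled; "percent signal
change relative to the preceding rest block" names the unit, not a
second division. The displayed bar is the moving average of the current
and up to two preceding values (`h₁ = x₁`, `h₂ = (x₁+x₂)/2`,
`h_k = (x_{k−2}+x_{k−1}+x_k)/3`). The bar shows blue at or below zero
(zero is a non-punitive tie-break) and red above; the fill fraction is
`clamp(height / target, 0, 1.25)`. The clamp at 1.25 lets
over-achievement slightly exceed the green target bar; both conventions
are configurable, since the study's display software is not described
at the pixel level. On noise-free data the mean late-block bar height
reproduces the −0.5% ground truth within 0.05.

## Offline analysis

`preprocess_offline()` drops the first five raw volumes (three dummies
plus two task volumes, with task regressors shifted accordingly),
despikes each voxel (points beyond 4 robust SDs of an 11-point running
median are clipped to the boundary), removes the RETROICOR basis and
the respiration-volume-per-time regressor — again with the task model
protected, since an unprotected pre-regression strips about `k/n` ≈ 4%
of the task amplitude and biases every downstream contrast — and scales
each voxel to percent change about its own run mean.

The run-level GLM design has 23 columns: HRF-convolved Focus and
Describe regressors (Describe is modeled explicitly because
Describe-versus-rest effects are a reported outcome; rest is the
implicit baseline), 12 motion terms (six parameters plus
backward-difference derivatives), three ventricle principal components
(SVD of the centred voxel series, signs fixed so the largest-magnitude
loading is positive), the white-matter average, and Legendre drift of
order 4, per run. Contrasts satisfy
`(Focus−Describe) = (Focus−Rest) − (Describe−Rest)` identically.

PPI follows the seed-times-task construction: the PPI regressor is the
mean-centred HRF-convolved Focus regressor multiplied by the seed
series (deconvolution is deliberately omitted; the raw ±-coded boxcar
is available as an option since the study does not state whether its
block regressor was convolved), the physiological regressor is the seed
orthogonalized to the PPI column, and volumes with framewise
displacement strictly above 0.3 mm (Power convention, 50-mm head
radius; the flagged volume only, no neighbour augmentation) are deleted
before fitting. Group maps use voxelwise one-sample t tests with
face-connected component extent reporting only — no autocorrelation-
calibrated cluster correction is attempted at desk scale.

## Group statistics

The battery mirrors the study's: one-sample t with Cohen's d; a
random-intercept mixed model `value ~ run (+ age + sex) + (1|subject)`
via `lmerTest` with Satterthwaite denominator degrees of freedom and a
Nakagawa-style marginal R² (a singular or degenerate fit falls back to
OLS with a warning); Tukey-family pairwise contrasts via
`multcomp::glht` (a contrast with estimate 0 and SE 0 reports t = 0,
p = 1 by convention); Cohen's `f = sqrt(R²/(1−R²))`; ICC(3,k) from the
subjects × runs ANOVA decomposition `(BMS − EMS)/BMS` with
F-distribution confidence bounds; Pearson correlations with an
explicit-family Bonferroni adjustment (the family size is an argument
because the study does not enumerate its family); and the
repeated-measures ANOVA power function
`λ = n·m·f²/(1−ρ)`, `df = (m−1, (n−1)(m−1))` under compound symmetry
(ε = 1). With the declared defaults ρ = 0.5, α = 0.05, m = 5 the
function reproduces the 97%-power design statement for n = 34 and
f = 0.25 (computed value 96.8%), and agrees with a 10,000-rep
Monte-Carlo simulation of the design within ±2 percentage points.

## Problem sizes and determinism

Every stochastic generator is a pure function of its parameters and a
seed; cohorts derive per-subject seeds from a master seed, and the
end-to-end pipeline is deterministic given its configuration. The
shipped analyses use a 24³ grid for parameter recovery (six-subject
cohorts, twenty master seeds), a 20³ grid for end-to-end feedback
checks, 1,000 simulated 20-subject cohorts (ROI-level fast path,
`simulate_roi_psc_table()`) for the mixed-model type-I check, 50
random 200-volume runs for the streaming-versus-batch oracle, and 100
seeded reruns for PPI sign recovery. These sizes were chosen so each
check resolves its tolerance comfortably.

## Known limitations

* The desk-scale geometry is a labelled phantom, not anatomy; spatial
  claims (cluster tables, peak coordinates) are bookkeeping checks.
* The real-time path runs per volume but makes no wall-clock latency
  claim.
* The mixed-model denominator degrees of freedom in the study
  (F(4,131) for 34 subjects × 5 runs) are not derivable from the text;
  Satterthwaite is declared rather than matched.
* Participant-level results (their Tables, ICC = 0.616, Cohen's d
  values) are not reproducible without the raw data; the package's
  claims are property-based: exact oracles, parameter recovery,
  calibrated error rates.
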