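# rtnf

Simulation and analysis of real-time fMRI neurofeedback experiments,
at desk scale.

In posterior-cingulate-cortex (PCC) targeted neurofeedback for
mindfulness training, a participant watches a bar whose height tracks
the noise-reduced BOLD signal of a 7-mm sphere at MNI (−5, −55, 23),
updated every TR (2 s), while alternating Focus-on-Breath, Describe and
Rest blocks. Building and validating such a pipeline is hard precisely
because nothing about it is observable twice: the physiological noise,
the motion, the feedback loop and the group statistics all interact.
`rtnf` re-creates the entire chain on synthetic data with known ground
truth, so that every stage — from the RETROICOR phase regressors to the
mixed-model omnibus test — can be checked against an exact answer. It
is aimed at researchers prototyping real-time fMRI methods, teaching
fMRI analysis, or stress-testing analysis choices before touching real
data.

## What is implemented

* **Paradigm** — block schedules (66-s rest lead-in, then
  Describe 20 s → Rest 30 s → Focus 70 s cycles), per-volume condition
  labels, boxcars, and a mode-parameterized double-gamma HRF whose
  convolved blocks plateau exactly at the effect amplitude, so task
  betas are percent signal change (PSC) directly.
* **Synthetic data** — a labelled 2-mm phantom (target sphere, white
  matter, ventricle), multiplicative percent-scale signal model
  `x = baseline · (1 + s/100)` with HRF-convolved task effects,
  Legendre drift, cardiac/respiratory fluctuation on a 25-ms clock,
  motion-coupled signal, and white noise; every generator is a pure
  function of (parameters, seed).
* **Nuisance regressors** — RETROICOR cardiac/respiratory phase
  harmonics (Glover-style linear and histogram-equalized phases),
  respiration volume per time, framewise displacement (Power
  convention, 50-mm head radius).
* **Real-time engine** — masked 6-mm Gaussian smoothing, percent
  scaling over the first 19 TRs, and a streaming nuisance regression
  (recursive least squares via Givens QR updating) that matches
  per-TR batch OLS refits to ~1e-12, with the task model protected so
  the feedback signal is not regressed away.
* **Feedback rule** — preceding-rest baselines (first two rest volumes
  excluded), feedback from the third Focus volume, 3-point
  moving-average bar, blue/red/hidden display with target levels
  −0.5 / −0.75 / −1.0% for NF1–NF3.
* **Offline analysis** — despiking, task-protected RETROICOR + RVT
  removal, 23-column run GLM (task, 12 motion, 3 ventricle PCs,
  white-matter average, 4th-order Legendre), PSC contrasts, spherical
  ROI extraction, group t-maps with face-connected cluster tables, and
  PPI with strict >0.3-mm FD censoring.
* **Group statistics** — one-sample t with Cohen's d, random-intercept
  mixed models (Satterthwaite F, marginal R², Cohen's f), Tukey
  pairwise contrasts, ICC(3,k) with F-bound confidence intervals,
  Bonferroni-adjusted correlations, and repeated-measures ANOVA power
  `λ = n·m·f²/(1−ρ)`.

## A worked example

```r
library(rtnf)

sched <- build_run_schedule("NF1")
sched
#> <nf_schedule> run NF1, 213 volumes @ TR 2 s, target -0.5%
#> # A tibble: 10 x 3
#>   condition onset duration
#> 1 REST          0       66
#> 2 DESCRIBE     66       20
#> 3 REST         86       30
#> 4 FOCUS       116       70
#> ...

sub <- generate_subject(list(NF1 = sched), default_geometry(20),
                        ground_truth(), seed = 7)
rt <- run_realtime(sub, "NF1")
fb <- feedback_trace(rt)
dplyr::filter(fb, !is.na(bar))[1:4, c("volume", "nf_value", "bar", "state", "fill")]
#>   volume nf_value    bar state  fill
#> 1     60   -0.165 -0.165 blue  0.331
#> 2     61   -0.281 -0.223 blue  0.446
#> 3     62   -0.824 -0.424 blue  0.847
#> 4     63   -0.696 -0.600 blue  1.20
```

The first bar appears at volume 60 — the third volume of the first
Focus block (onset 116 s = volume 58) — and is blue because the PCC
signal sits below its preceding-rest baseline; `fill` is the bar height
relative to the −0.5% target. `autoplot(fb)` draws the bars per block.

The offline GLM recovers the simulated deactivation
(−0.5% Focus, +0.2% Describe, so the contrast is −0.7):

```r
roi_psc_offline(sub, "NF1")
#> [1] -0.745
```

and the analytic power of the 34-subject, 5-run repeated-measures
design at a medium effect (f = 0.25, within-subject correlation 0.5):

```r
100 * rm_anova_power(n = 34, m_conditions = 5, f = 0.25)
#> [1] 96.8
```

`run_pipeline(pipeline_config())` chains simulate → real-time →
feedback → offline GLM → group statistics for a whole cohort and
returns tidy report tables (per-run PSC, one-sample t, mixed model with
Tukey follow-ups, ICC(3,k), feedback and PPI summaries), all
deterministic under the master seed. `inst/scripts/nf_pipeline.R` wraps
the same calls for shell use.

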