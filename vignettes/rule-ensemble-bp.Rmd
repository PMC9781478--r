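---
title: "Rule-ensemble modelling of beat-to-beat blood pressure from ECG and PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-ensemble modelling of beat-to-beat blood pressure from ECG and PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous, cuffless blood-pressure estimation rests on arterial wave
propagation: a pressure pulse launched at each heart beat arrives at the
periphery after a delay — the pulse arrival time (PAT), measured from the ECG
R peak to a landmark of the photoplethysmogram (PPG) pulse — that shortens as
pressure and arterial stiffness rise. Per-beat PAT variants (to the pulse
onset, systolic peak, maximum-slope point, diastolic peak), pulse wave
velocities (arterial path length / PAT), pulse amplitude and contour
descriptors therefore carry information about systolic, diastolic and mean
pressure (SBP, DBP, MBP), and the relationship is known to be nonlinear and
to involve interactions among predictors.

`pulserules` implements an end-to-end, fully automatic version of this
analysis: signal preprocessing, fiducial-point detection, per-beat feature
extraction and cleaning, and an interpretable *rule-ensemble* regression
whose diagnostics (term and variable importance, H-statistic interaction
screening, partial dependence) make the fitted relationship inspectable
rather than a black box. Because raw recordings of this kind are typically
not redistributable, the package is driven by a synthetic signal generator
that emulates the relevant study design — adolescent subjects recorded at
rest and during an isometric weight-bearing task (WBT, holding a 500 g
weight), at 1000 Hz — with complete per-beat ground truth, so every stage is
testable against known answers.

## The synthetic study conditions

`generate_subject()` draws a subject aged 13–18 with height, weight and BMI
in adolescent ranges, an arterial path length of 0.5 × height (a common
heart-to-finger approximation; the true path is not observable), and
subject-level intercept scatter for the pressure law.
`generate_session()` renders one rest or WBT session:

* **RR intervals** follow an AR(1) process (coefficient 0.8) around a state
  mean of 0.71 s (rest) / 0.68 s (WBT) with stationary SD 0.03 s — enough
  short-range correlation to look like sinus rhythm without a full
  baroreflex model.
* **ECG** is a train of Gaussian R spikes (8 ms width) with small Q, S, P
  and T deflections.
* **PPG** pulses start at the R peak plus the beat's PAT (mean 0.25 s rest /
  0.23 s WBT, SD 0.035 s) and are built from a two-lobe template: a systolic
  Gaussian (crest time ≈ 0.10 s), a reflected lobe producing the dicrotic
  notch (≈ 0.19 s) and diastolic peak (≈ 0.31 s), and a slow decay tail.
  The template's final ~30 ms are blended into an exact time-mirror of its
  start, so consecutive beats join in a *locally symmetric* foot valley:
  symmetric minima pass through zero-phase filters and centered smoothers
  unshifted, which is what makes millisecond-accurate onset timing a
  well-posed target. The composite channel is then low-passed at 12 Hz
  (real PPG front-ends are band-limited), and ground-truth landmark times
  are re-measured on the rendered waveform itself rather than taken from
  the ideal template.
* **ABP** is a piecewise-linear DBP baseline with knots at the beat feet
  plus a per-beat pulse lobe that vanishes at both feet, so every foot is an
  exact minimum at the beat's true DBP and every peak is scaled to hit the
  true SBP.
* **Pressure law.** Per-beat pressures follow
  `BP = a0 + a1/PAT + a2·AM + a3·RR + a4·I(PAT < 0.245)·AM + demographic
  terms + state shift + N(0, 2 mmHg)`. The reciprocal PAT term gives the
  expected inverse, mildly nonlinear dependence; the thresholded PAT × AM
  product plants a genuine non-additive interaction for the model
  diagnostics to recover. Defaults put rest means near 127/76 mmHg and WBT
  means near 138/83 mmHg. The interaction weights (8 for SBP, 3 for DBP)
  were fixed so that the planted interaction is comfortably detectable by
  the H-statistic on a pooled table of ~2000 beats at noise SD 2 mmHg —
  that detectability is part of the study conditions the generator is meant
  to create, and the remaining coefficients were rebalanced once so the
  state means stay at the levels above.
* **Artifacts.** `inject_artifacts()` produces the two failure modes the
  extraction stage must screen: flat lines (constant spans) and flat peaks
  (clipping above a quantile).

What the generator does *not* emulate: respiratory and baroreflex coupling,
baseline wander, motion artifacts other than the two flat classes,
arrhythmias, and sensor-specific transfer functions. Passing tests
therefore demonstrate the correctness of the pipeline's logic and the
recoverability of a known law under realistic beat-to-beat variability —
not clinical performance on real recordings.

## Preprocessing and fiducial detection

ECG is band-passed at 0.5–30 Hz and PPG at 0.5–15 Hz with 4th-order
Butterworth stages applied forward-backward (zero phase, so PAT timing is
unbiased). The band-pass is implemented as a high-pass/low-pass *cascade*:
a single 4th-order band-pass section with normalized edges as extreme as
0.0005–0.015 is numerically ill-conditioned and visibly corrupts shallow
waveform minima. PPG is z-score normalized per segment (after filtering;
the order is configurable). Smoothing for derivative estimation uses a
centered moving average, default 51 ms — below the narrowest timing feature
(crest time ≈ 90–100 ms).

R peaks are detected from a Shannon-energy envelope of the first difference
with an adaptive threshold and a 200 ms refractory period, refined to the
local ECG maximum. PPG fiducials are detected per R-R window: the
maximum-slope point from the smoothed first derivative, the systolic peak at
its next downward zero crossing, the onset as the pre-upstroke minimum —
located on the *input* signal, not the smoothed one (wide smoothing fills
the shallow foot valley and biases the minimum early), with a local
quadratic vertex fit for sub-sample precision — the dicrotic notch as the
first post-systolic local minimum (tie-broken toward the second-derivative
e-wave; falls back to the e-wave when no minimum exists), the diastolic peak
as the next local maximum, the a–e waves as alternating second-derivative
extrema in the systolic phase, and p1/p2 as zero-crossing-delimited
third-derivative extrema. Beats whose landmarks cannot be resolved keep
`NA` fields and are flagged rather than silently dropped — they become
incomplete rows that the cleaning stage removes, so the data flow stays
auditable. There is no manual correction step: the pipeline is fully
automatic.

ABP is used unfiltered (filtering would change the pressure values): per
R-R window the peak is the maximum (SBP) and the foot the pre-upstroke
minimum (DBP). Flat lines (runs of zero first difference ≥ 0.2 s) and flat
peaks (such runs sitting strictly above their neighbours) are masked, and
beats overlapping masked intervals are excluded.

## Features and cleaning

Each retained beat yields: amplitude AM; oPAT, pPAT, msPAT, diaPAT;
relative PATs (PAT/RR — the only dimensionless per-beat normalization
available); oPWV, pPWV, diaPWV; crest time cT; onset-to-onset and
peak-to-peak intervals dO, dP; RR; shape descriptors (DA: diastolic-to-
systolic amplitude ratio; AM25 and slope_BC as provisional stand-ins,
isolated in one function for easy replacement, since exact published
definitions for this descriptor family are not available); and the SBP,
DBP, MBP targets with MBP = (SBP + 2·DBP)/3. Cleaning drops rows with any
missing value first, then removes rows with any per-column |z| > 3 in a
single pass using the post-dropna statistics. The pass is deliberately not
iterated (removing outliers changes the mean and SD, so iteration would
keep shaving the tails); both step counts are logged. Cleaning is applied
per subject and state, matching the per-state reporting of the comparison
tables; a pooled mode is a config change away.

## The rule-ensemble model

The model is a sparse linear combination of two term families built on the
training data:

* **Rules.** Gradient boosting on squared loss grows small best-first
  regression trees on row subsamples (default 300 trees, shrinkage 0.01,
  subsample 0.5). Every non-root node contributes one rule — the
  conjunction of conditions on its root path, e.g.
  `oPAT <= 0.241 & AM > 2.53` — simplified to binding thresholds and
  de-duplicated. The terminal-node count of each tree is drawn as
  `2 + floor(Exp(mu))` with `mu` solved so the *mean* equals the configured
  tree size (default 3; the draw admits occasional deeper trees and hence
  higher-order interactions, while a mean of 2 forces stumps). A rule's
  support `s_k` is the fraction of training rows it covers.
* **Winsorized linear terms.** Each original predictor enters clipped at
  its 2.5% and 97.5% empirical quantiles (linear interpolation between
  order statistics — one convention, used everywhere), limiting the
  leverage of extreme beats.

The combined design (0/1 rule indicators, clipped linears) is standardized
internally and fitted with an L1 penalty; the penalty is chosen by 5-fold
cross-validation *inside the training split* over a 50-value log-spaced
path. Coefficients are reported on the original term scale. Three variants
are exposed: `linear_only`, `rules_only` (trees forced to stumps, so the
rule set spans an additive main-effects model) and `rules_plus_linear`.
At penalty 0 the fit reduces to ordinary least squares and at very large
penalty to the intercept `mean(y)` — both limits are tested exactly.

**Importance.** A linear term scores `|b_j|·sd(l_j(x_j))`; a rule scores
`|a_k|·sqrt(s_k(1-s_k))` (coefficient times the SD of a Bernoulli
indicator). A variable's importance adds its linear-term score and an equal
share of every rule it appears in, normalized so the top variable reads 100.

**Interaction screening.** For each variable the Friedman–Popescu
H-statistic measures how much the fitted function departs from additivity:
with centered partial-dependence functions evaluated on training rows,
`H_j^2 = sum(F - PD_j - PD_{-j})^2 / sum(F^2)`. For a rule ensemble the
partial dependences factorize — every rule splits into its conditions on
variable j and on the rest — so the computation is exact and cheap (no
O(n²) re-prediction); by default it runs on a 300-row subsample. Because
adaptive fitting produces non-zero H even on additive data, a null
reference is built by parametric bootstrap: an additive surrogate
(stump rules + linear terms) is fitted, null responses are its predictions
plus resampled residuals, the full model is refitted on each of 20 null
replicates (the published description of the null band does not specify its
construction; this surrogate bootstrap is the package's choice), and a
variable is flagged when its observed H exceeds the null mean + 2 SD. The
H estimate is meaningful only for an adequately fitted ensemble — an
underfit model shows spurious non-additivity — so interaction screening
should use at least the default number of boosting iterations.

## Evaluation protocol

`kfold_cv()` shuffles beats into 10 seeded folds (sizes differing by at
most one) and reports *pooled* metrics over the concatenated held-out
predictions — MAE and RMSE — rather than averaged per-fold metrics; both
are defined per beat in mmHg. Folding is over beats, not subjects: with
six subjects, within-subject information in training is what makes
few-mmHg errors attainable, and that choice materially affects results, so
it is logged and a grouped-by-subject policy is available via the config.
`compare_model_variants()` runs all three model variants and reports
non-zero term counts (both the median across CV folds and a full-data
refit, since a "number of rules" can reasonably mean either) alongside CV
and training-set errors. `percent_improvement()` expresses MAE reductions
in percent.

Rest-vs-WBT comparisons collapse beats to per-subject state means and use
an exact two-sided Wilcoxon signed-rank test: zero differences are dropped,
the exact distribution (`psignrank`) is used when ranks are untied, full
2^n sign enumeration when they are tied (n ≤ 20), and the tie-corrected
normal approximation beyond — at the study scale of n = 6 pairs the exact
path always applies, where the normal approximation would be invalid.

## Reproducing a full run

```r
library(pulserules)
cfg <- default_config()
cfg$n_subjects <- 2; cfg$duration <- 60; cfg$targets <- "DBP"
res <- run_pipeline(cfg, out_dir = tempfile("bundle"))
```

The bundle contains the beat table, exclusion intervals, model JSON, term
and variable importance CSVs, the state-comparison and model-comparison
reports, and a run log recording every effective setting — including all
defaults — so under-specified choices are always visible in the output.
Stage functions (`pipeline_synth()`, `pipeline_extract()`,
`pipeline_fit()`, `pipeline_evaluate()`) operate on the previous stage's
files and compose to exactly the same bundle; a thin command-line wrapper
(`inst/cli/pulserules.R`) exposes them as subcommands.

The test suite exercises tighter, smaller versions of everything above;
the larger recovery study (six subjects, two states, ~2000 beats) is run
by `scripts/acceptance.R` and by the corresponding test, at the problem
sizes stated there (10-fold CV, 20 null replicates). On one CPU the full
recovery study takes a few minutes.

## Numerical choices and limitations

* Zero-phase filtering throughout; the band-pass is a high-pass/low-pass
  cascade for conditioning (see above).
* Sub-sample landmark refinement: parabolic interpolation for peaks, a
  least-squares quadratic vertex over ±18 ms for the onset valley.
* Quantiles use linear interpolation between order statistics everywhere.
* Degenerate inputs: constant signals refuse z-scoring; constant columns
  get zero-SD linear terms (zero importance) and are skipped by the
  z-score outlier pass; empty penalty grids, invalid bands, and too-short
  sessions raise errors rather than guessing.
* Ties in the dicrotic search are broken toward the e-wave; beats whose
  landmark ordering cannot be established are flagged, never reordered.
* The synthetic PPG template is a modelling choice — no quantitative
  morphology was available to reconstruct — so contour-shape descriptors
  (DA, AM25, slope_BC) are provisional and the feature table is narrower
  than a full clinical descriptor set.
* Detection accuracy figures quoted by the tests (e.g. onset within 2 ms)
  are properties of this generator's signal-to-noise regime; real
  recordings with motion artifacts and baseline wander will be harder.
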