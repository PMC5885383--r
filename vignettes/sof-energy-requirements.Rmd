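---
title: "Modeling energy requirements of Special Operations training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling energy requirements of Special Operations training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opsfuel)
```

## The problem

Special Operations Forces (SOF) routinely train and operate at daily energy
expenditures far above garrison levels, while field feeding caps intake at
roughly what three combat rations provide. The result is recurrent energy
deficits and loss of body mass, including fat-free mass. Planning adequate
feeding needs a way to *predict* the daily energy requirement of a course or
mission from quantities a practitioner can actually obtain: a body mass and a
coarse description of how hard the activity is.

`opsfuel` implements the full analysis chain behind that prediction:

1. **Measurement** — total daily energy expenditure (TDEE) from doubly
   labeled water (DLW) isotope kinetics.
2. **Accounting** — decomposition of TDEE into resting metabolic rate (RMR),
   diet-induced thermogenesis (DIT) and activity-induced energy expenditure
   (AIEE), plus physical activity level (PAL) and energy balance.
3. **Classification** — quartile-binning of course PALs into a four-level
   physical activity factor (PAF).
4. **Prediction** — linear equations for TDEE from body mass (Model A) or
   fat-free mass (Model B) plus the PAF, with tools to evaluate them against
   measured data or refit them on new cohorts.
5. **Simulation** — a synthetic-cohort and isotope-series generator that
   reproduces the statistical structure the analysis assumes, so the whole
   chain is testable without access to individual-level study data.

## The DLW measurement model

A participant is dosed with water labeled with deuterium and oxygen-18. Both
isotopes wash out of body water exponentially; `{}^{18}`O additionally leaves
as CO2, so the difference between the two elimination rates measures CO2
production.

**Total body water** comes from isotope dilution between a pre-dose and a
post-dose urine sample:

$$\mathrm{TBW\ (mol)} = \frac{A}{MW_d}\cdot\frac{APE_d}{100}\cdot 18.02
  \cdot \frac{1}{R_{std}\,(E_s - E_p)} \cdot \frac{1}{1.01},$$

with dose mass $A$ (g), dose-water molecular weight $MW_d$ and atom percent
excess $APE_d$, the standard's heavy/light ratio $R_{std}$, and enrichments
$E_s$ (post-dose) and $E_p$ (pre-dose). The trailing divisor is the isotope
dilution-space correction (1.01 for the `{}^{18}`O space; an optional 1.04 is
offered when computing from the deuterium space). `compute_tbw()` returns
moles with an explicit kg conversion (× 18.02/1000) so units are never
ambiguous. Enrichment units are deliberately unvalidated beyond sign
consistency: $E_s$, $E_p$ and $R_{std}$ must simply share a scale, because
laboratory delta conventions vary and the equation only uses their ratio.

**Elimination rates** $k_O$ and $k_H$ (per day) are the negative slopes of
ordinary least squares fitted to $\ln(E(t) - E_p)$ against time
(`fit_elimination_rate()`). Samples at or below baseline carry no usable
excess; they are dropped with a warning, and fewer than two usable samples is
an error rather than a silent two-point fallback.

**CO2 production** uses the Schoeller two-pool equation

$$r\mathrm{CO}_2\ (\mathrm{mol/d}) = \frac{N}{2.078}(1.01\,k_O - 1.04\,k_H)
 - 0.0246\, r\mathrm{H_2O}_f,\qquad
 r\mathrm{H_2O}_f = 1.05\,N\,(1.01\,k_O - 1.04\,k_H),$$

with $N$ the body water pool in moles. A negative production (possible when
noise pushes $1.01 k_O$ below $1.04 k_H$) is flagged and reported, never
clipped, so downstream users see the data problem.

**Energy expenditure** multiplies $r\mathrm{CO}_2$ by the energy equivalent
of CO2. The source analysis cites the Weir relation but never prints the
constant; we derive it as $(1.106 + 3.941/RQ)$ kcal per liter of CO2 times
the ideal-gas molar volume 22.414 L/mol — about 127.5 kcal/mol at the food
quotient RQ = 0.86 used throughout. Both RQ and the molar volume are exposed
as arguments, and every pipeline run logs the constant actually used.

One choice deserves emphasis: `compute_ee_dlw()` takes the **back-extrapolated
zero-time intercept** of the log-linear fit as the post-dose enrichment for
the dilution equation (with `post_dose = "first"` available). Under a
mono-exponential washout the first sample already sits below the notional
dilution plateau, so only the intercept is self-consistent with the kinetic
model — and it makes the forward simulation exactly invertible, which the
round-trip tests exploit.

## Energy accounting

From measured TDEE and fat-free mass (FFM = TBW/0.73, assuming 73% hydration
of lean tissue):

* RMR (kcal/d) = 370 + 21.6 × FFM — an FFM-based estimate, not an indirect
  calorimetry measurement; this is a known limitation inherited from the
  source analysis.
* DIT = 10% of TDEE.
* AIEE = TDEE − RMR − DIT. The decomposition is exact by construction and is
  tested as an identity on 10^4 random participants.
* PAL = TDEE/RMR, and the activity share obeys the closed form
  pct AIEE = 100 × (0.9 − 1/PAL).
* Energy balance = intake − TDEE (negative = deficit). The published table's
  footnote states the subtraction the other way around, but every printed
  value follows intake − expenditure, so the printed numbers win.

Course summaries report t-based means and 95% CIs (`course_summary()`);
single-participant courses report a mean with the interval flagged absent.
Report rounding follows the published tables (kcal to integers, PAL to 2
decimals) and is applied only at output (`round_profile()`).

## The PAF scheme and the prediction models

Course-mean PALs are binned into quartiles to form the physical activity
factor: 0 "low" (mission prep), 1 "low-moderate" (common warrior tasks), 2
"moderate-high" (battle drills), 3 "high" (specialized intense activity).
Two details are deliberate:

* **Quantile estimator.** The source names quartiles but not an estimator;
  `derive_paf_scheme()` uses linear-interpolation quantiles
  (`stats::quantile` type 7, the most common default). The *published*
  cutpoints (2.10, 2.40, 2.75) are frozen as `default_paf_scheme()` so that
  downstream results never depend on this estimator choice.
* **Boundary handling.** The published bands leave gaps (2.10–2.11 and so
  on). Bands here are upper-inclusive — PAL ≤ 2.10 is factor 0, and so forth —
  which reproduces all 12 published course assignments; that 12/12
  reproduction is an acceptance test.

The prediction equations are numeric-PAF linear models (a single slope per
model, as published):

* Model A: TDEE = 47.97 × BM + 706.33 × PAF − 467.22 (SEE 642 kcal/d)
* Model B: TDEE = 61.99 × FFM + 716.49 × PAF − 721.30 (SEE 626 kcal/d)

`fit_prediction_model()` refits the same form by OLS with
SEE = √(RSS/(n − 3)); `evaluate_model()` compares measured and predicted
expenditure overall and per course. The source's exact ANOVA construction is
not recoverable from its description, so the per-course comparison here is a
two-sided one-sample t-test of (predicted − measured) within course with
Bonferroni correction over the courses tested, plus an omnibus F test; the
output labels this construction and it should be read as approximate.
Because the models are affine, the prediction at course-mean covariates
equals the course mean of predictions, which is what lets the published
predicted course means be reproduced from published course-mean masses.

## The synthetic generator

The generator exists so every stage is testable. It emulates:

* **Anthropometry and expenditure structure** per course: normal draws with
  means from the published course tables and standard deviations
  reconstructed from the printed 95% CIs as half-width × √n / 1.96 (a
  standard CI inversion, kept at 1.96 rather than a t quantile so the
  reconstruction is a fixed, documented transform). Pairs violating
  FFM ≤ BM are redrawn. When mass distributions overlap appreciably this
  truncation shifts the realized means from the nominal ones (about +0.6 kg
  body mass at sd 8 vs 5 with a 16 kg gap); moment-fidelity tests therefore
  check convergence where the rejection region is ~4 sd out, while
  realistic-parameter tests check containment in the published CIs instead.
* **Course phases.** The published tables split Small Unit Ranger Training
  into classroom and field phases without giving per-phase sample sizes; the
  packaged split is 6/7 (sum 13), an assumption that only affects simulated
  cohort composition, not any published-value reproduction.
* **Isotope kinetics.** Enrichment series are mono-exponential,
  $e(t) = e_0 e^{-kt}(1 + \varepsilon)$, with multiplicative noise of given
  CV (assay errors scale with signal; an additive option exists). The
  Schoeller equation constrains only $1.01 k_O - 1.04 k_H$, so the generator
  pins the remaining degree of freedom at $k_O/k_H = 1.25$, a typical DLW
  ratio (configurable). At zero CO2 production that ratio would force zero
  water turnover, which is unphysiological, so the generator instead keeps a
  baseline turnover $k_H = 0.10$/d with $1.01 k_O = 1.04 k_H$ — a flat net
  signal that still recovers $r\mathrm{CO}_2 = 0$. Initial enrichments come
  from inverting the TBW equation for the configured dose, keeping the
  forward model consistent with the analysis model: a noiseless series run
  through `compute_ee_dlw()` returns the configured truth to well under
  0.1%, verified over a grid of TBW ∈ [30, 55] kg and
  $r\mathrm{CO}_2 \in$ [15, 45] mol/d.
* **Model-truth cohorts.** For parameter-recovery experiments, expenditure
  can be generated as a known prediction model applied to each participant
  plus normal residuals; course specs carry a PAF for this purpose.

What the generator does **not** emulate: multi-compartment water turnover,
within-day feeding or activity patterns, inter-course correlation of
individuals (some soldiers appear in multiple phases of real training), or
non-normal anthropometry. Passing tests therefore demonstrate correctness of
the computational chain under the stated statistical model, not robustness
to every feature of field data.

## Numerical choices and degenerate inputs

* Zero dilution gradient ($E_s = E_p$) and non-positive computed body water
  are errors with named causes, not NaNs.
* RQ is validated to the physiologic range [0.7, 1.0].
* PAF values outside 0–3 warn but still predict (the equations extrapolate
  linearly); masses must be positive.
* Quartile derivation requires ≥ 4 distinct PALs and strictly increasing
  cutpoints; ties produce a degenerate-scheme error.
* All randomness flows through a single integer seed per config; identical
  configs give byte-identical outputs, which the pipeline test checks
  against written files.

## Problem sizes used by the test suite

Simulation-based tests use sizes chosen to make Monte-Carlo error small
relative to the tolerance being asserted while keeping the default suite
quick: 200 replicate cohorts for CI containment, 500 replicates for the
isotope-noise bias check and for coefficient recovery at the published
n = 133 design, 10^4 participants for moment convergence and the
decomposition identity.

## Known limitations and published-table defects

The published course tables are the fixtures for reproduction tests, and
three of their rows do not close arithmetically from their own printed
means; the test suite does not patch these, so the corresponding
expectations fail loudly by design:

* **Platoon Raids** is internally inconsistent: AIEE is linear in TDEE, RMR
  and DIT, so course means must satisfy AIEE = TDEE − RMR − DIT, yet the
  printed row gives 4484 − 1912 − 448 = 2124 against a printed 2554 (and a
  recomputed PAL of 2.35 against a printed 2.31, and fat mass 9.3 against
  BM − FFM = 10.9). Its printed Model A mean (4118) likewise disagrees with
  the equation applied to its printed mass mean (≈ 4182). The row is treated
  as a documented defect, excluded from the predicted-mean reproduction.
* **Combat Dive School, Model B**: the printed FFM mean 63.8 yields a
  predicted 4667 against a printed 4663; the unrounded FFM mean was
  evidently ≈ 63.74 (the printed CI midpoint is 63.75), which reproduces
  4663. Within the printed precision this 4 kcal gap is unrecoverable.
* **Pooled "Overall" row**: balance and AIEE cannot be recomputed from the
  pooled means because two courses lack intake data and the Platoon defect
  propagates into the pooled AIEE.

Beyond table defects: the PAF ignores the time domain (a short, intense
event and a long moderate one can share a factor), RMR is estimated rather
than measured, and the models were built on Army and Marine SOF trainees —
generalization to other populations is untested. The coefficient-recovery
experiment also shows a genuine statistical limit: with body mass centered
near 82 kg, the regression intercept is estimated with an SE near 500
kcal/d, so even the mean of 500 replicate fits fluctuates by ~22 kcal/d —
recovery claims about the intercept at the percent level are not testable at
that replication size, while both slopes and the SEE recover to well under
1%.
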