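---
title: "Methods: models, simulators and numerical choices in mpmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulators and numerical choices in mpmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmri)
```

# What the package models

`mpmri` implements the analysis chain of a longitudinal multiparametric
MRI study of diet effects on the mouse brain: quantitative parameter maps
(T2, ADC, MTR), region-of-interest summaries, sequential linear
mixed-effects modelling of the longitudinal tables, linear-combination
quantification of HRMAS spectra, and the repeated-measures power analysis
used to size such studies. Because raw animal data of this kind are rarely
shareable, the package carries its own synthetic-data layer: every
analysis stage can be exercised against inputs whose ground truth is known
exactly, which is also how the test suite validates the implementation.

# Signal models and parameter maps

Voxelwise models:

* T2 mapping: $S(TE) = S_0\,e^{-TE/T_2}$, echo times in ms, 50 log-spaced
  echoes between 12 and 600 ms by default.
* Diffusion: $S(b) = S_0\,e^{-b\,\mathrm{ADC}}$ with $b$ in s·mm⁻² and
  ADC reported in µm²/s (converted internally by $10^{-6}$ to mm²/s; at
  brain-tissue values, ADC ≈ 700 µm²/s, this gives decay exponents of
  order one over the 200–2000 s·mm⁻² range). Default b grids are 9 values
  evenly spaced on [200, 2000] and the short 3-value grid {300, 750,
  1200} s·mm⁻²; the printed source ranges are open intervals, so the
  exact sampled values are a package default, overridable per protocol.
* Magnetization transfer: $\mathrm{MTR} = (S_0 - S_{MT})/S_0 \times 100$,
  in percent, from the saturation-off/on pair.

**Fitting.** Exponential fits use ordinary least squares on the log
signal as the initialiser, refined by a bounded Levenberg–Marquardt
iteration on the exponential model, vectorised across voxels (per-voxel
2×2 normal equations in closed form). The log-linear estimate alone is
biased under Rician noise; the nonlinear refinement removes that at the
cost of a few iterations. Physical bounds during fitting are
1 ≤ T2 ≤ 2000 ms and 0 ≤ ADC ≤ 4000 µm²/s — deliberately wider than the
ROI-stage retention filters, so that filtering happens once, at the ROI
stage, in the same order as the original processing. Convergence uses a
relative SSE tolerance of $10^{-8}$ with at most 200 iterations; voxels
that do not converge, have non-positive amplitude, or land on a T2 bound
(e.g. a constant, non-decaying series) are flagged invalid and excluded
from every downstream statistic, never silently filled. An ADC of exactly
zero is retained in the map: the strict 0 < ADC filter downstream is the
contract that removes it.

On noise-free input the initialiser is already exact, so the round-trip
phantom → series → map → ROI table reproduces ground truth to machine
precision; the test suite asserts ≤ 10⁻⁶ relative error for all three
parameters in all four regions, and separately checks the fitter against
a dense grid-search oracle (amplitude profiled out in closed form) on
noisy voxels.

**DWI directions.** When per-direction volumes are present the three
orthogonal-direction signals are combined by arithmetic mean before
fitting; the geometric mean is available as an option. Whether the
original in-house program averaged signals or per-direction ADCs is not
recoverable; for monoexponential isotropic phantoms the two coincide.

# ROI template, filters, outliers

Manual per-animal ROI drawing is replaced by a deterministic geometric
template with the published voxel counts: hypothalamus 70-voxel
rectangle, hippocampus two 30-voxel squares, NAc two 40-voxel ovals, ILA
20-voxel circle. Curved shapes are realised by taking exactly *n* voxels
nearest the centre in aspect-scaled distance with a deterministic
tie-break, so realised counts equal the specification exactly and masks
are pairwise disjoint by construction. Component centres are stored as
matrix fractions, so the template scales with geometry while counts stay
fixed.

Value filters are strict inequalities exactly as printed
(30 < T2 < 80 ms, MTR > 0, 0 < ADC < 1200 µm²/s); they are what removes
CSF-dominated voxels, which is why the phantom's CSF compartment carries
T2 = 150 ms, ADC = 2500 µm²/s and MTR = 0 — valid fits that every filter
rejects. Outlier removal acts on ROI-level means within
diet × day × region (× parameter) groups: values outside
[Q1 − 1.5·IQR, Q3 + 1.5·IQR] are dropped. Quartiles use linear
interpolation between order statistics (`stats::quantile` type 7, the
common spreadsheet convention; configurable, since the convention changes
small-sample fences). Groups with fewer than four observations skip the
rule — fences from 2–3 points are meaningless — and are flagged instead.

# The mixed-model ladder

The response is log-transformed; all models share the random backbone

* random intercept per mouse,
* random intercept per area within mouse,
* AR(1) correlation of residuals over the time-point index within each
  mouse × area series,

and the "rs" models add a per-mouse random slope in day rescaled to
[0, 1] (rescaling keeps the slope variance comparable across designs).
The slope is fitted with a diagonal mouse-level covariance (`pdDiag`):
the generator draws intercept and slope independently, and the diagonal
structure is markedly more stable on study-sized data than a full 2×2
covariance. The AR(1) index is the session number, not the calendar day
— the correlation is between successive measurements, which are unevenly
spaced in time.

The nine fixed-effect structures form the chain B, A, AT, ATrs, ATrsD,
ATrsD.TA, ATrsD.TA.DT, ATrsD.TA.DT.DA, ATrsD.TA.DT.DA.DAT; each contains
its predecessor's terms. Time enters the fixed effects as a categorical
factor (needed for day-versus-baseline contrasts and for the model
naming); the random slope uses numeric day. The alternative interaction
spellings that occur in practice (e.g. `ATrsD.AT`) are accepted as
aliases. Only the chain is searched, as described for the original
analysis; a full-subset search is a possible extension, not implemented.

**Estimation.** All ladder models are fitted by maximum likelihood,
because AIC comparisons across different fixed-effect structures are
invalid under REML; the selected model is refit by REML for reported
coefficients, contrasts and diagnostics. Ties in AIC (within $10^{-6}$)
go to the simpler model. Non-converged fits are excluded from selection
with their reason recorded.

**Inference.** Type III Wald chi-square tests are computed with
`car::Anova` under sum-to-zero contrasts (set on all factors at data
preparation — type III marginality is only meaningful in that coding).
Day-versus-baseline contrasts come from `emmeans` on the time factor
within each diet × region cell; the familywise adjustment over the 4
post-baseline days uses the joint multivariate-t distribution of the
contrast statistics with correlation taken from the fitted covariance
(Dunnett-style, `adjust = "mvt"`, seeded for reproducibility). The
package also exposes `dunnett_adjust()` directly, with a seeded
Monte-Carlo fallback when the integrator fails; the tests verify it
against an independent 10⁵-draw max-|t| simulation to within 0.005.
Residual diagnostics use normalized (whitened) residuals, which are the
meaningful ones under AR(1) correlation, plus a Shapiro–Wilk summary.

# The cohort simulator

`simulate_cohort()` generates the log response as
$\mu(\text{diet}, t, a) + b_i + b_{ia} + s_i\,t_{01} + e_{iat}$ with
independent Gaussian components and a stationary AR(1) residual, then
exponentiates. Defaults emulate the study conditions: 7 SD + 8 HFD
animals per sex, days {0, 7, 14, 28, 70}, four regions. Fixed-effect
defaults mirror the phantom's regional T2 spread on the log scale
(0, 0.105, 0.200, 0.288), a mild monotone time decline (0 to −0.04), and
a small diet offset (+0.03); variance components default to
σ_mouse = 0.03, σ_area = 0.02, σ_slope = 0.02, σ_resid = 0.03 and
ρ_AR = 0.4 on the log scale — a few-percent biological variability,
which is the scale seen in quantitative MR parameters of inbred mice.
These are the generator's fixed study conditions, not tuning knobs; the
calibration experiments in the tests state their own (smaller) designs
explicitly.

What the simulator does *not* emulate: anatomically realistic regions
(shapes are geometric stand-ins with correct counts), scanner artifacts
or k-space effects, registration error, missing sessions, or
physiological covariates. Passing tests therefore demonstrate
correctness of the estimation chain under the declared generating model,
not robustness to all failure modes of real acquisitions.

# HRMAS quantification

The basis set is synthetic: each metabolite is a mixture of Lorentzian
lines at textbook chemical shifts, unit-area normalised on a shared ppm
grid (0.2–4.5 ppm, 2048 points, linewidth 0.02 ppm), covering the
metabolites and lipid/macromolecule signals quantified in this kind of
study. The measured "homemade" basis of the original workflow is not
recoverable; only the fitting contract matters here.

Fitting solves a non-negative least-squares problem (`pracma::lsqnonneg`)
for the metabolite amounts; a quadratic baseline (order configurable) is
included as signed column pairs so its coefficients stay unconstrained
inside the NNLS. Non-negativity reflects physical concentrations.
Precision is reported as `sd_percent` = 100·SE/amount, with SE from the
least-squares covariance over the active set and the noise variance
estimated in a signal-free window (default 4.2–4.5 ppm, which the
default basis leaves empty). This is a covariance-based relative
standard error standing in for a CRLB-style %SD; what the pipeline
preserves is its role — the quality filter at ≤ 20% (boundary
inclusive). Ratios are to total creatine (Cr+PCr), with the composite
sums Cho+GPC+PCh, mI+Gly, Cr+PCr and Glu+Gln appended.

Per-metabolite statistics fit `ratio ~ diet + area` versus
`ratio ~ diet + area + diet:area` as mixed models with a mouse random
intercept — with one spectrum per mouse × area, an area-within-mouse
component is not separable from the residual — choose by
likelihood-ratio test at α = 0.05 (ML fits), refit the winner by REML,
and report type III Wald tests plus, when the interaction is retained,
per-area diet contrasts with a Bonferroni correction over the four areas
(the original correction for these post-hoc tests is unnamed; Bonferroni
is the conservative default).

# Power analysis

`rm_anova_power()` uses the classical repeated-measures noncentral-F
formulation: $\lambda = f^2 N m \varepsilon/(1-\rho)$, numerator df
$(m-1)\varepsilon$ for within designs and $(g-1)(m-1)\varepsilon$ for
the within-between interaction, denominator df
$(N-g)(m-1)\varepsilon$. The alternative convention in which the effect
size already absorbs the correlation is available via
`power_scenario(f_is_adjusted = TRUE)`, since common power software
offers both. The three shipped scenarios are (f = 0.35, m = 5),
(f = 0.25, m = 5, 2 groups) and (f = 0.15, m = 20, 2 groups), all at
α = 0.05, ρ = 0.8. The analytic power is validated against a seeded
simulation of the actual F tests (compound-symmetric subjects, effect
pattern scaled to f). Under the default convention and a target power of
0.80 the solved group sizes are 6, 5 and 6; the original sizing arrived
at 8, 7 and 8 with an unstated target power and convention, so those
integers are not reproducible from the printed inputs alone — the
default target (0.80) is exposed and configurable.

# Problem sizes and reproducibility

All simulators accept integer seeds and are bit-reproducible. The test
suite uses study-sized cohorts (15 mice × 5 sessions × 4 regions) for
selection consistency (50 simulated cohorts per arm), a reduced
calibration design (12 mice per diet, 3 sessions, 2 regions — more
subjects and fewer cells, where Wald chi-square tests are well
calibrated) for the 500-run type-I-error checks, 200 runs for interval
coverage, and 64×64 phantoms for most image tests with the full 128×128
geometry in the end-to-end round trip. `scripts/acceptance.R` recomputes
the same quantities at moderately smaller Monte-Carlo sizes and writes
them as JSON.

# Known limitations

* Monoexponential models only: no multi-exponential T2, IVIM, kurtosis
  or tensor diffusion.
* No registration, motion or artifact handling; the ROI template is
  geometric, not anatomical.
* CSF exclusion is purely value-based (the filters); no anatomical CSF
  mask is used.
* LCModel-specific machinery (spline baselines, lineshape/eddy-current
  correction, true CRLBs) is out of scope; the linear-combination core
  and the %SD-filter contract are what is implemented.
* The mixed-model layer searches the prescribed chain only and assumes
  Gaussian log-scale responses; it reports diagnostics rather than
  attempting automatic remediation.
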