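# mpmri

Longitudinal multiparametric MRI analysis of the mouse brain, as a tested,
reusable R pipeline.

Diet-induced obesity studies follow the same animals over weeks with
quantitative MRI — T2 relaxometry, diffusion (ADC) mapping, and
magnetization transfer ratio (MTR) — in a handful of brain regions
(hypothalamus, hippocampus, nucleus accumbens, infralimbic area), and
complement them with ex vivo HRMAS spectroscopy of the same regions. The
statistics behind such studies are not a t-test: repeated measures within
animal, regions nested in animals, serial correlation over sessions, and a
family of candidate mixed models to choose among. `mpmri` implements that
full chain for quantitative-MRI researchers and for statisticians who want
to validate it against known ground truth:

* **Parametric maps** — voxelwise monoexponential fits
  S(TE) = S0·e^(−TE/T2) and S(b) = S0·e^(−b·ADC) (log-linear
  initialisation refined by bounded Levenberg–Marquardt, vectorised over
  voxels), and MTR = (S0 − S_MT)/S0 · 100.
* **ROI statistics** — a deterministic ROI template with exact voxel
  counts (70-voxel hypothalamus rectangle, two 30-voxel hippocampal
  squares, two 40-voxel NAc ovals, 20-voxel ILA circle), the strict
  retention filters 30 < T2 < 80 ms, 0 < ADC < 1200 µm²/s, MTR > 0, and
  Q1/Q3 ± 1.5·IQR outlier removal within diet × day × region groups.
* **Mixed-model ladder** — the nine nested models
  B → A → AT → ATrs → ATrsD → …·TA → …·DT → …·DA → …·DAT fitted on
  log-responses with `nlme::lme` (mouse and area-within-mouse intercepts,
  optional per-mouse time slope, AR(1) residuals over sessions),
  ML/AIC selection, type III Wald chi-square tests, and Dunnett-corrected
  day-versus-baseline contrasts per diet × region (4 comparisons per
  family, joint multivariate-t adjustment).
* **HRMAS quantification** — non-negative linear-combination fitting of
  1-D spectra against a metabolite basis set with a polynomial baseline,
  %SD precision estimates (filter at ≤ 20), ratios to total creatine
  (Cr+PCr), and the diet × area mixed-model comparisons.
* **Power analysis** — noncentral-F power and sample-size solving for the
  repeated-measures ANOVA scenarios used to size such studies.
* **Synthetic data** — digital phantoms with per-region S0/T2/ADC/MTR
  ground truth and a CSF rim, Rician/Gaussian noise simulators,
  longitudinal cohort simulators with nested random effects and AR(1)
  serial correlation, and spectral simulators. Every downstream stage is
  testable without any acquisition.

## Worked example

Simulate a noisy T2-mapping acquisition of the digital phantom, fit the
map, and extract the template ROI means:

```r
library(mpmri)

phantom <- make_phantom()
series  <- simulate_series(phantom, make_protocol("t2map"),
                           noise_sigma = 10, noise_model = "rician", seed = 1)
maps  <- fit_t2_map(series)
masks <- make_roi_masks(roi_template(), list(matrix = 128))
codes <- attr(masks, "region_codes")
for (reg in c("hypothalamus", "hippocampus", "nac", "ila")) {
  r <- roi_mean(maps$t2, masks, label = codes[[reg]])
  cat(sprintf("%-14s T2 = %5.2f ms  (n = %d voxels)\n",
              reg, r$value, r$n_voxels_used))
}
#> hypothalamus   T2 = 45.29 ms  (n = 70 voxels)
#> hippocampus    T2 = 50.24 ms  (n = 60 voxels)
#> nac            T2 = 55.15 ms  (n = 80 voxels)
#> ila            T2 = 60.16 ms  (n = 20 voxels)
```

The phantom truth is 45/50/55/60 ms in those regions; at ~1% Rician noise
the ROI means land within a fraction of a millisecond of it, using exactly
the template voxel counts.

Simulate a full two-diet longitudinal cohort on the log scale and run the
model ladder on the male arm:

```r
tab <- simulate_cohort(cohort_design(seed = 1))
sel <- select_best_model(tab[tab$sex == "male", ])
sel$aic_table
#>                 model       AIC  logLik converged
#> 1                   B  -992.735 501.367      TRUE
#> 2                   A -1139.672 577.836      TRUE
#> 3                  AT -1213.536 618.768      TRUE
#> 4                ATrs -1212.151 619.076      TRUE
#> 5               ATrsD -1215.306 621.653      TRUE
#> 6            ATrsD.TA -1216.195 634.097      TRUE
#> 7         ATrsD.TA.DT -1212.051 636.026      TRUE
#> 8      ATrsD.TA.DT.DA -1206.265 636.133      TRUE
#> 9  ATrsD.TA.DT.DA.DAT -1190.948 640.474      TRUE

final <- fit_lme(tab[tab$sex == "male", ], sel$best$spec, "REML")
anova_type3(final)
#>            term   chisq df         p
#> 1        region 1122.99  3 3.75e-243
#> 2        time_f   99.65  4  1.17e-20
#> 3          diet    5.31  1  2.12e-02
#> 4 region:time_f   24.71 12  1.62e-02
```

The default generator includes regional differences, a mild time decline
and a small diet offset; the ladder lands on `ATrsD.TA` (AIC −1216.2,
fitted AR(1) φ = 0.39) and the type III tests flag region and time
strongly, diet marginally — the same read-out structure the method
produces on real cohorts. `time_contrasts(final)` then gives the four
Dunnett-adjusted day-versus-baseline contrasts per diet × region.

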