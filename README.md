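# petkin

Kinetic quantification for dynamic brain PET studies with arterial blood
sampling, built around the workflow used to evaluate reversible
radiotracers in non-human primates — for example candidate GSK-3
radioligands, whose fast metabolism, sub-percent plasma free fractions
and brain-penetrant radio-metabolites make them a demanding test case
for quantification.

The package covers the full chain from extracted regional time–activity
curves (TACs) and sampled arterial blood to occupancy estimates:

* **Blood processing** — Hill-type parent-fraction models
  `pf(t) = c + (1−c)/(1+(t/t50)^n)`, metabolite-corrected input
  functions (total plasma × parent fraction), and ultrafiltration
  plasma free fractions (f_P) from triplicates.
* **Compartment modeling** — one- and two-tissue compartment models
  with a 5% vascular fraction, solved by analytic impulse response
  convolved with the input; weighted nonlinear least squares with
  multi-start Levenberg–Marquardt; V_T = K1/k2 (1T) or
  (K1/k2)(1 + k3/k4) (2T) with delta-method rSE; model selection by
  AIC = n·ln(RSS/n) + 2k.
* **Scan-truncation stability** — refits over windows from 30 to
  120 min; a flat V_T profile indicates model-consistent data, a
  monotone rise is the signature of radio-metabolite accumulation in
  brain.
* **Occupancy analysis** — Lassen plots (across-region OLS of
  baseline−blocking V_T on baseline V_T) on raw V_T or V_T/f_P, with
  occupancy as the slope, V_ND as the x-intercept,
  BP_ND = (V_T − V_ND)/V_ND, and Guo cross-tracer V_T regressions.
* **Synthetic studies** — a seeded generator producing blood data and
  frame-binned TACs (33 frames / 120 min) with count-statistics noise,
  blocking scans (reduced k3, raised f_P), and an optional
  brain-penetrant hydrophilic metabolite; two calibrated presets
  (`ocm44_like`, `ocm50_like`) emulate a fast-metabolizing C-11 tracer
  and a cleaner F-18 tracer.
* **File formats** — plain CSV for TAC tables, sectioned blood tables
  and regional V_T tables (missing cells as `n.d.`), plus a packaged
  fixture with the published 13-region × 8-condition V_T table and its
  f_P metadata.

## Worked example

```r
library(petkin)

# simulate a baseline + blocking study of the F-18-like tracer
cfg <- preset("ocm50_like", seed = 42)
cfg$fp_coupling <- TRUE
study <- simulate_study(cfg)

# blood processing: Hill parent-fraction fit and input function
base <- study$scans$baseline
pf <- fit_parent_fraction(base$blood$parent_samples$time_min,
                          base$blood$parent_samples$parent_fraction)
pf
#> <parent_fraction_model> c = 0.15, t50 = 18 min, n = 1.5 (pf(30) = 0.420)
input <- make_input_function(base$blood$plasma, pf)

# fit both compartment models to frontal cortex and compare by AIC
f1 <- fit_model(base$tacs$frontal_cortex, input, base$blood$whole_blood, "1T")
f2 <- fit_model(base$tacs$frontal_cortex, input, base$blood$whole_blood, "2T")
f1
#> <kinetic_fit> frontal_cortex 1T: V_T = 0.875 (rSE 1.0%), AIC = -48.76, converged
compare_models(f1, f2)$preferred
#> [1] "1T"

# occupancy from the published V_T table, correcting for the f_P rise
tab <- load_table2_fixture()
occ <- lassen(vt_column(tab, "f18_baseline_a3"),
              vt_column(tab, "f18_block_0.1_a3"),
              fp_base = 0.006, fp_block = 0.014, mode = "fp_corrected")
occ
#> <occupancy_result> occupancy = 73.8% (SE 12.7), V_ND = 22 (SE 14.5), R2 = 0.753 [fp_corrected, 13 regions]
```

Reading the output: the simulated baseline frontal-cortex V_T of
0.875 mL/cm³ matches the configured truth (0.87) with ~1% relative
standard error, and the 1T model is preferred, as expected for
fast-exchange kinetics. On the published table, dividing each scan's
V_T by its own f_P (0.6% at baseline vs 1.4% under blocking) turns an
uninterpretable raw-V_T comparison into a linear occupancy plot giving
~74% occupancy with V_ND/f_P ≈ 22 — the free-fraction rise would
otherwise mask the blockade.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the study narrative end to
end, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_studies.R   # synthetic studies -> CSVs
Rscript analysis/02_fit_kinetics.R       # 1T/2T fits, AIC, V_T/K1/rSE table
Rscript analysis/03_truncation.R         # V_T vs scan-duration profiles
Rscript analysis/04_occupancy.R          # Lassen/Guo/BP_ND analyses
```

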