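# dwbpet

Kinetic analysis of dynamic whole-body PET with metabolized radiotracers,
plus a synthetic-data generator that makes the entire chain testable
without patient data.

The motivating application is 16α-[18F]fluoroestradiol (FES) PET in
metastatic estrogen-receptor-positive breast cancer: a two-session
dynamic whole-body protocol (0–70 min, a 10-min intermission, 80–120 min)
with venous blood sampling, from which one derives a metabolite-corrected
image-derived input function (IDIF), fits tissue kinetics, and asks
whether parametric net-influx (Ki) images make lesions more visible than
conventional SUV images.

## What it computes

* **Two-tissue compartment model.** Serial 2TCM with rates K1, k2, k3, k4
  and fractional blood volume vB; measured signal
  `(1 − vB)(C1 + C2) + vB·Cwb`. The forward model is the exact
  bi-exponential convolution with a piecewise-linear plasma input —
  eigenvalues `α₁,₂ = (s ∓ √(s² − 4k₂k₄))/2`, `s = k₂+k₃+k₄` — with exact
  frame averaging and analytic handling of repeated eigenvalues.
  Irreversible uptake is the k4 = 0 submodel with net influx rate
  `Ki = K1·k3/(k2 + k3)`.
* **Model selection.** Bounded multi-start Levenberg–Marquardt fits of
  both submodels; `AIC = n·ln(RSS/n) + 2p`;
  `ΔAIC = AIC(reversible) − AIC(irreversible)` with |ΔAIC| > 2 decisive.
* **Blood input.** Aorta IDIF extraction, a three-parameter Hill-with-floor
  parent-fraction model `pf(t) = (1−b)/(1+(t/t50)^n) + b` calibrated
  exactly to measured anchors (90% at 2 min, 40% at 20 min, 20% at
  120 min), a constant plasma-to-whole-blood ratio (default 1.50), and
  `Cp(t) = Cwb(t)·R·pf(t)`.
* **Patlak analysis.** `y = C(t)/Cp(t)` vs `x = ∫Cp/Cp(t)`; OLS slope (Ki)
  and intercept (V) over 40–70 min; voxelwise parametric Ki/V/r² images
  bit-identical to looping the curve fit over voxels.
* **SUV and visibility.** Body-weight-normalized SUV from the 60–70 min
  window; SUVmax ≥ 1.5 lesion screening; 50% isocontour VOIs
  (26-connectivity); TBR and CNR against explicit background masks; paired
  log-ratio comparison of image types (geometric-mean ratio, 95% CI,
  paired t-test).
* **Synthetic data.** The clinical frame schedule; a bolus-shaped
  whole-blood curve; organ/lesion phantoms on a 64×64×48 grid with a liver
  calibrated to hold 30% of the injected dose at 30 min, an aorta for the
  IDIF, 8 receptor-avid lesions (8–25 mm) and one cold lesion; Gaussian
  PSF; activity/duration-scaled Gaussian TAC noise; everything seeded.

## Worked example

```r
library(dwbpet)

inp <- make_input_function()                 # default blood input, R = 1.50
sch <- default_schedule()                    # 41 frames, 0-70 + 80-120 min
kp  <- kinetic_params(0.35, 0.30, 0.06, 0, 0.05)   # a lesion-like tissue
y   <- simulate_tac(kp, inp, sch, seed = 1)  # noisy TAC, default alpha

fit_irr <- fit_2tcm(y, inp, sch, mode = "irreversible", seed = 1)
fit_rev <- fit_2tcm(y, inp, sch, mode = "reversible",   seed = 1)
fit_irr
#> <fit_2tcm> irreversible: K1=0.3568 k2=0.3021 k3=0.05985 k4=0 vB=0.06259
#>   Ki=0.059  RSS=39.97  AIC=6.96  (n=41, p=4, converged=TRUE)
compare_models(fit_rev, fit_irr)
#> <model_comparison> dAIC = 2.00 -> irreversible (significant)
patlak_fit(patlak_points(y, inp))
#> <patlak_fit> Ki = 0.05912 mL/cm3/min, V = 0.1168 (r2 = 0.9941, 6 pts, 40-70 min)
```

The generating tissue has Ki = 0.35·0.06/0.36 = 0.0583 mL·cm⁻³·min⁻¹: the
compartment fit recovers it to ~1% at this noise level, the AIC comparison
(correctly) finds no support for a free k4, and the graphical Patlak slope
lands within a few percent — its residual deficit against the true Ki is
the expected finite-window and blood-volume bias discussed in the methods
vignette.

The full phantom pipeline (simulate → IDIF → fits → Patlak → SUV →
visibility report) runs as

```r
res <- run_pipeline(pipeline_config(), "out/")   # or: Rscript inst/cli/dwbpet.R run-all --out out
res$ratios$tbr     # TBR(Ki) vs TBR(SUV), geometric-mean ratio with 95% CI
```

and writes CSV tables (blood samples, corrected input, per-region ΔAIC,
per-lesion TBR/CNR), NIfTI volumes and a JSON summary with provenance.

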