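# neckstick

Forward head posture — the habitual anterior translation (protraction) of
the head relative to the thorax — is associated with neck pain and
headache, and monitoring it requires a measurement model simple enough for
wearable sensors. `neckstick` implements a two-joint kinematic neck model
for exactly that: two ball joints, J1 near vertebra C7 and J2 near vertebra
C2, connected by a rigid neck-stick of length `l12`. The head center (J2)
relative to the thorax is then determined by just two rigid-body
orientations — neck and sternum — plus the stick length, and protraction is
`p = l12 * sin(phi)` with `phi` the angle between the stick and the
thorax-up direction.

The package is aimed at movement scientists working with optoelectronic
marker data (and, prospectively, IMU orientations). It covers:

* **Frame algebra and pose estimation** — rigid-body poses from
  three-marker tripods (orthogonal Procrustes), static-posture
  calibration, gimbal-lock-safe Euler extraction.
* **Parameter identification** — the prediction error of the forehead
  position is linear in the seven unknowns (`vs1`, `l12`, `v2h`), so all
  trials of a participant pool into one linear least-squares system,
  solved in a single step:
  `argmin over (l12, vs1, v2h) of sum_i sum_t || o_hat_h^s(i,t) - o_tilde_h^s(i,t) ||^2`
  with residuals reported per axis as mean error and 5%/95% percentiles.
* **Anthropometric length predictor** — OLS law `l12 = b1 * lC2C7 + b0`
  from the palpable C2–C7 distance, plus validation of the resulting
  parametrized model against the individually fitted one.
* **Synthetic motion-capture simulator** — standardized head-movement
  tasks (zigzag/cross pursuit, neutral or protracted, free movement) from
  known ground-truth parameters with configurable marker/orientation
  noise; the test bed for everything above.
* **Noise sensitivity** — a Monte-Carlo sweep re-identifying the length
  under 1/5/10-times inflated noise, 25 repetitions per cell, showing the
  orientation-noise attenuation bias and the position-noise unbiasedness.

## Worked example

Simulate one participant of a synthetic cohort performing the full task
battery at 120 Hz with 0.5 mm marker noise, then identify the model:

```r
library(neckstick)

cohort <- generate_cohort(4, seed = 42)
recs <- simulate_participant(cohort[[1]], seed = derive_seed(42, 1),
                             marker_noise_sd = 0.5e-3, sample_rate = 120)
fit <- fit_parameters(recs)
fit
#> <neck_fit> 12269 samples, condition number 13.3
#> <neck_parameters> l12 = 111.51 mm
#>   vs1 (mm):   7.33  99.45 -69.84
#>   v2h (mm): -0.13 76.92 91.34
#>  axis         me_mm     p5_mm   p95_mm
#>     x  1.246013e-15 -3.886568 3.868457
#>     y  8.053412e-14 -2.744800 2.798221
#>     z -3.511785e-15 -3.973223 4.010618

cohort[[1]]$params$l12 * 1000   # ground truth
#> [1] 111.8565
```

The identified neck length lands within 0.35 mm of the ground truth, and
the per-axis residual percentiles (about ±4 mm here) reflect the injected
marker noise; the mean errors are numerically zero because the thorax
vector acts as a per-axis intercept in the pooled least-squares system.

Protraction from the fitted length during a protracted-posture trial:

```r
tail(protraction_series(recs$zigzag_protracted, fit$params$l12), 3)
#>      time_s  p_mm phi_deg px_mm py_mm pz_mm
#> 1847  15.38 33.34   17.40  4.11 -4.84 33.12
#> 1848  15.39 30.77   16.02  1.79 -4.48 30.70
#> 1849  15.40 35.00   18.29  1.98 -5.18 35.02
```

The full pipeline (per-subject fits, cohort length law, parametrized-model
validation) writes its artifacts — per-participant parameter JSONs,
residual tables, the length-model JSON and a seed-provenance log — to an
output directory:

```r
out <- run_pipeline(tempfile("nk"), cohort = cohort, seed = 42,
                    marker_noise_sd = 0.5e-3)
out$length_model
#> <length_model> l12 = -2.8619 * lC2C7 + 0.2558 m  (residual SD 9.56 mm)
```

With only four subjects and ~1 cm of biological scatter the length law is
weakly determined (here the slope even changes sign) — the palpable C2–C7
distance is a weak predictor of the effective stick length, which is why
the parametrized model's J2 residuals are an order of magnitude larger
than the fitted model's.

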