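# usdeblur

Blind deblurring of speckle-corrupted grayscale ultrasound images with
**secondary sparse extreme channel priors**, for image-analysis work on
ultrasound guidance (e.g. nerve-block procedures) where motion and
interference blur the view and no ground-truth sharp image exists.

An observation `Z` is modeled as a sharp latent image `M` convolved with an
unknown point-spread function `h` plus multiplicative speckle.  Sharp
ultrasound scenes contain genuinely anechoic (dark) and strongly echogenic
(bright) structure, so the patch-minimum *dark channel* `A_M` and
patch-maximum *bright channel* `Z_M` — applied twice, giving the *secondary
sparse* channels `S(·)` — are sparse for sharp images and not for blurred
ones.  The package fits

```
min over M, h   || M ⊗ h − Z ||²  +  φ ||h||²
                +  ϑ [ θ ||S(A_M)||₀  +  ζ ||1 − S(Z_M)||₀ ]
                +  λ_g ||∇M||₀
```

by L0 hard-threshold half-quadratic splitting, alternating latent-image and
kernel estimation over a coarse-to-fine pyramid, with a noise-adaptive
kernel schedule and a final total-variation non-blind restoration.  Also
included: MSE / PSNR / SSIM evaluation with PSNR quality banding, a seeded
synthetic ultrasound-phantom benchmark with ground truth, clinical
summary-statistics reproduction (two-sample t, 2×2 chi-square), and a small
CLI.

## Worked example

```r
library(usdeblur)

# a ground-truthed synthetic nerve-region scene: motion blur of extent 7 px
# at 30 degrees, Rayleigh speckle at 20 dB SNR
spec <- phantom_spec(size = c(128, 128), scene = "nerve_region",
                     kernel_type = "motion", kernel_size = 9,
                     kernel_length = 7, kernel_angle = 30,
                     speckle_model = "rayleigh", speckle_snr_db = 20, seed = 1)
pair <- degraded_pair(spec)

fit <- deblur(pair$observed)      # blind: estimates both image and kernel
print(fit)
#> Blind deblurring fit: 128 x 128 image, 15 x 15 kernel, 6 pyramid level(s)
#> Objective (finest level): 188.73

quality_report(pair$observed, pair$truth)
#>   MSE 0.00445748 | PSNR 23.509 dB | SSIM 0.5681 | grade: poor
quality_report(fitted(fit), pair$truth)
#>   MSE 0.00229329 | PSNR 26.395 dB | SSIM 0.8254 | grade: poor
```

The blind fit recovers about +2.9 dB PSNR and lifts SSIM from 0.57 to 0.83
on this scene; `coef(fit)` returns the estimated kernel, `residuals(fit)`
the reblurring residual, and `plot(fit)` shows observed / restored / kernel
side by side.  Clinical summary tables are reproduced with

```r
clinical_report()   # rates 92 / 80 % and 8 / 16 %, chi-square and t tests
```

A command-line interface wrapping the same functions ships at
`system.file("cli", "usdeblur", package = "usdeblur")` with subcommands
`simulate`, `deblur`, `evaluate`, `channels` and `report`.

## Package layout

- `R/` — S3 model interface (`deblur()` + methods), channel operators,
  solver, metrics, phantom generator, clinical summaries, CLI dispatcher
- `src/` — C++ primitives: patch extremum with argmin/argmax maps, direct
  clipped-border convolution
- `vignettes/extreme-channel-deblurring.Rmd` — the methods vignette: model,
  solver, parameter rationale, generator realism and limitations
- `tests/testthat/` — unit, property and acceptance tests against
  brute-force oracles
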