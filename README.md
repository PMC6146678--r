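# ffasr — example-based super-resolution for fundus fluorescein angiography

`ffasr` is an R toolkit for patch-based single-image super-resolution
(SISR) of fundus fluorescein angiography (FFA) and other single-channel
retinal images.  It is aimed at researchers in retinal image analysis who
want reproducible, desk-scale implementations of the classical
example-based SR method families, a common training/evaluation pipeline
around them, and a synthetic fundus dataset generator so everything is
testable without clinical data.

## The methods

Training pairs come from the simplified degradation model `x_l = G x_h`
(`G` = bicubic downsampling by the factor `M` ∈ {2, 4}).  All methods work
on dense mean-removed 3×3 LR patches paired with 3M×3M HR windows, and by
default learn the *residual* over the bicubic interpolation, so a zero
prediction reproduces the baseline.  Implemented families:

| Method | Idea | Reference parameters |
|---|---|---|
| `bicubic` | interpolation baseline | — |
| `ne_ls`, `ne_nnls` | neighborhood embedding: combine the K nearest LR training patches with sum-to-one LS / non-negative LS weights, apply the weights to the paired HR patches | K = 24 |
| `sb_yang` | coupled dictionaries trained jointly under a shared L1 sparse code; lasso coding at test time | B = 2048, λ = 0.1 |
| `sb_zeyde` | K-SVD on LR patches + closed-form (pseudo-inverse) HR dictionary; OMP coding | B = 2048, L = 24 |
| `anr`, `aplus` | per-atom precomputed ridge projections `P_j = N_h (N_lᵀN_l + λI)⁻¹N_lᵀ` over the K nearest atoms (ANR) or training patches (A+) | K = 40 / 2048, λ = 0.1 |
| `jor` | EM-style alternation of per-cluster ridge maps and min-error reassignment; kNN majority vote picks the regressor at test time | O = 32, 20 iters, K = 32 |
| `srf` | random forest with a regularized split quality `E = mean(‖x_h − m(x_l)‖² + κ‖x_l − x̄_l‖²)` and ridge linear maps in the leaves, averaged over T trees | T = 6, depth 15, λ = 0.1, κ = 1 |

Reconstruction quality is scored by PSNR (dB, peak = 1.0 on the normalized
scale) and SSIM (11×11 Gaussian window, σ = 1.5).

## Worked example

```r
library(ffasr)

# a synthetic dataset of 10 simulated eyes, 4 homologous images each,
# degraded to HR/LR pairs at x2 and split ~23:14 per group
ds <- generate_grouped_dataset(n_groups = 10, per_group = 4,
                               factor = 2, image_size = 128, seed = 1)
ds
#> <grouped_dataset> 10 groups, 20 train / 20 test pairs, 128px, factor 2

# train a reduced-size SR forest and evaluate it against the baseline
cfg <- method_config("srf", factor = 2, seed = 1, n_trees = 3, max_depth = 10)
model <- train_model(cfg, ds$train_pairs)
report <- evaluate(ds$test_pairs, list(srf = model))
report
#> <metrics_report> factor 2x, 20 test images
#>   method mean_psnr_db mean_ssim n_images
#>  bicubic         30.0     0.926       20
#>      srf         32.5     0.949       20

sr <- super_resolve_image(ds$test_pairs[[1]]$lr, model)
psnr(ds$test_pairs[[1]]$hr, sr)
#> [1] 32.96819
```

The forest recovers about 2.5 dB over bicubic interpolation on this
dataset: vessel borders and the disc margin are reconstructed from learned
patch statistics instead of being smoothed away.  `benchmark(seed = 1)`
runs all nine methods end to end (about 4–5 minutes on one CPU) and
returns the same report layout with one row per method.

## Layout

- `R/` — imaging core (bicubic resampling, patches, PSNR/SSIM), the five
  SR method families, phantom/dataset generation, pipeline orchestration.
- `tests/testthat/` — unit, property and oracle tests per module plus the
  end-to-end acceptance suite.
- `vignettes/ffa-super-resolution.Rmd` — the models, their assumptions,
  parameter meanings, the phantom generator's scope, and design decisions.
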