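# msaunet

Multi-scale spatial attention U-Nets for segmenting small, irregular,
low-contrast organs — the *gallbladder regime* — in 2-D CT slices.

Gallbladder segmentation is a stress test for encoder–decoder networks:
the organ is small, its shape varies, and its gray level sits within noise
distance of neighboring soft tissue. `msaunet` implements a U-Net family
whose deepest encoder stages are replaced by **Multi-Spatial-Attention
(MSA) blocks**:

* **MSFEF** — multi-scale feature extraction and fusion: parallel
  convolutions with kernel banks (3, 5, 7) and (5, 7, 9), concatenated and
  fused 1×1. Version **V1** uses one bank per block; **V2** runs both banks
  in parallel.
* **MSSA** — multi-scale spatial attention: the classical
  channel-squeeze/spatial-excitation gate (sSE: 1×1 conv → sigmoid →
  per-pixel weight `w ∈ (0,1)`, `y = x ⊙ w`) extended with attention maps
  computed at average-pooled scales (factors 2 and 4), upsampled and fused
  into the final gate.
* a residual shortcut around each block, batch normalization after every
  convolution, and a bilinear-upsampling decoder with residual double
  convolutions.

Training uses the soft Dice loss
`L = 1 − 2(|GT ∩ Pred| + ε)/(|GT| + |Pred| + ε)`; evaluation uses the
seven-metric protocol — DSC, JSC, PPV, SE (overlap) and HD, RVD, VOE
(boundary/volume) — with mean ± SD aggregation and one-way ANOVA + Fisher
LSD model comparison.

Because the originating study's patient data are private, the package
ships a fully seeded **phantom generator**: perturbed-ellipse targets with
Fourier-series boundary irregularity, gray-level-similar neighbor blobs,
and Gaussian HU noise, plus the CT preprocessing chain (HU conversion,
window/level, CLAHE, paired affine augmentation). The network runs on a
small built-in reverse-mode autodiff engine with Rcpp convolutions — no
external deep-learning framework.

## Worked example

```r
library(msaunet)

# a 64x64 phantom: small irregular low-contrast target + 3 neighbor blobs
pair <- generate_phantom(phantom_spec(seed = 42))
#> phantom 64x64 | target area 191 px | 3 neighbor blob(s) | seed 42

# seven metrics for a deliberately imperfect prediction (mask shifted 1 px)
pred <- apply_affine(pair$mask * 1, pair$mask, shift = c(1, 0))$mask
case_metrics(pair$mask, pred, case_id = "shifted")
#>   case_id       dsc       jsc       ppv        se hd rvd       voe flagged
#> 1 shifted 0.9424084 0.8910891 0.9424084 0.9424084  1   0 0.1089109   FALSE
```

A one-pixel shift of a 191-pixel target already costs ~6 DSC points and
11 VOE points — exactly the sensitivity that makes small-organ
segmentation metrics demanding.

```r
# train a reduced-width MSAU-Net V1 (3 MSA blocks, MSSA) on 80 phantoms
cfg <- train_config(
  model = model_config("V1", n_msa_blocks = 3, attention = "MSSA",
                       base_channels = 8, depth = 3),
  data = list(n = 80, base_spec = phantom_spec(),
              jitter = list(target_axes = 2, target_mean_hu = 5)),
  epochs = 8, batch_size = 8, seed = 1)
res <- run_training(cfg, verbose = TRUE)
#> epoch   1 | train loss 0.8836 | val dice 0.0000
#> ...
#> epoch   8 | train loss 0.5656 | val dice 0.7964
rep <- run_evaluation(res, res$dataset, split = "test")
print(rep)
#> Metrics report for 'MSAU-Net V1 (n=3, MSSA)' (38 cases):
#>   DSC  0.7832 +/- 0.2152 (n=38)
#>   JSC  0.6833 +/- 0.2330 (n=38)
#>   PPV  0.9394 +/- 0.0741 (n=38)
#>   SE   0.7354 +/- 0.2654 (n=38)
#>   HD   3.3964 +/- 2.3575 (n=38)
#>   RVD  0.2707 +/- 0.2682 (n=38)
#>   VOE  0.3167 +/- 0.2330 (n=38)
```

Eight epochs on 80 phantoms (~80 s on one CPU) already reach DSC 0.78 on
held-out cases; the acceptance-grade run (200 training phantoms, 10
epochs, ~4 min) reaches DSC ≈ 0.94 against the repository bar of 0.85.
Comparing against the `n_msa_blocks = 0` improved-U-Net baseline trained
identically gives one F and p per metric:

```r
compare_reports(list(rep, rep0))$table
#>     metric   f_stat      p_value df_between df_within significant
#> dsc    dsc 450.0034 3.501019e-33          1        74        TRUE
#> ...                                                  (7 metrics)
```

Mean ± SD per model, the omnibus F, and LSD-protected pairwise flags
mirror the standard model-comparison table layout for this task.

## Command line

```sh
inst/cli/msau phantom --n 20 --out phantoms/ --seed 1 --format nifti
inst/cli/msau train --config cfg.json --out model.rds --seed 1
inst/cli/msau evaluate --checkpoint model.rds --config cfg.json --out report
inst/cli/msau predict --checkpoint model.rds --image slice.nii.gz --out mask.nii.gz
inst/cli/msau ablate --config cfg.json --out ablation/
```

Configs are JSON (YAML if the optional `yaml` package is installed) with
`model`, `loss`, `preprocess`, `train` and `data` blocks. Images and masks
travel as single-slice NIfTI-1 (`.nii`/`.nii.gz`), PGM, or PNG (optional
`png` package); each phantom gets a JSON sidecar recording its generating
spec.

## Package layout

| Area | Files |
| --- | --- |
| Phantom generator | `R/phantom.R` |
| CT preprocessing + augmentation | `R/preprocess.R` |
| Autodiff engine + layers | `R/autograd.R`, `R/layers.R`, `src/conv2d.cpp` |
| MSA architecture | `R/arch.R` |
| Dice loss | `R/loss.R` |
| Seven-metric evaluation | `R/metrics.R` |
| ANOVA / LSD | `R/stats.R` |
| Training / evaluation / ablation | `R/pipeline.R` |
| I/O (NIfTI, PGM, PNG, sidecars) | `R/io.R` |
| CLI | `R/cli.R`, `inst/cli/msau` |

See `vignettes/msaunet-methods.Rmd` for the model, the design decisions
taken where the source description is open, what the phantom world does
and does not establish, and known limitations.
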