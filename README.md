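# mriseg

Two-phase analysis of 2-D T2-weighted brain MR slices, for researchers who
need a tested, dependency-light reference implementation of
classification-then-segmentation tumor screening:

1. **Classification** — a lightweight block-structured CNN (stem +
   residual identity/projection blocks + inception blocks + softmax head)
   labels contrast-enhanced, geometrically augmented slices as *normal*
   or *abnormal*. For 256×256×1 input the resolved architecture counts
   **549,890 trainable + 3,904 non-trainable = 553,794 parameters**.
2. **Segmentation** — abnormal slices are thresholded by maximizing the
   multi-level Tsallis entropy of the gray-level histogram,

   H_i = (1 − Σ_k (h_k/P_i)^γ) / (γ − 1),   maximize Σ_i H_i over
   thresholds t_1 ≤ … ≤ t_m,

   with a DE/rand/1/bin differential-evolution search (D = m = 6,
   NP = 10·D, F = 0.5, CR = 0.9, ≤ 100 generations). The aggregate cut
   T_a is the mean of the three largest thresholds; pixels above T_a form
   the raw mask, which is refined by a morphological opening with a
   radius-10 disk. Quality is reported as Dice, TPR/TNR/PPV, F-score,
   accuracy, and balanced accuracy ((TPR+TNR)/2).

Since the original clinical corpus is not redistributable, the package
includes a seeded 256×256 phantom generator (elliptical head, tissue
strata, 0–3 hyperintense lesions with exact masks, noise and bias field)
so every stage runs and is tested fully offline. Images are read/written
as PGM (8/16-bit, ASCII or binary).

## Worked example

```r
library(mriseg)

# one abnormal phantom with a known 22-px lesion
ph <- make_phantom(phantom_spec(
  tumors = list(list(center = c(100, 150), radius = 22, intensity = 0.93)),
  seed = 7))

# enhance -> 6-threshold Tsallis/DE -> aggregate -> binarize -> open
res <- segment_image(ph$image, tsallis_params(gamma = 0.5, m = 6),
                     de_config(D = 6, seed = 17))
res$thresholds
#> <threshold_vector m=6: 11, 134, 156, 175, 199, 239 | objective 43.3622 | T_a 204.333>
dice(res$refined, ph$mask)
#> [1] 0.9947...
confusion_metrics(pixel_confusion(res$refined, ph$mask))
#> <metrics_report>
#>   accuracy 0.9998
#>   TPR      0.9895
#>   TNR      1.0000
#>   PPV      1.0000
#>   f_score  0.9947
#>   AUC      0.9947
```

The six thresholds partition the enhanced histogram's modes (background,
parenchyma, CSF, lesion); T_a ≈ 204 falls between the CSF and lesion
modes, so binarization isolates the lesion and the opening removes
speckle. Dice 0.995 means near-perfect pixel overlap with the ground
truth; TNR = PPV = 1 means no false-positive pixels survived refinement.

```r
# the resolved classifier and its parameter budget
model <- build_network(resolved_network_spec(), seed = 17)
model
#> <mriseg_model 256x256x1: 549,890 trainable + 3,904 non-trainable = 553,794>

# desk-scale training: quarter-width instance, stratified 5-fold CV
ds <- make_dataset(n_abnormal = 88, n_normal = 32, seed = 42)
cv <- crossvalidate(ds, train_config(optimizer = "adam", batch_size = 8,
                                     epochs = 3, folds = 5, seed = 7),
                    spec = reduced_network_spec())
cv$summary   # mean ± SD of accuracy, TPR, TNR, PPV, F, balanced accuracy
```

## Command line

```sh
Rscript inst/cli/mriseg.R simulate --abnormal 194 --normal 70 --seed 17 --out data/
Rscript inst/cli/mriseg.R augment  --manifest data/manifest.csv --factor 9 --out data_aug/
Rscript inst/cli/mriseg.R segment  --in data/ --thresholds 6 --gamma 0.5 --out seg/
Rscript inst/cli/mriseg.R evaluate --pred seg/ --truth data/ --out report
Rscript inst/cli/mriseg.R run      --manifest data/manifest.csv --out run/
```

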