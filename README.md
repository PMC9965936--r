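# hhocnn

Binary brain-tumor classification of 2-D grayscale MR slices, implemented
as a fully reproducible R pipeline:

1. **Synthetic brain phantoms** with exact ground truth (elliptical brain,
   optional hyperintense circular tumor, Gaussian + salt-and-pepper noise),
   plus PNG/TIFF dataset I/O in the standard two-folder (`yes`/`no`) layout.
2. **Preprocessing** — sliding-window median filtering and mean-split
   sub-histogram equalization (the gray range is split recursively at
   CDF-weighted mean levels and each segment equalized onto its own
   interval, limiting brightness shift).
3. **Segmentation** — fuzzy c-means clustering of pixel intensities
   (centers *V_j = Σ μ_ij^m x_i / Σ μ_ij^m*, memberships
   *μ_ij = 1 / Σ_k (d_ij/d_ik)^(2/(m−1))*), seeded region growing from each
   cluster's maximal-membership pixel, and candidate-lesion selection by
   circularity × boundary edge support.
4. **Features** — statistical moments (mean, sd, skewness, kurtosis) and
   GLCM texture descriptors (contrast, correlation, energy, homogeneity)
   of the candidate region.
5. **Classification** — a small CNN (conv → ReLU → max-pool → fully
   connected → sigmoid) trained by mini-batch gradient descent on the MSE
   loss *(1/g) Σ (F − F\*)²*, then refined by a Harris Hawks style
   population metaheuristic using the printed update branches
   *A′ = A_rand − v₁|A_rand − 2v₂A|* (exploration) and
   *A′ = (1 − v₁)A_rand + 2v₁v₂A* (exploitation); refined weights are
   accepted only if the training loss does not increase.
6. **Evaluation** — confusion matrix, accuracy/specificity/precision/
   recall/F1, ROC + trapezoid AUC, and segmentation Dice against the
   ground-truth masks.

The intended audience is researchers who want a transparent, dependency-light
reference implementation of this enhancement → clustering → region-growing →
metaheuristic-CNN chain, testable end to end without any external image
download.

## Worked example

```r
library(hhocnn)

run <- run_pipeline(pipeline_config(n_images = 100, seed = 1))
print(run)
#> hhocnn_run
#>   segmentation: mean tumor Dice 0.949
#> metrics_report (n = 20): TP 9  TN 10  FP 0  FN 1
#>   accuracy 0.9500  specificity 1.0000  precision 1.0000  recall 0.9000  F1 0.9474
#>   AUC 1.0000
```

One hundred 64×64 phantoms (50 with tumors) are generated from seed 1 and
split 80/20; the candidate regions recovered by FCM-seeded growing overlap
the true tumor masks with a mean Dice of 0.949; the trained and refined
classifier labels 19 of the 20 held-out images correctly (one small tumor
is missed, hence recall 0.90), and its probabilities rank every tumor above
every non-tumor (AUC 1). Rerunning the same call reproduces these numbers
exactly — every stage seed derives from the global seed.

The stages are also available individually (`median_filter()`,
`equalize()`, `fcm_fit()`, `region_grow()`, `select_candidate()`,
`glcm_features()`, `train_gd()`, `refine_hho()`, `hho_optimize()`, ...) and
through a command-line interface:

```sh
Rscript inst/cli/hhocnn.R generate --out data --n 100 --seed 1
Rscript inst/cli/hhocnn.R train --data data --out model
Rscript inst/cli/hhocnn.R predict --model model --data data --out pred.csv
Rscript inst/cli/hhocnn.R evaluate --pred pred.csv --out report
```

See `vignettes/tumor-phantom-pipeline.Rmd` for the methods account: model
assumptions, parameter defaults and why, what the phantoms do and do not
emulate, and the package's design decisions.

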