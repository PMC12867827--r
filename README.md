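# casnet

Curvature-aware cardiac MRI segmentation in R: a complete, CPU-only
implementation of the CASNet architecture — a U-Net backbone extended with a
**Multi-Scale Context Block** (MSCB) at the bottleneck, **Cross-Attentive
Skip Connections** (CASC) in place of naive concatenation, and a
**curvature-aware composite loss** — together with a synthetic short-axis
cardiac phantom generator, the full seven-metric evaluation suite, and a
training/ablation harness. All forward and backward passes are written
against BLAS-backed im2col kernels (RcppArmadillo), so no GPU and no
external deep-learning framework is needed.

## Who this is for

Researchers and students who want a transparent, fully testable reference
implementation of attention-augmented encoder–decoder segmentation with
boundary-geometry regularisation — one where every gradient is checked
against finite differences and every metric against a brute-force oracle —
rather than a black-box training script.

## The model

For a grayscale slice the network predicts per-pixel probabilities over
four classes (background, right ventricle, myocardium, left ventricle).
Three components extend the plain U-Net:

* **MSCB** (bottleneck): `F_out = Conv1x1(Concat(σ(Conv_k(F_in)), k ∈ {1,3,5}))`
  — parallel receptive fields fused back to the input width.
* **CASC** (each skip): queries from the decoder, keys/values from the
  encoder via 1×1 projections; attention `A_ij = softmax_j(⟨Q_i,K_j⟩/√C_a)`;
  output `Conv3x3(Concat(F_d, A·V))`.
* **Composite loss**: `L = 0.5·L_BCE + 0.4·L_Dice + 0.1·L_curv`, where
  `L_curv = (1/HW) Σ_ij ‖∇²Ŷ(i,j)‖²_F` penalises the squared Frobenius norm
  of the probability map's spatial Hessian (central differences), favouring
  smooth, anatomically plausible boundaries.

Evaluation reports DSC, recall, accuracy, precision, Jaccard, exact
Hausdorff distance and mean absolute contour distance (mm), per class and
macro-averaged.

## Worked example

```r
library(casnet)

# a 64x64 synthetic short-axis phantom
s <- generatePhantom(phantomSpec(), seed = 7)
table(sampleMask(s))
#>    0    1    2    3
#> 2661  393  424  618        # background, RV, MYO, LV pixels

# train the full model at desk scale (~2 min on one CPU core)
cfg <- experimentConfig(seed = 101, epochs = 15)
fit <- trainModel(cfg)
tail(fit$log, 1)
#>    epoch trainLoss valLoss    lr
#> 15    15    0.3491  0.4006 1e-04

# segment held-out phantoms and score them
test <- generateDataset(phantomSpec(), 4, seed = 999)
pred <- predictMasks(fit$model, test)
evaluateSegmentation(pred[[1]], sampleMask(test[[1]]))
#>   class    dsc  recall   acc precision    jc   hd  mad
#> 1     1  0.404   ...                                    # RV
#> 2     2  0.748   ...                                    # MYO
#> 3     3  0.924   ...                                    # LV
#> 4 macro  0.692   ...
```

The composite loss decomposes exactly into its three terms:

```r
p <- matrix(0.5, 128, 128)                  # maximally uncertain prediction
m <- matrix(0L, 128, 128); m[, 1:64] <- 1L  # half-foreground truth
compositeLoss(p, m, lossWeights(0.5, 0.4, 0.1))
#> [1] 0.5465587                              # = 0.5*ln(2) + 0.4*0.5 + 0
```

An 8-variant ablation over (MSCB, CASC, curvature loss) on a shared phantom
split is one call: `runAblation(experimentConfig(seed = 1))`.

A command-line interface wraps the same functions:

```sh
CASNET=$(Rscript -e 'cat(system.file("exec", "casnet", package = "casnet"))')
Rscript $CASNET phantoms --n 32 --size 64 --seed 1 --out-dir data --format png
Rscript $CASNET train --config cfg.yaml --checkpoint model.rds
Rscript $CASNET evaluate --pred-dir preds --true-dir truth --out report.csv
```

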