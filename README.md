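# myinet

Four-class semantic segmentation of short-axis cardiac late-gadolinium-
enhancement (LGE) MRI: background, blood pool, myocardium and LGE (scar).
The package is aimed at researchers who need a complete, reproducible
segmentation pipeline — model, class-imbalance weighting, training loop,
augmentation and evaluation — that runs on a plain CPU and can be exercised
end to end on a built-in synthetic cardiac phantom with pixel-perfect
ground truth.

## What is inside

* **Models.** An encoder–decoder network with three interchangeable
  backbones — `MI-ResNet18-AC`, `MI-ResNet50-AC`, `MI-MobileNet-AC` — all
  at output stride 16, an atrous-spatial-pyramid-pooling (ASPP) context
  module with branch rates (k, 2k, 3k), k = 6, and a decoder that fuses
  stride-4 low-level features before up-sampling to per-pixel class scores.
  Every layer (dilated/depthwise convolution, batch norm, bilinear
  resampling) is implemented in the package with explicit forward and
  backward passes on RcppArmadillo — no deep-learning framework required.
* **Median-frequency class balancing.** `W_i = median(F) / F_i` for class
  frequencies `F`, feeding a pixel-wise weighted cross-entropy. For four
  classes the two weights straddling the median have harmonic mean exactly
  1 — a built-in consistency check on any weight set.
* **Training.** Momentum SGD, initial learning rate 1e-3 divided by 3
  every 10 epochs, mini-batch 10, early stopping after 4 non-improving
  validations, best-validation-loss model selection, on-the-fly rotation
  and scaling augmentation of the training split only.
* **Metrics.** Confusion matrix, global / mean / per-class accuracy,
  IoU, weighted IoU, boundary F1 with distance tolerance 0.75 % of the
  image diagonal, per-image reports with LGE pixel counts — each validated
  against brute-force loops in the test suite.
* **Phantom generator.** Seeded, patient-grouped synthetic cohorts with
  concentric cardiac geometry, a scar wedge whose intensity is close to
  blood, optional MVO core merged into the LGE class, and severe class
  imbalance (background > blood > muscle > LGE), split 60/20/20 by patient.

## Worked example

```r
library(myinet)

params <- phantom_params(64)                      # 64 px phantoms
cohort <- generate_cohort(20, 3, params, seed = 1,
                          fractions = c(train = 0.8, validation = 0.2, test = 0))
freq <- class_frequencies(cohort$images)
round(freq, 4)
#> [1] 0.8123 0.1051 0.0696 0.0130      # background, blood, muscle, LGE

w <- median_frequency_weights(freq)
round(as.numeric(w), 4)
#> [1] 0.1075 0.8310 1.2554 6.7299      # rare classes get large weights

spec  <- model_spec("mi-resnet18", width_multiplier = 0.5)
model <- build_myinet(spec, seed = 1)
fit   <- train(model, cohort, train_config(max_epochs = 30, seed = 1))
tail(fit$history, 1)
#>    epoch           lr train_loss  val_loss val_gacc
#> 30    30 0.0001111111  0.1734     0.2672   0.9100

val  <- cohort_split(cohort, "validation")
pred <- lapply(val, function(li) segment(fit$model, li$pixels))
rep  <- metrics_report(Map(function(v, p) list(gt = v$labels, pred = p), val, pred))
rep
#> gAcc 0.9100 | aAcc 0.5362 | mean IoU 0.4862 | wIoU 0.8377 | bfscore 0.2879
#> per-class accuracy: 0.9978 0.9319 0.2130 0.0021
#> per-class IoU:      0.9238 0.8306 0.1883 0.0019
```

The history shows the step learning-rate decay (1e-3, then /3 every 10
epochs) and the validation global accuracy reached by the unweighted run;
`metrics_report` pools the validation confusion matrix (gAcc, wIoU) and
averages the boundary-F1 per image. Re-running `train` with
`class_weights = w` trades global accuracy for a several-fold higher LGE
recall — the behaviour the weighting exists to produce; compare
`class_accuracy()` of the two runs.

A command-line surface wraps the same functions
(`generate | train | predict | evaluate | describe`):

```sh
Rscript inst/cli/myinet.R generate --patients 10 --seed 7 --size 64 --out cohort/
Rscript inst/cli/myinet.R describe --backbone mi-mobilenetv2
```

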