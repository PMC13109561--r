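# varietyid

Fine-grained identification of crop varieties — rice accessions, maize
inbred lines — from whole-plant RGB images taken across growth stages
and from two viewpoints. The package is aimed at phenotyping and
breeding workflows where hundreds of closely related classes must be
told apart from a handful of images each, and where images arrive as
time series (front and side view per sampling date) from a greenhouse
imaging facility.

Three ideas carry the method:

* **Growth-stage and multi-view mixed augmentation.** Same-accession
  image pairs are interpolated pixelwise,
  `I_mix = λ·I_i + (1−λ)·I_j` (λ = 0.5 by default), along three axes:
  consecutive sampling dates at one viewpoint (*temporal*), front ×
  side view at one date (*viewpoint*), and front at date *t* × side at
  date *t+1* (*view-stage*). Labels are never interpolated — both
  parents share one class. On a complete grid of `D` dates and both
  views each accession contributes `4D − 3` mixed images.
* **Adaptive cross-entropy.** The loss
  `L = L_CE + (α/N) Σ_i wrong_i · ce_i` adds an α-weighted second copy
  of every currently misclassified sample's cross-entropy, steering
  training toward hard, visually ambiguous examples. `α = 0` recovers
  plain cross-entropy exactly.
* **Stage-aware evaluation.** Accuracy plus macro-averaged
  precision/recall/F1 (`Acc = Σ TP_i / N`,
  `P = (1/C) Σ TP_i/(TP_i+FP_i)`, …), broken down by growth stage, and
  a within/across-group partition of the confusion structure (e.g. by
  rice subspecies).

Around these sit a filename-grammar dataset layer
(`accession_tag_date_viewpoint.png`), stratified train/test splitting,
a CPU-trainable convolutional backbone (`tiny`: conv–batchnorm–ReLU
blocks, SGD lr 0.01 / momentum 0.9 / batch 64, random horizontal flip),
Grad-CAM attention maps (gradient of the class logit w.r.t. the last
convolutional layer's feature maps, channel-averaged and rectified), a
classical baseline (Hu moments, GLCM contrast, uniform LBP histogram,
HSV means → Naive Bayes / decision tree / SVM / KNN), and a
deterministic synthetic plant-image generator that makes the whole
pipeline testable offline.

## Worked example

```r
library(varietyid)

dir <- file.path(tempdir(), "demo")
man <- generate_synthetic_dataset(dir, n_accessions = 4, n_dates = 4,
                                  image_size = c(48, 64), seed = 7)
man <- split_dataset(man, test_fraction = 0.2, seed = 7)
aug <- run_gmma(man, file.path(dir, "mixed"))
print(aug$report)
#> Mixed-augmentation report
#>   original images : 24
#>   temporal mixes  : 16
#>   viewpoint mixes : 8
#>   view-stage mixes: 10
#>   total after augmentation: 58

fit <- variety_cnn(aug$manifest, input_size = c(48, 64), epochs = 10,
                   loss = "ace", alpha = 1, batch_size = 16, seed = 7)
print(fit)
#> Image-based variety classifier (backbone: tiny )
#>   classes: 4, training images: 58, input 48x64
#>   loss: ace (alpha=1), lr 0.01, momentum 0.9, batch 16, epochs 10
#>   final train loss 0.1487, train accuracy 1.000

rep <- evaluate_model(fit, man)
print(rep)
#> Evaluation over 8 images, 4 classes
#>   accuracy        1.0000
#>   macro precision 1.0000
#>   macro recall    1.0000
#>   macro F1        1.0000
rep$per_stage
#>   stage accuracy n_images
#> 1   042        1        3
#> 2   049        1        2
#> 3   063        1        3
```

The augmentation report counts the three pair types actually available
in the (stratified-split) training images; the per-stage table slices
test accuracy by sampling date — on real data this is where early-stage
(pre-heading) performance becomes visible. `gradcam(fit, image)`
returns the attention map for any image, and
`overlay_heatmap(image, map)` renders it blue (low) to red (high).

The 24 synthetic images here are generated in ~1 s; the ten-accession
configuration used by the verification suite trains in a couple of
minutes on one CPU core.

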