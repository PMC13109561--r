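---
title: "Identifying crop varieties from whole-plant images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying crop varieties from whole-plant images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Distinguishing varieties *within* one crop species — accessions of rice,
inbred lines of maize — from RGB photographs is a fine-grained
classification problem: hundreds of classes, subtle morphological
differences, and typically only tens of images per class. Phenotyping
facilities mitigate the data scarcity by imaging every plant repeatedly
over its growth period and from two viewpoints (front and side), which
this package exploits in three ways: a mixed-augmentation scheme that
interpolates images along the growth and viewpoint axes, a loss that
re-weights currently misclassified images, and evaluation tooling that
breaks accuracy down by growth stage.

`varietyid` implements the full pipeline: dataset parsing and splitting,
augmentation, a trainable convolutional backbone, macro-averaged
evaluation, gradient-based attention maps, a handcrafted-feature
baseline, and a synthetic image generator that makes everything testable
offline.

## Dataset model

Images are expected to carry their metadata in the filename,
`accession_tag_date_viewpoint.png`. The stem is split on underscores;
the first field is the accession label, the last the viewpoint
(`front`/`side`, case-insensitive, `f`/`s` accepted), the second-to-last
the sampling date, and everything in between is absorbed into a free
`tag` field, because real plant identifiers often contain underscores
themselves. Date tokens are ordered numerically when every token parses
as a number (days after sowing) and lexicographically otherwise (ISO
dates order correctly either way).

Train/test splitting is stratified per accession by default:
`round(test_fraction * n)` images per accession go to the test split,
capped so every accession keeps at least one training image. With
hundreds of classes and ~20 images per class, a global random split
would regularly orphan whole classes; stratification keeps every class
trainable and testable. A `stratify = FALSE` switch restores the global
draw.

Cropping, when requested, localizes the plant by Otsu-thresholding the
HSV saturation channel — greenhouse backgrounds are grey and
low-saturation while plant tissue is saturated — keeping the largest
connected component's bounding box with a 5 % margin. Resizing is
bilinear with antialiasing.

## Mixed spatiotemporal augmentation

For each accession, three families of same-class image pairs are
interpolated pixelwise with weight $\lambda$ (default 0.5, fixed per
run, left image weighted $\lambda$):

* **temporal** — same viewpoint, consecutive sampling dates;
* **viewpoint** — front and side view on the same date;
* **view-stage** — front view at date $t$ with side view at $t{+}1$.

"Consecutive" means adjacent in the sorted list of dates actually
present for that accession (per viewpoint for temporal mixing), not a
fixed calendar gap — real schedules have missed sessions. Only pairs
matching one of the three constructions are mixed; an all-pairs scheme
would produce quadratically many images and is not what the per-type
bookkeeping of the method implies. The view-stage construction is
directional (front at $t$, side at $t{+}1$); a
`view_stage_symmetric` switch adds the mirrored pairs. When a
(date, viewpoint) slot holds several images, the Cartesian product of
candidates is enumerated.

On a complete grid of $D$ dates and both views, one accession yields
$D$ viewpoint, $2(D-1)$ temporal and $D-1$ view-stage mixes — $4D-3$
in total; the test suite checks this closed form and an independent
brute-force pair enumerator against the implementation. Mixed images
are 8-bit PNGs (rounded and clipped) so they re-enter the same loading
pipeline as raw images; labels are never interpolated because both
parents share one accession.

## Backbone and training

`build_model()` exposes a registry of backbone names. The large
ImageNet architectures are listed for interface completeness but
constructing them requires an external deep-learning runtime and weight
bundle that this package does not ship; requesting one raises an error
that points to `tiny`, the bundled from-scratch backbone. `tiny` is a
compact convolutional network — four 3×3 same-padded convolution blocks
(3→8→16→32→32 channels), each followed by batch normalization and ReLU,
2×2 max pooling after the first three, global average pooling, and a
linear head — implemented with im2col + BLAS matrix products in C++.
Batch normalization is what lets the fixed training protocol (SGD,
learning rate 0.01, momentum 0.9, batch 64) converge in the few dozen
gradient steps that a small training set provides; without it the same
protocol needs many times more epochs. Inputs must be divisible by 8 in
both dimensions so the last convolutional layer retains a spatial map
(input/8 per side) for the attention analysis.

Training uses mini-batch SGD (PyTorch momentum convention
$v \leftarrow \mu v + g$, $w \leftarrow w - \eta v$), a constant
learning rate (the stated protocol; a decay schedule is deliberately
not applied), and random horizontal flipping with probability 0.5 at
load time, applied to raw and mixed images alike. The test split is
never flipped or augmented.

The loss is either plain cross-entropy
$L_{CE} = -\tfrac1N \sum_i \log \hat y_{i,y_i}$ or its adaptive
variant

$$L = L_{CE} + \frac{\alpha}{N} \sum_i [\text{wrong}_i]\,
      \left(-\log \hat y_{i,y_i}\right),$$

which adds an $\alpha$-weighted second copy of each currently
misclassified sample's cross-entropy. The indicator is computed from
the batch's forward pass (argmax, ties to the lowest class index) and
treated as a constant — no gradient flows through it; the per-sample
logit gradient is simply scaled by $1 + \alpha\,[\text{wrong}_i]$.
$\alpha$ defaults to 1, which makes the extra term comparable in
magnitude to the base loss; $\alpha = 0$ reproduces cross-entropy
bit for bit. Probabilities are floored at $10^{-12}$ before logs.

Reproducibility is promised per device: one seed drives
initialization, shuffling and flips, and two runs with the same seed on
the same machine produce identical histories. Batch-norm running
statistics are updated even when the learning rate is zero; the
"zero learning rate changes nothing" contract refers to the trainable
weights.

## Evaluation

Accuracy is $\sum_i TP_i / N$; precision, recall and F1 are computed
per class and macro-averaged with equal class weight. A class with no
true and no predicted samples contributes $P = R = F1 = 0$ to the
macro means: with hundreds of classes and a 20 % test split, empty
classes occur, and dropping them would inflate the averages.

`stage_accuracy()` slices test accuracy by growth-stage label (sampling
dates or stage tokens); the image-count-weighted mean of the per-stage
accuracies equals overall accuracy whenever the stages partition the
test set, which the tests assert as an identity.
`bin_phenological_stage()` maps dates to the four rice phenological
bins (pre-heading, heading→MPA, MPA→pre-harvest, harvest) when the
caller supplies per-accession milestone dates; the package does not
invent milestones. `confusion_partition()` splits errors by whether the
predicted and true classes share a group (e.g. subspecies), the
computation behind within- vs across-group confusion analyses.
`relative_improvement()` is the percentage-change arithmetic used when
comparing models.

## Attention maps

`gradcam()` implements gradient-weighted class activation mapping: the
gradient of the **pre-softmax logit** of the target class is taken with
respect to a convolutional layer's post-ReLU feature maps (default: the
last, `conv4`), spatially averaged into one weight per channel
($\alpha_k = \tfrac1F \sum_{ij} \partial y^v / \partial A^k_{ij}$), and
the weighted channel sum is rectified into a non-negative map, then
upsampled bilinearly to the input size. The raw map is kept in the
returned object; min–max normalization to [0, 1] happens only for
display in `overlay_heatmap()` (blue = low to red = high). At inference
the batch-norm layers use running statistics, so the map is a
deterministic function of the image.

## Handcrafted baseline

`extract_features()` computes the classical descriptor vector: seven Hu
invariant moments of the grayscale image, signed-log10 transformed
($\mathrm{sign}(h)\log_{10}(|h|+\varepsilon)$, since raw invariants
span many orders of magnitude); gray-level co-occurrence contrast on a
32-level quantization, symmetric and normalized, at distances {1, 2, 3}
× orientations {0°, 45°, 90°, 135°} (diagonal offsets are the exact
$(d, d)$ pixel offsets); a uniform local-binary-pattern histogram with
radius 3 and 24 sampling points (26 bins, computed over pixels at least
R from the border, neighbors bilinearly interpolated); and mean H, S, V
(H in [0, 1), S, V in [0, 1]). The implementation was cross-checked
against an independent scientific-imaging library on a deterministic
reference image; those values are frozen in the test suite. The
grayscale weights are the standard luminance coefficients
(0.2125, 0.7154, 0.0721). The seventh Hu invariant's sign depends on
the axis convention; tests compare its magnitude.

Features are z-score normalized with train-only statistics (sample
standard deviation, $n-1$), constant columns mapping to zero, and fed
to four classical classifiers: Gaussian Naive Bayes and an RBF-kernel
SVM (e1071 defaults), a decision tree (rpart with `minsplit = 2`,
`cp = 0.01` — the library default `minsplit = 20` cannot split the
small per-class samples typical of accession datasets), and
k-nearest-neighbours with k = 5. The same train/test partition as the
CNN run is used for comparability.

## The synthetic generator

`generate_synthetic_dataset()` emulates the structure the pipeline
needs, not plant photography: a uniform grey-blue background, one
elliptical "plant" per image whose area grows monotonically with the
date index (semi-axes scale with $0.65 + 0.35\,d/D$, about a 1.7×
area range), a per-accession signature — base hue evenly spaced along a
band chosen away from the background hue, a stripe frequency and phase,
and a brightness offset — and a side view obtained by evaluating the
front-view pattern under a fixed affine coordinate transform. Gaussian
pixel noise (sd 0.02 of full scale) flows from a single seeded
generator, so equal seeds give byte-identical PNGs. `class_signal`
interpolates between fully distinct signatures (1) and identical
appearance (0), which calibrates the separability tests: at signal 1 a
nearest-centroid classifier on mean-HSV features is perfect, at
signal 0 it sits at chance. The hue band and the brightness offset are
chosen so that whole-image color statistics separate classes even for
the smallest (earliest-date) plants; the growth range is kept moderate
for the same reason.

What the generator deliberately does **not** emulate: real plant
morphology, lighting variation, occlusion, background clutter, or the
subtle within-species differences that make the real task hard.
Passing tests therefore demonstrate the correctness of the machinery —
enumeration, mixing algebra, losses, metrics, attention arithmetic —
and the trainability of the backbone, not real-data accuracy levels.

## Problem sizes and numerical choices

The end-to-end checks run the full pipeline at a deliberately small
scale: 10 accessions × 5 dates × 2 views at 96×128 px, an 80/20
stratified split, augmentation of the training split, and 20 epochs of
each loss. At this scale the complete-grid augmentation count is
exactly $10 \times (4 \cdot 5 - 3) = 170$ mixed images, training
reaches ≥ 95 % train and ≥ 90 % test accuracy with both losses, and
attention maps rank foreground above background on at least 80 % of
held-out images.

Other fixed numerical choices: mixed pixels are rounded half-up and
clipped to [0, 255]; max-pool ties route gradients to the first
(column-major) slot; argmax ties resolve to the lowest class index;
batch-norm uses $\varepsilon = 10^{-5}$ and running-average momentum
0.1; probability flooring uses $10^{-12}$; bilinear upsampling for
heatmaps without antialiasing. Degenerate inputs are defined rather
than left to chance: empty augmentation groups yield empty job lists,
an all-background image skips the crop with a warning, a single-image
accession stays in the training split, and 0/0 per-class metrics are 0.

## Known limitations

* Only the `tiny` backbone is trainable; the ImageNet architectures in
  the registry are interface placeholders that explain themselves when
  requested. Transfer learning from published weights is consequently
  out of reach offline, and headline real-data accuracies are not
  reproducible here.
* Raster I/O covers PNG (and TIFF reading); JPEG inputs must be
  converted first.
* Training is single-device CPU; reproducibility across different
  BLAS/hardware is not promised.
* The rice phenological binning requires user-supplied milestone dates;
  without them only per-date accuracy is reported.
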