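---
title: "Methods: patch-based classification of H&E breast histology images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based classification of H&E breast histology images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-resolution breast histology microscopy images (the reference geometry
is 1536 x 2048 RGB) carry one label each: normal tissue, benign lesion,
in situ carcinoma (malignancy confined to the mammary ductal-lobular
system) or invasive carcinoma. Whole images are too large to classify
directly at desk scale, so the pipeline classifies overlapping patches and
then aggregates patch decisions into an image decision. The difficulty this
creates is twofold: patches inherit their parent image's label even when
they show healthy tissue inside a cancerous image (label noise), and the
patch-to-image step must be learned rather than hard-coded.

## Pipeline overview

`fit_pipeline()` runs the stages below and returns a fitted object with
`print`, `summary` and `predict` methods.

1. **Splitting.** Stratified 65/15/20 train/validation/test by class,
   largest-remainder rounding per class, deterministic given the seed.
   Before the image-level stage the validation images are merged into
   training, so the aggregator trains on 80% of the images while the test
   set stays untouched.
2. **Patching.** 512 x 512 windows at stride 256 (50% overlap), row-major;
   a 1536 x 2048 image yields exactly 5 x 7 = 35 patches. Margins that do
   not fit a full window are dropped rather than padded: padding would
   fabricate tissue. Every patch inherits the image label.
3. **Stain normalization** (Macenko). Pixels map to optical density
   OD = -log10(I / I0); stain contributions add linearly there
   (Beer-Lambert). Tissue pixels (all OD channels above beta = 0.15) are
   projected onto the top-2 principal plane of their OD cloud; the
   hematoxylin and eosin vectors are the directions at the 1st/99th
   percentile angles, sign-fixed nonnegative and unit-normalized; the
   blue-dominant column (larger blue-to-red OD ratio) is hematoxylin.
   Concentrations are solved by exact two-column nonnegative least squares
   (closed form; a clipped plain-least-squares fast path is configurable)
   and rescaled to the template's 99th-percentile concentrations. The
   template is the first patch of the first training image unless
   overridden.
4. **Augmentation.** Training patches only: Bernoulli horizontal and
   vertical flips (p = 0.5 each), rotation uniform in +-15 degrees,
   translation uniform in +-10% of each dimension, bilinear interpolation,
   reflected borders. Defaults are conventional mild histology
   augmentation; the paper-style stack gives no magnitudes. The pipeline
   applies augmentation as an offline expansion (one copy per training
   patch by default) because the per-patch preprocessing is cached once;
   per-epoch on-the-fly regeneration would dominate runtime at this scale.
5. **Feature extraction.** A backbone maps each patch to a spatial feature
   map; the fine-tuning head on top is conv(512 kernels, 3 x 3, stride 1,
   no padding) -> maxpool(2 x 2, stride 2) -> global average pooling ->
   batchnorm -> dropout(0.4) -> dense(64, sigmoid, He-uniform, L2) ->
   dense(4) -> softmax. Patch features are read at the GAP output, so they
   are 512-dimensional regardless of the backbone; with several backbones
   the per-backbone features are concatenated.
6. **Patch ensemble.** Five classical classifiers (k-nearest neighbours
   with k = 5, probability-calibrated RBF support-vector machine, random
   forest and SAMME adaptive boosting with 200 trees each, gradient-boosted
   trees) fit on standardized features; their probability vectors are fused
   by the average rule by default (product and maximum are available) and
   renormalized through a softmax.
7. **Aggregation.** Per image, a frequency array counts argmax patch
   predictions per class in the order [normal, benign, insitu, invasive];
   a 2-bin variant [cancerous = insitu + invasive, noncancerous = normal +
   benign] feeds a tiny network (softmax -> one L2-regularized affine unit
   -> sigmoid) trained with binary cross-entropy that outputs the cancer
   probability p. The 4-bin counts are then weighted as
   [n(1-p), b(1-p), i*p, v*p], softmax-normalized, and passed through the
   final network (dense(4, sigmoid) -> dense(4, softmax)). The binary call
   is cancerous iff p > 0.5; the class call is the argmax.
8. **Metrics.** Confusion matrices plus one-vs-rest accuracy, precision,
   recall and F1 per class; per-class accuracy includes true negatives,
   which is why it differs from recall. 0/0 ratios report 0 with a warning.

## Training the neural components

No deep-learning runtime is involved: the head, the tiny backbone and the
two aggregation networks are implemented directly in R (im2col
convolutions, max-pool routing, batchnorm, hand-written backprop) with an
Adam optimizer (beta1 = 0.8, beta2 = 0.99). Training is full-batch; the
learning rate starts at 0.008 and decays as lr <- lr / (1 + decay) after
each epoch with decay = lr0 / max_epochs. Because training is full-batch,
the batch-normalization statistics used at inference are the dataset
statistics of the final (best) epoch rather than a momentum-smoothed
running average, which at these short schedules never leaves its
initialization.

Early stopping waits for `early_stop_patience = 5` consecutive epochs
without improvement and restores the best weights. It monitors validation
cross-entropy by default rather than validation accuracy: with desk-scale
validation sets (a dozen patches) accuracy moves in steps of 1/n and
plateaus spuriously, which made premature stops restore underfit weights;
the continuous loss avoids that. The monitor is configurable
(`early_stop_metric = "accuracy"`).

The bundled tiny backbone trains fully together with the head: two 3 x 3
conv + ReLU + 2 x 2 maxpool blocks over an 8x block-mean downsample, plus a
fixed average-pooling branch that appends the raw RGB channels
block-averaged onto the output grid. The pooling branch feeds local stain
density to the head directly; the conv branch learns texture. A frozen
variant of this backbone was tried first and rejected: random-projection
GAP features separated the training patches but did not generalize across
images on some data draws. Adapters for pretrained networks (VGG-16,
VGG-19, Inception-ResNet v2) plug in through the same `backbone()`
interface with `trainable_depth` metadata (4 terminal layers by
convention); the package ships no pretrained weights.

The two image-stage networks use the same optimizer with
`max_epochs = 400` by default: their inputs are softmax-normalized count
arrays that are nearly one-hot, so gradients are small and the tiny models
(fewer than 50 parameters) need a longer schedule at the same lr0 —
negligible cost at their size.

## The synthetic fixture generator

Fixtures emulate H&E microscopy through a two-stain Beer-Lambert mixture:
`pixels = I0 * 10^(-M C) + noise`, with a known unit-column 3 x 2 stain
matrix M and two nonnegative concentration fields. The hematoxylin field is
a sum of Gaussian nuclei blobs (radius 5-9 px, peak concentration 1.8-3.0)
whose expected count per 512 x 512 tile is 12 / 48 / 110 / 200 for
normal / benign / in situ / invasive — strictly ordered, so the classes are
separable by construction. The eosin field is a smooth low-frequency
texture rescaled to a constant spatial mean per image: without that
constraint the random eosin mass varied between images by more than the
normal-vs-benign nuclei gap and broke the separability the generator is
supposed to guarantee. The texture keeps near-zero regions and the blobs
reach high peak concentration so that near-pure pixels of both stains
exist, which is what makes Macenko stain-vector recovery checkable against
the generative truth (noiseless recovery is within 5 degrees per column).
The truth stain matrix is chosen consistent with the package's
hematoxylin/eosin assignment convention (hematoxylin is the blue-dominant
OD column). An optional heterogeneous mode confines cancerous-class blobs
to a sub-region so some patches of a cancerous image look normal,
reproducing the label-noise regime of real tissue.

What the fixtures do **not** emulate: real nuclear morphology and
chromatin texture, architectural patterns (ducts, lobules, stroma),
scanner noise, stain variation between labs, or any relationship between
blob density and actual malignancy. Passing the fixture benchmark shows
the pipeline's machinery is sound end-to-end — it says nothing about
accuracy on real histopathology, which requires the external 400-image
microscopy dataset and pretrained backbones.

## Numerical choices and degenerate inputs

- Argmax ties break to the lowest class index everywhere.
- Softmax is computed with max-shift stabilization; cross-entropy guards
  `log` with 1e-12.
- Stain estimation errors on fewer than two tissue pixels and on rank-1 OD
  clouds (single stain); the pipeline's default is to pass such patches
  through unnormalized (`on_degenerate = "passthrough"`), the module-level
  function errors by default.
- The pipeline normalizes whole images before patching by default
  (`stain$mode = "image"`). Per-patch normalization is available but was
  measured to be harmful at this scale: the 99th-percentile concentration
  of a single 512 x 512 patch with sparse nuclei is a noisy, density-
  dependent statistic, and dividing by it collapsed a class margin that was
  cleanly present in the raw pixels.
- The 2-class network's softmax input layer makes it scale-invariant in the
  counts: every balanced array (k, k) receives the same probability. This
  representational quirk is inherited from the architecture and is covered
  by a test.
- Fractional split sizes use largest-remainder rounding per class; ties go
  to train, then validation, then test.

## Benchmark problem sizes

The test suite and the acceptance script exercise the full pipeline on a
fixture set of 6 images per class at the fast 512 x 1024 profile (3 patches
per image), a scaled-down stand-in for the reference 400-image study. At
that size a full `fit_pipeline()` run takes on the order of a minute on one
CPU; the suite runs it twice to check bit-level reproducibility of the
predictions under a fixed seed.

## Known limitations

- Classical-classifier hyperparameters (k, tree counts, kernel) are fixed
  defaults, not tuned per dataset.
- The frequency-array aggregator assumes a constant patch count per image
  within a run; mixed image sizes in one collection work only through the
  grouping-by-parent path, and count normalization to fractions is off by
  default.
- Training the tiny backbone is full-batch and single-threaded; it is meant
  for desk-scale data, not for the full-scale study, where pretrained
  backbones would be fine-tuned instead.
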