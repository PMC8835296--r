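---
title: "Automated volumetric quantification of pleural plaques"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated volumetric quantification of pleural plaques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquevol)
```

## The measurement problem

Pleural plaques (PP) — circumscribed hyaline-fibrosis thickenings of the
parietal pleura — are the most frequent CT manifestation of past asbestos
exposure. They attenuate like soft tissue (tens of HU), sometimes calcify
(hundreds of HU), and hug the inner chest wall where ribs (higher HU still)
are often in contact with them. Visual scores and manual delineation are the
traditional quantification routes; both are slow and only moderately
reproducible. `plaquevol` implements a fully automated volumetric
alternative: a 2D convolutional network segments plaques slice by slice, a
Hounsfield threshold isolates the calcified subset, and mask voxels are
integrated into millilitre volumes that can be compared across screening
rounds.

## Pipeline

1. **Thin MIP preprocessing** (`compute_mip`). The native volume (1–1.25 mm
   axial slices) is collapsed into consecutive non-overlapping 5-mm slabs,
   each pixel the maximum over its constituent slices; ~300 slices become
   ~60 slabs. The maximum preserves the relatively bright plaques against
   lung and fat, and 5 mm is thin enough that plaques and ribs rarely
   overlap within one slab. Slabs partition the slice range; a trailing
   partial slab keeps its true thickness so the scanned z-extent — and hence
   volumetrics — is conserved. A sliding-window scheme would not reduce the
   image count and is deliberately not offered.
2. **Segmentation** (`train_unet` / `predict_unet`). A U-Net with two 3×3
   convolutions per block, channel width doubling from 24 per level
   (24, 48, 96, …), 2×2 max-pooling, bilinear upsampling with concatenation
   skips, dropout 0.5 after each descending-path block, a single input
   channel and a sigmoid output. Training minimizes
   $L = L_\mathrm{BCE} + L_\mathrm{DL}$ with
   $L_\mathrm{DL} = 1 - \frac{2\sum y\hat y + 1}{\sum y + \sum \hat y + 1}$,
   Adam at learning rate 0.001, batch size 1, and random horizontal/vertical
   flips applied identically to image and mask. The Dice term handles the
   extreme class imbalance (plaques are a tiny pixel fraction), the BCE term
   keeps per-pixel probabilities calibrated.
3. **Quantification** (`binarize`, `split_calcified`, `quantify_exam`).
   Probabilities are thresholded at 0.5 (inclusive), calcified plaque is the
   mask subset at ≥ 100 HU (inclusive), and volumes are pixel counts times
   pixel area times slab (or slice) thickness. On the MIP path the slab
   image itself serves as the HU reference for calcification: the maximum
   projection preserves maxima, so a calcified pixel keeps ≥ 100 HU after
   projection. Both thresholds' inclusivity is a package convention, stated
   here because convention is all it is.
4. **Evaluation** (`pixel_similarity`, `lin_ccc`, `bland_altman`,
   `correlate_scores`, `paired_wilcoxon`, `longitudinal_compare`). 2D
   similarity is micro-averaged: confusion counts are pooled over all slices
   before computing Dice, balanced accuracy, precision and recall. Pooling
   is the only convention that accommodates plaque-free slices (per-slice
   Dice is undefined on empty/empty slices); it weights every pixel equally.
   3D agreement per exam uses Lin's concordance correlation coefficient with
   population moments and a Fisher-z confidence interval, plus Bland–Altman
   mean difference and limits of agreement (±1.96 sample SD). Longitudinal
   change is summarized by median paired difference and median percent
   increase with seeded bootstrap percentile CIs (2000 resamples) and a
   two-sided Wilcoxon signed-rank test; participants with a zero baseline
   volume are excluded from percent increases (logged) but kept in absolute
   differences. Spearman correlation (average ranks on ties) links volumes
   to the ordinal visual extent score, the product of thickness, extent and
   count categories (range 1–48).

## The synthetic thorax phantom

Clinical cohorts of asbestos-exposed workers are not redistributable, so the
package ships a parametric phantom (`phantom_spec`, `generate_exam`) that
reproduces exactly the image properties the method exploits: an elliptical
soft-tissue body (+40 HU), two air-like lungs (−800 HU), short rib arcs
(+700 HU) along the chest wall, and crescent-shaped plaques on the lung rim
at +60 HU (soft) or +400 HU (calcified), with additive Gaussian noise
(SD 10 HU). Only the soft/calcified split across the 100-HU threshold is
method-constrained; the remaining HU values are plausible tissue defaults.
Noise is truncated at ±3 SD so the tissue-class separation is exact by
construction, which is what makes the generator's masks usable as exact
ground truth. Ground-truth volumes are obtained by counting rasterized mask
voxels — the generator has no separate analytic bookkeeping that could
drift from the rasterization.

`sample_phantom_spec` draws desk-scale exams (64 × 64 pixels at ~5.5 mm,
40 slices of 1 mm) with 2–4 plaques of 9–20 mm thickness, 40–110° arc and
50 % calcification probability. Plaque axial extents are aligned to 5-slice
multiples by default: with 1-mm slices and 5-mm slabs, slab-geometry volumes
of aligned ground truth equal native volumes exactly, so MIP-path volume
errors isolate network error instead of mixing in slab-discretization
effects. `generate_longitudinal_pair` grows each plaque's thickness and arc
by $\sqrt{g}$ so the rasterized volume ratio tracks a chosen growth factor
$g$ while shapes stay plausible.

What the phantom deliberately does not emulate: beam hardening and streak
artifacts, respiratory/cardiac motion, anatomical variability of the thorax
outline (the ellipse geometry is fixed; only plaques vary), diaphragmatic
and mediastinal plaque locations, scanner-model heterogeneity, and plaques
thinner than one pixel. Passing the synthetic recovery tests therefore
demonstrates that the implementation learns and measures correctly on data
with the right contrast structure — not that the shipped desk-scale weights
transfer to clinical scans, which require training at full resolution on
real delineations.

## Numerical and design choices

- **HU normalization.** Inputs are windowed to [−200, 800] HU and scaled to
  [0, 1]. The window is fixed — never fitted per exam — so the 100-HU
  calcification semantics are identical across exams. Its width matters: the
  discriminating soft-plaque vs chest-wall contrast is only ~20 HU, and a
  full-range [−1000, 1000] window compresses it to 1 % of the input scale,
  which measurably destabilizes desk-scale training (held-out volume biases
  swinging ±20 % across training seeds); the adopted soft-tissue-weighted
  window keeps that contrast at 2 % while still separating calcified plaque
  (~400 HU) from rib (~700 HU) below its upper clip.
- **Dropout placement.** "Dropout after each descending-path block" is
  implemented as: the encoder block output feeds the lateral skip
  connection, and dropout applies to the copy that continues down the
  descending path (and to the bottleneck output entering the decoder).
  Dropping the skip copies as well was evaluated and rejected — at 8 base
  filters the skips lose half their boundary information, visibly degrading
  convergence.
- **Upsampling.** The decoder uses bilinear interpolation (half-pixel
  centres), the 2D restriction of trilinear interpolation; a 2D network has
  no third axis to interpolate.
- **Dropout** is inverted elementwise dropout, active only during training;
  inference is fully deterministic, which is why repeated runs reproduce to
  Dice 1.
- **Loss clipping.** Cross-entropy probabilities are clipped to
  [1e−7, 1 − 1e−7]; the Dice term uses the smoothing constant 1 in numerator
  and denominator, making the empty/empty case exact zero loss.
- **Gradients** are computed by hand-derived backpropagation through the
  gemm-based convolution, pooling and upsampling kernels; the test suite
  verifies every layer against central finite differences (biases nudged off
  zero first — with zero biases, pixels whose entire receptive field is
  ReLU-inactive sit exactly on the kink where one-sided finite differences
  disagree with the subgradient).
- **Seeding.** One seed drives initialization, sample order, flips and
  dropout; identical data and config reproduce identical weights bit for
  bit. The CLI derives fixed per-stage child seeds from a single run seed.
- **Ties and degeneracies.** Max-pooling resolves ties to the first element
  in scan order; `split_exams` floors/caps so both split sides are
  non-empty; CCC raises an error when both series are constant with equal
  means (the coefficient is undefined); an all-zero-difference Wilcoxon
  comparison reports p = 1 with a warning rather than failing.
- **Slice indexing** is 1-based everywhere, matching R convention, with
  axial slices as the third array dimension.
- **CCC confidence intervals** use the Fisher z-transform with Lin's
  asymptotic standard error; bootstrap percentile CIs are used for medians
  (the Hodges–Lehmann estimator was considered and set aside to keep one CI
  method throughout).

## Desk-scale protocol and problem sizes

Training the full-scale configuration (512 × 512, 24 base filters,
200 epochs) is a GPU-days task. The package's reference experiments instead
use the desk-scale preset (`desk_scale_config`): 64 × 64 inputs, 8 base
filters, depth 5, 25 epochs. The bundled acceptance experiment trains on
600 MIP slabs from 75 synthetic exams, evaluates on 12 held-out exams
(96 slabs), and reuses the trained network for a 20-participant longitudinal
cohort generated with growth factor 1.7 (mirroring a ~70 % median volume
increase between screening rounds). These sizes were chosen as the smallest
at which the network reliably exceeds the clinical-scale similarity
figures (pooled Dice 0.63 overall, 0.82 calcified) on the easier synthetic
task while a full run stays in the minutes range on one
CPU core.

Per-exam volume concordance is the tightest of the recovery checks: the
decisive soft-plaque boundaries are only ~20 HU above the chest wall, and
one 64 × 64 slab pixel already corresponds to ~0.15 mL, so a ±1-pixel
run-dependent calibration of the crescent arc ends moves exam volumes by
several percent. The pooled Dice margins above those floors are
wide and insensitive to the training seed; the volume CCC is the quantity
that varies most between independent training runs, because it inherits
that arc-end calibration directly. Smaller training sets or a full-range
[−1000, 1000] HU window make this visibly worse, which is what motivated
both protocol choices. At clinical resolution the same rim uncertainty is
an order of magnitude smaller in relative volume.

## Worked example

```{r example, eval = FALSE}
library(plaquevol)

# three synthetic participants, two screening rounds each
cohort <- lapply(1:3, function(p) {
  spec <- sample_phantom_spec(seed = 100 + p)
  generate_longitudinal_pair(spec, growth_factor = 1.7,
                             participant_id = sprintf("p%02d", p))
})

# train a small network on MIP slabs of the round-2 exams
slabs <- lapply(cohort, function(pair) {
  st <- compute_mip(pair$round2$volume, 5)
  list(images = st$slabs, masks = mask_to_mip(pair$round2$pp_mask, st))
})
images <- do.call(c, lapply(slabs, function(s)
  lapply(seq_len(dim(s$images)[3]), function(i) s$images[, , i])))
masks <- do.call(c, lapply(slabs, function(s)
  lapply(seq_len(dim(s$masks)[3]), function(i) s$masks[, , i])))
model <- train_unet(images, masks, desk_scale_config(epochs = 10L))

# quantify both rounds and summarize progression
quants <- do.call(rbind, lapply(cohort, function(pair) rbind(
  quantify_exam(pair$round2$volume, model),
  quantify_exam(pair$round3$volume, model))))
longitudinal_compare(quants)
```

## Known limitations

- The shipped training loop is CPU-bound R/C++; it is meant for the
  desk-scale preset and for methodological validation, not for training at
  512 × 512 on thousands of slices.
- Plaque detection/classification and per-plaque instance measurements are
  out of scope; the package quantifies total and calcified plaque burden.
- The phantom's fixed thorax geometry means a network trained on it learns
  that geometry; synthetic performance figures are upper bounds, to be read
  as implementation validation (see the phantom section above).
- Multi-network voting, multiplanar consensus and 3D architectures are not
  implemented.
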