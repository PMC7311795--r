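---
title: "Caliper-marker shortcuts in ultrasound nodule detection: models, phantoms and suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Caliper-marker shortcuts in ultrasound nodule detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sonomark)
```

## The problem

Clinical ultrasound workstations burn measurement calipers — bright plus- or
cross-shaped glyphs — directly into the stored frame, usually at the points
where a nodule's contour touches the sides of its tight enclosing rectangle,
in groups of two (left/right) or four (one per side). Historical archives of
thyroid ultrasound are therefore *marker-layered*: every annotated nodule
carries glyphs that are spatially locked to the lesion. A detector or
classifier trained on such archives can satisfy the training objective by
recognizing the calipers instead of the tissue. On prospective, marker-free
images the learned shortcut is absent and performance collapses. `sonomark`
provides an end-to-end, seed-reproducible desk-scale pipeline to generate
this situation synthetically, to measure it, and to test the two families of
remedies: removing markers (inpainting) and making the representation
shortcut-resistant (a variational information bottleneck).

## The speckle phantom and what it does (not) emulate

No public marker-layered thyroid dataset exists, so every experiment runs on
a synthetic phantom:

* **Background**: a smooth low-frequency echogenicity field (bilinear
  interpolation of a coarse uniform grid, mean 0.5, amplitude 0.12,
  correlation length 16 px) multiplied by unit-mean gamma noise — the
  standard fully-developed-speckle approximation. The noise field is
  Gaussian-smoothed with a *grain* of 1.2 px, emulating the finite
  resolution cell that makes real speckle spatially correlated. Grain
  matters twice: template matching and exemplar-based inpainting both rely
  on local texture being structured rather than pixelwise independent.
  The gamma shape default is 3 (noise variance 1/3 before smoothing).
* **Nodules**: rotated ellipses (major semi-axis 8–16 px, aspect ratio
  0.55–0.95), hypoechoic with multiplicative contrast 0.25–0.4 and a 2 px
  feathered edge, placed with pairwise bbox IoU exactly 0 (one box per
  nodule, as in clinical annotation).
* **Confounders**: elongated dark bands (vessels/fascia/shadowing analogs)
  and rounded soft-edged hypoechoic blobs (cyst/vessel cross-sections).
  These are essential, not decorative: without look-alike structures,
  "dark blob" is a perfectly sufficient detection cue and *no* model would
  ever need the marker shortcut — the phenomenon under study would be
  absent from the benchmark by construction. With them, tissue
  discrimination is a genuine shape/texture task that a small network can
  learn but only with effort, while the burned-in calipers remain a
  trivially salient high-amplitude feature. This "hard tissue, easy
  marker" asymmetry is the regime in which shortcut learning occurs in
  clinical practice.

The phantom does **not** emulate: acoustic point-spread-function physics,
depth-dependent attenuation or gain, anatomic layout, vendor UI chrome,
measurement lines between calipers, or inter-observer annotation
variability. Passing the phenomenon tests therefore demonstrates the
*mechanism* — marker/label entanglement and its suppression — not clinical
performance on real data.

## The marker model

Glyphs default to plus-shaped calipers (arm 4 px, thickness 1 px, intensity
1.0; burned by replacement, so the original pixels are irrecoverable — as in
real devices). Real annotations place glyphs at the geometric tangency
points of the nodule contour with its rectangle, computed from the ellipse;
pseudo groups (the decoupling tool) use a seeded-random position along each
edge of a rectangle whose width/height never exceed those of the largest
nodule box and whose IoU with every real nodule box is exactly 0. Marker
*mixup* keeps exactly 1 of a 2-group (uniformly 1–3 of a 4-group), erases
removed glyphs by texture inpainting, and burns the same number of
replacement glyphs at random positions whose footprints have IoU 0 with all
nodule boxes.

## Inpainting

The removal stage is classical exemplar-based texture synthesis: masked
pixels are filled boundary-inward, each copied from the centre of the
best-matching (SSD over a 9×9 window, known pixels only) fully-known patch
of the same image; candidates within 10% of the minimal SSD are tie-broken
by a seeded uniform draw. The seed affects only ties. A generative
adversarial inpainter with contextual attention is the scaled-up analog of
this stage; at 128×128 desk scale, self-similar speckle makes the
learning-free method both adequate and exactly reproducible. An optional
learned *coarse* backend — a small fully-connected network predicting a
masked pixel from its masked 9×9 neighbourhood plus mask channel, trained
with L1 reconstruction loss only and applied onion-peel — covers the
"reconstruction-loss-only coarse network" stage of the scaled-up design.
Masks come either from the annotation oracle (the removal-by-hand analog)
or from normalized cross-correlation template matching against the glyph
bank (threshold 0.6, strict 3×3 local maxima, footprint stamped and dilated
by 1 px). Mask dilation of 1 px before inpainting covers soft glyph edges.

## The VIB classifier and its baseline

The crop classifier encodes a `crop_size × crop_size` crop (default 32,
bilinear-resampled from the box plus a 25% context margin) into a diagonal
Gaussian posterior: the encoder outputs a 2K vector, the first K entries
are the mean, the last K pass through a softplus to give the scale. The
default encoder is a small convolutional network (two valid-padding
conv + mean-pool blocks, 8 and 16 filters, kernels 5 and 3, then a linear
map to 2K); a one-hidden-layer MLP encoder is available and is what the
sliding-window detector uses for speed. Training minimizes

  E[-log q(y|z)] + beta * KL(p(z|x) || N(0, I)),

with `z = mu + sigma * eps` (reparameterization trick, one Monte-Carlo
sample per step), a linear decoder to two logits and softmax likelihood.
The matched baseline is identical except that it decodes `z = mu`
deterministically with plain cross-entropy — no sampling, no KL — so any
robustness difference is attributable to the bottleneck. Defaults K = 32,
beta = 1e-3 (the common practice for this objective; the source design
reports neither), Adam at 1e-3, batch 32, 40 epochs. Evaluation decodes at
the posterior mean by default; Monte-Carlo sample-averaged decoding is
available.

All gradients are hand-derived and verified against finite differences in
the test suite; training is exactly reproducible from `(data, config,
seed)` in a single-threaded session.

## The detector

A deliberately simple stand-in for a region-proposal detector: square
sliding windows at 24 and 40 px with stride 6, each resized crop scored by
the patch classifier, thresholded at 0.5, then greedy NMS at IoU 0.3 with
deterministic tie-breaks (score, then x0, then y0). Training harvests the
ground-truth boxes (plus two mildly jittered copies per box, IoU ≥ 0.65,
so the scorer tolerates the imperfect framings the sliding grid produces)
and three background windows per image with IoU exactly 0 against every
ground-truth box. The jitter amplitude is a sensitive design point: with
aggressive jitter the marker positions inside positive crops become too
variable to exploit and the shortcut dissolves; with none, the scorer is
brittle on grid-aligned test windows. The default (±8% shift, 0.92–1.1
scale) keeps caliper layouts learnable while remaining usable as a
detector.

## Evaluation

Matching is greedy, score-ordered and one-to-one per image at a given IoU
threshold; precision, recall and F follow the standard ratios, and AP uses
all-point interpolation — the exact integral over recall of the maximum
precision at or beyond each recall level, which is what the defining
integral of interpolated average precision evaluates to for a finite
detection list. With a single "nodule" class, mAP equals AP. The
condition-grid report evaluates at IoU 0.3 and 0.4. Recall and F-score are
reported at the F-optimal score threshold (the operating point is not fixed
by the source design; a fixed-0.5 column is also emitted).

## The condition grid and study design

From one phantom dataset: A0 burns calipers at every training nodule;
A1 inpaints them under the oracle mask (careful manual removal analog);
A2 inpaints under the automatically located mask; A3 applies marker mixup;
B1/B2 are the marker-layered/marker-free test variants of the same test
images. All conditions share ground truth. The detection study trains one
detector per condition per seed (3 seeds by default) and evaluates on both
test variants; the classification study builds, per seed, a crop benchmark
of marker-layered positive crops and pseudo-marker-added negative crops
(the near-balanced clinical ratio, scaled to 200 + 200 training and
200 + 200 test crops by default), trains the baseline and the VIB model on
identical data, and evaluates the six test cases. The study's VIB uses
beta = 0.05 rather than the module default 1e-3: at these problem sizes
the smaller value produces no measurable compression, and a one-decade
probe (1e-3, 1e-2, 5e-2) showed 5e-2 is where bottleneck behaviour
becomes clearly visible. The cases cross negatives
pseudo-marked/as-is × positives marker-layered/marker-free × two models.
Negative crops are drawn as the darkest of eight admissible pseudo-rects,
emulating the hypoechoic look-alike regions a proposal stage would emit.
Ordering claims (the A0 generalization gap, its suppression under A2, the
baseline-versus-VIB stability comparison) are decided by one-sided sign
tests across seeds at alpha = 0.05; single-seed comparisons are logged but
not asserted.

Module default sizes are 200 train / 100 test phantoms at 128×128 for
detection and 200 + 200 crops for classification, with 3 and 5 study
seeds; a full default-size detection grid takes tens of minutes on one
CPU (about 35 of which are the twelve detector trainings and their
sliding-window evaluations). The acceptance entry points — the end-to-end
test block and `scripts/acceptance.R` — therefore run the detection study
on a reduced 80 train / 25 test grid, sized so the whole suite fits a
CPU test budget; the classification study runs at its full default size.
Per-seed metrics are noisier at the smaller scale.

## Numerical and degenerate-case policy

* All images live in `[0, 1]`; every compositing step clips.
* Boxes are half-open `(x0, y0, x1, y1)` with x = column, y = row, 0-based;
  degenerate boxes are contract errors, not silent zeros.
* Rejection samplers (nodule placement, pseudo rects, scatter markers)
  carry explicit attempt caps and fail with the item index rather than
  looping forever.
* Empty masks are identities; all-ones masks are context errors.
* `P`/`R`/`F` with no detections *and* no ground truth return `NA` with a
  warning; F is defined 0 when `P + R = 0`.
* PSNR of a perfect reconstruction is reported as a capped 99 dB sentinel.
* Every seeded operation restores the caller's RNG state; study runners
  derive child seeds so that adding a stage never shifts another stage's
  stream.

## Known limitations

The phantom's shortcut strength depends on the salience balance described
above; real archives differ in marker size, density and vendor style, and
the quantitative gaps measured here do not transfer. The texture-synthesis
inpainter assumes self-similar background within one image and would
degrade on images dominated by unique structure. The detector has no box
regression, so localization is quantized by the window grid; mAP at strict
IoU thresholds (≥ 0.5) is limited by that quantization, which is why the
report uses the 0.3/0.4 operating points. The coarse reconstruction model
is a pixelwise predictor, not a full encoder–decoder; it exists to make the
"learned reconstruction-only" stage testable at this scale.

Two phenomenon-level orderings are borderline rather than robust. The
marker-trained generalization gap is positive in every seed at both
scales, but its seed-mean magnitude fluctuates on small test sets (one
seed's gap shrinks from ~20 to ~6 points on a 25-image test set). And
marker-mixup training does not reliably sit *strictly between*
marker-layered and inpainted training on marker-free data: at both
scales its marker-free mAP matches or slightly exceeds the inpainted
conditions, i.e. mixup can close the gap entirely rather than only part
way. Both are reported as measured.
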