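# sonomark

Burned-in caliper markers — the bright plus-shaped glyphs clinicians place
at a nodule's boundary during an ultrasound exam — are stored as part of
the image in most clinical archives. Because the glyphs are spatially
locked to the lesions, a detector or classifier trained on such historical
images can learn the *markers* instead of the tissue, and then collapse on
prospective, marker-free images. `sonomark` is an R package for studying
and suppressing this annotation-shortcut effect at desk scale: it
generates seed-reproducible speckle phantoms with ground-truth nodules,
models the clinical caliper annotation (tangency placement, pseudo-marker
groups, random marker mixup), removes markers by exemplar-based
texture-synthesis inpainting with an automatic glyph localizer, trains a
variational-information-bottleneck (VIB) crop classifier next to a matched
cross-entropy baseline, runs a sliding-window nodule detector, and scores
everything with interpolated average precision at configurable IoU
thresholds.

It is aimed at researchers studying shortcut learning / annotation leakage
in medical imaging who need a fully controlled, reproducible benchmark
rather than private clinical data.

## The core quantities

* **Detection**: precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)`,
  `F = 2PR/(P+R)`, and average precision
  `AP = ∫₀¹ P(R₀) dR₀` with `P(R₀) = max{P : R ≥ R₀}` (all-point
  interpolated AP; mAP is the mean over classes, here the single class
  "nodule"). Matching is greedy, score-ordered and one-to-one at IoU 0.3
  or 0.4.
* **VIB classifier**: the encoder maps a crop to a diagonal Gaussian
  `p(z|x) = N(mu(x), diag(sigma(x)^2))` (a 2K-vector split into mean and
  softplus-scale); training minimizes the variational bound
  `E[-log q(y|z)] + beta * KL(p(z|x) || N(0,I))` via the
  reparameterization trick, with a softmax decoder. The matched baseline
  decodes `z = mu` with plain cross-entropy — the only difference is the
  bottleneck.
* **Condition grid**: from one phantom dataset, marker-layered training
  images (A0), oracle-mask inpainted (A1), automatically located and
  inpainted (A2), and marker-mixup (A3) training variants, evaluated on
  marker-layered (B1) and marker-free (B2) versions of the same test
  images.

## A worked example

```r
library(sonomark)

# a marker-layered phantom and its restoration
ds  <- render_dataset(phantom_config(n_train = 1, n_test = 0), seed = 7)
it  <- ds$items[[1]]
ann <- annotate_image(it$image, it$nodules, seed = 3)   # burn calipers
mask <- locate_markers(ann$image)                        # find them again
res  <- inpaint_texture(ann$image, mask, seed = 5)       # remove them
inpaint_quality(it$image, res$image, mask)

post <- encode(train_classifier(
  x = matrix(runif(40 * 1024), 40), y = rep(0:1, 20),
  classifier_config(use_vib = TRUE, epochs = 2), seed = 1),
  matrix(0.5, 32, 32))
kl_to_standard_normal(post)
```

On this seed the localizer covers the burned glyph footprint exactly
(Dice 1 against the annotation mask) and the quality report prints

```
$masked_mse
[1] 0.004969805

$masked_psnr
[1] 23.03661
```

masked MSE/PSNR are computed only over the restored pixels against the
pre-annotation original; the same fixture gives a mean-fill baseline of
16.9 dB, so texture synthesis recovers about 6 dB.

The phenomenon itself is a two-liner (about ten minutes of compute at
this reduced 80 + 25 phantom scale; the module defaults of 200 + 100
take tens of minutes):

```r
grid <- build_condition_grid(
  render_dataset(phantom_config(n_train = 80, n_test = 25), seed = 42),
  seed = 43)
rep  <- run_detection_study(grid, detector_config(), seeds = 1:3)
rep$ordering
```

`rep$summary` is the condition-grid table (mAP / recall / F in percent at
IoU 0.3 and 0.4); `rep$ordering` carries the headline contrasts: the
marker-trained detector's generalization gap `mAP(B1) - mAP(B2)` (large
and positive in every seed), the inpaint-trained detector's gap (small or
negative), the per-seed marker-free improvement of A2 over A0, and
whether mixup training lands between the two.

`run_classification_study()` is the crop-level counterpart: six test
cases (baseline vs VIB × negatives pseudo-marked/as-is × positives
marker-layered/marker-free) with per-seed accuracies and sign tests.

A thin CLI over the same functions ships in
`inst/scripts/sonomark-cli.R` (subcommands `simulate`, `annotate`,
`inpaint`, `evaluate`, `reproduce`).

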