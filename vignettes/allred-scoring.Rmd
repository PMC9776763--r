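---
title: "Automated Allred scoring of ER-IHC images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated Allred scoring of ER-IHC images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Estrogen-receptor (ER) status guides the decision to offer hormonal therapy
in breast carcinoma.  In routine practice a pathologist examines an
immunohistochemistry (IHC)-stained slide in which DAB chromogen marks
receptor-positive nuclei brown and hematoxylin counterstain marks negative
nuclei blue, estimates the fraction of positively stained tumour cells and
the dominant staining intensity, and combines the two in the **Allred
score**: a proportion score (0-5) plus an intensity score (0-3), total in
{0, 2..8}, with scores of 3 and above supporting hormonal therapy.  Manual
estimation over a gigapixel slide is laborious and subject to sampling
bias; `erallred` automates the four stages — cell detection,
positive/negative classification, weak/moderate/strong grading, and Allred
scoring — and ships an evaluation harness plus a synthetic data generator
so every stage is testable without any external image.

## Cell detection by score-map regression

Detection regresses a per-pixel *score map* that encodes proximity to the
nearest cell centre.  For annotated centroids the training target at pixel
$p$ is

$$ s(p) = \max\!\left(0,\; 1 - d(p)/R \right), $$

where $d(p)$ is the Euclidean distance to the nearest centroid and
$R = 32$ px is the cell radius at the working magnification (20x,
0.243 um/px).  This linear cone is the simplest target consistent with a
radius-$R$ circular annotation convention, and it makes the detection
threshold of 0.2 an iso-contour at $0.8R$ from the centre.

The regressor is a fully convolutional network: eight 3x3
convolution+ReLU blocks with two 2x2 max-pools and two nearest-neighbour
upsample+convolution stages back to input resolution, closed by a linear
1x1 convolution (at most 20 layers; widths are configurable through
`detector_config()`).  Nearest-upsample-plus-convolution was preferred to
transposed convolution to avoid checkerboard artifacts.  The effective
receptive field (about 30 px) covers the informative part of the cone.
Training windows are 64 x 64: one window per annotated cell plus an equal
number of background windows sampled at least $R$ from any centroid —
without background windows the regressor has no incentive to predict zero
anywhere.

At inference the network runs over the whole image in one pass (inputs are
reflect-padded to a multiple of 4 and cropped back), so there are no patch
stitching seams.  Post-processing in `extract_cells()`:

1. binarise the map at `score_threshold = 0.2`;
2. seed a watershed-style propagation from local maxima of the map, with a
   minimum peak separation of $R/2$ and ties broken by first occurrence in
   row-major order;
3. drop regions smaller than `min_region_area = 240` px^2;
4. return region centroids, sorted by y then x.

Two numerical choices deserve comment.  First, the **area rule
direction**: at 0.243 um/px a radius-32 cell covers roughly 2000 px^2
above threshold, so 240 px^2 is interpreted as a *minimum* region area —
it removes watershed debris; removing regions *larger* than 240 px^2 would
delete every true nucleus.  Both the direction and the value are exposed
in `detection_params()`.  Second, **seed smoothing**: a regressed map is
locally bumpy, and raw local maxima oversegment single nuclei into several
seeds.  The map used for seeding (only) is therefore Gaussian-smoothed
with `smooth_sigma = R/8`; binarisation, areas and centroids always use
the raw map.  On analytic cone fixtures the smoothing is exact: a cone's
apex is also the smoothed maximum.

## Positive/negative classification

A 32 x 32 block is extracted around each detected centroid (reflection
padding at image borders) and converted to HSV.  Hue and value are
averaged with weights decreasing linearly with distance from the block
centre, $w(p) = 1 - d(p)/d_{max}$ with $d_{max}$ the half-diagonal, so
neighbouring cells caught at the block's edge influence the estimate
little, and every pixel keeps a strictly positive weight.  The two-step
rule is then:

* if the weighted value $wV < 50$ the block is dark — positive regardless
  of hue;
* otherwise the weighted hue decides: $wH \le 40$ positive (brown),
  $wH > 40$ negative (blue).

All channels use the **0-255 scale**; it is the only scale on which both
thresholds are simultaneously sensible (brown hue sits near 10-35, blue
near 140-175).  Weighted hue uses the plain arithmetic mean, not the
circular mean: both stain families sit far from the 0/255 hue wrap point,
and a documented limitation is that the rule would need a circular mean if
a stain family ever straddled the wrap.  Boundary behaviour is fixed as
positive at exactly $wH = 40$ and negative at exactly $wV = 50$ (when
$wH > 40$); the thresholds themselves are configurable
(`pn_thresholds()`).

## Weak/moderate/strong grading

Positive cells are graded by a nine-weight-layer convolutional classifier
(`train_wms()`): eight 3x3 convolutions in back-to-back pairs with three
max-pools, dropout before a fully connected softmax output over
strong/moderate/weak.  Inputs are the same 32 x 32 blocks, normalised to
$[-0.5, 0.5]$; augmentation is horizontal flipping and random 28 x 28
crops resized back.  Note the normalisation deliberately preserves
absolute brightness — staining intensity *is* the class signal, so
per-patch standardisation would destroy it.

Training uses stochastic gradient descent with the two-phase schedule
(10^-2 for the first 10 epochs, 10^-4 thereafter; 600 epochs by default)
and zero-mean Gaussian (He-scaled) initialisation.  Gradients are averaged
over mini-batches of 10: the schedule assumes batched updates, and
per-sample steps at 10^-2 are demonstrably unstable (they kill the ReLUs
and collapse the classifier to a constant).  Ties in the output argmax
break toward the stronger class, the same conservative convention used for
the intensity score.  All randomness — initialisation, shuffling,
augmentation, dropout — is drawn from R's RNG after a single
`set.seed(cfg$seed)`, so training is bit-reproducible on a fixed platform.

## Allred scoring

`proportion_score()` bins the positive percentage with real-valued,
half-open edges: $0 \to 0$, $(0,1) \to 1$, $[1,10] \to 2$, $(10,33] \to 3$,
$(33,66] \to 4$, $(66,100] \to 5$.  The published score table lists integer
ranges ("1 to 10", "11 to 33", "34 to 66"); edges at 10/33/66 are the only
placement consistent with every row of the bundled reference cohort (for
example 33.5% scores 4 and 73.15% scores 5).  `intensity_score()` takes
the *majority* positive class (3/2/1 for strong/moderate/weak dominant),
not a weighted average — confirmed by reference slides where a strong
majority at 0.19% positivity yields intensity 3, and a weak numeric
maximum yields intensity 1.  Exact ties go to the stronger class:
deterministic, and conservative toward recommending treatment.
`treatment()` recommends hormonal therapy for scores of 3 to 8; a score of
1 cannot occur (a positive proportion forces a non-zero intensity) and is
rejected wherever it appears, including in reports read back from disk.

Slides with a positive fraction below 0.1% are flagged `low_positive`
rather than specially rescored: at that level the score hinges on a
handful of detections, and the reference evaluation shows exactly this
failure mode on 0%-ER slides, where stray brownish artifacts inflate an
all-negative slide to score 2-4.  The package exposes the raw score plus
the flag and leaves the clinical special-casing to the user.

## The synthetic generator

`generate_scene()` renders elliptical nuclei (semi-axes 12-20 px, mild
rotation) in two stain families — hematoxylin-like negatives (hue ~155,
value ~165 on the 0-255 scales) and DAB-like positives (hue ~20) at three
darkness levels (value ~200 / ~140 / ~64 for weak/moderate/strong) — on a
warm near-white background, with per-nucleus colour sampling, per-pixel
jitter, additive Gaussian noise (sd 3 of 255), and 8-bit quantisation.
Placement is rejection sampling on centre distance with a configurable
overlap allowance, and an explicit error when a request cannot be packed.
The defaults were chosen once so that the positive/negative thresholds
separate the families cleanly (the published description constrains the
colours only qualitatively — blue/purple versus brown — so the simulator
is calibrated to the rule's thresholds, not to any particular scanner).

What the generator does *not* emulate — and hence what green synthetic
benchmarks do and do not show: no stain-physics (Beer-Lambert mixing,
stain deconvolution), no tissue architecture (glands, stroma, clustered
growth), no non-tumour cell types, no scanner artifacts beyond Gaussian
noise, no uneven illumination.  Passing the synthetic end-to-end
benchmarks demonstrates that the pipeline's machinery — regression,
thresholding, instance splitting, colour rules, scoring — composes
correctly; it does not certify accuracy on clinical material, for which
the bundled reference tables provide the published cell-level and
slide-level error rates.

## Problem sizes and benchmarks

The test-suite benchmarks are sized for a laptop-class single CPU: the
shared detector trains on three 256 x 256 scenes (about 110 nuclei, 12
epochs, roughly a minute), the staining classifier on 390 patches of
32 x 32 (15 epochs).  The end-to-end benchmark evaluates three held-out
384 x 384 fields (225 nuclei, overlap fraction 0.1) and asserts detection
F1 >= 0.90 at the 16 px matching tolerance and four-class accuracy
>= 0.90 on matched cells; the slide-recovery benchmark runs five 512 x 512
synthetic slides composed to span Allred scores {0, 2, 3, 5, 8}.  Under
the fixed test seeds the current implementation reaches F1 about 0.98,
four-class accuracy about 1.0, and recovers 5/5 slide scores.  Epoch
budgets, scene sizes and seeds are fixed in the tests; the full 600-epoch
default schedule is available for real training runs.

## Evaluation conventions

Detections are matched to ground truth one-to-one, greedily by ascending
distance, with pairs beyond 16 px (= R/2) rejected — the published
evaluation does not state its matching criterion, so the tolerance is a
package convention and is configurable.  Whole images are processed in
non-overlapping high-power fields; each field is expanded by a 32 px
context margin for detection (so nuclei straddling a field border are seen
whole), detections are kept only inside their core field, and residual
seam duplicates within 8 px are merged to their mean.  Tiling is an
artifact of bounded memory, and these two conventions make its effect on
counts negligible.  Confusion-matrix metrics take labelled matrices whose
rows may include spill-over classes (negative or non-tumour cells wrongly
passed to a later stage); excluding those rows yields the "only true
cells" variant of accuracy, and both variants are reported in the bundled
reference tables.  One reference slide (05459) has printed class
proportions that are internally inconsistent with its printed ER
percentage (weak 2.84 versus ER 0.56%); it is flagged in the fixture and
excluded from exact-reproduction checks.

## Known limitations

* The CNNs here are compact models run on CPU; the architecture is sized
  for the synthetic benchmarks and small annotated regions, not for
  high-throughput clinical deployment.
* Hue averaging is non-circular (see above).
* No tumour/stromal discrimination: like the published system, every
  detected object within the analysed region is scored, and stromal or
  epithelial cells picked up by the detector dilute the proportions.
* Whole-slide formats are out of scope; the package operates on exported
  RGB tiles (PNG/TIFF).

## A worked example

```{r example}
library(erallred)

# simulate, train at reduced budgets, and score one field
scenes <- lapply(1:3, function(i) generate_scene(scene_spec(
  width = 256, height = 256, n_cells = c(N = 15, W = 7, M = 7, S = 7),
  seed = 100 + i)))
detector <- train_detector(scenes, cfg = detector_config(epochs = 12, seed = 5))
wms <- train_wms(generate_patchset(130, seed = 11),
                 cfg = wms_config(epochs = 15, seed = 5))

slide <- generate_scene(scene_spec(width = 512, height = 512,
                                   n_cells = c(N = 60, W = 50, M = 6, S = 4),
                                   seed = 9004))
report <- run_slide(slide$image, detector, wms)
report$allred

# the bundled reference cohort
rs <- reference_slides()
agreement_stats(rs$manual_allred, rs$auto_allred)
```
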