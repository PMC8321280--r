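---
title: "Automatic seeded region growing for brain-tumor segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic seeded region growing for brain-tumor segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growseg)
```

## The problem

Seeded region growing is a classical, interpretable segmentation method:
starting from a seed pixel, it absorbs neighbors whose intensity is close
enough to the region's. Its weakness is the seed — placed manually, it makes
results operator-dependent. `growseg` implements a fully automatic variant
for brain MR slices, exploiting the fact that gliomas are hyperintense on
FLAIR: after non-brain tissue is removed, the brightest tiles of the slice
are reliable tumor candidates, so their centers can serve as seeds without
human input.

## Pipeline model and assumptions

Every slice is resized (bilinearly) to a 256×256 working grid and its
declared intensity range mapped linearly onto [0, 1]. These two conventions
matter: all tolerances below are on the normalized scale, and all metrics
are computed on the working grid (reference masks are resampled to it by
nearest neighbor; the final mask is mapped back to the native shape the
same way).

**Skull stripping** assumes the slice shows dark background, bright skull,
and mid-bright brain, with skull and brain separated by a dark CSF gap. The
Otsu threshold (maximizing between-class variance over a 256-bin histogram)
separates tissue from background; opening removes speckle; one dilation
consolidates tissue; the *largest* 8-connected component is kept — this is
the step that actually discards the skull, which forms a thin ring of
smaller area than the brain; closing and hole filling produce a solid brain
mask. The method fails by design on slices where the skull is connected to
the brain at this resolution (no dark gap): the largest component then
includes the ring.

**Seed initialization** partitions the working grid into 1024
non-overlapping 8×8-pixel tiles, computes each tile's mean intensity, and
takes the centers (tile origin + 3 in both axes) of the five brightest
tiles as seeds, each carrying its tile mean as reference intensity. Tiles
whose center falls outside the brain mask are excluded before ranking
(`restrict_to_brain`, default on); without this, residual bright artifacts
at the mask boundary can waste seed slots. Ties in tile mean break by
row-major tile order, so results are deterministic.

**Region growing** is breadth-first from the seed. A frontier pixel `p` is
tested once, on first encounter, and accepted when `|I(p) − μ| ≤ τ`. Two
criteria are available for `μ`:

* `running_mean` (default): `μ` is the mean of the region accepted so far,
  initialized to the seed's tile mean. This is classic seeded region
  growing — robust when the seed pixel is slightly off the tumor's modal
  intensity, and appropriate because tumor regions are largely homogeneous.
* `fixed_seed`: `μ` stays at the reference. This makes the result exactly
  the connected component of `{p : |I(p) − ref| ≤ τ}` containing the seed,
  which is what the test suite verifies against an independent flood-fill
  oracle, and gives monotonicity in τ.

The FIFO frontier makes the running-mean result deterministic: identical
inputs always produce identical regions. Stripped-out pixels are never
accepted, and growth stops if the region reaches `max_region_fraction`
(default 0.5) of the image — a guard against flooding a near-uniform slice;
the growing criterion alone has no such bound.

**Hole filling** (background 4-connectivity, complementary to the
8-connected foreground — the standard dual pairing that avoids topological
paradoxes) is applied to each grown candidate. Its purpose is specific:
tumors with a necrotic dark core grow only as a bright rim, and filling the
enclosed background recovers the core.

**Best-ROI selection** scores each of the five candidates against the
reference mask and keeps the argmax of the configured metric (Dice by
default), ties toward the higher-ranked seed. Selecting against the ground
truth is the method's evaluation protocol; it is unusable at inference
time, so when no reference is supplied the package falls back to a
reference-free proxy — the candidate with the greatest contrast between its
mean interior intensity and its 2-pixel dilated rim — and flags the result
as `"unsupervised"`. The proxy favors regions that are bright relative to
their surroundings, which is exactly the property the seeds were chosen by.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `tolerance` | 0.1 | normalized intensity | growing acceptance band; larger floods into edema/brain |
| `k_seeds` | 5 | count | candidate ROIs per slice |
| `block_size` | 8 | px | seed tile side; 8 gives 1024 tiles at 256×256 |
| `selem_radius` | 3 | px | disk radius for all stripping morphology |
| `connectivity` | 8 | — | growing neighborhood |
| `max_region_fraction` | 0.5 | fraction | flood-out guard |
| `selection_metric` | `dss` | — | best-ROI criterion (`dss`, `iou`, `acc`) |

The defaults are the method's stated operating point (five seeds, 8×8
tiles, tolerance 0.1 on [0, 1]). The structuring-element radius is not
specified by the method description; 3 px at 256×256 is small enough to
preserve the brain outline and large enough to detach thin bridges, and it
is exposed in the configuration. A single shared radius is used for
opening, dilation and closing, since nothing indicates the steps used
different elements.

## The phantom generator

`generate_phantom()` emulates the geometry the pipeline relies on: dark
background, a bright elliptical skull ring (intensity 0.8), a brain ellipse
(0.45) separated from the ring by an 8-px dark gap, and a hyperintense
tumor disk (0.9 ± randomization, always ≥ 0.3 above brain in the suite
defaults), plus clipped additive Gaussian noise (σ = 0.02). The skull ring
is deliberately *brighter* than brain so the stripping stage must discard
it by component size rather than by intensity. `core_dark = TRUE` inserts a
dark center at half the tumor radius, exercising the hole-filling rescue.
`generate_suite()` randomizes tumor position (uniform over placements that
keep the disk inside the brain ellipse), radius (10–18 px) and intensity
(0.78–0.95), with all randomness derived from one master seed.

What the phantoms do **not** emulate: partial-volume boundaries, bias
fields, Rician noise, anatomical texture, multifocal or non-convex tumors,
and skull-brain contact. Passing the phantom suite therefore demonstrates
the pipeline's mechanics — stripping, seeding, growing, rescue, selection —
not clinical-grade accuracy; on real FLAIR data the intensity contrasts are
weaker and the reported scores will be lower.

## Numerical and degenerate-input choices

* Constant slices normalize to all zeros (no segmentable signal; avoids
  0/0), and the Otsu threshold of a constant image is the constant itself.
* An all-background slice yields an empty brain mask, a warning, and a
  result with zero candidates rather than an error, so batch runs skip
  degenerate slices gracefully.
* Empty-vs-empty masks score Dice 1 (perfect agreement); metrics whose
  denominator vanishes (sensitivity/overlap/extra fraction with an empty
  reference) are `NA` in reports and explicit errors as scalars.
* PSNR uses the standard `10·log10(255²/MSE)` on 0/255-encoded masks and is
  `Inf` for identical masks. Published PSNR values for mask comparisons
  sometimes exceed what this formula can produce; this package reports the
  standard definition only.
* Equal-size largest components tie-break toward the component whose first
  pixel comes earliest in row-major order; seed-intensity ties break by
  tile order; candidate-score ties break toward the better-ranked seed. All
  three rules exist purely for determinism.
* A tile's mean can be a poor reference if the tile straddles the tumor
  boundary; the running-mean criterion absorbs this, since after the first
  few acceptances the reference reflects actual region intensities.

## Problem sizes in the test suite

The suite verifies the growing engine against a brute-force flood-fill
oracle on 100 random 16×16 grids, the metric report against per-pixel
enumeration on 200 random 64×64 mask pairs, seed selection against a
stable sort on 100 random tile lists, and the full pipeline on suites of
10–20 phantoms at 256×256 — sizes chosen to exercise every code path many
times while keeping a full run around half a minute.

## Known limitations

* 2-D only; no volumetric growing or 3-D stripping.
* Intensity-only similarity; no texture or edge terms.
* Supervised best-ROI selection needs a reference mask; the unsupervised
  fallback is a heuristic and is flagged as such in the output.
* The skull stripper assumes ring-and-gap anatomy typical of axial slices;
  it is not an atlas- or surface-based method.
* No DICOM input, bias-field correction, or cross-scanner intensity
  standardization.
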