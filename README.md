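# growseg

Fully automatic brain-tumor segmentation for 2-D MR slices by **enhanced
seeded region growing**. Classic region growing needs a manually placed
seed; `growseg` removes that requirement by stripping the skull, ranking
tile mean intensities to find the brightest tissue (gliomas are
hyperintense on FLAIR), and growing a candidate region from each of the
top-ranked tiles. It is intended for researchers evaluating classical
segmentation baselines against learned methods, and as a transparent,
dependency-light reference implementation of the approach.

## Method

For a slice `I` (resized to the 256×256 working grid and normalized to
[0, 1]):

1. **Skull stripping.** Threshold at the Otsu level `T` (256-bin
   histogram), then apply morphological opening and dilation with a disk,
   keep the largest 8-connected component (the brain, not the skull ring),
   close, and fill holes. All pixels outside the resulting brain mask are
   set to 0.
2. **Seed initialization.** Partition the image into non-overlapping 8×8
   tiles and compute each tile's mean intensity
   `AvgI = (1/64) Σ_j Σ_k I_jk`. The centers of the `k = 5` brightest tiles
   (inside the brain mask) become seed points; each seed's reference
   intensity is its tile mean.
3. **Region growing.** From each seed, breadth-first growth absorbs a
   neighboring pixel `p` when `|I(p) − μ| ≤ τ`, with tolerance `τ = 0.1`
   and `μ` the running mean of the region grown so far. Holes in the grown
   region are filled, which recovers tumors whose core is dark and only the
   rim hyperintense.
4. **Best-ROI selection.** Each of the 5 candidate ROIs is scored against
   the reference mask (Dice score by default; IoU and accuracy also
   available) and the best one is returned. Without a reference, an
   unsupervised fallback picks the candidate with the highest
   interior-vs-rim intensity contrast.

Evaluation reports eight metrics per mask pair: accuracy, IoU
(TP/(TP+FP+FN)), Dice (2TP/(2TP+FP+FN)), sensitivity, specificity, extra
fraction (FP/(TP+FN)), overlap fraction (TP/(TP+FN), identical to
sensitivity), and PSNR on the 0/255-encoded masks.

A synthetic phantom generator (dark background, bright skull ring,
mid-intensity brain ellipse, hyperintense tumor disk, optional dark core,
Gaussian noise) provides ground-truth images so the whole pipeline is
testable without clinical data.

## Worked example

```r
library(growseg)

ph  <- generate_phantom(phantom_spec())          # noisy synthetic slice
res <- run_pipeline(ph$image, ref = ph$tumor_truth)
res
#> <pipeline_result: 5 candidates, selection reference>
#> <metric_report: Acc 100.0%  IoU 1.000  DSS 1.000  Sn 100.0%  Sp 100.0%  EF 0.000  OF 1.000  PSNR Inf>

res$seeds
#>   rank row col reference_intensity
#> 1    1 108 148           0.9078474
#> 2    2 100 140           0.9013234
#> 3    3 100 156           0.9000049
#> 4    4 100 148           0.8996994
#> 5    5 108 140           0.8978145
```

All five seed tiles land inside the simulated tumor (the brightest interior
structure), and the best grown candidate matches the ground-truth disk
pixel-for-pixel: Dice score (DSS) 1.0, zero extra fraction, infinite PSNR
(identical masks). On harder inputs the five candidates differ and the
report shows the best one's scores.

The same pipeline is scriptable from a shell via the bundled CLI
(`system.file("cli", "growseg", package = "growseg")`), with subcommands
`strip`, `seeds`, `grow`, `evaluate`, `segment`, `batch`, and `synth`.

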