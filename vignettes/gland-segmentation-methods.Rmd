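---
title: "Gland segmentation by seeding, searching, and ensembling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gland segmentation by seeding, searching, and ensembling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandseg)
```

## The problem and the model

Intestinal glands in H&E-stained tissue are rings of darkly stained
epithelial cell nuclei around a bright cytoplasm/lumen interior, embedded in
a mid-bright stroma speckled with other dark nuclei. `glandseg` detects and
segments individual glands while preserving their true borders — the failure
mode it is designed against is *leaking*, where a segmentation spills through
a weak border arc into neighboring tissue.

The pipeline has six stages:

1. **Seeding.** Seeding points are sampled on a uniform grid
   (`grid_spacing`, default 20 px) and dark seeds (intensity below
   `seed_intensity_min` = 0.05) are discarded: nuclei themselves are poor
   anchors for a surrounding-contour search, and a dense unbiased grid keeps
   small, densely packed glands covered.

2. **Searching.** Around each seed, `n` rays (default 360, one per degree)
   of length `r` (default 100 px, matching gland long diameters of
   80–160 px) are sampled at `m` radial positions. This polar sampling grid
   is a multi-column DAG: node \((i, j)\) is the \(i\)-th sample on ray
   \(j\), edges connect consecutive columns with a *hard smoothness
   constraint* \(|\Delta i| \le 1\), and node weights are

   \[ w_{ij} = I(i,j) + \lambda \sum_{i'=1}^{i} E(i',j), \]

   where \(I\) is the bilinearly interpolated image intensity and \(E\) the
   Sobel gradient magnitude sampled the same way (an inclusive prefix sum per
   ray). A cyclic shortest path — the cheapest path from column 1 to a
   zero-weight replica column \(n{+}1\) that starts and ends on the same row
   — is a closed, smooth, dark contour around the seed. The intensity term
   pulls the contour onto nucleus borders; the cumulative edge term is a
   region cost that discourages enclosing extra edge mass and thereby
   penalizes leaking across gaps into neighboring glands.

3. **Ensembling.** One search is one fallible suggestion. For every pixel,
   the boundary probability map (BPM) is the fraction of covering contours
   (boundary or enclosed region) that place the pixel *on* their boundary;
   pixels covered by nothing get 0. Accumulation uses two integer counters
   and a single division, so it is order-independent and exact.

4. **Proposals.** BPM values below `bpm_threshold` (default 0.5) are zeroed
   and the truncated map, viewed as elevation, is partitioned by Meyer's
   flooding watershed into non-overlapping catchment basins — glands in
   tissue seldom overlap, so the method commits to a partition rather than
   arbitrary overlapping proposals. Proposals smaller than `prune_min_area`
   (500 px; gland areas at these scales run to thousands of pixels) or whose
   contour has mean boundary probability below `prune_boundary_prob` (0.3)
   are pruned.

5. **Scoring.** Each surviving proposal is described by five basic features
   (region mean/SD intensity, area, contour mean/SD intensity — glands are
   bright inside, large, and dark-rimmed) plus a dense HOG descriptor of its
   bounding-box patch, and scored by a random-forest regressor trained
   against the proposal's best Jaccard overlap with any ground-truth gland.
   A proposal is called a gland when its score reaches `detect_threshold`
   (0.5); sweeping this threshold yields the precision–recall curve.

6. **Post-processing.** *Re-weighting*: gland borders are a consumable
   resource held in the BPM. In decreasing score order each proposal measures
   the mean remaining resource on its one-pixel-dilated contour band; if it
   falls below `avail_threshold` (0.3) the score is multiplied by
   `lambda_d` (1/2), and the band is then zeroed. True glands consume the
   borders first; border-less artifacts wedged between them are pushed down.
   *Merging*: neighboring gland proposals with merge affinity
   \(P_{pq} \ge\) `merge_threshold` (0.5) are merged greedily, highest
   affinity first, to repair over-segmented irregular glands.

## Design choices where the design was open

Several components admit more than one reasonable construction; the package
settles them as follows.

**Coordinates and interpolation.** Pixels form a row-major grid with 0-based
continuous coordinates, pixel centers at integers, \(x\) = column, \(y\) =
row; all sub-pixel sampling (polar positions, patch resizing) is bilinear,
and samples beyond the border clamp to the nearest border pixel. Clamping,
rather than assigning a repelling maximal intensity, keeps border-adjacent
seeds usable.

**RGB conversion.** Inputs are reduced to luminance with the ITU-R BT.601
weights \(0.299R + 0.587G + 0.114B\) — any fixed convention works; this one
is standard and deterministic.

**The edge scale and \(\lambda\).** The Sobel magnitude is *not*
renormalized, so the region term's scale rides on the intensity scale and
the kernel convention (the classic unnormalized 3×3 kernels give step
responses of 4× the step height). With intensities in \([0,1]\), the
cumulative edge sum along a 50–100 px ray — including the noise floor of a
realistic image — reaches the order of several units, while the intensity
saving of sitting on a dark ring is only ~0.6 per column. The default
`lambda_region = 0.05` balances the two so that the region cost penalizes
enclosing extra structure without overwhelming the intensity term and
collapsing contours inward; it was chosen by this scale analysis plus
inspection of per-gland proposal quality on a development scene. It is the
one parameter that must be revisited if the intensity or edge convention
changes.

**Solver tie-breaking.** Among equal-cost paths the solvers prefer the
smaller start row, then the lexicographically smallest row sequence
(reconstruction walks forward taking the smallest optimal next row). This
makes outputs deterministic and testable. The divide-and-conquer solver
(solve the middle start row, then recurse above and below inside the
corridor bounded by solved paths; \(O(mn\log m)\) versus the naive
\(O(m^2n)\)) guarantees the same *cost*; its equality with exhaustive
enumeration is fuzz-tested on more than a thousand random graphs.

**Radial resolution.** `m = 50` samples per ray puts radial samples every
\(r/m = 2\) px at the default radius — below the size of a nucleus, so the
discretization does not limit boundary accuracy, at acceptable cost.

**Watershed details.** Basin markers are the 4-connected plateaus of the
global minimum of the truncated map (the zeroed sub-threshold area — the
motivation for truncation is precisely to avoid meaningless shallow basins).
Flooding is 4-connected with FIFO tie-breaking, so the labeling is
deterministic. A pixel reached by two basins becomes a ridge pixel; ridge
pixels are then assigned, in synchronized rounds, to the adjacent basin
whose neighboring pixels have the lower mean elevation (ties to the lower
basin id), so the final proposals partition the image exactly.

**Merge affinity.** Disjoint watershed regions never literally share contour
pixels, so the "shared contour" between neighbors \(p, q\) is realized as
the contour pixels of either region 8-adjacent to the other, dilated by one
pixel within \(p \cup q\); \(P_{pq}\) is 1 minus the mean BPM over that
band. Averaging over the band is deliberate: a true inter-gland border is a
near-unanimous (BPM ≈ 1) ridge that keeps the band mean high even with its
flanking interior pixels, while an over-segmentation seam carries only
partial consensus and fails to defend itself. A line-only definition would
make merging at threshold 0.5 unsatisfiable, since every ridge that survived
truncation at 0.5 has mean ≥ 0.5 by construction. Merged regions take the
union of pixels and the area-weighted mean score; only gland-flagged
proposals participate (merging background fragments serves no purpose).

**Re-weighting.** Applied once (not iterated to a fixed point), on a
one-pixel-dilated contour band so that neighboring regions genuinely compete
for the same border pixels. The availability threshold reuses 0.3, the same
scale as the pruning threshold on mean boundary probability.

**Training set.** Only proposals surviving the pruning step are labeled and
used to train the forest — the pruned ones never reach the classifier at
test time either. The forest uses 200 trees, the regression default
`mtry`, and a fixed seed; out-of-bag RMSE is logged at training.

## The synthetic scene generator

Real annotated H&E images cannot ship with the package, so every stage is
exercised on synthetic scenes with exact ground truth. A scene is a mid-gray
stroma (0.55) holding star-shaped glands: a dark nucleus ring (0.15, default
thickness 8 px) around a bright interior (0.75) with a brighter central
lumen disk (0.95), plus Poisson-scattered small dark disks (0.2) for
stromal/immune nuclei and optional Gaussian noise. The palette reproduces
the H&E contrast ordering — nuclei dark, cytoplasm and lumen bright. Gland
radii default to 40–80 px (long diameters 80–160 px, the scale the default
search radius of 100 px is matched to).

Shape irregularity perturbs the radius with a low-order harmonic sum scaled
to unit peak, which keeps every gland star-shaped about its center — a
requirement of the polar search, and the default 0.2 reflects that real
glands are ovals rather than circles. Border weakness is emulated by erasing
one contiguous arc of the ring (`gap_fraction` of the circumference) to a
washed-out intensity midway between interior and stroma. Glands are placed
by rejection sampling, largest first, with non-overlap enforced on the
worst-case perturbed radius; when the packing is too tight fewer glands are
placed and logged — at the default density (8 requested glands of these
radii in a 512 px scene) a shortfall of a gland or two per scene is normal
and the evaluation always uses the placed ground truth.

The `seam` option draws a thin (2 px), very dark line across each gland
interior. Contours launched from either side adopt the seam as part of their
boundary, the BPM develops a ridge with *partial* consensus across the
gland, and the watershed splits it — a controlled over-segmentation fixture
used to validate that greedy merging restores the generated instance count.
The seam darkness/thickness defaults were set by checking that the splits
actually occur; they are fixture dials, not method parameters.

What the generator does **not** emulate: staining variation and hue (scenes
are single-channel), texture inside cytoplasm and stroma, touching glands
with shared borders, non-star-shaped (bent or branched) glands, and
out-of-focus or sectioning artifacts. Passing the synthetic study therefore
demonstrates that the machinery is correct and self-consistent at realistic
geometry and noise — not clinical-grade performance on real slides.

## The evaluation protocol and the bundled study

Detection follows the PASCAL VOC convention: detections and ground-truth
instances are matched one-to-one greedily by decreasing overlap, and a match
counts only when the intersection-over-union *strictly* exceeds 0.5.
Precision is TP/(TP+FP), recall TP/(TP+FN), F their harmonic mean;
segmentation is additionally scored pixel-by-pixel on the union of detected
gland pixels. Average precision uses step (not trapezoidal) interpolation
over the threshold sweep.

The package's reference study — recomputed from scratch by
`scripts/acceptance.R` and asserted by the acceptance tests — is
leave-one-image-out cross-validation over 10 generated scenes of 512×512 px
with 8 requested glands each, border gap fraction 0.15, and noise σ = 0.05.
Each fold trains the forest only on the nine other images; pooled counts are
reported with and without the merging step. The problem sizes (10 scenes,
~60 glands, ~600 radial-search launches per scene) were chosen so the whole
study runs in minutes on a single core while still pooling enough instances
for stable metrics. A second, noise-free construction (no gaps, no
irregularity) checks boundary recovery directly: contours launched inside a
gland must lie on the dark ring band \([R, R+t]\) with mean radial deviation
under one radial sampling step (2 px).

## Numerical notes and degenerate inputs

* Path costs are compared exactly where mathematics guarantees exact
  equality (both solvers sum the same weights); reconstruction re-derives
  the DP argmin rather than comparing subtracted floats.
* A constant image has a fully degenerate search: every closed path costs
  the same and the tie-break returns the innermost circle. The resulting
  speckle of tiny contours is removed by the area prune; a blank image ends
  with zero detections.
* An all-zero truncated BPM yields a single proposal covering the image.
* Gradient magnitudes below 1e-12 are treated as zero in the HOG descriptor
  so interpolation dust cannot survive block normalization; a uniform patch
  has an exactly zero descriptor.
* Proposals degenerate to single pixels keep themselves as their own
  contour; polygon rasterization with fewer than three distinct pixels
  yields an empty region and keeps the boundary.
* Masks with non-contiguous labels are relabeled with a warning; masks are
  written as 16-bit single-channel TIFF, limiting a scene to 65535
  instances.

## Known limitations

* The polar search can only represent contours star-shaped about the seed;
  strongly bent glands are recovered through the ensemble/merging route, not
  by a single search.
* `lambda_region` is scale-coupled (see above) and would need recalibration
  for differently normalized inputs.
* The watershed commits to a hard partition; overlapping glands (rare in
  tissue) cannot be represented.
* The forest is trained per study; no pretrained model ships with the
  package, and scoring refuses a model whose feature configuration
  fingerprint does not match.
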