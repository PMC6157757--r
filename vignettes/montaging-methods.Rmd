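---
title: "Methods: fast feature-based montaging of AOSLO retinal tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fast feature-based montaging of AOSLO retinal tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An adaptive-optics scanning light ophthalmoscope (AOSLO) resolves single
photoreceptors, but its corrected field of view is bounded by the eye's
isoplanatic patch, so a session yields 50–150 small tiles of 1–1.5° that
must be stitched into a montage before cone metrics can be referenced to
retinal location. Each tile holds up to three simultaneously captured,
pixel-registered modalities — confocal, non-confocal split detection and
dark field — and the operator records a nominal fixation position per tile
in degrees of visual angle. `aomontage` stitches such tile sets with
binary features and a greedy, good-enough growth rule, trading exhaustive
search for speed without giving up pairwise alignment accuracy.

## Pipeline

### Keypoints

Corners are detected with the FAST segment test: pixel *(x, y)* is a
corner when at least η = 9 contiguous pixels on the 16-pixel Bresenham
circle of radius 3 are all brighter than *I(x, y)* + λ or all darker than
*I(x, y)* − λ, with λ = 21 grey levels and wrap-around runs. The segment
score (sum of absolute differences over the qualifying run) feeds a 3×3
non-maximum suppression; survivors are re-scored with the Harris measure
det *M* − 0.04 tr²*M* over a 7×7 Gaussian-weighted (σ = 1) window of
central-difference gradients, and the best N = 5000 keypoints pooled over
all pyramid levels are kept. The pyramid uses scale factor 1.2 and 8
levels; each level is Gaussian-smoothed (σ = ½√(s² − 1)) before bilinear
decimation, and levels smaller than the 31 px descriptor patch are
dropped. Keypoints stay ≥ 15 px from every edge at their detection level,
which is why a minimum tile overlap of > 30 px is structurally required
for matching. Level-k coordinates are mapped to the full-resolution frame
with pixel-centre alignment, *(x + ½)s − ½*; the naive *xs* mapping
carries a systematic ~½(s − 1) px bias that noticeably hurts coarse-level
keypoints.

Each keypoint receives an orientation from the intensity centroid of the
15 px disc around it, θ = atan2(m01, m10). On a quasi-periodic cone
mosaic the centroid vector is a weak signal, so the moments are computed
on a copy of the level smoothed with σ = 4 (`orientation_blur_sigma`);
this cut the median orientation error under a 15° test rotation enough to
matter for matching (accept-and-correct rate 0.60 → 0.63). Zero moments
yield θ = 0 by convention.

### Descriptors

The 256-bit descriptor applies binary tests: bit *i* is 1 iff
*I(p1ᵢ) < I(p2ᵢ)* for a fixed pair pattern inside a 31×31 patch, rotated
to the keypoint orientation. The pattern is generated once from a seeded
Gaussian (σ = 31/5, seed 42), shipped as a plain-text table, and is part
of the descriptor definition: descriptors are only comparable under one
pattern. Two numerical choices matter here:

* **Comparison image.** Bits are sampled on the level smoothed with
  σ = 2 (`blur_sigma`). Single-pixel comparisons on the raw image are not
  repeatable under rotation/resampling — switching to the smoothed copy
  raised best-neighbour correctness under a 15° rotation from 0.59 to
  0.67 in our diagnostic harness.
* **Rotation discretization.** Orientations are quantized to 120 bins of
  3°, with one rounded integer pattern precomputed per bin. 30 bins of
  12° — the textbook choice — let bin quantization dominate the (well
  estimated, ~4° median error) orientation and cost ~8 percentage points
  of match rate; 120 bins keep the scheme deterministic and cacheable
  while making quantization negligible against estimation error.

Keypoints whose rotated pattern would leave the image are dropped
together with their descriptors, keeping the two sequences index-aligned.

### Matching

Descriptors are compared by Hamming distance. The two nearest stored
descriptors per query come either from exact brute force or from a
bit-sampling LSH index: b = 6 tables, each hashing 16 seed-chosen bit
positions; the query is compared exhaustively against the union of its
buckets, so reported distances are exact and bounded below by the true
optimum (the true neighbour can only be missed, never beaten). A match is
accepted by the ratio test when best < 0.75 × second-best; queries with
fewer than two candidates are rejected. Matching runs independently per
shared modality and the union of the per-modality match sets is pooled —
the modalities are pixel-registered, so all coordinates live in one tile
frame and weak modalities simply contribute fewer pairs. Matching is
directional (source → destination) with no cross-check; RANSAC absorbs
false matches.

### Alignment

Inter-tile motion is modelled as pure translation; the minimal RANSAC
sample is one correspondence. Up to i = 1000 candidates are scored by
their inlier count (residual ≤ δ = 10 px, boundary inclusive); when there
are at most 1000 matches every match is tried once in order, making the
scan exhaustive and deterministic — random sampling (seeded) only engages
beyond that. Ties keep the first candidate. The winner is refined as the
mean of its inlier displacements, and the inlier set is recounted under
the refined translation so the reported inliers always satisfy the δ rule
for the reported transform. The pre-refinement consensus count is kept
separately because it is the quantity the acceptance thresholds apply to.

### Montage growth

Tiles are compared only when nominally close: Euclidean distance between
recorded fixation positions ≤ d = 7 (degrees by default; both metric and
unit are configurable since the recorded positions' units vary by site).
A random (seeded) unaligned tile seeds each component as tile-of-reference
with the identity transform. Sweeps over the unaligned tiles (seeded
random order) try each against the aligned, nominally close tiles of the
current component, nearest nominal position first — the ordering that
maximises the chance of an immediate accept. An alignment with more than
T1 = 50 consensus inliers is taken on the spot and remaining candidates
are never evaluated; otherwise the best candidate is accepted if it
exceeds T2 = 10. The thresholds are strict inequalities, following the
algorithm's printed form rather than the looser "at least" phrasing. When
a full sweep aligns nothing, the component is closed and a new reference
drawn; disjoint imaged regions therefore emerge as separate montage
pieces. Candidates are restricted to the current component: alignment of
a pair is deterministic given features and seeds, so a tile that failed
against a closed component would fail again, and cross-component edges
could not be represented in the output. Global transforms accumulate by
composing each accepted pairwise translation with the destination's
global transform.

Rendering paints tiles in alignment order, last-painted-wins, with
transforms rounded to the pixel grid; it is an inspection artifact. All
quality metrics are computed on pairwise overlaps under the accepted
(unrounded-then-rounded) transform, the only transform-faithful choice.

## Quality metrics

NCC is the Pearson correlation of the two intensity arrays over an
overlap (undefined on constant arrays, which is reported as an error).
NMI is 2 I(A;B) / (H(A)+H(B)) from a 32-bin joint histogram over
[0, 255], bounded in [0, 1], with degenerate single-bin marginals scored
0 by convention; variant and bin count are configurable because the
symmetric-ratio form is one of several in circulation. Montage scores
average the metrics over all accepted edges and report the component
count. The overlap sweep crops one tile of a truth-known pair on the side
facing the other — preserving the survivor's pixel frame, or shifting the
truth by the removed width when the leading edge is cropped — and counts
a trial as a success when the alignment is accepted (> T2 consensus
inliers) and lands within 2 px of truth; trials at one width differ in
the LSH sampling seed, the matcher's stochastic element.

## The synthetic fixture

The generator plants cone centres on a hexagonal lattice (default
spacing 12 px at 600 px/degree, i.e. ~0.02° spacing) with 15% positional
jitter, seeded dropout, and renders three pixel-aligned modalities:
Gaussian spots (σ = 2.5 px) on a dim background for confocal, the signed
horizontal derivative of the spot field remapped around mid-grey for
split detection, and an inverted, more strongly blurred spot field for
dark field, all under a mild radial vignette applied at scene level.
Tiles are carved on a regular grid with known integer offsets (±2 px
seeded jitter); nominal positions are the true positions in degrees plus
seeded fixation error, recorded separately from the truth. Acquisition
noise is added per tile, not per scene: real tiles are independent
acquisitions, and scene-level noise would make overlapping tiles agree
noise-and-all, freezing NCC at 1 regardless of the noise setting. The
frozen validation fixture is an 1800×1800 scene carved into a 3×3 grid of
720 px tiles at 30% nominal overlap with noise σ = 5 and dropout 0.1;
1800 px is the smallest round scene that fits the grid (720 + 2 × 504).

What the generator does **not** emulate: intra-tile eye-motion
distortion, torsion, inter-modality misregistration, per-tile
illumination differences, or the diffuse image-quality loss of real
pathology. The last point matters for interpretation: cleanly deleting
cones from a quasi-periodic mosaic makes the surviving local patterns
*more* distinctive — gaps act as landmarks — so heavier dropout lowers,
rather than raises, the overlap needed for reliable matching in this
fixture. Clinical pathology degrades contrast and signal alongside cone
loss, and that degradation, not sparsity per se, is what drives the
larger overlap requirement seen on patient data. Passing tests on this
fixture demonstrate the pipeline's geometry, determinism and robustness
to noise and moderate dropout; they do not certify behaviour on
low-quality clinical images.

## Problem sizes used in validation

The test-suite and acceptance-script runs use the frozen 9-tile fixture
(27 images of 720² px), a 400² rotation harness, 5000-descriptor LSH
recall sets with 500 queries, 100 seeded RANSAC trials of 100 matches,
and overlap sweeps over 8 widths × 3 trials on a 512 px pair — sizes
chosen so the full validation cycle completes in minutes on one core
while every rate is estimated from hundreds of events.

## Known limitations

* Pure translation: residual rotation or scale between tiles, torsion,
  or within-tile motion distortion are not modelled and will depress
  inlier counts rather than be corrected.
* Greedy growth has no loop closure; long chains accumulate drift that a
  bundle adjustment would remove. Pairwise accuracy, not global rigidity,
  is the validated quantity.
* The ratio test on strongly periodic mosaics rejects many correct
  matches (the second-best is genuinely similar); sufficient overlap
  compensates.
* NMI values depend on the variant and bin count; compare only within
  one configuration.
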