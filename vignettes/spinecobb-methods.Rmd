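---
title: "Methods: LCM spinal segmentation and geometric Cobb angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LCM spinal segmentation and geometric Cobb angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical choices and the design
decisions behind `spinecobb`, in the spirit of a methods section: what the
pipeline assumes, which knobs matter, and what the synthetic phantoms do
and do not demonstrate.

## The local-center-of-mass model

The segmentation primitive assigns every position of a 1D signal the
intensity-edge-weighted mean index of all positions,

$$C_n = \frac{\sum_m w_{m,n}\, m}{\sum_m w_{m,n}}, \qquad
  w_{m,n} = e^{-|D_m - D_n|}, \qquad
  D_n = \alpha \sum_{i<n} |f_{i+1}-f_i|^p .$$

Two positions on opposite sides of a strong edge differ greatly in
cumulative edge energy $D$, so their mutual weight vanishes; within a
homogeneous interval all weights are close to one and $C$ points at the
interval's center. Segmentation falls out of clustering positions with
similar $C$.

**Index convention.** The printed summation range for $D$ runs to $i = n$
with the final difference padded, which double-counts the edge adjacent to
each position: two pixels immediately across an edge would then both carry
the edge in their energies and their weight would be $1$ rather than
$e^{-\alpha s^p}$. The package defaults to the `edge_complete` convention
($D_1 = 0$, sum to $n-1$), under which $|D_m - D_n|$ is exactly the energy
of the edges strictly between $m$ and $n$ — the stated intent of the
weighting. The padded variant is retained as `as_printed` for fidelity
experiments.

**Exact O(N) evaluation.** A direct evaluation of the rearranged prefix
and suffix sums multiplies $e^{-D_n}$ by $\sum_m e^{D_m}$, which overflows
for $\alpha$ in the thousands. The implementation instead uses the
recurrences
$S_n = S_{n-1} e^{D_{n-1}-D_n} + n$ (and analogues for the three other
sums), in which every exponent is $\le 0$ because $D$ is nondecreasing.
This is an exact algebraic rearrangement, runs in O(N), and cannot
overflow at any $\alpha$ (tested to 5000, the top of the reported
parameter range). The O(N²) brute force that materializes the full weight
matrix is kept as the reference oracle and the two agree to $10^{-6}$ on
hundreds of random signals.

**Parameters.** $\alpha$ (default 2000, the reported optimum for
radiograph segmentation; tested range 100–5000) scales the edge penalty:
larger $\alpha$ makes weaker edges act as region boundaries. $p$ (default
1 in `lcm_params()`) is the edge exponent. The *pipeline* default is
$p = 2$ — see "Noise and the pipeline defaults" below.

## From 1D profiles to a 2D segmentation

The published description computes local CMs in K orientations (K = 180,
1° angular resolution) and iterates for 1000 iterations of which 250 are
"phase 2", but does not specify how the per-orientation results combine
nor what the phases do. The package's realization, documented here as its
own design:

1. **Scanline geometry.** For each angle, a family of parallel lines at
   unit spacing covers the image; sample ladders are centered on the image
   center so that the sample set is symmetric under rotation and
   reflection (this makes 90°-rotation equivariance of the label map exact
   when K is divisible by 4) and coincides with the pixel grid for
   axis-aligned angles. Intensities are sampled bilinearly; each line's
   in-image segment is processed by the O(N) recurrence.
2. **Displacement field.** Per orientation, $C_n - n$ is a signed
   displacement along the line direction, mapped back to pixels by
   bilinear interpolation; the field $V$ is the mean over orientations.
   Pixels of a homogeneous region are pushed toward the region's center of
   mass.
3. **Phase 1.** One tracker per pixel iterates $x \leftarrow x + V(x)$
   (field bilinearly interpolated, positions clamped to the frame) for
   `t_total − t_phase2` steps.
4. **Phase 2.** Each tracker moves to the weighted mean of all trackers
   within `merge_radius` (2 px) of it — a mode-seeking consolidation.
   Near-coincident trackers are pooled on a grid of pitch
   `merge_radius/4` first; this bounds the cost of the exact
   neighbor-mean without visibly changing it.
5. **Labelling.** Single linkage constrained to the pixel grid: 4-adjacent
   pixels whose final trackers lie within `cluster_eps` (1 px) share a
   label. An elongated region's trackers settle along its medial axis — a
   chain of nearby modes rather than one point — and the spatial
   constraint keeps such a region one label while pixels whose trackers
   diverge to distant attractors are separated. (Unconstrained single
   linkage over tracker positions was tried first; it either fragmented
   elongated regions or, with a loose threshold, merged distinct ones.)

The pipeline is deterministic end to end: there is no randomness anywhere
in segmentation or measurement, so identical inputs give bit-identical
label maps and summaries. One caveat: the phase-2 pooling grid is aligned
to the coordinate origin, so *with phase 2 enabled* rotation equivariance
is only approximate near mode boundaries (it is exact with
`t_phase2 = 0`; the property test covers the exact case).

The desk profile (K = 8, `t_total = 50`, `t_phase2 = 12`) keeps the
1:4 phase-2 proportion of the full profile and is the configuration used
throughout the test suite and the acceptance script; reducing K and the
iteration count is the documented route to tractable runtimes, and on the
phantoms it does not measurably degrade the mask (Dice stays above 0.99).

## Noise and the pipeline defaults

With a linear edge exponent, white noise of standard deviation
$\sigma_\nu$ contributes edge energy at a rate of roughly
$\alpha\,\mathbb{E}|\Delta f| \approx \alpha \sigma_\nu$ *per pixel*. At
the paper-scale $\alpha = 2000$ even $\sigma_\nu = 0.02$ collapses the
weighting window to below a pixel and the field degenerates. Two pipeline
defaults address this while preserving the published $\alpha$:

* `p = 2`: squaring suppresses many small noise differences relative to
  one large boundary step (for a step $s$ the boundary energy is
  $\alpha s^2$ while the noise rate falls to $\alpha \sigma_\nu^2$);
* `denoise_sigma = 1.5` px of Gaussian smoothing immediately before the
  displacement field (after CLAHE and ROI cropping, so the published
  stage order is unchanged).

`lcm_params()` keeps `p = 1` as its own default so the 1D primitive
matches the printed definition; the quadratic exponent is a pipeline
choice, exercised together with `p = 1` in the unit tests.

CLAHE's `clip_limit` is expressed as a fraction of the tile histogram mass
(default 0.01 with 8×8 tiles) and converted internally to the clip
multiple expected by the underlying routine (`limit = clip_limit × 256`
bins). A constant image is returned unchanged.

## Spine mask: background subtraction rather than label picking

On real and synthetic radiographs the LCM segmentation legitimately
resolves *individual vertebrae* — the inter-vertebral gaps are real edges —
so no single label covers the column. The pipeline therefore follows the
background-subtraction route: labels whose mean intensity falls below
Otsu's threshold of the image are background; everything else is
foreground, and the largest 4-connected foreground component is the
spinal column. This is robust to any degree of over-segmentation of the
column itself. `select_spine_label()` (bright × centered scoring) is kept
for the simple cases where one label is the spine.

**Center curve.** Per mask row, the midpoint of the leftmost and
rightmost Canny edge is the midline (`wall_midpoint`; the mean of all
edge pixels is available as `mean`, and both agree on clean masks — the
wall midpoint is the default because interior texture edges do not move
it). Rows inside the span with no edges are filled by linear
interpolation. Canny runs on the zero-padded mask (the frame border is an
edge when the mask touches it) with $\sigma = 1$ and hysteresis at
0.1/0.2 of the maximum gradient; non-maximum suppression uses a small
tolerance so that plateau ties are kept symmetrically — without it,
last-bit convolution noise breaks the mirror symmetry of the edge map.

**Tip repair.** The first and last vertebrae cut the mask obliquely: a
block tilted by $\tau$ overhangs the true curve end by
$(w/2)\sin\tau$ rows and biases the row-midpoints up to $w\sin\tau$ rows
into the mask ($w$ = column width, estimated as the median row span).
Those rows would otherwise drag the chord endpoints toward the apex and
shrink the measured angle by several degrees. The repair estimates the
end tilt from a quadratic fit on interior rows, cuts the overhang rows,
and replaces the biased rows with a constant-curvature (circle)
continuation of the trusted section — exact for an arc, a straight line
in the zero-curvature limit. Smoothing (centered moving average,
half-width 5 rows, window shrinking symmetrically at the ends so linear
curves are preserved exactly) is applied *after* the repair; applied
before, it smears the cap bias into the trusted interior.

## The Cobb construction

`U` and `L` are the curve's endpoints; the chord UL meets the curve at
`M` and `N` (the endpoints are exact zeros of the chord offset, so
`M = U`, `N = L`, and interior offset sign changes — S-shaped curves —
are recorded as diagnostics); the apex `C` maximizes the absolute
perpendicular deviation from the chord; the perpendiculars to MC at M and
to NC at N meet at `O`; `P` is the foot of the perpendicular from O on
MN, a definition the source text leaves implicit and which is adopted
here because it makes triangle MOP right-angled at P.

Two conventions are implemented because the source's formula and its
prose disagree by a supplement: `mon` reports
$2\arctan(|MP|/|OP|) = \angle MON$, `eq5_printed` reports
$2\arctan(|OP|/|MP|)$, and the two sum to 180° exactly. `mon` is the
default: for a circular arc of central angle $\varphi$ it returns exactly
$\varphi/2$ (O is the apex antipode and the inscribed-angle relation
applies), it is invariant under similarity transforms and mirroring, and
it grows strictly with apex deviation. Note the arc identity also means
the construction's angle is *not* the tangent-endplate Cobb angle of
clinical practice ($\varphi$ for the same arc); ground truth for the
phantoms is therefore defined by the same construction applied to the
continuous curve, so that end-to-end error isolates the pixel pipeline
rather than a definitional offset.

**Apex refinement.** The deviation profile of a smooth bow is flat near
its peak (it changes by $\delta^2/2R$ over $\delta$ rows), so the raw
argmax wanders by ±10 rows under sub-pixel midline noise, and the MOP
formula is sensitive to that (~0.35°/row on the phantoms). With
`apex_refine = TRUE` (the default in `classify_scoliosis()`), the apex is
relocated to the parabola vertex fitted to the deviation profile within
±20 samples of the argmax, snapped to the nearest curve sample. The
literal argmax (and the source's literal minimum-column rule, `min_x`)
remain available.

Curves whose maximum chord deviation is below `min_dev_px` (default 3 px
at 256×256; the source names no numeric threshold for its "no scoliosis"
branch) are classified as no scoliosis with angle 0 and no construction.

## The phantom generator

`phantom_spec()` renders an AP-spine phantom: `n_vertebrae = 12`
rectangles of width 28 px, centered on and locally perpendicular to a
parametric center curve (circular arc of central angle $\varphi$, cosine
bow, or straight), separated by 3 px inter-vertebral gaps, blocks at
intensity 0.8 on a 0.2 background with additive Gaussian noise
($\sigma = 0.02$) under a fixed Mersenne–Twister seed recorded in the
bundle. The gaps render at 0.65 — discs on an AP film are less opaque
than bone but well above soft-tissue background — which keeps the column
a single *connected* bright structure (the mask stage depends on
connectivity, not on the column being one segmentation label). The truth
mask is the noiseless foreground (blocks and discs); the truth curve is
the continuous parametric curve; the truth angle applies the `mon`
construction to that curve at 10× row supersampling with an odd sample
count, so symmetric curves keep their apex exact — for arcs this equals
$\varphi/2$ to $10^{-6}$ degrees.

What the phantoms emulate: a bright, curved, block-structured column on a
darker noisy background, with analytically known geometry. What they do
not emulate: ribs, pelvis and lung-field clutter, projection physics,
scatter, intensity inhomogeneity, or anatomical variation in vertebra
shape. Passing the phantom suite therefore demonstrates that the
implementation measures its own construction correctly through the full
pixel pipeline under noise — not clinical-grade performance, for which
the published clinical figures (97.3% accuracy, Dice 0.54 on a 50-image
hospital set) would require the clinical data.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at the desk
profile on 256×256 phantoms: 20 noisy arc phantoms with construction
truths spanning 10–45° for the accuracy envelope (max |error| ≤ 3°,
matching the reported ±3° agreement with expert readers), noiseless
fixtures for the Dice ≥ 0.95 segmentation property, and 200 random
signals (N ≤ 512) for oracle equivalence at $10^{-6}$. A full-profile run
(K = 180, 1000 iterations) of a single image is minutes-scale and is not
part of the default suite.

Degenerate inputs are handled explicitly: empty projections raise an
empty-ROI error; an all-background segmentation raises an empty-mask
error; collinear constructions and straight curves take the no-scoliosis
branch rather than dividing by zero; 0/0 metric ratios return `NA`, never
a silent 0, so averages over batches cannot be corrupted. In batch mode
every per-image failure becomes a structured record and processing
continues; reruns are bit-identical.

## Known limitations

* The phase semantics of the published two-phase iteration are not
  specified in the source; the consolidation rule here is a documented
  stand-in honoring the printed iteration counts.
* Single-apex construction: for S-curves the dominant bow is measured and
  interior chord crossings are reported as a warning count, not measured
  separately.
* The tip repair assumes the column ends with an obliquely cut block; on
  masks with ragged ends (severe under-segmentation) it falls back to the
  unrepaired curve when fewer than `fit_rows` trusted rows remain.
* DICOM support covers single-frame, monochrome, uncompressed
  little-endian files — radiograph exports — not the general standard.
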