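---
title: "Automated hot-spot selection for Ki-67 scoring: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated hot-spot selection for Ki-67 scoring: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The Ki-67 proliferation index of a tumor section is the percentage of
immunopositive (DAB-stained, brown) nuclei among all nuclei, evaluated in
a small number of microscope fields placed in "hot spots" — regions of
locally maximal immunopositive-cell density. Because the choice of fields
is left to the observer, it dominates inter- and intra-observer
variability. This package automates the choice on brightfield whole-slide
images (WSI) and quantifies concordance between selections.

## Pipeline and assumptions

All localization runs at a *working resolution*, an 8-fold block-mean
reduction of a 0.279 µm/px scan (≈ 2.2 µm/px). The assumption is that
hot-spot localization needs the ratio of brown to blue material and
coarse texture, not single-cell detail; nuclei are still a few pixels
wide at this scale.

**Specimen map.** Brightfield glass is bright; tissue absorbs. Each RGB
channel is divided by a morphological background estimate: the opening of
the absorbance image with a disk of radius 100 px — in transmitted-light
polarity a dilation followed by an erosion, i.e. the operator that
removes dark structures smaller than the disk while following slow
illumination trends. This makes the map invariant to global illumination
scaling (the ratio cancels). The equalized B and R channels are
thresholded by Otsu's criterion; *tissue is the below-threshold side*
(stated explicitly because polarity is otherwise implicit), and the two
channel masks are combined by union — union maximizes tissue recall, and
the hemorrhage classifier downstream deals with over-inclusion. Cleanup
is erosion and dilation with disk radius 2 px and hole filling. The
radius-2 elements are small relative to nucleus scale at working
resolution; Otsu runs on the *equalized* channels (the alternative —
raw channels — would reintroduce illumination sensitivity).

**Texture features.** The texture bank uses sum/difference-histogram
features: for displacement $(d_1,d_2)$ (default $(3,3)$ — the
displacement magnitude is the stated parameter, the diagonal direction a
configurable choice),
$s_{k,l} = f_{k,l} + f_{k+d_1,l+d_2}$ and
$d_{k,l} = f_{k,l} - f_{k+d_1,l+d_2}$, with edge replication at borders
(replication avoids spurious border minima later). Eight features are
computed over a disk $\Omega$ of radius 10 px around every pixel, in
their *modified* printed forms — notably energy as
$(\sum_\Omega s^2)(\sum_\Omega d^2)/N_\Omega^2$, a product of sums rather
than the classic histogram energy; fidelity to these modified
definitions is deliberate, and the correlation feature is implemented but
unused by the default classifier (it is selected for no channel).
Features are evaluated by expanding the centered powers into raw disk
sums of element-wise transformed planes, each a single linear filter
pass; the suite verifies bit-level agreement (relative 1e−9) with a
naive per-pixel oracle. The bank spans 8 planes — R, G, B, u(Luv)+C(CMYK),
C, M, Y, K — for 64 layers. The u+C composite min-max normalizes each
plane over the image before summing; CMYK is the naive device conversion
(no ICC management) and Luv assumes sRGB primaries with D65 white, since
no working space is stated for the scanners.

**Hemorrhage removal.** Regions pooled over the bank (mean of each
feature map over the region — the minimal pooling choice) are z-scored,
ranked by the two-class Fisher score
$J = (\mu_1-\mu_2)^2/(\sigma_1^2+\sigma_2^2)$, and the top 25 feed an
RBF-kernel SVM (C = 1, γ = 1/(25·median feature variance); these
hyperparameters are undocumented in the original description and exposed
in the API). Classification tiles the tissue into square patches; a
patch needs ≥ 25% tissue to be classified. Because features within one
disk radius of a hemorrhage boundary are contaminated by it, the
detected mask is grown by that radius before exclusion. The shipped
default feature subset is the 25-index set of the published bank; training
re-derives its own set.

**Hot-spot density.** The u\* channel of CIE Luv is strongly associated
with red/brown content, so DAB-stained cells are deep minima of −u\*.
Marks are the extended regional minima of that plane with depth
$h = 0.1 \times$ (within-tissue dynamic range) — $h$ is unpublished, and
a range fraction makes it exposure-invariant. Extended minima are
computed as the regional minima of the h-minima transform, both via
grayscale reconstruction by erosion (compiled raster-sweep
implementation; the plane is quantized to 1024 levels, the standard way
to define plateaus on float images). Mark *centroids* (the mark/centroid
choice is undocumented; centroids are scale-free) are convolved with a
normalized disk of radius half the FOV diagonal; border marks are
re-weighted by in-bounds kernel mass so the density integrates exactly
to the mark count.

**Field selection.** Greedy: at each step the candidate center
maximizing density × penalty is taken, where

$$\mathrm{penalty} = \max\!\Big(0,\; 1 - \rho \sum_i \frac{1}{d_i}\Big),$$

$d_i$ the distances to already-selected fields *in FOV widths* (the
distance unit is unstated in the source; FOV widths make ρ = 0.2
transferable across resolutions), floored at 0 because many near
selections would otherwise invert preferences. Candidates must have
≥ 80% of their rectangle covered by the hemorrhage-excluded specimen
map and may overlap a selected field by at most 50% — enough to let a
dominant hot spot host several fields (which the method intends) while
preventing degenerate stacking. Every working-resolution pixel is a
candidate; a stride option trades resolution for speed (the shipped
experiments use stride 2, which at working resolution displaces
candidates by at most 2 px).

**ρ calibration.** `calibrate_rho()` scans ρ over {0.1, …, 0.5} in steps
of 0.05, scoring each selection against reference field sets with the
localization concordance measure and returning the LCM-minimizing ρ.
The shipped experiment is a self-consistency recovery: reference
selections that embody ρ = 0.2 dispersion (perturbed by observer-like
positional jitter of 2 working px) are rediscovered by the grid scan as
an interior LCM minimum at ρ = 0.2. A stricter two-route variant —
references built from the ground-truth immunopositive-nucleus density,
calibration on the image-derived mark density — shows the same
qualitative dip but its minimum can drift by one grid step, because
mark-cluster density is systematically flatter than per-nucleus density;
the ground-truth route (`truth_reference_selection()`) remains available
for such experiments.

**Ki-67 scoring.** The per-field counter is deliberately a *stand-in*
with a plug-in contract (the original workflow delegates to a separate
segmentation tool): H-DAB color deconvolution with the standard
published stain vectors, per-channel smoothing, Otsu thresholding
clamped from below at a minimum stain concentration of 0.4 OD (Otsu on a
nearly-unstained channel otherwise splits the background; palette
measurements put true stains ≥ 0.7 and counterstained stroma ≤ 0.31),
hole filling, distance-transform watershed splitting, and a 16-px
minimum component area. DAB components count as immunopositive;
hematoxylin components not majority-overlapped by DAB as immunonegative.
Staining intensity is intentionally not graded. Fields only partially
covered by a hot spot are counted over the whole rectangle — the score
dilution this produces is inherent to the whole-rectangle definition and
is preserved by design.

**Concordance statistics.** For reference fields $i$ with nearest-test
distances $d_i$,

$$\mathrm{LCM} = \sum_i w_i \,\mathrm{sigm}\!\left(\frac{d_i}{4\,\mathrm{FOV}_{size}}\right),
\qquad \mathrm{sigm}(x) = \frac{2}{1+e^{-x}} - 1,$$

with weights $w_i = L_{E,i}/\bar L_E$ (the reference Ki-67 level over
its mean, so weights average 1). The sigmoid is not specified beyond its
two requirements — near fields must matter little and weights must track
the Ki-67 level — and the printed weight denominator is typographically
corrupted in the source; both choices here are documented defaults, the
weight normalization configurable. Kendall's τ_b uses the standard tie
correction and returns NA for constant variables (undefined
denominator); confidence intervals are percentile bootstrap with
B = 100 resamples (the source's "100 order changes" is read as
bootstrap per its surrounding text), seed-mandatory. Agreement tables
drop missing scores pairwise and mark cells with fewer than three shared
slides as not computable.

## The synthetic slide generator

No accession-deposited data exist for this method, so the generator
defines the test surface. It renders, fully determined by one seed:

* bright glass (235, 235, 240) and pale counterstained stroma
  (216, 196, 208) modulated by absorbance micro-texture (0.60–0.85 of
  the tint) with sparse near-glass bright gaps emulating vessels and
  clefts — these gaps are what anchor the morphological background
  estimate inside large sections, as they do in real tissue;
* blue hematoxylin-like (60, 70, 140) and brown DAB-like (120, 80, 40)
  soft-edged nuclei of radius 2.5–3.5 px placed by a hard-core Poisson
  process (minimum center distance two radii: tangential packing, dense
  like tumor tissue but never interpenetrating, so counts stay well
  defined), 100 nuclei per FOV area background rate;
* hot spots (4 disks of radius 150 px) where the rate triples and the
  immunopositive fraction is 15% against a 5% background — values in the
  range reported for grade I/II meningioma;
* hemorrhage patches (2 disks of radius 90 px) of coarse red blotch
  texture, each with its own full-contrast modulation, without nuclei;
* Gaussian pixel noise (σ = 3 of 255).

The proxy slide is 1600 × 1600 px at a nominal 1 µm/px with 128 × 128 px
fields and a working downsample of 2 — chosen so the *physical* working
resolution (≈ 2 µm/px) and the nucleus size in working pixels match the
real 8×-reduced 0.279 µm/px setting; the structuring elements and
texture radii keep their published pixel values at that working
resolution. A real slide is gigapixels; the proxy scales every spatial
extent down ~20-fold while preserving the relations the algorithm
depends on (nucleus/texture/FOV/hot-spot ratios).

What the generator does **not** emulate: chromatic aberration and
scanner-specific color response, stain variability between laboratories,
tissue folds, pen marks, out-of-focus regions, nucleoli and chromatin
texture inside nuclei, and overlapping (as opposed to touching) nuclei.
Passing tests therefore demonstrate the algorithmic contracts — masking,
texture discrimination, density/dispersion selection, counting,
statistics — not robustness to real-world staining variation.

## Numerical choices and degenerate inputs

* Working-resolution geometry is 0-based, (row, col), half-open
  rectangles; all conversions to full resolution go through
  `selection_to_level0()`.
* Otsu on a constant channel is undefined: the channel contributes an
  empty mask with a warning.
* A zero nucleus count makes the Ki-67 index undefined: NA with a
  warning, excluded from slide means.
* Constant-variable τ_b is NA, never 0; degenerate bootstrap resamples
  are skipped.
* The penalty errors on a zero-distance candidate (callers must exclude
  occupied centers); selection stops early when no candidate has a
  positive adjusted score, with a warning if the first step already
  fails.
* Ties in the Fisher ranking break toward the lower feature index; ties
  in the greedy selection toward the first candidate in column-major
  order — both make reruns bit-identical.
* Problem sizes in the shipped tests: 64 × 64 oracle planes, 800 × 800
  working rasters, two to three synthetic slides for calibration —
  sizes chosen so the full suite exercises every stage at realistic
  texture scales.

## Known limitations

* The hemorrhage classifier is trained on synthetic texture; on real
  slides it must be retrained from annotated patches
  (`train_texture_classifier()` takes any 64-column sample matrix).
* The nucleus counter is a documented stand-in, not a reimplementation
  of the original segmentation tool; its contract makes it replaceable.
* Plain tiles only (PNG/TIFF): pyramid-level extraction is emulated by
  block-mean reduction, and physical resolution must be supplied for
  files without embedded metadata (default 0.279 µm/px).
* Fields are axis-aligned rectangles of one size per run; rotated or
  mixed-size fields are out of scope.
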