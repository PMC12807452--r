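---
title: "Methods: punctate colocalization statistics and the scrambling null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: punctate colocalization statistics and the scrambling null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spotcoloc)
```

This vignette documents the statistical procedures, the conventions they
rest on, and the design choices made where more than one reasonable
convention exists. Everything here is descriptive of what the code does;
no empirical claim is made beyond what the test suite and the acceptance
script themselves compute.

## The measurement model

The package treats a punctate fluorescence image as a binary raster with a
known physical pixel size. All analyses are 2D and per-plane. Three kinds of
objects circulate between modules:

* a **binary mask** — an integer 0/1 matrix plus `pixel_size_nm`. Pixel
  `(r, c)` (1-based) has its centre at `(x, y) = (c - 0.5, r - 0.5)` pixel
  units; all distances are centre-to-centre. This single convention is
  stated once and used everywhere, which prevents half-pixel drift between
  the generator, the distance statistics and the scrambler.
* a **particle set** — the connected components of a mask under a stated
  connectivity (default 8, the common particle-analysis convention; 4 is
  available), with per-particle pixel footprints, centroids and areas.
  Areas are always the footprint area `n_px × pixel_size_nm²`, so the
  set-level bookkeeping is exact by construction.
* a **cell geometry** — a simple closed polygon (pixel-unit vertices) for
  the traced cell perimeter, read and written as a two-column CSV.

## Colocalization statistics

**Overlap colocalization.** The two binary channels are multiplied. A
particle is *object-colocalized* when at least one of its pixels lies in the
product mask; *area colocalization* is product pixels over the foreground
pixels of a denominator channel. Published percentages of this kind are
ambiguous about the denominator, and the two directions can differ several
fold whenever the channels differ in abundance, so the package always
computes and reports both directions and tags the convention in the result.

**Compartment classification** assigns each punctum inside/outside an
organelle mask. The default mode is the centroid pixel: puncta are small
relative to compartment masks (PM bands, ER networks), so centroid
assignment is unambiguous and insensitive to footprint raggedness. An
any-pixel mode is provided for analyses where touching should count.

**Nearest distances.** The edge-to-edge distance from an A particle to
channel B is the minimum centre-to-centre distance between any A footprint
pixel and any B foreground pixel (0 when footprints overlap). It is computed
by sampling the Euclidean distance transform of B at A's footprint. The EDT
is the exact two-pass lower-envelope algorithm (implemented in C++), so the
result equals the brute-force all-pairs minimum *exactly* — the test suite
asserts bit-level equality against a brute-force oracle, not approximate
agreement.

**Within-distance fractions and dilation.** The fraction of A particles
within `d` nm of B is the empirical CDF of the nearest distances. Dilation
is defined *through the same distance transform*: a pixel belongs to the
dilation of B by radius `r` when its distance to B is at most `r`. The
dilation route (count A particles touching the dilated B) therefore agrees
with the nearest-distance route identically on every input — a designed
internal-consistency property rather than an approximation to be tolerated.

**Ring (localization-preference) profiles.** Channel A is dilated by an
increasing radius ladder — by convention 20, 40, 60, 80, 100, 200 nm — and
each dilation is multiplied with channel B; the captured fraction of B
foreground is the cumulative occupancy. The normalized profile divides by
the value at the largest radius, so it ends at exactly 1 whenever that
value is nonzero; when it is zero the normalized profile is undefined
(returned as `NA`) and the raw profile is still reported. Radii are
converted to whole-pixel disk radii by rounding, and the residual is kept
as an attribute rather than silently discarded; whole-pixel disks make the
profile bit-reproducible, at the cost of a sub-pixel approximation that is
negligible at localization-map pixel sizes (5 nm/px: 200 nm = 40 px
exactly). The per-annulus variant takes successive differences of the
cumulative profile; both are provided because "cumulative dilation" and
"concentric annuli" are both used in practice for the same figure style.

## The scrambling null

The randomization control must hold particle number and particle sizes
fixed while destroying spatial structure. Each input particle is redrawn as
a circle of radius `sqrt(area/pi)` at a uniform random position inside the
cell perimeter. Design choices, each of which was genuinely open:

* **Whole-footprint containment.** The circle centre must lie at least one
  radius from the perimeter, so the entire footprint stays inside the cell.
  Clipping circles at the boundary would silently destroy the area
  conservation the null is prized for.
* **Non-overlapping placement** (rejection sampling, largest circles
  first, default cap 10 000 attempts per particle). Overlap would shrink
  the union area and bias the baseline downward. An `allow_overlap` escape
  hatch exists for pathologically dense inputs; it is off by default and
  its use shows up in the area diagnostics.
* **Continuous radius; rasterization decides the painted area.** A circle
  of radius `r` paints the pixels whose centres fall within `r`; averaged
  over random centre positions the painted count is an unbiased estimate of
  `pi r²`, so per-trial total-area differences are small and zero-mean, and
  they are *reported* (per trial and averaged) rather than corrected by
  nudging radii. On 50-particle lognormal fixtures (median 16 px, sigma
  0.5) the acceptance script measures the mean absolute difference at well
  under 1 %.
* **Seed ladder.** Trial `k` (0-based) uses `base_seed + k`, so a
  published run is reproducible from one integer. Three trials is the
  default averaging convention.

The scrambled baseline for two *independent* channels converges to the
complete-spatial-randomness expectation: the expected area colocalization of
the scrambled channel equals the partner's foreground fraction within the
cell. The test suite checks this calibration over 20 seeds (3σ of the
simulation mean), and checks placement uniformity with a chi-square test on
a 4×4 occupancy grid (2 000 placements, α = 0.01, expected counts taken
from the rasterized interior).

## The synthetic-scene generator

The generator exists so that every statistic above can be exercised against
known ground truth; it emulates the *geometry* of punctate data, not its
photophysics.

* **Cell**: a star-shaped polygon (24 vertices, radial jitter scaled by an
  irregularity knob in [0, 1)); star-shapedness guarantees simplicity.
* **Organelles**: a PM band (interior pixels within a set distance of the
  boundary), an ER network (minimum spanning tree over random anchors,
  rasterized at a configurable tubule width, default 150 nm — the ER
  tubule calibre reported for the cell types this kind of data comes
  from), sparse ER exit-site pixels on the ER, and one compact Golgi blob.
  All masks are subsets of the interior; ERES ⊆ ER by construction.
* **Particles**: Poisson counts at densities in per-100 µm² (the unit used
  for transcript and cluster densities; a fixed-count override exists),
  uniform placement inside the perimeter with whole-footprint containment,
  lognormal areas (defaults: medians 1691 and 975 nm² for the two
  channels — the median cluster footprints reported for the BK/Ca_V
  system this analysis style comes from — and sigma 0.5, a round value
  chosen once since the source material prints medians but not
  dispersions; densities default to 50 per 100 µm², in the range of the
  printed cluster and transcript densities).
* **Coupling**: each B particle is, with probability `f`, placed with its
  centre uniform in the disk of radius `r_A + delta` around a uniformly
  chosen A particle. This guarantees an edge-to-edge distance ≤ `delta`,
  and at `delta = 0` it guarantees genuine footprint overlap — a
  tangent-only rule at `delta = 0` would rasterize to zero shared pixels
  and make "fully coupled" scenes measure as uncoupled. The ground-truth
  table records every coupled flag and partner, which is what the
  parameter-recovery tests consume.

What the generator does **not** model: PSF blur, localization error,
detector noise (beyond an optional smooth background for binarization
tests), 3D structure, and any biologically motivated clustering of a single
channel beyond the coupling rule. Consequently, passing parameter-recovery
tests shows the *pipeline arithmetic* is faithful; it does not certify
performance on real images with fused clusters or segmentation artifacts.
Within one channel, independently placed particles can touch and merge when
labeled from the raster — realized labeled counts therefore sit slightly
below simulated counts at high densities, which is the same phenomenon real
particle analysis exhibits at the resolution limit.

## Numerical and convention choices

* **Area filter** uses ≥: "smaller than 400 nm² excluded" keeps a particle
  of exactly 400 nm².
* **Median** of particle areas uses lower interpolation on even n (the
  lower of the two middle order statistics); percentile conventions differ
  between tools and this one is stated and tested.
* **Otsu** thresholding refuses constant images; the applied threshold is
  always recorded on the output. Background subtraction is grayscale
  morphological opening with a disc (the flat-kernel analogue of
  rolling-ball), radius default 50 px, both configurable and logged.
* **Degenerate inputs**: empty particle sets report densities of 0 and
  *missing* (not zero) medians and percentages; empty partner channels are
  an error for nearest-distance statistics; zero occupancy at the maximum
  ring radius leaves the normalized profile undefined while the raw profile
  is returned.
* **Determinism**: every stochastic routine takes an explicit seed;
  identical configurations produce bit-identical rasters and byte-identical
  JSON reports (the report writer uses full-precision JSON and no
  timestamps in the machine-readable summary).

## Problem sizes

The test suite and the analysis scripts run on scenes of roughly 250–2100
pixels square with tens to a few hundred particles per channel, and 10–20
replicate seeds for the calibration and recovery suites; these sizes give
sampling noise comfortably inside the asserted tolerances (e.g. ±5
percentage points for coupling-fraction recovery averaged over 10 seeds)
while keeping a full run in the tens of seconds on one CPU.

## Known limitations

* 2D only; no volumetric or per-plane-stack orchestration.
* Overlap colocalization is binary; no intensity-correlation measures
  (Pearson/Manders) are provided.
* The scrambler redraws particles as circles; highly anisotropic particles
  (e.g. ER-hugging patches) are represented in the null only by their
  area, not their shape.
* No inferential statistics between conditions — outputs are descriptive
  per-cell quantities intended for downstream statistical software.
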