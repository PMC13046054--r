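---
title: "Semi-automated lesion annotation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated lesion annotation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammotrace)
```

This vignette is the package's own account of its methods: the live-wire
segmentation model and its parameters, the annotation data model, the
measurement definitions, the synthetic phantom that stands in for clinical
data, and the numerical and design choices made where more than one
reasonable option existed.

## The problem

Building annotated mammography datasets requires outlining lesions on DM
projections and DBT slice stacks, categorizing them with the BI-RADS
lexicon, measuring them, and exporting masks and tables — while guaranteeing
the clinical DICOM sources are never altered. `mammotrace` implements this
as a headless library: stylus interaction is replaced by coordinate files,
which makes every annotation a pure function of its inputs and therefore
reproducible and testable.

## Live-wire segmentation

### Cost model

`compute_cost_map()` derives three per-pixel features from the annotated
slice:

* **Gradient cost** $f_G(q) = 1 - G(q)/\max G$, where $G$ is the Sobel
  gradient magnitude. Strong edges are cheap (0 at the global maximum),
  flat regions cost 1. Normalization is per image, not per tile: all
  segments of one contour then price edges on the same scale. A constant
  image has $\max G = 0$ and yields the valid degenerate map
  $f_G \equiv 1$.
* **Laplacian zero-crossing cost** $f_Z(q) \in \{0, 1\}$: 0 where the
  Laplacian of the Gaussian-smoothed image (default $\sigma = 1$ px)
  changes sign within the 4-neighborhood, with the crossing assigned to the
  pixel of smaller magnitude. This pins paths to the sub-pixel edge locus.
  An exactly zero Laplacian counts as a crossing only when it separates a
  positive and a negative neighbor; without that qualification the all-zero
  Laplacian of a constant image (and the zero far field outside the
  smoothing kernel's support) would spuriously read as one giant edge.
* **Direction feature** $f_D(p,q) \in [0,1]$: with $D(p)$ the unit vector
  perpendicular to the gradient and $L(p,q)$ the bidirectional unit link
  vector oriented so $D(p) \cdot L \ge 0$,
  $f_D = \frac{2}{3\pi}\left[\arccos(D(p) \cdot L) + \arccos(L \cdot D(q))\right]$.
  It is cheap to move along the local edge direction and expensive to cut
  across it. Where both endpoint gradients vanish there is no defined edge
  direction and $f_D$ is set to 0; where only one vanishes, its term
  contributes $\pi/2$ through a zero direction vector. The all-zero
  convention makes path costs on uniform images exactly
  $d \cdot (w_Z + w_G)$ for a $d$-step axial geodesic, which the tests pin
  down.

A step from $p$ to an 8-neighbor $q$ costs
$l(p,q) = [\,w_Z f_Z(q) + w_D f_D(p,q) + w_G f_G(q)\,] \cdot \mathrm{len}(p,q)$,
$\mathrm{len} = \sqrt 2$ for diagonal moves (without the geometric
correction, paths develop a diagonal bias). The default weights are
$(w_Z, w_G, w_D) = (0.43, 0.43, 0.14)$. This split keeps the two edge
detectors (zero-crossing and gradient) dominant and uses the direction term
as a tie-breaker; the classic interactive formulation weighted direction
more heavily because its dynamic training relied on it, which does not
apply to this static, non-training implementation. Weights are exposed and
normalized to sum to one.

### Search

`shortest_path()` runs Dijkstra (compiled, binary heap) on the 8-connected
pixel graph. Ties are broken by the fixed neighbor order N, NE, E, SE, S,
SW, W, NW and FIFO among equal keys, so identical inputs give identical
paths across runs and platforms. `trace_contour()` connects consecutive
waypoints (and last back to first) and, by default, restricts each
segment's search to a bounding box around the waypoint pair padded by twice
their Chebyshev distance (minimum 4 px), clipped to the image. On 2–4K
clinical matrices a full-image search per segment would be wasted work;
the padding leaves room for realistic detours, and `bounding_box = FALSE`
restores the exact global search. Because the features are evaluated at the
destination pixel, the graph is directed: tracing the same waypoints
clockwise and counterclockwise can differ by a pixel here and there (the
package tests require Dice > 0.99 between the two orientations rather than
exact reversal).

Waypoint edits are local by construction: `adjust_waypoint()` recomputes
only the two incident segments and splices every other segment unchanged,
and equals a full retrace of the edited waypoint list exactly.
`add_waypoint()`/`remove_waypoint()` retrace the edited list.

### Freehand mode

`freehand_to_contour()` closes the stroke (appending the first point when
the gap exceeds one 8-connected step), joins samples with Bresenham chains,
and derives display waypoints by uniform arc-length subsampling at about
every 24th chain point (minimum 4) — dense enough to grab and adjust, sparse
enough not to clutter a lesion-sized outline. The spacing is a display
convention only; it does not affect the stored contour.

### Degenerate inputs

Fewer than 3 waypoints (or 8 stroke points) is an error; `start == end`
returns a single-point path of cost 0; constant images trace fine through
the degenerate cost map (paths become straight geodesics).

## Coordinates and conventions

All coordinates are 1-based (row, col) pixel centers, matching R's matrix
indexing; DBT slice indices are 1-based both internally and in every export
and log. A single convention end to end was preferred over the
0-based-internal/1-based-display split common in other languages, since R
is natively 1-based and an internal 0-base would manufacture off-by-one
hazards at every boundary.

## Annotation model and persistence

`morphology()` carries the BI-RADS descriptor heads — mass (shape, margin,
density), calcification (morphology, distribution), architectural
distortion, asymmetry — as closed vocabularies; unknown strings are
rejected at construction and at load, because silent free-text drift
destroys downstream grouping. `validate_morphology()` enforces that mass
sub-descriptors are present exactly when the lesion is a mass, calcification
sub-descriptors exactly for calcifications, and neither for distortion or
asymmetry. Calcified areas are stored as one rough enclosing contour, not
per-calcification marks. Each lesion type has a fixed outline color
(masses red) so downstream renderings are consistent.

Annotations persist in one JSON sidecar per case
(`<case_id>.annotations`, `schema_version` 1.0) written atomically
(temp file + rename) into the case directory. Save-then-load is the
identity, and saving a reloaded set reproduces the file byte for byte —
property-tested on randomized sets. The DICOM sources are never opened for
writing anywhere in the package; `scan_case_directory()` records an MD5
manifest and `verify_unmodified()` re-derives it on demand.

## Measurements

* **Feret diameter**: the maximum pairwise distance between contour
  vertices after scaling rows/cols by the (row, col) pixel spacing —
  continuous geometry on the polygon, not a rasterization-dependent mask
  caliper. Above 500 vertices a convex-hull/rotating-calipers path is used;
  both routes compute the same exact maximum (the farthest pair is an
  antipodal hull pair) and are cross-checked in the tests.
* **Area**: shoelace formula on the scaled polygon, orientation-independent;
  self-intersecting contours are rejected.
* **Equivalent circle diameter**: $2\sqrt{A/\pi}$, and
  `circular_area_from_diameter()` gives $\pi (d/2)^2$ for converting a
  single reference diameter to an assumed cross-section area.
* **Cohort comparison**: `size_comparison()` stores signed per-case
  differences (annotated − reference) with mean and sample (n−1) SD; the
  print method states the direction in words ("annotations larger/smaller
  than reference") instead of relying on a sign convention the reader must
  remember. Measurements are 2-D within the annotated slice; no
  through-plane size is attempted for DBT.

## Rasterization semantics

`rasterize()` fills pixel centers strictly inside the polygon under the
even-odd rule and additionally sets the 8-connected boundary chain, so a
mask always contains its own outline. By Pick's theorem this
boundary-inclusive count exceeds the shoelace area by roughly half the
perimeter plus one: a 41×41 px square contour yields exactly 1681 set
pixels against a shoelace area of 1600. The two quantities converge only
as the region grows — within 2% for smooth shapes upwards of ~100 px
across, which is the regime the area-consistency tests exercise; for small
ROIs the vertex polygon, not the mask, is the measurement of record (and is
what the measurement functions use). `mask_to_contour()` (Moore-neighbor
tracing with Jacob's stopping criterion) inverts rasterization to within
2% in area on the same regime. Self-intersecting polygons are rejected
(`strict = FALSE` applies the even-odd fill regardless, used to score
imperfect traced contours against ground truth).

A traced contour is stored raw; collinear-run simplification — iterated to
a fixpoint so zero-area spikes (pixel, waypoint, same pixel) collapse —
is applied when judging simplicity and counting vertices. A contour that
remains self-intersecting after simplification is rejected when the
annotation is created and again at save time.

## The synthetic phantom

The phantom generator exists so every module can be exercised against known
truth with no clinical data.

* **Background**: inverse-spectral synthesis — white Gaussian noise shaped
  to a $1/f^\beta$ power spectrum, standardized and scaled. Default
  $\beta = 3$, the classical spectral exponent of mammographic structure
  noise, mean level 600 and SD 80 in stored units (12-bit range). This
  reproduces the low-frequency "cloudy" clutter that distracts edge-based
  segmentation, which is what live-wire stress tests need.
* **Lesions**: analytic boundaries — ellipses, star-convex spiculated
  outlines $r(\theta) = R(1 + A\cos(n\theta))$, and calcification clusters
  (bright discs scattered in a containing circle whose ground truth is that
  circle). The lesion adds `contrast × dynamic_range` (default range 1000)
  inside the region, Gaussian-blurred by an edge sigma (default 2 px).
  Ground-truth contours are sampled at 1° (360 vertices), fine enough that
  polygon and analytic Feret/area differ by under 0.1%.
* **Determinism**: the seed fixes pixel content, metadata, UIDs and the
  constant study date, so two generations of the same spec are
  byte-identical — checksummable in tests.
* **DICOM dialects**: DBT is written as a one-file-per-slice series by
  default or as a single multiframe object; the reader normalizes both to
  one ordered stack (slice-location, then instance-number, then file-name
  ordering, with the key recorded).

What the phantom deliberately does not model: projection physics, scatter,
detector blur/noise correlation, anthropomorphic anatomy, dose. Passing the
phantom suite therefore demonstrates algorithmic correctness (optimal
paths, exact geometry, lossless round trips, non-mutation) and
edge-attraction under controlled contrast/blur/clutter — not clinical
segmentation accuracy on real breasts.

## DICOM handling

The package includes a minimal DICOM codec (Explicit VR Little Endian,
single-frame and multiframe, unsigned 16-bit grayscale) covering the
attribute subset mammography work needs: geometry, laterality and view,
pixel spacing, instance/series/study identity. Laterality is read from
ImageLaterality falling back to Laterality, the view from ViewPosition;
missing tags yield `"unknown"` rather than a guess from pixel data. Files
without the DICM magic are kept per case in an `unclassified` list instead
of failing the scan, since clinical folders routinely carry presentation
states and reports. Raw stored pixel values are handed to segmentation
unchanged — no windowing or VOI LUT is applied.

## Numerical choices

Cost-map convolutions (Sobel, Gaussian, Laplacian) are direct small-kernel
shift-add operations rather than FFT products: FFT convolution leaves
~1e−12 residues that would break exact contracts (a constant image must
give $f_G \equiv 1$ and an exactly zero Laplacian) and bit-level
reproducibility across platforms. Dijkstra tie-breaking is fully specified
(neighbor order + FIFO) for the same reason. The brute-force Dijkstra used
to verify optimality in the tests is an independent implementation with no
priority queue at all, kept in the test helpers so it can never share a bug
with the production search.

## Problem sizes in the test suite

The suite runs phantoms at 512×512 (the default disk phantom; 30 traced
contours across three contrast levels and ten seeds), oracle comparisons on
twenty 32×32 and five 64×64 random images, 200 random polygons for the
calipers cross-check, 100 randomized annotation sets for persistence
round-trips, and a 10 000-case simulated cohort for bias/SD recovery —
sizes chosen so the full suite and the acceptance script each complete in
well under a minute-scale budget on one CPU while still exercising every
code path at realistic scale.

## Known limitations

* No interactive "live" preview, path cooling, or on-the-fly cost training;
  the cost map is static and the method is waypoint-connected edge
  following only.
* The DICOM codec reads the dialect it writes (Explicit VR LE) plus
  well-formed files of the same encoding; compressed transfer syntaxes and
  undefined-length sequences are out of scope.
* Measurements are 2-D per slice; DBT lesions get no volumetric size.
* Clockwise/counterclockwise tracing symmetry is approximate (directed
  graph), as discussed above.
* The phantom's realism limits are listed in its section; conclusions about
  clinical accuracy require clinical data.
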