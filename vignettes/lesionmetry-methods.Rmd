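---
title: "Measuring lesion surface area: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lesion surface area: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Chronic-wound care needs repeatable surface-area estimates from equipment a
patient or nurse already has: a phone camera. A single photograph carries no
depth information, so a naive pixels-to-cm² conversion fails as soon as the
skin surface bends or the camera is not exactly perpendicular. `lesionmetry`
implements two complementary estimators:

* **2D, single photo.** A flexible paper ruler printed with a checkerboard of
  known square size is laid next to the lesion, following the skin's
  curvature. Because the ruler bends with the surface, the pixel distance
  between its corner rows measures the *local* scale at each position along
  the ruler. The lesion area is then assembled from many small squares, each
  converted with its own local scale.
* **3D, image sequence.** Structure from motion recovers a sparse surface
  model from an orbiting camera; a reference length fixes the metric scale
  and the area is summed over mesh triangles labelled as wound.

Both paths require only a rough user-drawn region of interest (ROI) around
the lesion.

## The 2D model

### Ruler detection

The grayscale image is analysed with the structure tensor
$J_\rho = G_\rho * (\nabla g_\sigma \, \nabla g_\sigma^\top)$ with gradient
scale $\sigma$ (`gradient_sigma`, default 1 px) and window scale $\rho$
(`window_sigma`). Its eigenvalues $\lambda_1 \ge \lambda_2 \ge 0$ classify
local geometry: one large eigenvalue is an edge, two large eigenvalues a
corner. Corner candidates are local maxima of $\lambda_2$ above
`quality * max(lambda2)`, non-max suppressed.

The tensor window must stay well below the checker square size: at the square
spacing the responses of adjacent corners merge once $\rho$ approaches half a
square. We therefore run a coarse pass with $\rho = 3$ px to estimate the
square size in pixels (the median nearest-neighbour corner distance) and a
second pass with $\rho = $ square/4. This adaptive choice, rather than a
fixed fraction of the square size, is what keeps detection independent of how
many squares are visible.

**Sub-pixel corners.** A checkerboard corner is a saddle point of the
smoothed intensity, locally $g \approx k\,(x-x_0)(y-y_0)$. We fit a quadric
in a 7×7 window and jump to its stationary point when the Hessian is
indefinite. A 1D quadratic fit on the corner *response* is not used: when
the true corner sits between pixel centres the discrete response becomes
bimodal and a per-axis parabola lands up to a pixel off, while the saddle fit
stays exact for any sub-pixel phase.

**Checkerboard classification.** A square window (0.6 × corner spacing) is
placed on each candidate and small patches at its four corners are compared
diagonally: each diagonal pair must agree within 15% of the image intensity
range and the two pairs must differ by more than 25%. The thresholds are the
package's own; only the diagonal comparison itself is prescribed by the
method. Corners of plain (non-checker) objects fail the "both diagonals
internally similar, mutually different" pattern.

**Centerline and pairing.** The Euclidean distance transform of the corner
points has a ridge midway between the two corner rows; we extract it as the
transverse maxima in the corner set's principal-axis frame (the "local
maxima" of the transform are ambiguous between 1D and 2D readings; the
transverse reading is stable on bent rulers) and fit a smoothing spline.
Scanning the image intensity along this midline gives an alternating
dark/light profile; sub-pixel crossings of its mid-level mark the interior
column edges. At each crossing a circular window (0.4 × smallest corner
distance) collects high-$\lambda_1$ pixels and PCA yields the edge line;
walking that line in both directions reaches the nearest checkerboard corner
on each row, giving the pair $(p_1, p_2)$ and the local scale
$d = \lVert p_1 - p_2 \rVert_2$. When two corners are equally close, the one
whose connecting direction best aligns with the edge line wins.

### Grid extrapolation and the area rule

Each pair's line is continued beyond the ruler with points placed every $d$
pixels, forming a quadrilateral lattice over the wound; rows are added until
the ROI bounding box is covered (plus one margin row, capped at 50). Columns
are only grown towards the ROI side — the ruler is placed next to the
lesion, so nothing is measured behind it. Per-pair directions and spacings
are lightly smoothed (moving average over 3 neighbouring pairs): the
direction of a single pair carries ~1° of corner-localisation noise, which
over 15 extrapolated rows would translate into several pixels of lateral
drift and quad overlap.

Every quad maps to one physical square of edge $s$ cm. It is unwarped to a
square patch by the 4-point homography and the wound mask is sampled with
nearest-neighbour lookup; the quad's wound area is
$A_w = (N_w / N)\, s^2$ and the lesion area is the sum over all quads.

Numerical care in the unwarp: output samples are placed at the midpoints of
an $n \times n$ subdivision of the quad (the homography maps the square
$[-\tfrac12, n-\tfrac12]^2$ onto the quad). Corner-anchored sampling puts a
full row of samples on each shared quad edge, which either double-counts
them or — if de-duplicated — systematically loses half a pixel per edge;
midpoint samples tile cleanly. Where a bent grid makes quads genuinely
overlap, a sample is kept only if its position is closest to the owning
quad's centre among the quads containing it, so overlapping regions are
counted once. The unwarp resolution defaults to the median $d$ (at least
16), i.e. roughly one sample per source pixel.

Degenerate configurations are reported rather than silently measured: a quad
shrinking below 25% of its column's first quad ("converging grid") and wound
pixels outside the grid footprint, mirroring the exclusion rules of the
phantom-study protocol.

### Segmentation

The general path is a random-forest pixel classifier over a 24-feature
filter bank: Gaussian smoothings at $\sigma = 1, 2$, gradient magnitude and
Laplacian, per R, G, B, L, a, b channel, followed by Otsu's threshold on the
probability map (256-bin histogram) and ROI masking. Defaults: 100 trees,
unlimited depth, at most $10^5$ training pixels per image, seeded. Both
colour spaces are used because lesion/skin contrast moves between them
across wound types; the exact bank composition and forest hyper-parameters
are this package's own design. Phantom validation uses plain luminance
thresholding instead, one threshold per image, as in the phantom protocol.

## The 3D model

Interest points (minimum structure-tensor eigenvalue) are matched between
consecutive frames with normalized 11×11 patch descriptors (mutual best
match + distance-ratio test). Feature selection is tiled (16×12 tiles,
round-robin by within-tile rank) so darker, lower-contrast wound regions
keep their share of features — a global top-N would starve exactly the
region we need to label.

Two-view geometry is estimated by model selection: RANSAC over both a
homography (4-point, symmetric transfer error) and an essential matrix
(8-point, Sampson error, 1 px, 600 iterations, seeded). Wound surfaces are
smooth and low-relief, where the 8-point problem is quasi-degenerate; the
homography is preferred unless the essential model clearly dominates
(1.5× the inliers). The chosen model's $(R, t)$ — for the homography via its
four-fold decomposition, with cheirality filtering and, between the two
exactly-valid planar interpretations, the plane normal closest to the
optical axis (the acquisition protocol holds the camera roughly
perpendicular to the skin) — is refined by minimising a robustly clipped
Sampson error over the inliers. Poses are chained incrementally from the
consecutive pair with the most inliers; the translation scale of each new
pair is the median ratio between known track depths and their unit-baseline
triangulations. Tracks seen in ≥ 2 posed frames are triangulated linearly;
points with median reprojection error above 2 px are discarded. No bundle
adjustment or loop closure is performed: the target sequences are short
single-sweep orbits.

Isolated points (fewer than 5 neighbours within 2× the median
nearest-neighbour distance) are removed. Colours — and, re-run with the
binary segmentation masks, gray values in [0, 255] — are per-point means
over the track observations. The cloud is meshed by 2.5D Delaunay
(projection onto the total-least-squares plane; wound surfaces are height
fields, so a full 3D Delaunay with surface extraction would be
over-engineering), smoothed by 10 Laplacian iterations with $\lambda = 0.5$
and fixed boundary, and interior holes (boundary loops shorter than 75% of
the longest loop) are fan-filled from their centroids. After scaling with a
manually measured reference length, the wound area is the sum of triangle
areas with at least two vertices whiter than 127; the sum is taken on the
smoothed geometry, matching the processing order of the published pipeline.

## The synthetic phantom generator

Physical validation phantoms — paper shapes of known area photographed on
flat and cylindrical supports with the ruler — are unavailable, so the
package renders synthetic ones with *exact* ground truth:

* Scenes are laid out in the flat chart of the support. A cylinder is
  developable, so wrapping the chart onto it is an isometry and the analytic
  chart area (ellipse $\pi a b$, rectangle $wh$, polygon shoelace) stays the
  exact truth at any curvature. Low and high curvature use the radii of the
  physical phantom supports, 19.5 cm and 8.5 cm.
* Rendering is inverse ray casting through a pinhole camera (no lens
  distortion), 2×2 supersampled so that checker edges antialias and
  sub-pixel detection is meaningful. A half-pixel-aligned edge would
  otherwise rasterise a full pixel off.
* The background is low-amplitude value noise in skin tones; the wound is a
  darker red so that luminance thresholding emulates the per-image manual
  thresholds of the phantom protocol (the generator reports a suggested
  threshold computed from its own colours).
* Defaults: square edge 0.5 cm (the physical square size is not published;
  it is configurable), 3 checker rows, 18 columns (the ruler must span the
  widest shapes, mirroring the protocol's requirement that the phantom lie
  inside the grid), camera 30 cm above the surface with ~17.5 px per square,
  tilt configurable (validation draws it uniformly from [0°, 5°]).
* Mesh phantoms are structured grids (default spacing 0.04 cm) over planes,
  cylinders and spheres with a rectangular chart patch of exact geodesic
  area (developable supports: chart area; sphere: the latitude–longitude
  rectangle formula; "bumpy" planes: converged quadrature of the first
  fundamental form, a numeric rather than closed-form truth). The reference
  segment's true length is the exact 3D distance between two mesh vertices.
  Multi-view renders use a deterministic high-contrast speckle texture — the
  "trackable small structures" of the physical 3D phantoms.

What the generator does **not** emulate: specular reflections (handled
manually in the physical study; the CLI exposes `--manual-point` for the
same repair), lens distortion, colour casts, motion blur, and real lesion
boundary fuzziness. Passing the synthetic suites therefore demonstrates the
geometry and counting machinery under ideal acquisition, not clinical
robustness — the same caveat the phantom protocol itself carries.

## Validation design and problem sizes

The published phantom study reports mean ± SD errors on ~109 images
(flat 4.48 ± 3.90%, low curvature 14.02 ± 9.91%, high curvature
12.00 ± 10.42%, overall 9.86 ± 9.31%) and five 3D phantom videos (all
< 1 cm² and < 5%). The originals are not available, so validation runs
scaled-down synthetic analogues against those printed values as upper
bounds: 20 flat phantoms, 30 mixed-curvature phantoms with ≤ 5° tilt, 10 per
cylinder radius (areas drawn uniformly from 1.13–28.09 cm²), and the five
mesh phantoms at the published sizes (10.8/16.2/21.6 cm² low, 10.8/16.2 cm²
high curvature) with 0.2 mm Gaussian vertex noise standing in for
reconstruction error. The full frames-to-area 3D pipeline is exercised
separately on a 9-view, ±12° orbit of a high-curvature phantom at 480×360 px
with 2000 features per frame; these sizes keep a desk-scale run while
leaving every stage in play. `scripts/acceptance.R` recomputes all of these
end to end; `tests/testthat/` holds the per-operation oracles
(brute-force Otsu, exhaustive nearest-corner distances, 8-unknown
homography solve, closed-form 2×2 eigen-decompositions, empty-circumcircle
checks, closed cube/sphere areas).

## Known limitations

* Tilt is tolerated, not corrected: no perpendicularity check or calibration
  coefficient is applied, so errors grow with camera tilt beyond the few
  degrees the protocol allows.
* The 2D grid extrapolates straight lines in the image; strongly curved
  surfaces are handled only insofar as the local scale $d$ varies along the
  ruler. The cylinder batches quantify the residual error.
* The SfM stage assumes a textured, smooth, mostly rigid scene and a short
  orbit with a roughly surface-perpendicular camera; the planar-twin
  disambiguation relies on that acquisition geometry.
* Reconstruction scale rests entirely on one reference length; its endpoint
  accuracy enters the area quadratically.
* Video decoding is out of scope: frames must be extracted to PNG first.
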