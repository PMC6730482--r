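---
title: "White-matter path-length maps and anisotropic radiotherapy margins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter path-length maps and anisotropic radiotherapy margins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractmargin)
```

## The problem

Glioma cells migrate preferentially along large white-matter bundles, yet the
standard radiotherapy clinical target volume (CTV) for glioblastoma is an
isotropic 1.5–2 cm expansion of the gross tumor volume (GTV). An expansion
that follows the white-matter architecture should cover migrating tumor cells
more specifically: larger margins along bundles connected to the tumor,
smaller margins across them.

`tractmargin` implements the core quantity for such planning: the
**white-matter path-length (WMPL) map**. Given a tractography dataset — a set
of streamlines, each an ordered 3-D polyline modeling a fiber trajectory —
and a target ROI (here, the GTV), each voxel of the map is assigned

> the minimum arc-length distance, measured *along any streamline*, from
> that voxel back to the ROI,

with a sentinel fill value (default −1) in voxels no streamline visits.
Thresholding the map at an expansion path length (EPL) and combining with the
GTV yields an anisotropic CTV that follows the fiber architecture.

## The WMPL algorithm

For each streamline with vertices $p_1,\dots,p_n$:

1. Each vertex is assigned to a voxel of the ROI grid and classified
   ROI-interior or not by voxel membership.
2. Cumulative arc length $c_k$ is the running sum of Euclidean segment
   lengths $\lVert p_{k+1}-p_k\rVert$.
3. The path distance of vertex $k$ is
   $d_k = \min_{m \,\in\, \text{interior}} |c_k - c_m|$ — the nearest
   interior vertex *in either direction* along the polyline, because the
   shortest along-streamline path to the ROI may run backwards.
4. Each vertex deposits $d_k$ into its voxel; the map keeps the minimum
   deposit per voxel. Streamlines with no interior vertex contribute nothing
   and are counted.

Three design choices here were genuinely open and are recorded as package
decisions, not facts about the underlying method:

* **Vertex-based visitation.** A segment crossing a voxel without a vertex in
  it deposits nothing. We made the discretization explicit and controllable
  instead of hiding it: `densify()` inserts collinear vertices so no segment
  exceeds a cap (the pipeline default is half the smallest voxel size), which
  preserves total arc length to within 1e-9 relative while bounding the
  visitation gap. No partial-segment distance is interpolated into boundary
  voxels; this keeps the brute-force oracle trivially exact and is the main
  known approximation.
* **ROI membership is voxel membership.** A vertex is "in" the ROI iff its
  voxel is set, not when it lies within some Euclidean distance of the ROI
  surface. Distances are defined *along streamlines back to* the ROI, so the
  grid-consistent definition is the voxel one.
* **Distance to the nearest interior vertex, not to first entry.** "Shortest
  path along any streamline" is a minimum over directions.

`path_length_oracle()` re-implements the same contract by exhaustive
per-vertex-pair enumeration with no shared code, and the test suite requires
*exact* equality between the two on randomized phantoms (lines and arcs,
jitter on and off, anisotropic voxels). Both implementations accumulate arc
length by sequential double-precision addition so that the comparison is
meaningful at the last bit.

## Coordinate frames

TrackVis TRK streamline coordinates are voxel-size-scaled with corner origin:
voxel $(i,j,k)$ spans the half-open box
$[i\,v_x,(i{+}1)\,v_x)\times\cdots$, its center sits at
$((i{+}0.5)v_x,\dots)$, and voxel lookup is
$\lfloor \text{coordinate}/\text{voxel size}\rfloor$ after axis reordering.
Points exactly on a boundary belong to the higher-index voxel; this tie rule
is asserted in tests because determinism of the voxel assignment matters more
than which side wins.

`reconcile_affine()` builds the 4×4 map from grid voxel indices to streamline
point coordinates using the *orientation labels* (the TRK `voxel_order`
against the NIfTI orientation codes), never dimension-matching heuristics —
equal-dimension cubic grids would make those ambiguous. Axis flips
(e.g. LPS grid against RAS streamlines) become sign flips plus
$\text{dim}-1$ offsets. Whether real inputs ever arrive in mismatched
orientations, the reconciliation path stays fully general and is exercised by
corner-voxel enumeration and whole-grid round-trip tests.

## Streamline selection and tracking

* `target_streamlines()` keeps exactly the polylines with at least one
  ROI-interior vertex — the "GTV-connected" subset of a whole-brain
  tractogram.
* `cluster_confidence()` scores each streamline by the Cluster Confidence
  Index: resample to a fixed number of equally spaced vertices, compute the
  minimum average direct-flip (MDF) distance to every other streamline, and
  sum $(1/\text{MDF})^{\text{power}}$ over neighbors within a distance cap.
  Isolated outliers collect (near) zero. Defaults — 12 sample points,
  power 1, 5 mm cap, threshold 1 — mirror the standard reference
  implementation of the index, since only "default parameters" are specified
  for the original analysis; all are exposed. Exact-duplicate pairs
  (MDF = 0) are excluded from the sum so the score stays finite, and
  duplicates are counted. Because it is not established whether outlier
  filtering belongs in the quantitative path or only in visualization, the
  pipeline makes CCI filtering opt-in, default off.
* `track_deterministic()` is a minimal deterministic tracker over a supplied
  per-voxel principal-direction field: one seed at the center of every voxel
  with FA above 0.15, bidirectional fixed-step propagation along the local
  direction sign-aligned with the incoming heading, terminating on
  FA ≤ threshold, turning angle > 60°, grid exit, or a length cap. FA and
  directions are looked up nearest-voxel rather than trilinearly — this keeps
  phantom expectations exact and is a documented simplification relative to
  full q-ball/ODF tracking pipelines, which are out of scope. Only
  one-seed-per-voxel is supported; a deterministic sub-voxel seeding scheme
  would add arbitrary choices without a defining reference.

## CTV construction

`build_anisotropic_ctv()` computes
$\big((\text{GTV} \cup \{\text{WMPL} \le \text{EPL}\})
\oplus r\big) \cap \text{brain}$, with EPL thresholds of 10, 20 and 30 mm by
default, a final $r = 5$ mm expansion to suppress small contour islands, and
brain clipping. The threshold is inclusive and excludes the fill value, so a
WMPL of exactly the EPL is still in-target. The isotropic control is a 20 mm
metric dilation of the GTV; the island-suppression expansion is *not* applied
to it (it belongs to the union construction), and whether the control is
brain-clipped is configurable (default: clipped, as tissue outside the brain
is never a target).

Dilation is **metric**: a voxel is included iff its center lies within $r$
world-mm of a source voxel center, computed by an exact separable squared
Euclidean distance transform (lower-envelope-of-parabolas) with anisotropic
spacings — correct for the 1.09 × 1.09 × 2 mm voxels typical of the intended
acquisitions, where structuring-element approximations are not. The
acceptance suite measures the reach of the 5 mm expansion empirically on a
0.5 mm grid against a brute-force distance computation; the tolerance is half
a voxel diagonal, the resolution limit of a center-based criterion.

`extract_slice_contours()` traces each axial slice into closed polygons along
voxel boundaries (interior on the left; at checkerboard corners the sharpest
left turn keeps touching regions as separate simple loops, and holes emerge
as separate polygons). Even-odd rasterization at voxel centers inverts it
exactly, which is the property a contour hand-off to a planning system must
preserve. No separate island-removal pass exists beyond the 5 mm expansion;
none is defined for the original procedure.

`compare_ctvs()` reports world-mm³ volumes, the percent difference
$100\,(V_a - V_b)/V_b$, and recurrence coverage fractions. The percent
difference is antisymmetric under argument swap only up to the differing
denominator; this is documented and tested numerically rather than hidden.

## Phantoms: what they emulate and what they do not

The patient imaging behind the original analysis is not publicly available,
so `make_phantom()` generates the study inputs synthetically: line and
circular-arc bundles with known geometry, an FA volume (0.8 inside a
two-voxel corridor around each curve — wide enough to give the tracker a
well-posed domain — and 0 outside), a tangent direction field, and
sphere/box ROI masks. Jitter is Gaussian, applied as a constant per-streamline
offset in the plane orthogonal to the curve tangent, truncated at 3 sd so
curves stay in-grid and arc-length expectations survive approximately.
Generation is a pure function of the spec including its seed.

For jitter-free bundles `expected_wmpl()` returns closed-form path lengths —
distance along the line, or radius × angular offset for arcs — with a stated
tolerance of half the vertex spacing plus the chord-vs-arc deficit
$L s^2 / (24 r^2)$. The headline analytic check: on a noiseless
quarter-circle of radius 20 mm sampled at 1 mm, the WMPL at the far end must
match $10\pi \approx 31.4159$ mm within 0.05 mm.

What passing these tests does **not** show about real data: phantoms have no
crossing fibers, no noise in the direction field, no partial-volume FA, and
bundle geometry far simpler than peritumoral anatomy; the tracker here is a
contract-checking tool, not a replacement for a full reconstruction chain.
The phantom results validate the *path-length and margin machinery*, not any
clinical claim. The original cohort's clinical numbers (median 19 % smaller
target volumes; 2 of 3 marginal recurrences covered) depend on that
unavailable imaging and are deliberately not reproduced here; the package
instead demonstrates the qualitative mechanism — a recurrence planted along a
bundle beyond the isotropic margin but within the bundle's path length is
covered by the anisotropic CTV and missed by the control — as a property
test.

## Numerical choices and problem sizes

* Fill value −1 (configurable); written into the NIfTI sidecar JSON.
* Boundary ties: floor on half-open boxes (higher-index voxel wins).
* Dilation inclusion uses `d² ≤ r² + 1e-9` — an absolute slack far below
  half the squared voxel spacing of any supported grid, so no discrete
  offset can flip category.
* Voxel-size agreement between streamline header and grid is required to
  1e-3 mm; affine column norms must match voxel sizes to 1e-6 relative.
* Uniform-scaling covariance is tested with factor 2, where IEEE arithmetic
  makes the scaling exact and the equality check meaningful bitwise.
* Test and acceptance problem sizes — grids of 10–60 voxels per axis, tens
  of streamlines, 50 randomized oracle-equivalence phantoms — were chosen so
  the full suite completes in well under a minute while every code path
  (anisotropy, flips, jitter, arcs) is exercised; the quantities being
  checked (exact oracle equality, closed-form arc lengths, metric reach) do
  not sharpen with scale.

## Known limitations

* Vertex-based voxelization can miss grazing voxels even after
  densification; the bound is the densify step, half the smallest voxel
  size by default.
* Distances are deposited only at vertices; no partial-segment interpolation
  into boundary voxels.
* The tracker's nearest-voxel interpolation produces blockier trajectories
  than trilinear schemes.
* TRK is the only streamline dialect (no TCK/VTK); NIfTI-1 the only volume
  format; no image resampling or registration — inputs must share a grid.
* DICOM-RT export and treatment-planning-system integration are out of
  scope; `extract_slice_contours()` provides the vendor-neutral hand-off.
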