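---
title: "Measuring archosaur hindlimb joint poses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring archosaur hindlimb joint poses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointpose)
```

## The measurement model

A joint pose is the rigid relationship between two adjacent limb segments.
`jointpose` measures it the way the human-biomechanics community does for
the knee: each segment carries an *anatomical coordinate system* (ACS) — an
origin plus a right-handed orthonormal triad derived from the segment's own
articular morphology — and each joint is measured by a *joint coordinate
system* (JCS) built from the fixed (proximal) and mobile (distal) ACS of
its segment pair. Three conventions pin everything down:

* **Rotations** are intrinsic Z–Y–X Tait–Bryan angles of the relative
  rotation `R_rel = Fᵀ M` (F, M the world-frame axis triads of the fixed
  and mobile ACS):
  `R_rel = Rz(FE) · Ry(ABAD) · Rx(LAR)`.
  Flexion–extension turns about the fixed ACS Z, long-axis rotation about
  the mobile ACS X, and abduction–adduction about a floating Y that stays
  orthogonal to both. The two body-fixed axes need not stay perpendicular
  to each other; any nonzero ABAD drives the Z–X angle away from 90°.
* **Translations** are the components of the vector between the two ACS
  origins measured along the *fixed ACS* axes (not the JCS axes, which can
  be non-orthogonal).
* **The reference pose** is the configuration in which every mobile ACS is
  exactly registered onto its fixed ACS, proximal to distal, starting from
  a ground-based pelvic ACS. All six DOF are zero at every joint there, by
  construction; the limb is collapsed and bone models interpenetrate, which
  is expected and harmless. The `assemble_reference_pose()` +
  `decompose_pose()` zero check is the basic consistency test of any ACS
  set, and right/left reference-pose asymmetries are a practical
  diagnostic for patch-selection or fitting errors (`cmd_refpose()`
  reports both).

Segments are represented by their *T-shaped principal vectors*: a long axis
between the proximal and distal primitive centroids and a transverse axis
(a fitted cylinder axis, or a landmark pair in the dynamic foot). The two
are deliberately **never re-orthogonalized** against each other;
orthonormal triads arise purely through the cross-product sequences, so
genuine anatomical obliquity (e.g. condylar skew) propagates into the
coordinate systems instead of being erased. A guard rejects T pairs within
5° of parallel, where the cross products become ill-conditioned; real limb
geometry sits far from this bound.

### Asymmetry by design

The ACS constructions differ between sides (subtraction orders and one
cross-product order flip) so that *equivalent anatomical motions have equal
sign and magnitude in both limbs*: extension, abduction and external
long-axis rotation are positive at hip and ankle on both sides. The knee is
the one exception — keeping its triads right-handed forces its ABAD
convention to reverse (adduction positive), which `label_pose()` translates
into anatomical vocabulary per joint. The mirrored-limb test in the suite
drives one limb with transforms constructed by reflecting the other limb's
motion through the sagittal plane and verifies numeric equality of all
rotation time series.

### The pelvis pseudo-joint and the ground ACS

Pelvic position and orientation are measured against a non-anatomical
ground ACS whose Z is exactly world-up; rotations read as yaw
(counter-clockwise positive in dorsal view), pitch (nose-up positive) and
roll (right-acetabulum-up positive). The horizontal heading of the ground X
axis is user-defined; note that the pelvic ACS X points *caudally*, so a
heading chosen opposite to the direction of travel makes a level, forward-
facing pelvis read near-zero yaw.

## Primitive fitting

All articular inputs are patches: named subsets of mesh faces. Fitting is
geometric least squares throughout, deterministic, with no random
restarts:

* **Sphere** — algebraic (linear) initialization, then Levenberg–Marquardt
  on the radial residuals `|pᵢ − c| − r` (relative tolerance 1e-10, max
  200 iterations).
* **Cylinder** — each principal direction of the point cloud seeds a trial
  axis; axis position and radius are initialized by an algebraic circle fit
  of the points projected perpendicular to the trial axis, then all five
  parameters are refined by Levenberg–Marquardt on the point-to-surface
  distances. The converged trial with the lowest residual wins. A warning
  is raised when the patch covers under 30° of arc about the fitted axis,
  where orientation becomes poorly identifiable. The reported centroid is
  the midpoint of the extremal projections of the patch vertices onto the
  fitted axis line — a reproducible, mesh-extent-aware stand-in for the
  "centroid of the cylinder", which commercial fitting tools leave
  unspecified.
* **Plane** — total least squares (smallest singular vector of the
  centered vertices). The reported centroid is the *area-weighted* centroid
  of the patch faces projected onto the plane, so sliver triangulation
  cannot bias the origin; with bare point input the vertex mean is used.

Fitted axes and normals are sign-ambiguous. All anatomical sign conventions
("axis positive laterally", "positive cranially") are enforced by optional
per-patch *reference directions* — unit vectors supplied with the patch
file that only ever flip a sign and never influence the fitted geometry.
The same vectors back the direction assertions that `cmd_build()` reports.

The suite checks the fitters against independent oracles: a
centre-candidate grid search with Nelder–Mead polish for the sphere, and an
exhaustive 2° spherical grid over axis orientations (each scored by an
algebraic circle fit) for the cylinder, plus rigid-motion and scale
equivariance and local-minimum properties.

## The pedal coordinate system

Feet with a fused or tightly bound metatarsus get a static ACS: long axis
from the proximal-plane centroid to the metatarsal-III condylar cylinder
centroid, transverse axis from that cylinder. Unfused, mobile metatarsals
(crocodylian-like feet) get a *dynamic* ACS recomputed every frame: the
distal point is the midpoint of the medial-most and lateral-most condylar
landmarks and the transverse axis runs between them, so intermetatarsal
spread and skew enter the measured ankle pose. Any consistently trackable
point pair on the outermost metatarsals may serve as landmarks; the
synthetic generator uses the condylar cylinder centroids. With the
metatarsals frozen, the two formulations coincide (the generator places
the MT-III condyle at the midpoint of the outer pair, and the suite checks
agreement to 1e-6°); under scripted spread/skew the dynamic transverse
axis rotates within the foot while the segment-fixed MT-III axis cannot.

## Numerical choices

* Orthonormality/right-handedness of every ACS is validated at 1e-9;
  rotation matrices re-orthonormalized via SVD after text round-trips and
  long composition chains.
* Euler extraction clamps the `asin` argument to [−1, 1]; ABAD is
  restricted to the principal range [−90°, 90°]. At |ABAD| = 90 (detected
  at |cos ABAD| < 1e-8) the FE and LAR axes are collinear, only their
  combination is determined, and the decomposition reports that
  combination as FE with LAR = 0 and raises `gimbal_flag` — a convention,
  chosen because no tie-break is anatomically meaningful there. The
  package flags the singularity; it does not re-parameterize across it.
* `find_gimbal_singularity()` sweeps ABAD through the forward composer,
  brackets where the world Z/X line angle falls below the detection
  threshold (1e-6 rad), and then polishes to the actual collinearity point
  by secant iteration on the (linearly vanishing) line angle. The
  threshold crossing itself sits a threshold-width short of the
  singularity by construction, so the polished value — 90° to ~1e-9 — is
  the reported quantity.
* `compose_pose()` rejects |ABAD| ≥ 90 (outside the principal range, where
  the floating-Y sign flips and the representation stops being unique).
* An optional unwrapping pass (`unwrap_deg()`, `limb_pose_table(unwrap =
  TRUE)`) restores continuity of FE/LAR time series across ±180°; raw
  principal values are always kept alongside.
* Transform CSVs store rotations as unit quaternions (scalar-first), which
  round-trip through text far better than raw matrices; a 9-element
  row-major rotation dialect is also accepted. Pose tables round-trip all
  numeric fields within 1e-9. Units are millimetres and degrees
  throughout.
* Meshes and patch files are 1-based inside R (the native convention);
  OBJ is 1-based on disk and the patch JSON interchange format is 0-based,
  both converted at the I/O boundary.

## What the synthetic generator does and does not emulate

`generate_limb()` builds bones as unions of primitive-capped pieces —
spherical caps, cylinder bands, flat disks, plus unlabelled connecting
shafts — with guineafowl-like default dimensions (70/110/55 mm
femur/crus/pes, 15° condylar skew, 40 mm acetabular separation) and an
optional crocodylian-like unfused pes (outer condyle pair 24 mm apart).
Labelled patch vertices lie *exactly* on their generating primitives, so
fitted parameters can be compared against exact truth; optional isotropic
Gaussian vertex noise emulates segmentation/mesh error. The default mesh
resolution (128 angular subdivisions, a few thousand vertices per
articular patch) approximates the polygon density of CT-derived bone
models; unit tests that exercise exactness rather than estimation error
use coarser meshes (10–32 subdivisions) for speed.

What passing tests show: the coordinate-system constructions, the Euler
machinery, the chain kinematics and the fitting estimators are correct and
mutually consistent, and estimation error under realistic mesh density and
noise stays within ~0.4° of joint angle at noise of 0.5% of femur length
(0.35 mm; verified across seeds, worst observed 0.42°, with a fixed test
seed near that worst case). What they do not show: robustness to the
things real specimens add — subjective patch selection, cartilage,
taphonomic deformation, partially non-cylindrical condyles — none of which
the primitive-capped geometry emulates. The generator validates the
*measurement machinery*, not the anatomical judgment upstream of it.

Gait scripts are smooth sinusoidal excursions (defaults well inside
|ABAD| ≤ 85°; `stress = TRUE` permits singularity-stress trials). The
suite's end-to-end check generates a limb, animates it with the exact
ground-truth ACSs, re-estimates everything from the noisy meshes, and
requires the decomposed trajectories to match the script within 0.5°
(10 frames, one stride).

## Known limitations

* Whole segments are required: a knee JCS needs a complete femur and crus,
  so fragmentary fossils need alternative ACS constructions out of scope
  here.
* Only inter-segment motion is measured; patellar, fibulo-tibial and
  intermetatarsal kinematics beyond the dynamic pedal transverse axis are
  not represented.
* Exact numeric agreement with primitives fitted by commercial packages is
  not claimed; their objectives are unpublished. The fitters here are
  plain geometric least squares with stated tolerances, and the oracle
  cross-checks bound their behaviour.
* Cartilage-bearing surface models can in principle be processed through
  the same machinery (the patches just lie on cartilage), but no
  cartilage-specific support is provided.
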