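---
title: "Conformal lattice toolpaths and discretization accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal lattice toolpaths and discretization accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchpath)
library(ggplot2)
```

## The problem

Extrusion bioprinting of scaffolds onto curved anatomical surfaces — a
cartilage patch on a humeral head, say — cannot use conventional planar
slicing: flat layers produce stair-stepped filaments that do not conform to
the anatomy. `patchpath` implements a *non-planar* alternative. The target
surface, a triangulated patch in STL form, is intersected with two
orthogonal families of parallel vertical planes; each intersection is a
curve lying on the surface; ordering, resampling and concatenating these
curves yields a single lattice deposition path that follows the surface
everywhere. The path is then checked against a kinematic model of the
4-DOF desktop arm that will execute it, to confirm that the chosen waypoint
spacing cannot be distinguished from the ideal trajectory at the arm's own
repeatability.

Two parameters govern the construction, both in millimetres:

* **interplanar distance `d`** (default 1 mm) — the spacing of the slicing
  planes and therefore the pore pitch of the printed lattice;
* **spatial step `S` = `max_step`** (default 2.09 mm) — the maximum distance
  between consecutive path waypoints. The default is not arbitrary: it is
  the coarsest step for which the circle benchmark below stays under the
  0.05 mm repeatability of the arm.

## Slicing model and its conventions

Several geometric conventions are genuinely open choices; the ones used
here are:

* **Plane placement.** For a mesh spanning `[lo, hi]` along the slicing
  axis, planes sit at `lo + k·d`, strictly inside the interval. Boundary
  planes would only graze the patch rim, so they are excluded; a 10 mm
  plate with `d = 1` therefore gets exactly 9 planes per family, and plane
  counts are deterministic and testable.
* **Tangential contacts.** Plane–triangle intersection uses symbolic
  perturbation: a vertex lying on the plane counts as lying on the positive
  side. A coplanar triangle or an isolated vertex touch contributes
  nothing, while a mesh edge lying exactly in a slicing plane is emitted
  once — by the triangle on the negative side — never twice. This matters
  in practice: with a structured grid mesh whose pitch divides `d`, *every*
  contour is such an edge-in-plane case.
* **Upward faces only.** Faces with downward normals are skipped: a
  vertically held nozzle can only deposit on upward-facing surface, and the
  synthetic fixtures are height fields by construction for the same reason.
* **Ordering.** Within a plane, contour points are ordered monotonically
  along the in-plane horizontal coordinate (y for an x-normal plane and
  vice versa). Height fields make this ordering strict; for general meshes
  a contour is split wherever the sweep coordinate reverses, an extension
  beyond what height-field patches need.
* **Tolerances.** Geometric predicates use 1e-9 mm, endpoint chaining
  1e-6 mm — both far below the 0.05 mm repeatability floor, so they cannot
  influence any physical conclusion. Vertex merging at load time uses
  1e-9 mm for the same reason.

Resampling subdivides each contour chord into `ceiling(length / S)` equal
parts. Subdivision points lie *on* the original polyline, so resampling
never adds geometric error; it only bounds the waypoint spacing.

## Lattice assembly

The two families are deposited in one pass, X-family lines first, then
Y-family (a `layers` option replays the path with the family order swapped
on alternate layers and a caller-supplied `layer_height`; no default layer
height exists because filament height depends on ink and nozzle, which are
outside this package's scope). Within a family the lines are ordered
serpentine-fashion — every second line reversed — and consecutive lines are
joined by a straight *travel* move, the shortest 3D vector between the
previous end and the next start. Travel moves are straight segments by
design; a z-hop or surface-following retreat would need extrusion control
that is likewise out of scope.

```{r lattice-demo, fig.width = 5, fig.height = 4.5}
cap <- make_spherical_cap(cap_diameter = 20, sphere_radius = 25,
                          resolution = 0.5)
path <- generate_lattice_path(cap, d = 1, max_step = 2.09)
path_metrics(path)
autoplot(path)
```

On the flat-plate limit the construction reduces exactly to the classic
planar grid infill (all z = 0, pitch = `d`), which is the strongest simple
oracle for the whole slicing stack and is asserted in the test suite.

## The arm model

The simulated arm matches the topology of MG400-class desktop arms: base
yaw, a parallelogram-constrained shoulder/elbow pair that keeps the tool
vertical, and a wrist yaw. With link lengths `L1..L4` the forward map is

```
r = L2 sin(t2) + L3 cos(t3) + L4
x = r cos(t1),  y = r sin(t1)
z = L1 + L2 cos(t2) - L3 sin(t3)
yaw = t1 + t4
```

The parallelogram form was chosen over a free 4R chain because the physical
device mechanically constrains the end-effector vertical — which is also
precisely what a deposition nozzle needs. Inverse kinematics is analytic
(two-link planar problem in the `(r, h)` plane); the elbow-up branch is the
default because it is the device's working posture, with elbow-down behind
an argument. Joint limits are checked and produce warnings rather than
errors: paths are expected to be constrained to the central workspace by
construction, and hard failures would mask the more informative
reachability error. Dynamics — backlash, compliance, velocity profiles —
are deliberately absent; trajectory quality is judged purely as positional
deviation under ideal actuation.

## The circle benchmark

Accuracy of a discretized trajectory cannot be defined on an arbitrary
anatomical surface, so a circle of diameter D = 20 mm is used as the
analytic reference. `N` waypoints are placed uniformly on the circle and
the closed polygon through them is executed; with chord interpolation the
executed path is the inscribed polygon, sampled densely (M = 200 points
per chord, uniform, shared endpoints counted once). Every sampled point's
distance from the centre is recorded; the mean radius and the sample
standard deviation of those radii summarise how far the polygon is from
the ideal circle:

```{r benchmark, fig.width = 5, fig.height = 3.5}
arm <- arm_model()        # repeatability 0.05 mm
rep <- discretization_report(arm, N_list = c(5, 10, 20, 30), D = 20)
knitr::kable(as.data.frame(rep), digits = 3)
autoplot(rep)
```

The spatial step per waypoint is `S = pi * D / N` (`spatial_step()`); its
reciprocal, waypoints per millimetre of arc, is available as
`discretization_density()`. As `N` grows the mean radius rises toward the
ideal 10 mm and the deviation falls; at `N = 30` (S = 2.09 mm) the
deviation is ≈ 0.02 mm, below the 0.05 mm repeatability — the arm cannot
physically distinguish this discretization from a perfect circle, which is
what justifies `max_step = 2.09` as the default for lattice resampling.
Two deliberate statistic choices: "deviation" is the standard deviation of
sampled radii about their *mean* (an RMS-from-ideal column is also
reported, and is the stricter of the two), and the chord model is the
reference interpolation because it is geometry-only — the test suite
verifies that its statistics are bit-identical across different arm
geometries, while `joint_linear` mode (IK–interpolate–FK) converges to it
as waypoints densify and is retained for arm-specific studies.

The mean radius is bounded above by D/2 for any chord-interpolated
trajectory — chords lie inside the circle. Reported mean radii of an
executed physical trajectory can approach the bound faster than the chord
model predicts if the controller's interpolation weights samples toward
the waypoints themselves; since the interpolation scheme of any given
firmware is unknown, only the `N = 10` mean and the `N = 30` deviation —
which the chord model reproduces — are treated as reference values, and
the coarser/finer rows are checked as bound-plus-monotonicity properties
instead.

## Synthetic fixtures

No public anatomical patch mesh exists, so the package generates its own
stand-ins (all deterministic, all height fields):

* `make_spherical_cap()` — the demonstration geometry; the default
  (sphere radius 25 mm, footprint diameter 20 mm) has the same footprint
  scale and smooth convex curvature as a humeral-head patch. Vertices lie
  on the sphere to floating-point accuracy, so surface membership of
  sliced contours can be checked against the sphere equation in closed
  form; the apex sagitta `R - sqrt(R^2 - (D/2)^2)` is another closed-form
  oracle.
* `make_wavy_patch()` — a sinusoidal height field for irregular-surface
  stress tests, with an optional seeded vertex jitter.
* `make_flat_plate()` — the planar-limit oracle.

What the fixtures do *not* emulate: anatomical noise, scanning artifacts,
holes, or non-height-field overhangs. Passing tests therefore demonstrate
correctness of the geometry pipeline, not robustness to defective
real-world scans — an STL from a segmentation pipeline should be inspected
(`mesh_summary()` reports degenerate-face counts) before slicing.

## Problem sizes and determinism

The shipped examples and tests use fixture resolutions of 0.5–1 mm
(thousands of faces) and benchmark sampling M = 200, sizes at which every
quantity here recomputes in seconds while leaving the reported statistics
converged (halving M changes the N = 30 deviation in the fourth decimal).
Nothing in the default pipeline is stochastic: the only randomness anywhere
is the optional fixture jitter and test-case sampling, both seeded.

## Limitations

* Single-surface paths: no volumetric multi-layer slicing with adaptive
  interplanar spacing.
* No collision avoidance, joint-motion optimisation or dynamics — the
  simulator validates spatial discretization only.
* STL in, CSV/JSON out; no PLY/OBJ, no mesh repair.
* Extrusion (flow rate, crosslinking, dwell) is entirely out of scope: the
  exported path is what a robot driver would consume, not a complete
  printing program.
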