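---
title: "Registration, reproducibility and average shape models for 3D hand scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration, reproducibility and average shape models for 3D hand scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handmorph)
```

## The problem

A 3D stereophotogrammetric capture of a hand is a triangle mesh of its skin
surface, in millimetres. Two analyses make such meshes clinically usable:

1. **Reproducibility.** If the same hand is captured twice (say a week
   apart), how similar are the two surfaces after the best rigid alignment?
   The answer bounds what longitudinal changes the modality can detect. The
   hand is harder than the face here: subjects cannot hold their fingers
   perfectly still, so the error budget mixes true sensor noise with
   physiological articulation.
2. **Averaging.** To describe a population (or compare groups such as male
   and female hands), repeated landmark sets must be brought into one frame
   and averaged, with a per-landmark measure of residual variation.

`handmorph` implements both, plus a synthetic articulated hand generator
that stands in for clinical scans so that every claim the package makes is
testable by construction.

## The synthetic hand and what it emulates

`generate_hand()` builds a schematic hand: a palm slab (width × length ×
thickness, default 80 × 95 × 24 mm) joined to five capsule-shaped digits in
a fully spread pose, with defaults near an adult female hand (finger
lengths 58–80 mm). The geometry is deliberately schematic: the algorithms
under study are geometry-generic, and a slab-plus-capsules surface already
has the two features that matter — a rigid palm and independently mobile
digits with a region decomposition. Each hand comes with:

* a **24-landmark set** (`hand24` schema): per digit the tip, a distal and a
  proximal joint point on the dorsal skin, and the knuckle base, plus four
  palm-boundary landmarks. Joint landmarks sit on the skin surface, not on
  the bone axis — a digit's four landmarks are coplanar but never collinear,
  which keeps per-digit rigid fits well posed;
* a **region map** assigning every vertex to palm, thumb, index, middle,
  ring or little.

Generation is a pure function of its parameters: identical parameters give
bit-identical meshes. Scaling all lengths by a factor `s` (the `sex_scale`
parameter) scales the vertex array exactly, so size contrasts propagate
through the pipeline undistorted.

`simulate_repeat_acquisition()` emulates the second capture: each digit
rotates by a random flexion angle about its base landmark (affecting only
that digit's vertices, with a 3 mm linear blend at the knuckle so the
surface does not tear), then one global rigid pose change is applied, then
isotropic Gaussian noise displaces every vertex. Landmarks ride along with
the articulation and pose maps. The motion magnitudes default to 3° of
articulation per digit, 5°/10 mm of global pose change and 0.1 mm of sensor
noise — values chosen once as a plausible "subject tried to hold still"
regime; they put the fingertips a few millimetres from their first-capture
positions while the palm moves only with the global pose, which is the error
structure repeat hand captures exhibit.

`generate_cohort()` draws subjects log-normally around sex-specific medians
(male median = female median × `male_scale`, default 1.1, i.e. a hand about
10% larger in every length — broader base and longer fingers). The default
between-subject spread (log-sd 0.04 per length) is a modest, realistic
anthropometric variation.

What the generator does **not** emulate: real skin detail, per-phalanx
kinematics, capture holes/occlusions, or landmark placement error by a human
observer. Tests passing on synthetic cohorts therefore demonstrate
correctness of the algorithms under the stated motion model, not clinical
performance on 3dMD-style data.

## Rigid registration

**Kabsch.** For corresponded point sets the optimal rigid map is closed
form: centre both sets (weighted centroids), form the cross-covariance
`H = Σ wᵢ (sᵢ − s̄)(tᵢ − t̄)ᵀ`, take `H = UΣVᵀ`, and set
`R = V diag(1, 1, det(VUᵀ)) Uᵀ`, `t = t̄ − R s̄`. The determinant correction
returns the best *proper* rotation even when a reflection would fit better
(e.g. registering a hand to its mirror image), which is essential because
left and right hands are never pooled. Configurations of rank < 2
(collinear) are rejected rather than silently resolved.

**ICP.** `icp_register()` alternates exact closest-point correspondences
with a Kabsch update. Choices the underlying literature leaves open are
fixed as follows:

* *Correspondence direction*: source vertices → target **surface**
  (point-to-surface, exact triangle closest points), matching how the
  distance maps are defined, so registration optimises the quantity the
  evaluation measures.
* *Stop criterion*: `|rms_k − rms_{k−1}| < tol` (default 1e-4 mm) or the rms
  itself below `tol`, capped at `max_iter = 100`.
* *Initialisation*: centroid translation with identity rotation (captures
  share a calibrated frame, so this suffices); a landmark-based Kabsch fit
  can be passed as `init` for cold starts.
* *Trimming*: `trim_fraction` (default 0 = classic ICP) discards the worst
  correspondences per iteration for data with unmatched border regions.
  With no trimming the rms sequence is provably non-increasing, and the
  suite asserts it.
* *No scaling*, anywhere.

The closest-point kernels are written in C++ (exact point-to-triangle
closest points; a uniform spatial grid over triangle bounding boxes with a
ring-expansion lower bound that terminates only when no unexplored cell can
beat the current best). The grid path is therefore *exactly* equivalent to
brute force — the suite checks agreement at 1e-9 mm — just faster.

## Distance maps and their summaries

`surface_distance_map()` samples one distance per source vertex (a
reproducible, resolution-controlled sampling scheme) against the target
surface; meshes must already be registered, the function applies no
transform. Summaries report the absolute mean and the 50th/90th percentiles
with linear interpolation between order statistics (R's default quantile
type 7) — the convention is declared because percentile definitions differ
across software. By convention the second acquisition (T1) is the source and
T0 the target; the asymmetry between directions is small.

The signed variant orients each distance by the side of the closest target
face (positive = outside, by the target's outward face normals), after
verifying orientation consistency via directed edges. On composite surfaces
signs can be locally wrong where components interpenetrate (e.g. where an
enlarged palm edge pokes into the reference's finger capsules); group
contrasts therefore read the *mean* signed distance, not individual signs.

## Groupwise registration and the average hand

`average_hand()` is the package's estimator. Two registration engines:

* **Method 1 — whole-hand Procrustes.** Every landmark set is rigidly
  aligned (no scaling) to a randomly chosen reference set; the landmark-wise
  mean is computed; every original set is re-aligned to that mean and the
  mean recomputed. The canonical procedure is exactly these two passes;
  `n_passes` can be raised, and the suite verifies the two-seed stability
  and idempotence this buys.
* **Method 2 — per-subregion adapted ICP.** Palm and each digit are
  registered independently: Kabsch on the subregion's landmarks, refined by
  surface ICP of the subregion's vertices against the reference subregion
  when meshes are available (`use_surface = TRUE`, the default; a
  landmark-only mode exists). The aligned set is re-assembled landmark-wise
  from the per-region alignments — the minimal faithful re-unification,
  since nothing stronger is implied by the procedure. Digit base landmarks
  participate in both their digit and the palm fit; articulation rotates
  digits about their bases, so the bases move (almost) with the palm and
  stabilise it. In passes after the first, the reference is the current
  average: its surface is obtained by warping the pass-1 reference mesh onto
  the current mean landmarks (see below), so the "average hand as reference"
  step is well defined for the surface ICP too.

Because articulation between captures is, to good approximation, a rigid
motion of each digit, method 2 absorbs it while method 1 must average over
it — the package's central, test-backed contrast. Both report precision as
the pooled RMS over all specimens and landmarks of the landmark-to-mean
distance (pooled, rather than per-specimen-averaged, is the declared
definition), and a paired t-test on per-specimen RMS compares methods at the
5% level.

The fitted model carries per-landmark sample covariances (denominator
n − 1) and **variation ellipsoids**: semi-axes `2·√eigenvalues` — two
standard deviations along each principal direction — with eigenvector axes,
sorted by size. A Monte-Carlo test (n = 1000, one landmark perturbed with
known σ) pins the 2σ definition to within 10%.

**Average surface.** Landmark averaging does not average surfaces, so the
average surface is built by thin-plate-spline warping (`U(r) = r` kernel in
3D) of a reference specimen's mesh, carrying its landmarks exactly onto the
mean landmarks with unchanged topology. TPS reproduces affine — hence
rigid — maps exactly on exact data, which the suite asserts. The choice of
interpolant is isolated in `build_average_surface()` so it can be swapped;
coincident source landmarks are an error (the spline is undefined there).

## Statistics

`paired_t_test()` delegates the regular case to `stats::t.test(paired =
TRUE)`; the degenerate zero-variance branch is explicit (p = 1 if all
differences are zero, else p = 0 with a warning). Tests verify the statistic
against its closed form (d = (1, 2, 3) → t = 2√3, df = 2) and the p-value
against direct quadrature of the t density to 1e-6.

`compare_sex_averages()` registers the female average surface into the male
frame (landmark Procrustes + surface ICP, rigid only — the size difference
must survive as signal) and reports the signed map with the **male surface
as source**, so a positive mean signed distance reads "the male hand is
larger", together with per-landmark deltas (male − female). With a 10% male
size factor the pipeline recovers a clearly positive contrast and outward
fingertip deltas; with no size factor the contrast is centred on zero across
seeds, which the suite checks. No inferential test is attached to the sex
contrast: five subjects per group is a pilot-sized, descriptive comparison.

## The pipeline and problem sizes

`run_pipeline()` chains synthesis → repeat acquisitions → ICP registration →
distance-map summaries (full + palm) → both averaging methods → paired
t-test → sex contrast, is deterministic given config + seed (the report
embeds a config hash), and aborts with a stage-named error on failure. The
default study emulates the clinical design: 17 subjects (13 female, 4 male)
for reproducibility and the method comparison, and a 5 + 5 pilot for the sex
contrast. Default mesh resolution is a 6 mm target edge length (~1500
vertices per hand) — dense enough that per-vertex distance maps resolve the
articulation error structure, small enough that the full pipeline runs in
about a minute on one core; the suite's property checks use coarser 8–10 mm
instances where density is irrelevant to the property.

## Known limitations

* The synthetic hand is schematic; absolute error magnitudes depend on its
  motion parameters and should be read as orderings (palm vs full hand,
  method 2 vs method 1), not as predictions of clinical error values.
* Method 2's surface ICP can slide slightly along a digit's axis when two
  digits differ mainly in length (a capsule is locally translation-invariant
  along itself); landmarks anchor the fit, and residual slide appears in the
  RMS rather than corrupting it.
* Signed distances use the closest face's normal; on open or
  interpenetrating composite surfaces individual signs near junctions can
  flip, so only aggregate signed statistics are reported.
* Landmark placement error by an observer is not modelled; adding it would
  inflate both methods' RMS equally and narrow the method-1/method-2 gap.
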