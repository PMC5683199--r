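---
title: "Geometry-aware stereo endoscopy reconstruction: models and methods"
author: "endogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-aware stereo endoscopy reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Augmented-reality guidance in minimally invasive surgery needs two things at
once: the pose of the endoscopic camera at every frame, and a dense metric
model of the tissue surface in view, so that annotations, labels and
measurements can be anchored to the curved anatomy rather than to a plane.
`endogeo` implements an offline version of this pipeline for rectified stereo
endoscopes: feature-based stereo SLAM for the trajectory, dense ZNCC stereo
matching for per-keyframe depth, incremental world-space fusion and meshing
for the surface, and a set of geometry-aware AR operations (picking, labels,
surface measurement, area highlighting) on the reconstructed mesh.

This vignette documents the models, the parameters that matter, the numerical
choices, and what the bundled synthetic evaluation does and does not show.

# Camera model and stereo depth

Both cameras of the rig are identical pinholes with focal length $f$ (px),
principal point $(c_x, c_y)$ and a pure horizontal baseline $B$ (mm); images
are assumed rectified, so corresponding points share an image row and the
disparity $d = x_l - x_r$ of a correspondence determines its depth by similar
triangles:

$$Z = \frac{f \, B}{d}.$$

Conventions, fixed once and used everywhere: right-handed camera frame with
$+z$ along the optical axis, $+x$ right, $+y$ down; image origin at the
top-left pixel centre with 0-based integer pixel centres; quaternions
scalar-first and camera-to-world ($X_w = R(q) X_c + r$); the world frame is
the first camera frame of a run. The depth error of stereo triangulation
grows as $Z^2/(fB)$ per pixel of disparity error, which is why observations
below a minimum disparity (default 0.5 px) are rejected outright: at the
default synthetic rig ($f = 500$ px, $B = 5$ mm) a feature at 90 mm depth
moves by about 3.2 mm per pixel of disparity error, so sub-pixel disparity
refinement (a ZNCC parabola over three integer offsets) is applied to every
stereo feature match.

# Feature detection and specular filtering

Keypoints come from a FAST-style segment test (contiguous arc of 9 of 16
circle pixels brighter or darker than the centre by a threshold, default 10
on a 0-255 scale) over a 3-level image pyramid (scale step 1.2), with an
oriented BRIEF-style 256-bit binary descriptor sampled from a box-blurred
patch and steered by the intensity-centroid orientation. No feature-detection
library is available in this R stack, so the detector is implemented in the
package's compiled code; it follows the standard oriented-FAST/rotated-BRIEF
design and its outputs (binary descriptors compared by Hamming distance) are
what the rest of the pipeline assumes.

Stereo correspondence is mutual-best Hamming matching gated by the rectified
epipolar constraint (rows within 2 px), a distance threshold (64 of 256
bits), a best/second-best ratio (0.9), and positive disparity. Saturated
specular highlights — the light rides on the endoscope, so highlights move
with the camera and violate the static-scene assumption — are removed by an
intensity threshold (default 240/255) applied to every keypoint.

# Tracking

Between frames the camera pose is predicted by a constant-velocity motion
model: position advances by $v_t \Delta t$, orientation composes with the
quaternion of the rotation vector $\omega_t \Delta t$, and the velocity
update terms ($a$, $\alpha$) default to zero, which is the behaviour of the
cited constant-velocity formulation; finite-difference acceleration
estimation is available behind `update_motion_state(estimate_acceleration =
TRUE)` but is off by default, since with per-frame re-estimation of $v$ and
$\omega$ the extra terms amplify noise.

Map landmarks are re-projected through the predicted pose and matched to the
current frame's detections inside square guided-search windows. Matching runs
twice per frame: a coarse pass with windows widened to three times the
nominal radius feeds the robust pose estimator, and a fine pass at the
nominal 15 px radius, centred on the *estimated* pose, defines the frame's
tracked keypoint set. The two-pass scheme exists because the constant
velocity prediction can be off by more than the window radius at direction
reversals of the camera; the wide window tolerates that, while the fine pass
keeps the keyframe bookkeeping tight.

The pose itself comes from robust rigid alignment of 3D-3D correspondences:
each tracked feature's stereo triangulation in the current camera frame
paired with its landmark's world position. RANSAC samples three pairs,
solves the minimal alignment in closed form (SVD-based Kabsch), scores all
pairs by 3D residual against a 1 mm threshold, adapts its iteration count by
the standard 0.99-confidence formula (capped at 500), and refines on the
full inlier set of the best hypothesis; the refinement never increases the
inlier objective. Fewer than 10 inliers signals tracking loss; the pipeline
then holds the last pose with zeroed velocities (skipping the frame) rather
than extrapolating, which keeps the guided windows near the last known view
so later frames can re-acquire. Relocalisation and loop closure are out of
scope.

The alignment convention is documented explicitly because it is easy to
invert silently: `solve_rigid(A, B)` returns the $(R, T)$ minimising
$\sum_i \|a_i - (R b_i + T)\|$; with $A$ the world (or earlier-frame)
positions and $B$ the current camera-frame positions this is directly the
camera-to-world pose of the current camera.

# Keyframes and bundle adjustment

A frame becomes a keyframe when its shared-keypoint fraction with the last
keyframe drops below 0.80 while its total keypoint count exceeds 50 — the
published selection rule. The published statement does not fix the
denominator; the implementation uses the smaller of the two keypoint counts.
In the pipeline the "current frame's keypoints" are its detections, with
tracked detections carrying their landmark ids (shared with the keyframe
when it observed the same landmark) and untracked detections carrying unique
ids. Several bookkeeping details keep this overlap a measure of *view
change* rather than of detector noise, because the raw single-frame match
rate sits close to the 0.80 threshold and would otherwise set the cadence
by noise: the tracked set is the union over the last three frames (a
landmark counts as common if it matched in any of them); new landmarks are
only created from corners scoring above the frame's 0.4 score quantile
(weak corners re-detect unreliably); a candidate landmark on the same
viewing ray as an existing one (lateral distance below 0.5 mm, along-ray
tolerance six times that, matching the anisotropy of stereo depth noise) is
recorded as a re-observation rather than a duplicate; matched landmarks'
descriptors are refreshed at each keyframe so they do not go stale as the
viewpoint rotates; and a tracked landmark within 1 mm of one the keyframe
observed is credited as that observation when assignment flips between
close neighbours.

On insertion, the new keyframe stores its landmark observations (left-image
pixel, plus the right-image x-coordinate when the detection stereo-matched)
and bundle adjustment runs over a sliding window of the last 5 keyframes
(all-keyframe BA is available as an option). BA minimises the total
Huber-robust reprojection cost

$$\sum_{i,j} \rho_h\!\left(\| p_{i,j} - \mathrm{CamProj}(KF_i, P_j) \|\right)$$

over keyframe poses and landmark positions, with $\rho_h$ quadratic below
$\delta = 2$ px and linear above. Numerics: Levenberg-Marquardt on sparse
normal equations (`Matrix`), IRLS Huber weights recomputed each outer
iteration, rotations updated by local 3-parameter increments right-composed
onto the quaternion and renormalised, and the first keyframe pose held fixed
to anchor the gauge. Accepted steps never increase the robust cost. Stereo
observations contribute a third residual component (the right-camera
x-coordinate): with left-only residuals and the short baselines of a
keyframe window, landmark depth is nearly unobservable and drifts along the
viewing rays, which measurably corrupts the 3D-3D tracking; the stereo
component anchors it.

# Dense reconstruction

At keyframes only (matching the real-time configuration of the original
system), a dense disparity map is computed in three stages:

1. **ZNCC cost volume.** For every pixel and every disparity in $[1, 64]$,
   the zero-mean normalised cross-correlation of $7\times7$ patches between
   the left image and the disparity-shifted right image. ZNCC is invariant
   to affine intensity changes, which is the reason this family of costs
   suits endoscopic illumination. The volume stores the *negated*
   correlation so that lower is better everywhere downstream; border pixels
   and zero-variance patches are masked invalid, never NaN. The
   implementation uses integral images (window sums in constant time per
   pixel) and is verified against a brute-force double loop in the tests.
2. **Winner-takes-all** per-pixel argmin with ties broken toward the smaller
   disparity, followed by parabolic sub-pixel refinement on the three costs
   around the winner.
3. **Huber-L1 variational smoothing.** The WTA map initialises a descent of
   $$E(u) = \sum_p g_p \, H_\epsilon(\nabla u(p)) + \lambda\, C(p, u(p)),$$
   with $H_\epsilon$ the Huber penalty of the disparity gradient
   ($\epsilon = 0.1$ px), per-edge weights $g_p = e^{-\beta |\nabla I|}$
   preserving disparity edges where the image gradient is strong, and the
   data term sampling the cost volume by linear interpolation along $d$.
   The solver is projected gradient descent with backtracking, so the energy
   is non-increasing by construction; this satisfies the energy contract of
   the primal-dual formulation the design allows, with considerably less
   machinery. The pipeline default is 25 iterations, where the descent has
   saturated on the synthetic scenes.

A median-deviation speckle filter (5×5 window, 2 px tolerance) then
invalidates isolated false matches — repetitive texture occasionally
produces a confidently wrong winner that survives the variational smoothing
and, once back-projected through $Z = fB/d$, lands hundreds of millimetres
off the surface. Median depth error on the synthetic scenes is around
0.1 mm; without the speckle filter the *root-mean-square* error is dominated
entirely by these rare outliers.

The filtered map is back-projected densely, subsampled (stride 2),
transformed to world space by the keyframe's estimated pose, and fused into
the global cloud on a 1 mm voxel grid (one centroid per occupied voxel).
The global surface is re-triangulated from the fused cloud at every fifth
keyframe and always after the last frame (`mesh_every = 1` restores
per-keyframe re-meshing): re-triangulation is linear in the accumulated
cloud, so meshing at every keyframe makes late keyframes progressively more
expensive for a mesh that an offline batch run only consumes at the end.
Incremental and end-of-run meshing agree to within the fusion voxel size,
so the cadence is a cost knob, not an accuracy one.

# Meshing

Surface triangulation is greedy-projection style: normals from a local plane
fit (20 neighbours, oriented toward the observing camera), then each point's
neighbourhood is projected onto its tangent plane and locally
Delaunay-triangulated (Bowyer-Watson on the projected points); the star of
each point contributes candidate triangles, and a triangle is kept when at
least two of its three vertices generate it. On consistently sampled
surfaces local stars agree and the union is a clean manifold-enough mesh;
the agreement threshold prunes the occasional inconsistent sliver at the
price of small holes in thinly sampled regions, which are reported as
unreferenced points rather than patched.

# Geometry-aware AR operations

All AR operations work on the world-space mesh:

* **Picking** casts the viewing ray of a pixel and returns the nearest
  ray-triangle intersection with barycentric coordinates and the
  interpolated vertex normal (verified against an all-triangles oracle).
* **Re-projection** is a software z-buffer rasterisation of the mesh into
  the camera (depth + face-id buffers) — the interactive geometric layer.
* **Measurement** runs Dijkstra over the mesh edge graph between two
  anchors, then iteratively slides the intermediate points along their
  crossed mesh edges to shorten the polyline. The refined path approximates
  the surface geodesic to within a few percent on meshes at the package's
  default resolutions (the hemisphere test requires 3%); its length is
  always at least the straight chord. A true exact-geodesic (window
  propagation) algorithm is out of scope.
* **Area highlighting** computes a geodesic distance field from the anchor
  by iterative triangle unfolding (exact on planar meshes, first-order on
  curved ones) and sums the areas of faces whose centroid distance is within
  the bound.
* **Labels** sit at an anchor with their normal equal to the interpolated
  surface normal; the in-plane spin aligns to the camera up-vector at
  placement time.

# The synthetic evaluation protocol

The bundled generator reproduces the structure of the original simulation
study: a single-valued height-field surface whose principal dome spans
140 mm (the reported average liver diameter of 14.0 cm), with band-limited
random undulation (3 mm RMS), a multi-scale random albedo texture, a strong
Phong specular component, and a spot light co-located with the camera —
rendered at $840 \times 640$, the published image size, with a software
rasteriser. Rig parameters ($f = 500$ px, $B = 5$ mm) are not stated in the
original study; they are chosen so that working depths of 50-200 mm give
disparities in roughly the 5-50 px range. The camera hovers on a smooth
orbit (22 mm radius, 4 mm vertical bob, look-at the dome) over 300 frames.
The texture grid (0.75 mm) is deliberately finer than the height-field mesh
grid (1.5 mm) so that rendered frames carry feature-scale detail; the
default frame yields well over 500 detectable keypoints.

Reconstruction quality is measured exactly as in the original protocol:
both surfaces are aligned to the world frame (the generator's ground-truth
pose of the first camera provides the alignment), grid-sampled in $(x, y)$
at 2 mm spacing, and compared by

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{mn} \sum_x \sum_y (Z_{x,y} - z_{x,y})^2},$$

where the reconstructed height of a cell is the median $z$ of the fused
cloud points falling in it (the median makes the cell estimate robust to the
rare stray point; cells with no points are excluded and the exclusion
fraction reported, with a warning below 50% coverage). Trajectory accuracy —
not evaluated in the original study but the natural intermediate check — is
the RMS translation/rotation error after rigid (no-scale) alignment.

What the synthetic study shows: that the full pipeline recovers the
trajectory to well under a millimetre and the surface to under the published
2.37 mm RMSD under endoscope-like illumination, specularity and organ-scale
geometry. What it does not show: robustness to tissue deformation (the scene
is rigid; deformation is handled only by RANSAC rejection of non-rigid
points), rolling shutter, lens distortion, fluid/smoke, or real tissue
appearance. The acceptance benchmark is therefore a scaled-down,
self-generated analogue of the published ground-truth study, not a
reproduction of its (unpublished) Blender scene.

# Problem sizes and determinism

The package's own test and benchmark sizes: unit tests run on a
$320 \times 240$ rig with a 90 mm scene; the benchmark run uses the full
$840 \times 640$, 300-frame default. All stochastic components (scene
generation, RANSAC) draw from R's RNG seeded from configuration, and scene
generation saves/restores the global RNG state, so a fixed config and seed
reproduce a run bit-for-bit.

# Known limitations

* Tracking has no relocalisation: after a loss the pipeline holds pose and
  waits for the view to return.
* The keyframe overlap criterion depends on detector repeatability; scenes
  with very unstable corners will over-insert keyframes (bounded-cost, but
  slower).
* The greedy-projection mesher can leave holes in thinly sampled regions
  and does not guarantee watertightness.
* Surface paths are polyline approximations of geodesics; their error is
  bounded by the mesh resolution, not by a user tolerance.
* The variational smoother descends the Huber-L1 energy but is first-order:
  it inherits the WTA minimum's basin and will not jump to a distant better
  one.
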