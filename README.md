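# endogeo

Geometry-aware surface reconstruction and augmented-reality overlay for
stereo endoscopy.

Augmented reality can guide minimally invasive surgery only if two
quantities are available live and in metric units: the pose of the
endoscopic camera and a dense model of the curved tissue surface in view.
`endogeo` implements that pipeline offline, in R, for rectified stereo
endoscopes:

* **Stereo SLAM** — FAST/BRIEF-style binary features with specular-highlight
  filtering; depth from disparity, `Z = f·B/d`; constant-velocity pose
  prediction with guided re-projection search; robust camera pose from
  3-point RANSAC rigid alignment of 3D-3D correspondences; keyframe
  selection (shared keypoints < 80 % and count > 50) and sliding-window
  bundle adjustment minimising the Huber-robust reprojection cost
  `Σ ρ_h(‖p_ij − CamProj(KF_i, P_j)‖)`.
* **Dense stereo** — patch-based ZNCC cost volume (affine-illumination
  invariant), winner-takes-all with sub-pixel refinement, Huber-L1
  variational smoothing, speckle filtering.
* **Surface** — per-keyframe clouds transformed to world space, fused on a
  voxel grid, and triangulated incrementally into a global mesh
  (greedy-projection local Delaunay).
* **Geometry-aware AR** — ray picking, z-buffered mesh re-projection,
  surface-anchored oriented labels, geodesic area highlighting, and
  measurement lines that follow the curved surface.
* **Synthetic ground truth** — a liver-scale (14 cm), textured, specular
  scene with endoscope-style co-located spot lighting, a hovering stereo
  camera, per-frame true poses and depth, and the grid-sampled surface RMSD
  metric `RMSD = sqrt(mean((Z_xy − z_xy)^2))`.

## A worked example

Generate a small synthetic sequence, run the full pipeline, and measure a
distance along the reconstructed surface:

```r
library(endogeo)

rig   <- camera_rig(250, c(159.5, 119.5), baseline_mm = 5,
                    image_size = c(320, 240))
scene <- generate_scene(seed = 7, extent_mm = 45, structure_span = 80,
                        dome_height_mm = 14, bump_amplitude_mm = 2)
traj  <- hover_trajectory(n_frames = 24, orbit_radius = 14, bob_mm = 2,
                          scene = scene)
frames <- render_sequence(scene, traj, rig)

res <- run_pipeline(frames, rig, pipeline_config(seed = 5))
res$report$n_keyframes
#> [1] 7
res$report$tracked_fraction
#> [1] 1

# trajectory accuracy against the generator's ground truth
gt <- lapply(traj, function(p) pose_compose(pose_inverse(traj[[1]]), p))
trajectory_error(res$trajectory, gt)$rms_translation_mm
#> [1] 0.8602764

# surface accuracy: grid-sampled RMSD in the scene frame
cloud <- to_world(res$cloud, frame_to_world(traj[[1]]))
grid  <- evaluation_grid(scene, cloud, spacing = 2, extent = 25)
rmsd_surfaces(grid)
#> [1] 0.2493631
#> attr(,"coverage")
#> [1] 1

# measure along the curved surface between two picked points
a <- pick(c(80, 120),  res$trajectory[[1]], rig, res$mesh)
b <- pick(c(240, 120), res$trajectory[[1]], rig, res$mesh)
measure_on_surface(a, b, res$mesh)
#> surface_path: 65.830 mm along the surface (chord 61.150 mm, 92 points)
```

The numbers mean: all 24 frames tracked with 7 keyframes; the camera
recovered to ~0.86 mm RMS; the fused surface agrees with the known ground
truth to ~0.25 mm RMSD over the whole evaluated grid; and the measurement
line between the two picked pixels runs 65.8 mm along the curved surface —
7.7 % longer than the straight 61.2 mm chord, as it should be on a dome.

A thin command-line driver for on-disk datasets ships in `inst/cli/`:

```sh
Rscript inst/cli/endogeo synth --out data --frames 60
Rscript inst/cli/endogeo run --calib data/calib.yaml --frames data --out out
Rscript inst/cli/endogeo measure --mesh out/mesh.ply --from 0,0,80 --to 20,5,78
```

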