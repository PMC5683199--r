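# Pipeline driver: ties detection, tracking, keyframing, bundle
# adjustment, dense stereo, fusion and meshing together in the standard
# flow (track every frame; reconstruct densely at keyframes only), plus
# configuration and dataset I/O.

#' Pipeline configuration
#'
#' All tunables of the reconstruction pipeline with their defaults.  The
#' keyframe thresholds (overlap 0.80, count 50) are the published
#' selection criterion; the remaining values are package defaults.
#'
#' @param feature [feature_params()] list.
#' @param specular_threshold specular-intensity cutoff (default 240).
#' @param ransac_threshold_mm RANSAC 3D inlier threshold (default 1).
#' @param ransac_max_iterations hypothesis cap (default 500).
#' @param ransac_min_inliers tracking-lost bound (default 10).
#' @param keyframe_overlap shared-keypoint fraction below which a keyframe
#'   is due (default 0.80).
#' @param keyframe_min_count keypoint count that must be exceeded (50).
#' @param ba_window sliding window size in keyframes (default 5).
#' @param ba_global run one all-keyframe BA at the end (default FALSE).
#' @param huber_delta_px Huber transition in px (default 2).
#' @param search_radius_px guided-search half window (default 15).
#' @param d_range dense disparity range (default c(1, 64)).
#' @param patch_radius ZNCC patch radius (default 3).
#' @param smooth_lambda,smooth_iterations Huber-L1 data weight and steps.
#' @param dense_min_zncc minimum winner correlation for a dense disparity
#'   to be kept (default 0.9; see [filter_disparity_quality()]).
#' @param dense_stride pixel stride when back-projecting keyframe
#'   disparities (default 2).
#' @param voxel_mm fusion voxel size (default 1).
#' @param mesh_every re-triangulate the fused cloud at every this-many
#'   keyframes (default 5; \code{Inf} re-meshes only once at the end; the
#'   final mesh is always built).
#' @param new_landmark_score_q corner-score quantile (within the frame)
#'   below which an unmapped feature is not promoted to a landmark
#'   (default 0.4; weak corners re-detect unreliably).
#' @param landmark_dedup_mm lateral (across-ray) distance below which a
#'   candidate landmark is treated as a re-detection of an existing one
#'   (default 0.5; the along-ray tolerance is 6x this, reflecting stereo
#'   depth noise).
#' @param ba_max_iterations Levenberg-Marquardt iteration cap per
#'   keyframe bundle adjustment (default 15).
#' @param seed RNG seed used for the RANSAC sampler (default 1).
#' @return a named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(feature = feature_params(),
                            specular_threshold = 240,
                            ransac_threshold_mm = 1.0,
                            ransac_max_iterations = 500,
                            ransac_min_inliers = 10,
                            keyframe_overlap = 0.80,
                            keyframe_min_count = 50,
                            ba_window = 5,
                            ba_global = FALSE,
                            huber_delta_px = 2.0,
                            search_radius_px = 15,
                            d_range = c(1, 64),
                            patch_radius = 3,
                            smooth_lambda = 1.0,
                            smooth_iterations = 25,
                            dense_min_zncc = 0.9,
                            dense_stride = 2,
                            voxel_mm = 1.0,
                            mesh_every = 5,
                            new_landmark_score_q = 0.4,
                            landmark_dedup_mm = 0.5,
                            ba_max_iterations = 15,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$keyframe_overlap > 0, cfg$keyframe_overlap <= 1,
            cfg$voxel_mm > 0, cfg$ransac_threshold_mm > 0)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  y <- rapply(y, as.numeric, classes = "integer", how = "replace")
  feat <- do.call(feature_params, y$feature)
  y$feature <- NULL
  do.call(pipeline_config, c(list(feature = feat), y))
}

#' Load an image file as a grayscale matrix
#'
#' PNG or TIFF, returned on a 0-255 intensity scale (RGB converted by
#' Rec. 601 luminance).
#' @param path image path.
#' @return numeric matrix.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("unreadable frame: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  as_gray(img)
}

#' Frame provider over an on-disk dataset
#'
#' @param dir dataset directory with \code{left/\%06d.png} and
#'   \code{right/\%06d.png}.
#' @return list \code{n_frames} and \code{get(i)} returning
#'   \code{list(left, right)}.
#' @export
frame_directory <- function(dir) {
  lf <- sort(list.files(file.path(dir, "left"), full.names = TRUE,
                        pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
  rf <- sort(list.files(file.path(dir, "right"), full.names = TRUE,
                        pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
  if (length(lf) == 0) stop("no frames found under ", dir)
  stopifnot(length(lf) == length(rf))
  list(n_frames = length(lf),
       get = function(i) list(left = load_image(lf[i]),
                              right = load_image(rf[i])))
}

# internal map state for a run
new_map <- function() {
  env <- new.env(parent = emptyenv())
  env$positions <- matrix(numeric(0), 0, 3)
  env$descriptors <- matrix(integer(0), 0, 32)
  env$obs_count <- integer(0)
  env$keyframes <- list()
  env
}

add_landmarks <- function(map, positions, descriptors) {
  n0 <- nrow(map$positions)
  map$positions <- rbind(map$positions, positions)
  map$descriptors <- rbind(map$descriptors, descriptors)
  map$obs_count <- c(map$obs_count, rep(1L, nrow(positions)))
  n0 + seq_len(nrow(positions))
}

# match left-image detections to visible map landmarks inside guided
# windows around their projections through `cam_pose`
match_to_map <- function(map, keypoints, descriptors, cam_pose, rig, cfg,
                         radius) {
  regions <- guided_search_regions(cam_pose, map$positions, rig, radius)
  if (nrow(regions) == 0 || nrow(keypoints) == 0) {
    return(data.frame(landmark = integer(0), feature = integer(0)))
  }
  dl <- map$descriptors[regions$landmark, , drop = FALSE]
  res <- hamming_match_cpp(dl, descriptors, keypoints$x, keypoints$y,
                           regions$cx, regions$cy, radius = radius)
  ok <- which(!is.na(res$match) & res$dist <= cfg$feature$max_hamming &
                keypoints$intensity[res$match] <= cfg$specular_threshold)
  df <- data.frame(landmark = regions$landmark[ok], feature = res$match[ok],
                   dist = res$dist[ok])
  # one landmark per feature: keep the closest descriptor
  df <- df[order(df$dist), ]
  df <- df[!duplicated(df$feature), ]
  df[order(df$landmark), c("landmark", "feature")]
}

run_ba_window <- function(map, rig, cfg, window = NULL) {
  n_kf <- length(map$keyframes)
  if (n_kf < 2) return(invisible(NULL))
  sel <- if (is.null(window)) seq_len(n_kf) else
    seq.int(max(1, n_kf - window + 1), n_kf)
  kfs <- map$keyframes[sel]
  res <- bundle_adjust(kfs, map$positions, rig,
                       huber_delta = cfg$huber_delta_px,
                       max_iterations = cfg$ba_max_iterations)
  map$positions <- res$landmarks
  for (i in seq_along(sel)) map$keyframes[[sel[i]]] <- res$keyframes[[i]]
  invisible(res)
}

insert_keyframe_dense <- function(map, frame, left_feats, stereo, pts_cam,
                                  matched, cam_pose, rig, cfg, state) {
  # observations of already-mapped landmarks: left pixels plus, when the
  # detection stereo-matched, the right-camera x (anchors depth in BA)
  srow <- match(matched$feature, stereo$matches$feature_left)
  obs <- data.frame(landmark = matched$landmark,
                    x = left_feats$keypoints$x[matched$feature],
                    y = left_feats$keypoints$y[matched$feature],
                    x_right = ifelse(is.na(srow), NA_real_,
                                     stereo$matches$x_right[srow]))
  map$obs_count[matched$landmark] <- map$obs_count[matched$landmark] + 1L
  # refresh matched landmarks' descriptors from the current view: binary
  # descriptors go stale as the viewpoint rotates, and stale descriptors
  # depress the match rate that the keyframe criterion measures
  map$descriptors[matched$landmark, ] <-
    left_feats$descriptors[matched$feature, ]
  # new landmarks from stereo features whose left detection is unmapped;
  # weak corners are skipped — they re-detect unreliably and churn the map
  score_floor <- stats::quantile(stereo$matches$score, cfg$new_landmark_score_q,
                                 na.rm = TRUE)
  newr <- which(is.finite(pts_cam[, 3]) &
                  !(stereo$matches$feature_left %in% matched$feature) &
                  stereo$matches$score >= score_floor)
  if (length(newr) > 0) {
    Pw <- to_world(pts_cam[newr, , drop = FALSE], frame_to_world(cam_pose))
    # spatial dedup: a candidate that lies on the same viewing ray as an
    # existing landmark is a re-detection whose descriptor match failed,
    # not a new point — record it as an observation of that landmark
    # instead of aliasing the map with a duplicate.  The test is
    # anisotropic: tight laterally (pixel accuracy), loose along the ray
    # (stereo depth noise scales with Z^2 / fB).
    if (nrow(map$positions) > 0) {
      lm_cam <- to_world(map$positions, frame_to_world(cam_pose),
                         inverse = TRUE)
      cand_cam <- pts_cam[newr, , drop = FALSE]
      dup <- logical(nrow(Pw)); nn_id <- integer(nrow(Pw))
      along_tol <- cfg$landmark_dedup_mm * 6
      for (k in seq_len(nrow(Pw))) {
        ray <- cand_cam[k, ] / sqrt(sum(cand_cam[k, ]^2))
        diff <- lm_cam - matrix(cand_cam[k, ], nrow(lm_cam), 3, byrow = TRUE)
        along <- as.numeric(diff %*% ray)
        lat2 <- rowSums(diff^2) - along^2
        hit <- which(lat2 <= cfg$landmark_dedup_mm^2 &
                       abs(along) <= along_tol)
        if (length(hit) > 0) {
          dup[k] <- TRUE
          nn_id[k] <- hit[which.min(lat2[hit])]
        }
      }
      re <- which(dup & !(nn_id %in% obs$landmark))
      re <- re[!duplicated(nn_id[re])]
      if (length(re) > 0) {
        obs <- rbind(obs, data.frame(landmark = nn_id[re],
                                     x = stereo$matches$x_left[newr[re]],
                                     y = stereo$matches$y_left[newr[re]],
                                     x_right = stereo$matches$x_right[newr[re]]))
        map$obs_count[nn_id[re]] <- map$obs_count[nn_id[re]] + 1L
      }
      newr <- newr[!dup]
      Pw <- Pw[!dup, , drop = FALSE]
    }
  }
  if (length(newr) > 0) {
    ids <- add_landmarks(map, Pw,
                         stereo$descriptors[newr, , drop = FALSE])
    obs <- rbind(obs, data.frame(landmark = ids,
                                 x = stereo$matches$x_left[newr],
                                 y = stereo$matches$y_left[newr],
                                 x_right = stereo$matches$x_right[newr]))
  }
  id <- length(map$keyframes) + 1L
  map$keyframes[[id]] <- keyframe(id, cam_pose, obs, frame = frame)
  ba <- run_ba_window(map, rig, cfg, window = cfg$ba_window)
  kf_pose <- map$keyframes[[id]]$pose
  # dense reconstruction at the (refined) keyframe
  vol <- build_cost_volume(state$left, state$right, cfg$d_range,
                           cfg$patch_radius)
  wta <- winner_takes_all(vol)
  sm <- smooth_disparity(vol, wta, lambda = cfg$smooth_lambda,
                         iterations = cfg$smooth_iterations,
                         image = state$left)
  sm <- filter_disparity_quality(vol, filter_disparity_speckles(sm),
                                 min_zncc = cfg$dense_min_zncc)
  dp <- disparity_to_points(sm, rig, stride = cfg$dense_stride)
  cloud_w <- to_world(dp$points, frame_to_world(kf_pose))
  list(ba = ba, disparity = sm, cloud = cloud_w, kf_id = id)
}

#' Run the full reconstruction pipeline
#'
#' Executes the standard flow over a stereo sequence: per-frame feature
#' detection, stereo matching and specular filtering; constant-velocity
#' pose prediction with guided map matching and RANSAC rigid alignment;
#' keyframe insertion by the overlap/count criterion, followed by windowed
#' Huber bundle adjustment, dense ZNCC disparity estimation, world-space
#' fusion and re-meshing.  Dense reconstruction runs at keyframes only.
#'
#' @param frames list of \code{list(left, right)} images, or a
#'   [frame_directory()] provider.
#' @param rig a [camera_rig()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for trajectory (TUM), mesh
#'   (PLY), landmark cloud (PLY), per-keyframe disparity (TIFF) and the run
#'   report (JSON).
#' @param verbose print per-keyframe progress.
#' @return list \code{trajectory} (poses per frame), \code{tracked}
#'   (logical per frame), \code{keyframes}, \code{landmarks},
#'   \code{cloud} (fused world points), \code{mesh}, \code{disparities},
#'   \code{report}.
#' @export
run_pipeline <- function(frames, rig, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  provider <- if (is.list(frames) && !is.null(frames$get)) frames else
    list(n_frames = length(frames), get = function(i) frames[[i]])
  n <- provider$n_frames
  if (n == 0) stop("empty frame sequence: nothing to reconstruct")
  set.seed(config$seed)
  map <- new_map()
  trajectory <- vector("list", n)
  tracked <- logical(n)
  disparities <- list()
  cloud <- matrix(numeric(0), 0, 3)
  mesh <- NULL
  reproj_err <- NA_real_
  mstate <- motion_state()
  recent_matches <- list()

  for (i in seq_len(n)) {
    fr <- provider$get(i)
    state <- list(left = as_gray(fr$left), right = as_gray(fr$right))
    fl <- detect_features(state$left, config$feature)
    frt <- detect_features(state$right, config$feature)
    sm <- detect_and_match(state$left, state$right, config$feature, fl, frt)
    sm <- filter_specular(sm, config$specular_threshold)
    pts_cam <- triangulate(stereo_observation(sm$matches$x_left,
                                              sm$matches$x_right,
                                              sm$matches$y_left),
                           rig, config$feature$min_disparity)
    # stereo row (hence camera-frame 3D) for each left detection, if any
    stereo_of <- rep(NA_integer_, nrow(fl$keypoints))
    stereo_of[sm$matches$feature_left] <- seq_len(nrow(sm$matches))
    if (i == 1) {
      if (sm$untrackable) stop("first frame untrackable: too few matches")
      cam_pose <- pose()  # world frame = first camera frame
      trajectory[[1]] <- cam_pose
      tracked[1] <- TRUE
      ok3 <- which(is.finite(pts_cam[, 3]))
      ids <- add_landmarks(map, pts_cam[ok3, , drop = FALSE],
                           sm$descriptors[ok3, , drop = FALSE])
      obs <- data.frame(landmark = ids,
                        x = sm$matches$x_left[ok3],
                        y = sm$matches$y_left[ok3],
                        x_right = sm$matches$x_right[ok3])
      map$keyframes[[1]] <- keyframe(1L, cam_pose, obs, frame = 1L)
      vol <- build_cost_volume(state$left, state$right, config$d_range,
                               config$patch_radius)
      wta <- winner_takes_all(vol)
      smd <- smooth_disparity(vol, wta, lambda = config$smooth_lambda,
                              iterations = config$smooth_iterations,
                              image = state$left)
      smd <- filter_disparity_quality(vol, filter_disparity_speckles(smd),
                                      min_zncc = config$dense_min_zncc)
      dp <- disparity_to_points(smd, rig, stride = config$dense_stride)
      cloud <- fuse(cloud, dp$points, config$voxel_mm)
      disparities[[1]] <- smd
      mstate <- motion_state(cam_pose)
      next
    }
    pred <- predict_pose(mstate)
    est <- list(ok = FALSE)
    if (!sm$untrackable) {
      # coarse pass: wide windows around the predicted projections give the
      # 3D-3D correspondences for RANSAC
      m1 <- match_to_map(map, fl$keypoints, fl$descriptors, pred$pose, rig,
                         config, radius = 3 * config$search_radius_px)
      srow <- stereo_of[m1$feature]
      keep <- !is.na(srow) & is.finite(pts_cam[ifelse(is.na(srow), 1, srow), 3])
      if (sum(keep) >= 3) {
        est <- estimate_rigid_ransac(
          map$positions[m1$landmark[keep], , drop = FALSE],
          pts_cam[srow[keep], , drop = FALSE],
          inlier_threshold = config$ransac_threshold_mm,
          max_iterations = config$ransac_max_iterations,
          min_inliers = config$ransac_min_inliers)
      }
    }
    if (!est$ok) {
      # tracking lost: hold the last pose with zeroed velocities (skip the
      # frame rather than extrapolate), so later frames can re-acquire
      trajectory[[i]] <- mstate$pose
      tracked[i] <- FALSE
      mstate$linear_velocity <- c(0, 0, 0)
      mstate$angular_velocity <- c(0, 0, 0)
      next
    }
    cam_pose <- pose(est$transform$translation,
                     rotmat_to_quat(est$transform$rotation))
    tracked[i] <- TRUE
    # fine pass from the estimated pose: the frame's tracked keypoint set
    matched <- match_to_map(map, fl$keypoints, fl$descriptors, cam_pose, rig,
                            config, radius = config$search_radius_px)
    kf_last <- map$keyframes[[length(map$keyframes)]]
    # frame keypoints for the keyframe criterion: tracked landmarks keep
    # their (shared) ids, unmapped detections get unique pseudo-ids.  The
    # tracked set is smoothed over the last three frames (a landmark counts
    # as present if it matched in any of them) and, as the map densifies,
    # best-descriptor assignment can flip between nearby landmarks frame to
    # frame, so a tracked landmark within 1 mm of one the keyframe observed
    # is credited as that observation: both keep the overlap a measure of
    # view change rather than of per-frame matching noise.
    recent_matches <- c(tail(recent_matches, 2), list(matched$landmark))
    cur_ids <- unique(unlist(recent_matches))
    kf_ids <- kf_last$observations$landmark
    miss <- which(!(cur_ids %in% kf_ids))
    if (length(miss) > 0 && length(kf_ids) > 0) {
      kf_pos <- map$positions[kf_ids, , drop = FALSE]
      for (k in miss) {
        d2 <- rowSums(sweep(kf_pos, 2, map$positions[cur_ids[k], ])^2)
        j <- which.min(d2)
        if (d2[j] <= 1.0) cur_ids[k] <- kf_ids[j]
      }
      cur_ids <- unique(cur_ids)
    }
    frame_ids <- c(cur_ids,
                   -setdiff(seq_len(nrow(fl$keypoints)), matched$feature))
    if (should_insert_keyframe(frame_ids, kf_last$observations$landmark,
                               config$keyframe_overlap,
                               config$keyframe_min_count)) {
      res <- insert_keyframe_dense(map, i, fl, sm, pts_cam, matched,
                                   cam_pose, rig, config, state)
      cloud <- fuse(cloud, res$cloud, config$voxel_mm)
      disparities[[res$kf_id]] <- res$disparity
      cam_pose <- map$keyframes[[res$kf_id]]$pose
      if (!is.null(res$ba)) {
        rn <- ba_residuals(ba_flatten(list(map$keyframes[[res$kf_id]])),
                           list(cam_pose), map$positions, rig)$norm
        reproj_err <- mean(rn)
      }
      if (is.finite(config$mesh_every) &&
          res$kf_id %% config$mesh_every == 0 && nrow(cloud) >= 10) {
        mesh <- triangulate_surface(cloud, radius = 2.5 * config$voxel_mm,
                                    viewpoint = cam_pose$position)
      }
      if (verbose) {
        message(sprintf("frame %d: keyframe %d (%d landmarks, %d cloud pts)",
                        i, res$kf_id, nrow(map$positions), nrow(cloud)))
      }
    }
    trajectory[[i]] <- cam_pose
    mstate <- update_motion_state(mstate, cam_pose)
  }
  if (config$ba_global && length(map$keyframes) >= 2) {
    run_ba_window(map, rig, config, window = NULL)
  }
  if (nrow(cloud) >= 10) {
    vp <- trajectory[[n]]$position
    mesh <- triangulate_surface(cloud, radius = 2.5 * config$voxel_mm,
                                viewpoint = vp)
  }
  report <- list(
    n_frames = n,
    tracked_fraction = mean(tracked),
    n_keyframes = length(map$keyframes),
    n_landmarks = nrow(map$positions),
    n_cloud_points = nrow(cloud),
    n_mesh_faces = if (is.null(mesh)) 0L else nrow(mesh$faces),
    mean_reprojection_error_px = reproj_err,
    first_lost_frame = if (all(tracked)) NA_integer_ else which(!tracked)[1]
  )
  out <- list(trajectory = trajectory, tracked = tracked,
              keyframes = map$keyframes, landmarks = map$positions,
              cloud = cloud, mesh = mesh, disparities = disparities,
              report = report, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_tum(trajectory, file.path(out_dir, "trajectory.txt"))
    if (!is.null(mesh)) write_ply_mesh(mesh, file.path(out_dir, "mesh.ply"))
    if (nrow(map$positions) > 0) {
      write_ply_points(map$positions, file.path(out_dir, "landmarks.ply"))
    }
    for (k in seq_along(disparities)) {
      if (!is.null(disparities[[k]])) {
        write_disparity(disparities[[k]],
                        file.path(out_dir, sprintf("disparity_kf%03d.tif", k)))
      }
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}
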