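# World-space fusion of keyframe point clouds and incremental surface
# meshing: rigid transform to world, voxel-grid fusion, greedy-projection
# triangulation, mesh bookkeeping and export.

#' Frame-to-world rigid transform
#'
#' The transform taking keyframe camera-frame coordinates to the world
#' frame, i.e. the camera pose as an explicit (R, T) pair.
#'
#' @param p a camera [pose()] (camera-to-world), or use \code{rotation} and
#'   \code{translation} directly.
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @param translation 3-vector mm.
#' @return object of class \code{frame_to_world}.
#' @export
frame_to_world <- function(p = NULL, rotation = NULL, translation = NULL) {
  if (!is.null(p)) {
    rotation <- quat_to_rotmat(p$orientation)
    translation <- p$position
  }
  stopifnot(max(abs(t(rotation) %*% rotation - diag(3))) < 1e-6,
            det(rotation) > 0)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "frame_to_world")
}

#' Transform a camera-frame cloud to world space
#'
#' @param points n x 3 camera-frame points (mm).
#' @param tf a [frame_to_world()] transform.
#' @param inverse apply the world-to-camera inverse instead.
#' @return n x 3 world-frame points.
#' @export
to_world <- function(points, tf, inverse = FALSE) {
  points <- matrix(points, ncol = 3)
  if (inverse) {
    sweep(points, 2, tf$translation) %*% tf$rotation
  } else {
    points %*% t(tf$rotation) +
      matrix(tf$translation, nrow(points), 3, byrow = TRUE)
  }
}

#' Fuse two world-frame point clouds on a voxel grid
#'
#' Concatenates the clouds and keeps one representative (centroid) per
#' occupied voxel, so repeated surface observations collapse instead of
#' accumulating.
#'
#' @param global_cloud,new_cloud n x 3 world-frame matrices (either may be
#'   empty).
#' @param voxel_size voxel edge in mm (default 1).
#' @return fused n x 3 matrix.
#' @export
fuse <- function(global_cloud, new_cloud, voxel_size = 1.0) {
  if (is.null(global_cloud) || nrow(global_cloud) == 0) {
    both <- matrix(new_cloud, ncol = 3)
  } else if (is.null(new_cloud) || nrow(new_cloud) == 0) {
    both <- matrix(global_cloud, ncol = 3)
  } else {
    both <- rbind(matrix(global_cloud, ncol = 3), matrix(new_cloud, ncol = 3))
  }
  if (nrow(both) == 0) return(both)
  voxel_downsample_cpp(both, voxel_size)
}

#' Triangulate a point cloud into a surface mesh
#'
#' Greedy-projection style local triangulation: each point's neighbourhood
#' (within \code{radius}) is projected onto its tangent plane and locally
#' Delaunay-triangulated; consistent local stars are merged into one
#' oriented mesh whose vertices are a subset of the cloud.  Sparse or
#' collinear regions are simply left untriangulated and reported via
#' \code{n_unreferenced}.
#'
#' @param cloud n x 3 matrix (>= 3 non-collinear points).
#' @param radius neighbour radius in mm; default 3x the median
#'   nearest-neighbour spacing.
#' @param k neighbours for the normal plane fit (default 20).
#' @param max_nn neighbour cap per local star (default 16).
#' @param viewpoint orientation reference for normals: a single 3-vector or
#'   an n x 3 matrix of per-point observing camera positions (default far
#'   along -z, matching a camera looking down +z).
#' @return object of class \code{surface_mesh}: \code{vertices} (n x 3),
#'   \code{faces} (m x 3, 1-based), \code{normals} (n x 3 unit),
#'   \code{n_unreferenced}.
#' @export
triangulate_surface <- function(cloud, radius = NULL, k = 20, max_nn = 16,
                                viewpoint = c(0, 0, -1e6)) {
  cloud <- matrix(cloud, ncol = 3)
  stopifnot(nrow(cloud) >= 3)
  if (is.null(radius)) {
    i <- seq(1, nrow(cloud), length.out = min(500, nrow(cloud)))
    sub <- cloud[unique(round(i)), , drop = FALSE]
    dn <- apply(sub, 1, function(p) {
      d2 <- colSums((t(cloud) - p)^2)
      sqrt(min(d2[d2 > 1e-12]))
    })
    radius <- 3 * stats::median(dn, na.rm = TRUE)
  }
  vp <- matrix(viewpoint, ncol = 3)
  normals <- estimate_normals_cpp(cloud, vp, as.integer(k),
                                  radius = 1.5 * radius)
  faces <- greedy_triangulate_cpp(cloud, normals, radius,
                                  max_nn = as.integer(max_nn))
  used <- unique(as.integer(faces))
  structure(list(vertices = cloud, faces = faces, normals = normals,
                 n_unreferenced = nrow(cloud) - length(used),
                 radius = radius),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces (%d unreferenced points)\n",
              nrow(x$vertices), nrow(x$faces), x$n_unreferenced))
  invisible(x)
}

#' Total mesh area
#' @param mesh a \code{surface_mesh}.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(face_areas(mesh))
}

face_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Write a mesh as ASCII PLY
#' @param mesh a \code{surface_mesh}.
#' @param path output path.
#' @export
write_ply_mesh <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           sprintf("element face %d", nrow(F)),
           "property list uchar int vertex_indices", "end_header")
  vb <- sprintf("%.6f %.6f %.6f %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3],
                mesh$normals[, 1], mesh$normals[, 2], mesh$normals[, 3])
  fb <- sprintf("3 %d %d %d", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1)
  writeLines(c(hdr, vb, fb), path)
  invisible(path)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a \code{surface_mesh}.
#' @param path output path.
#' @export
write_obj_mesh <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  writeLines(c(sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]),
               sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), path)
  invisible(path)
}

#' Read an ASCII PLY mesh or point cloud
#' @param path file path.
#' @return a \code{surface_mesh} (faces may be empty for a point cloud).
#' @export
read_ply_mesh <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nfl <- grep("^element face", lines, value = TRUE)
  nf <- if (length(nfl)) as.integer(sub("element face ", "", nfl)) else 0L
  vprops <- grep("^property float", lines[seq_len(end)])
  npr <- length(vprops)
  vdat <- matrix(scan(text = lines[end + seq_len(nv)], quiet = TRUE),
                 ncol = npr, byrow = TRUE)
  V <- vdat[, 1:3, drop = FALSE]
  N <- if (npr >= 6) vdat[, 4:6, drop = FALSE] else NULL
  F <- matrix(integer(0), 0, 3)
  if (nf > 0) {
    fdat <- matrix(scan(text = lines[end + nv + seq_len(nf)], quiet = TRUE),
                   ncol = 4, byrow = TRUE)
    F <- fdat[, 2:4, drop = FALSE] + 1
  }
  structure(list(vertices = V, faces = F, normals = N,
                 n_unreferenced = nrow(V) - length(unique(as.integer(F)))),
            class = "surface_mesh")
}
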