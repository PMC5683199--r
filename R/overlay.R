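# Geometry-aware AR operations on the reconstructed world-space mesh:
# ray picking, z-buffered re-projection (the interactive geometric layer),
# surface-constrained measurement, geodesic area highlighting, and
# normal-anchored label placement.

#' Surface anchor
#'
#' A point on the mesh: face id, barycentric coordinates (non-negative,
#' summing to 1), world position, and the interpolated surface normal.
#'
#' @param face face index (1-based).
#' @param bary barycentric coordinates (3).
#' @param position world position (3, mm).
#' @param normal unit surface normal (3).
#' @return object of class \code{surface_anchor}.
#' @export
surface_anchor <- function(face, bary, position, normal) {
  stopifnot(all(bary >= -1e-9), abs(sum(bary) - 1) < 1e-6)
  structure(list(face = as.integer(face), bary = as.numeric(bary),
                 position = as.numeric(position),
                 normal = as.numeric(normal) / sqrt(sum(normal^2))),
            class = "surface_anchor")
}

anchor_from_hit <- function(mesh, face, u, v) {
  tri <- mesh$faces[face, ]
  b <- c(1 - u - v, u, v)
  b <- pmax(b, 0); b <- b / sum(b)
  p <- as.numeric(b %*% mesh$vertices[tri, , drop = FALSE])
  n <- if (!is.null(mesh$normals)) {
    as.numeric(b %*% mesh$normals[tri, , drop = FALSE])
  } else {
    a <- mesh$vertices[tri[2], ] - mesh$vertices[tri[1], ]
    bb <- mesh$vertices[tri[3], ] - mesh$vertices[tri[1], ]
    c(a[2] * bb[3] - a[3] * bb[2], a[3] * bb[1] - a[1] * bb[3],
      a[1] * bb[2] - a[2] * bb[1])
  }
  surface_anchor(face, b, p, n)
}

#' Pick a surface point through a pixel
#'
#' Casts the viewing ray of an image pixel into the world and returns the
#' first (nearest) ray-mesh intersection as a [surface_anchor()]; the
#' anchor normal interpolates the vertex normals of the hit face.
#'
#' @param pixel \code{c(x, y)} pixel (0-based, inside the image).
#' @param cam_pose camera [pose()].
#' @param rig a [camera_rig()].
#' @param mesh a \code{surface_mesh}.
#' @return a \code{surface_anchor}, or \code{NULL} when the ray misses.
#' @export
pick <- function(pixel, cam_pose, rig, mesh) {
  stopifnot(pixel[1] >= 0, pixel[1] <= rig$width - 1,
            pixel[2] >= 0, pixel[2] <= rig$height - 1,
            nrow(mesh$faces) > 0)
  dir_cam <- c((pixel[1] - rig$cx) / rig$fx, (pixel[2] - rig$cy) / rig$fy, 1)
  R <- quat_to_rotmat(cam_pose$orientation)
  dir_world <- as.numeric(R %*% dir_cam)
  hit <- ray_mesh_cpp(cam_pose$position, matrix(dir_world, 1, 3),
                      mesh$vertices, mesh$faces)
  if (hit$face[1] == 0) return(NULL)
  anchor_from_hit(mesh, hit$face[1], hit$u[1], hit$v[1])
}

#' Re-project the global mesh into a camera view
#'
#' Software z-buffer rasterisation of the mesh through the camera: per-pixel
#' depth and face-id buffers, the "interactive geometric layer" that AR
#' overlays are drawn from.
#'
#' @param mesh a \code{surface_mesh}.
#' @param cam_pose camera [pose()].
#' @param rig a [camera_rig()].
#' @return list \code{depth} (h x w mm, NA where empty) and \code{face}
#'   (h x w face ids, 0 where empty).
#' @export
reproject_mesh <- function(mesh, cam_pose, rig) {
  Vc <- transform_points(mesh$vertices, cam_pose, inverse = TRUE)
  ras <- raster_mesh_cpp(Vc, mesh$faces, matrix(0, nrow(Vc), 0),
                         rig$fx, rig$fy, rig$cx, rig$cy,
                         rig$width, rig$height)
  list(depth = ras$depth, face = ras$face)
}

mesh_edge_graph <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  list(edges = e, lengths = len)
}

#' Measure a distance along the reconstructed surface
#'
#' Shortest path between two anchors along the mesh: Dijkstra over the mesh
#' edge graph (anchors linked to their faces' vertices), then iterative
#' path straightening that slides the intermediate points along the crossed
#' mesh edges.  The returned polyline lies on the mesh and its length is
#' always at least the straight-line chord between the anchors.
#'
#' @param a,b [surface_anchor()]s on the mesh.
#' @param mesh the \code{surface_mesh}.
#' @param refine_iterations maximum straightening sweeps (default 120;
#'   sweeps stop early once the path stops moving).
#' @return object of class \code{surface_path}: \code{points} (polyline,
#'   world mm), \code{length_mm}, \code{chord_mm}.
#' @export
measure_on_surface <- function(a, b, mesh, refine_iterations = 120) {
  V <- mesh$vertices
  F <- mesh$faces
  n <- nrow(V)
  # unique mesh edges and one midpoint node per edge
  eall <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  ekey <- paste(pmin(eall[, 1], eall[, 2]), pmax(eall[, 1], eall[, 2]))
  ukey <- !duplicated(ekey)
  edges <- cbind(pmin(eall[ukey, 1], eall[ukey, 2]),
                 pmax(eall[ukey, 1], eall[ukey, 2]))
  ne <- nrow(edges)
  eid <- match(ekey, ekey[ukey])  # 3 per face: edges 12, 23, 31
  nf <- nrow(F)
  eid <- matrix(eid, nf, 3)
  mid <- (V[edges[, 1], , drop = FALSE] + V[edges[, 2], , drop = FALSE]) / 2
  # graph nodes: vertices, edge midpoints, anchor a, anchor b
  coords <- rbind(V, mid, a$position, b$position)
  face_nodes <- cbind(F, n + eid)  # 6 nodes per face
  pair_idx <- utils::combn(6, 2)
  ge <- do.call(rbind, lapply(seq_len(ncol(pair_idx)), function(k) {
    cbind(face_nodes[, pair_idx[1, k]], face_nodes[, pair_idx[2, k]])
  }))
  ge <- rbind(ge,
              cbind(n + ne + 1, as.integer(face_nodes[a$face, ])),
              cbind(n + ne + 2, as.integer(face_nodes[b$face, ])))
  wl <- sqrt(rowSums((coords[ge[, 1], , drop = FALSE] -
                        coords[ge[, 2], , drop = FALSE])^2))
  g <- igraph::make_graph(t(ge), n = n + ne + 2, directed = FALSE)
  igraph::E(g)$weight <- wl
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = n + ne + 1, to = n + ne + 2,
                           output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2) {
    stop("anchors lie in disconnected mesh components: unreachable")
  }
  interior <- vp[vp <= n + ne]
  pts <- rbind(a$position, coords[interior, , drop = FALSE], b$position)
  # sliding refinement: midpoint nodes move along their mesh edge, mesh
  # vertices stay put
  on_edge <- interior > n
  epts <- interior - n
  s <- rep(0.5, length(interior))
  pos_of <- function(k) {
    if (!on_edge[k]) return(V[interior[k], ])
    e <- edges[epts[k], ]
    V[e[1], ] + s[k] * (V[e[2], ] - V[e[1], ])
  }
  if (length(interior) > 0) {
    for (it in seq_len(refine_iterations)) {
      moved <- 0
      order_k <- if (it %% 2 == 1) seq_along(interior) else
        rev(seq_along(interior))  # alternate sweep direction
      for (k in order_k) {
        if (!on_edge[k]) next
        prev <- if (k == 1) a$position else pos_of(k - 1)
        nxt <- if (k == length(interior)) b$position else pos_of(k + 1)
        e <- edges[epts[k], ]
        p <- V[e[1], ]; q <- V[e[2], ]
        obj <- function(t) {
          x <- p + t * (q - p)
          sqrt(sum((x - prev)^2)) + sqrt(sum((x - nxt)^2))
        }
        opt <- stats::optimize(obj, c(0, 1), tol = 1e-10)
        moved <- moved + abs(opt$minimum - s[k])
        s[k] <- opt$minimum
      }
      if (moved < 1e-9) break
    }
    pts <- rbind(a$position,
                 t(vapply(seq_along(interior), pos_of, numeric(3))),
                 b$position)
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  structure(list(points = pts, length_mm = sum(seg),
                 chord_mm = sqrt(sum((a$position - b$position)^2))),
            class = "surface_path")
}

#' @export
print.surface_path <- function(x, ...) {
  cat(sprintf("surface_path: %.3f mm along the surface (chord %.3f mm, %d points)\n",
              x$length_mm, x$chord_mm, nrow(x$points)))
  invisible(x)
}

#' Geodesic distance field from an anchor
#'
#' Per-vertex distance along the surface from the anchor point, computed by
#' iterative triangle-unfolding relaxation (first-order geodesic
#' approximation; exact on planar meshes).
#'
#' @param anchor a [surface_anchor()].
#' @param mesh the \code{surface_mesh}.
#' @return numeric vector, one distance (mm) per mesh vertex.
#' @export
geodesic_distances <- function(anchor, mesh) {
  fa <- mesh$faces[anchor$face, ]
  d0 <- sqrt(colSums((t(mesh$vertices[fa, , drop = FALSE]) -
                        anchor$position)^2))
  geodesic_dist_cpp(mesh$vertices, mesh$faces, fa, d0)
}

#' Highlight a surface area around an anchor
#'
#' Geodesic flood fill: all faces whose centroid lies within the given
#' surface distance of the seed anchor; the highlighted area is the summed
#' face area.  An infinite radius highlights the whole mesh.
#'
#' @param anchor seed [surface_anchor()].
#' @param radius surface-distance bound in mm (may be \code{Inf}).
#' @param mesh the \code{surface_mesh}.
#' @return list \code{faces} (indices), \code{area_mm2}, \code{distances}
#'   (per-vertex geodesic field).
#' @export
highlight_area <- function(anchor, radius, mesh) {
  d <- geodesic_distances(anchor, mesh)
  cd <- (d[mesh$faces[, 1]] + d[mesh$faces[, 2]] + d[mesh$faces[, 3]]) / 3
  sel <- which(is.finite(cd) & cd <= radius)
  areas <- face_areas(mesh)
  list(faces = sel, area_mm2 = sum(areas[sel]), distances = d)
}

#' Place an oriented label at a surface anchor
#'
#' The label plane sits at the anchor with its normal equal to the anchor's
#' surface normal; the in-plane spin aligns the label's up direction with
#' the camera up-vector at placement time.
#'
#' @param anchor a [surface_anchor()].
#' @param cam_pose camera [pose()] at placement (fixes the in-plane spin).
#' @param size_mm label edge length (default 5).
#' @return list \code{position}, \code{normal}, \code{up}, \code{right},
#'   \code{corners} (4 x 3 world coordinates).
#' @export
place_label <- function(anchor, cam_pose = pose(), size_mm = 5) {
  nrm <- anchor$normal
  R <- quat_to_rotmat(cam_pose$orientation)
  cam_up <- as.numeric(R %*% c(0, -1, 0))  # image y points down
  rightv <- c(cam_up[2] * nrm[3] - cam_up[3] * nrm[2],
              cam_up[3] * nrm[1] - cam_up[1] * nrm[3],
              cam_up[1] * nrm[2] - cam_up[2] * nrm[1])
  if (sqrt(sum(rightv^2)) < 1e-9) rightv <- c(1, 0, 0)
  rightv <- rightv / sqrt(sum(rightv^2))
  upv <- c(nrm[2] * rightv[3] - nrm[3] * rightv[2],
           nrm[3] * rightv[1] - nrm[1] * rightv[3],
           nrm[1] * rightv[2] - nrm[2] * rightv[1])
  h <- size_mm / 2
  corners <- rbind(anchor$position - h * rightv - h * upv,
                   anchor$position + h * rightv - h * upv,
                   anchor$position + h * rightv + h * upv,
                   anchor$position - h * rightv + h * upv)
  list(position = anchor$position, normal = nrm, up = upv, right = rightv,
       corners = corners)
}

#' Render and write an AR overlay frame as PNG
#'
#' Composites the re-projected geometric layer over a camera image: mesh
#' coverage is tinted, and optional anchors and surface paths are projected
#' and drawn on top.
#'
#' @param image grayscale frame (0-255 matrix).
#' @param mesh the \code{surface_mesh} (may be \code{NULL}).
#' @param cam_pose camera [pose()].
#' @param rig a [camera_rig()].
#' @param path output PNG path.
#' @param anchors list of [surface_anchor()]s drawn as dots.
#' @param paths list of \code{surface_path}s drawn as polylines.
#' @return the output path, invisibly.
#' @export
write_overlay_png <- function(image, mesh, cam_pose, rig, path,
                              anchors = list(), paths = list()) {
  img <- as_gray(image) / 255
  rgb <- array(rep(img, 3), c(nrow(img), ncol(img), 3))
  if (!is.null(mesh) && nrow(mesh$faces) > 0) {
    buf <- reproject_mesh(mesh, cam_pose, rig)
    cov <- is.finite(buf$depth)
    # green tint over mesh coverage
    g <- rgb[, , 2]
    g[cov] <- pmin(1, g[cov] * 0.7 + 0.3)
    rgb[, , 2] <- g
  }
  draw_disc <- function(px, py, channel, radius = 3) {
    xs <- round(px) + (-radius):radius
    ys <- round(py) + (-radius):radius
    for (x in xs[xs >= 0 & xs < rig$width]) {
      for (y in ys[ys >= 0 & ys < rig$height]) {
        if ((x - px)^2 + (y - py)^2 <= radius^2) {
          for (ch in 1:3) rgb[y + 1, x + 1, ch] <<- as.numeric(ch == channel)
        }
      }
    }
  }
  for (p in paths) {
    pr <- project_points(p$points, cam_pose, rig)
    ok <- which(pr$in_image)
    for (k in ok) draw_disc(pr$x[k], pr$y[k], 2, radius = 1)
  }
  for (a in anchors) {
    pr <- project_points(matrix(a$position, 1), cam_pose, rig)
    if (isTRUE(pr$in_image)) draw_disc(pr$x, pr$y, 1)
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Serialise anchors and paths to a JSON sidecar
#'
#' @param anchors list of [surface_anchor()]s.
#' @param paths list of \code{surface_path}s.
#' @param path output JSON file.
#' @export
write_overlay_json <- function(anchors = list(), paths = list(), path) {
  obj <- list(
    anchors = lapply(anchors, function(a) {
      list(face = a$face, bary = a$bary, position = a$position,
           normal = a$normal)
    }),
    paths = lapply(paths, function(p) {
      list(length_mm = p$length_mm, chord_mm = p$chord_mm,
           points = unname(apply(p$points, 1, as.numeric, simplify = FALSE)))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
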