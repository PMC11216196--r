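#' Build a bounding-volume hierarchy over a mesh
#'
#' Axis-aligned BVH by median split on the face-centroid longest axis, leaves
#' holding at most `leaf_size` faces.  Only valid (non-degenerate) faces are
#' indexed; hit face indices always refer to the original mesh.  Construction
#' is deterministic for a given mesh.
#'
#' @param mesh A [triangle_mesh()].
#' @param leaf_size Maximum faces per leaf.
#' @return An object of class `bvh` usable with [intersect_first_hit()] and
#'   [cast_rays()].
#' @export
build_bvh <- function(mesh, leaf_size = 4L) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  keep <- which(mesh$valid)
  if (length(keep) == 0L) stop("mesh has no valid (non-degenerate) faces")
  faces <- mesh$faces[keep, , drop = FALSE]
  tree <- cpp_bvh_build(mesh$vertices, faces, as.integer(leaf_size))
  structure(list(tree = tree, faces = faces, face_map = keep,
                 vertices = mesh$vertices),
            class = "bvh")
}

#' Cast a batch of rays and return first hits
#'
#' For each ray, finds the intersection with the smallest distance
#' `t > t_min` over all valid faces (both windings; photogrammetric meshes
#' have inconsistent orientation).  Misses are returned as NA rows, not
#' errors.  When two candidate hits are within 1e-12 m along the ray the
#' lower face index is reported, so results are deterministic.
#'
#' @param bvh A [build_bvh()] index.
#' @param origins n x 3 matrix of ray origins (metres).
#' @param directions n x 3 matrix of unit ray directions.
#' @param t_min Minimum hit distance (self-intersection guard), metres.
#' @return A data.frame with columns `face` (original mesh face index, NA on
#'   miss), `t`, `x`, `y`, `z`, `b0`, `b1`, `b2`.
#' @export
cast_rays <- function(bvh, origins, directions, t_min = 1e-6) {
  stopifnot(inherits(bvh, "bvh"))
  origins <- matrix(as.numeric(origins), ncol = 3L)
  directions <- matrix(as.numeric(directions), ncol = 3L)
  if (nrow(origins) != nrow(directions))
    stop("origins and directions must have the same number of rows")
  hits <- cpp_raycast(bvh$vertices, bvh$faces, bvh$tree,
                      origins, directions, t_min)
  face <- bvh$face_map[hits[, 1L]]
  data.frame(face = ifelse(is.na(hits[, 1L]), NA_integer_, face),
             t = hits[, 2L], x = hits[, 3L], y = hits[, 4L], z = hits[, 5L],
             b0 = hits[, 6L], b1 = hits[, 7L], b2 = hits[, 8L])
}

#' First intersection of one ray with a mesh
#'
#' @param ray A `ray` from [pixel_to_ray()], or a list with `origin` and
#'   `direction`.
#' @inheritParams cast_rays
#' @return A list (`face`, `t`, `point`, `barycentric`) or NULL on miss.
#' @export
intersect_first_hit <- function(ray, bvh, t_min = 1e-6) {
  h <- cast_rays(bvh, matrix(ray$origin, 1L, 3L),
                 matrix(ray$direction, 1L, 3L), t_min = t_min)
  if (is.na(h$face[1L])) return(NULL)
  list(face = h$face[1L], t = h$t[1L],
       point = c(h$x[1L], h$y[1L], h$z[1L]),
       barycentric = c(h$b0[1L], h$b1[1L], h$b2[1L]))
}
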