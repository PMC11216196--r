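#' A reprojected (3D) annotation
#'
#' Produced by [reproject_annotation()].  `status` is `"reprojected"` when
#' every 2D vertex hit the mesh, `"partial"` when some vertices missed but at
#' least three survived (lenient mode only), and `"discarded"` when the
#' annotation could not be placed on the model (its geometry is then empty).
#'
#' @param annotation_id,label,source_image Carried over from the 2D
#'   annotation.
#' @param status One of `"reprojected"`, `"partial"`, `"discarded"`.
#' @param vertices_local k x 3 matrix of mesh hit points (metres), or NULL.
#' @param vertices_geo k x 3 matrix of (lat, lon, height), or NULL.
#' @param shape Original 2D shape name.
#' @param radius_m Estimated 3D radius for Circle annotations (else NA).
#' @return An object of class `annotation3d`.
#' @export
annotation3d <- function(annotation_id, label, source_image, status,
                         vertices_local = NULL, vertices_geo = NULL,
                         shape = NULL, radius_m = NA_real_) {
  status <- match.arg(status, c("reprojected", "partial", "discarded"))
  if (status == "discarded" &&
      !is.null(vertices_local) && nrow(vertices_local) > 0L)
    stop("a discarded annotation must have empty geometry")
  if (!is.null(vertices_geo) && !is.null(vertices_local) &&
      nrow(vertices_geo) != nrow(vertices_local))
    stop("local and geodetic vertex lists must have the same length")
  structure(list(annotation_id = as.character(annotation_id),
                 label = as.character(label),
                 source_image = as.character(source_image),
                 status = status, vertices_local = vertices_local,
                 vertices_geo = vertices_geo, shape = shape,
                 radius_m = radius_m),
            class = "annotation3d")
}

#' Reproject one annotated pixel onto the mesh
#'
#' Rescales the annotated pixel to the calibrated resolution (when
#' `annotated_size` is given), builds the viewing ray and returns the first
#' ray-mesh intersection — the 3D position of the annotated feature.
#'
#' @param pixel Length-2 (u, v) in annotated-image pixels.
#' @param camera Camera entry (list with `intrinsics` and `pose`).
#' @param bvh A [build_bvh()] index over the scene mesh.
#' @param annotated_size Optional (width, height) of the annotated image.
#' @return Length-3 hit point in the local frame, or NULL on miss.
#' @export
reproject_vertex <- function(pixel, camera, bvh, annotated_size = NULL) {
  if (!is.null(annotated_size))
    pixel <- scale_annotation_pixel(pixel, annotated_size, camera$intrinsics)
  ray <- pixel_to_ray(pixel, camera$intrinsics, camera$pose)
  hit <- intersect_first_hit(ray, bvh)
  if (is.null(hit)) NULL else hit$point
}

#' Reproject a 2D annotation onto the mesh
#'
#' Each vertex of the annotation is cast onto the mesh; the 3D position of a
#' vertex is the first intersection of its viewing ray with the model.  A
#' `Point` whose ray misses the model is discarded.  For multi-vertex shapes
#' the default (`mode = "strict"`) discards the whole annotation when any
#' vertex misses; `mode = "lenient"` drops missing vertices and returns a
#' `partial` annotation when at least three vertices survive.  A `Circle` is
#' reprojected at its center, with the 3D radius estimated from the
#' reprojection of the rim point `(cx + r, cy)`.
#'
#' @param annotation An [annotation2d()].
#' @param camera Camera entry matching the annotation's image.
#' @param bvh A [build_bvh()] index.
#' @param mode `"strict"` (default) or `"lenient"` handling of partial
#'   polygon misses.
#' @param anchor Optional [geo_anchor()]; when supplied, vertices are also
#'   georeferenced to WGS84.
#' @return An [annotation3d()].
#' @export
reproject_annotation <- function(annotation, camera, bvh,
                                 mode = c("strict", "lenient"),
                                 anchor = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "annotation2d"))
  asize <- annotation$annotated_image_size
  finish <- function(status, vl = NULL, radius = NA_real_) {
    vg <- NULL
    if (!is.null(vl) && !is.null(anchor)) vg <- local_to_geodetic(vl, anchor)
    annotation3d(annotation$annotation_id, annotation$label,
                 annotation$image_filename, status, vl, vg,
                 shape = annotation$shape, radius_m = radius)
  }

  if (annotation$shape == "Circle") {
    ctr <- reproject_vertex(annotation$points[1:2], camera, bvh, asize)
    if (is.null(ctr)) return(finish("discarded"))
    rim <- reproject_vertex(annotation$points[1:2] + c(annotation$points[3], 0),
                            camera, bvh, asize)
    radius <- if (is.null(rim)) NA_real_ else sqrt(sum((rim - ctr)^2))
    return(finish("reprojected", matrix(ctr, 1L, 3L), radius))
  }

  verts2d <- ann_vertices(annotation)
  hits <- vector("list", nrow(verts2d))
  for (i in seq_len(nrow(verts2d)))
    hits[i] <- list(reproject_vertex(verts2d[i, ], camera, bvh, asize))
  missed <- vapply(hits, is.null, TRUE)

  if (annotation$shape == "Point")
    return(if (missed[1L]) finish("discarded")
           else finish("reprojected", matrix(hits[[1L]], 1L, 3L)))

  if (!any(missed))
    return(finish("reprojected", do.call(rbind, hits)))
  if (mode == "strict") return(finish("discarded"))
  survivors <- hits[!missed]
  if (length(survivors) < 3L) return(finish("discarded"))
  finish("partial", do.call(rbind, survivors))
}

#' Reproject a whole annotation set
#'
#' Matches each annotation to its camera by exact filename (optionally
#' falling back to a case-insensitive stem match), reprojects it, and checks
#' conservation: every input annotation comes out exactly once, as
#' reprojected, partial or discarded.
#'
#' @param annotation_set An `annotation_set` from [read_biigle_csv()], or a
#'   plain list of [annotation2d()].
#' @param cameras A `camera_set` from [parse_camera_file()].
#' @param bvh A [build_bvh()] index.
#' @param mode Polygon miss handling, see [reproject_annotation()].
#' @param anchor Optional [geo_anchor()]; defaults to the camera set's.
#' @param fuzzy_match Allow case-insensitive filename-stem camera matching.
#' @return List with `annotations` (list of [annotation3d()]) and `counts`
#'   (named vector: input, reprojected, partial, discarded).
#' @export
reproject_annotations <- function(annotation_set, cameras, bvh,
                                  mode = c("strict", "lenient"),
                                  anchor = NULL, fuzzy_match = FALSE) {
  mode <- match.arg(mode)
  anns <- if (inherits(annotation_set, "annotation_set"))
    annotation_set$annotations else annotation_set
  if (is.null(anchor)) anchor <- attr(cameras, "anchor")
  fns <- vapply(cameras, `[[`, "", "filename")
  stems <- tolower(tools::file_path_sans_ext(basename(fns)))
  find_camera <- function(fn) {
    i <- match(fn, fns)
    if (is.na(i) && fuzzy_match)
      i <- match(tolower(tools::file_path_sans_ext(basename(fn))), stems)
    i
  }
  missing_fns <- unique(vapply(anns, `[[`, "", "image_filename"))
  missing_fns <- missing_fns[is.na(vapply(missing_fns, find_camera, 0L))]
  if (length(missing_fns) > 0L)
    stop(sprintf("no camera for image(s): %s",
                 paste(missing_fns, collapse = ", ")))
  out <- vector("list", length(anns))
  for (i in seq_along(anns)) {
    cam <- cameras[[find_camera(anns[[i]]$image_filename)]]
    out[[i]] <- reproject_annotation(anns[[i]], cam, bvh, mode = mode,
                                     anchor = anchor)
  }
  status <- vapply(out, `[[`, "", "status")
  counts <- c(input = length(anns),
              reprojected = sum(status == "reprojected"),
              partial = sum(status == "partial"),
              discarded = sum(status == "discarded"))
  stopifnot(counts[["input"]] ==
              counts[["reprojected"]] + counts[["partial"]] +
              counts[["discarded"]])
  list(annotations = out, counts = counts)
}

#' Compute the on-mesh footprint of an image
#'
#' Casts rays through the four image corners (order: top-left, top-right,
#' bottom-right, bottom-left) plus `densify_n` evenly spaced boundary pixels
#' per edge, and collects the mesh hit points in boundary order.  Status is
#' `complete` when every boundary ray hit, `partial` with at least three
#' hits, `discarded` otherwise.  Corner-only footprints (`densify_n = 0`)
#' under-represent relief on rugged terrain, which is why densification is
#' exposed.
#'
#' @param camera Camera entry (list with `intrinsics` and `pose`).
#' @param bvh A [build_bvh()] index.
#' @param densify_n Extra boundary points per edge (>= 0).
#' @param anchor Optional [geo_anchor()] to georeference the vertices.
#' @return An object of class `footprint`: `image_filename`,
#'   `vertices_local`, `vertices_geo` (or NULL), `status`, `n_rays`,
#'   `n_hits`.
#' @export
compute_footprint <- function(camera, bvh, densify_n = 0L, anchor = NULL) {
  stopifnot(densify_n >= 0L)
  w <- camera$intrinsics$image_size[1]
  h <- camera$intrinsics$image_size[2]
  corners <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
  boundary <- NULL
  for (e in 1:4) {
    a <- corners[e, ]
    b <- corners[if (e == 4L) 1L else e + 1L, ]
    boundary <- rbind(boundary, a)
    if (densify_n > 0L) {
      fr <- seq_len(densify_n) / (densify_n + 1)
      boundary <- rbind(boundary,
                        outer(fr, b - a) + matrix(a, densify_n, 2L,
                                                  byrow = TRUE))
    }
  }
  dirs <- t(apply(boundary, 1L, function(px) {
    n <- undistort_pixel(px, camera$intrinsics)
    d <- as.numeric(t(camera$pose$rotation) %*% c(n, 1))
    d / sqrt(sum(d^2))
  }))
  origins <- matrix(camera$pose$center, nrow(dirs), 3L, byrow = TRUE)
  hits <- cast_rays(bvh, origins, dirs)
  ok <- !is.na(hits$face)
  status <- if (all(ok)) "complete" else if (sum(ok) >= 3L) "partial"
            else "discarded"
  vl <- if (sum(ok) > 0L && status != "discarded")
    as.matrix(hits[ok, c("x", "y", "z")]) else NULL
  vg <- if (!is.null(vl) && !is.null(anchor)) local_to_geodetic(vl, anchor)
        else NULL
  structure(list(image_filename = camera$filename %||% camera$pose$image_id,
                 vertices_local = vl, vertices_geo = vg, status = status,
                 n_rays = nrow(boundary), n_hits = sum(ok)),
            class = "footprint")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a 3D feature back in survey images
#'
#' Projects a 3D point into every camera; a camera is a candidate when the
#' point projects in front of it inside the image bounds, and `visible` when
#' the viewing ray through that pixel actually first hits the mesh within
#' `epsilon` of the query point (occlusion test).  This supports re-finding
#' a feature, once reprojected, on images taken from other angles.
#'
#' @param point_local Length-3 point on or near the mesh.
#' @param cameras A `camera_set` or list of camera entries.
#' @param bvh A [build_bvh()] index.
#' @param epsilon Visibility tolerance in metres (default 1e-3, an order
#'   below typical model resolution).
#' @return data.frame with columns `image`, `u`, `v`, `candidate`, `visible`.
#' @export
locate_in_images <- function(point_local, cameras, bvh, epsilon = 1e-3) {
  n <- length(cameras)
  res <- data.frame(image = character(n), u = NA_real_, v = NA_real_,
                    candidate = FALSE, visible = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cam <- cameras[[i]]
    res$image[i] <- cam$filename %||% cam$pose$image_id
    px <- project_point(point_local, cam$intrinsics, cam$pose)
    if (any(is.na(px))) next
    res$u[i] <- px[1]
    res$v[i] <- px[2]
    w <- cam$intrinsics$image_size[1]
    h <- cam$intrinsics$image_size[2]
    if (px[1] < 0 || px[1] > w || px[2] < 0 || px[2] > h) next
    res$candidate[i] <- TRUE
    hit <- intersect_first_hit(pixel_to_ray(px, cam$intrinsics, cam$pose),
                               bvh)
    if (!is.null(hit) &&
        sqrt(sum((hit$point - point_local)^2)) <= epsilon)
      res$visible[i] <- TRUE
  }
  res
}
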