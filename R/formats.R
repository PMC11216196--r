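#' A single 2D image annotation
#'
#' Geometry is a flat coordinate list `[x1, y1, x2, y2, ...]` in
#' annotated-image pixels, as exported by BIIGLE CSV reports.  `Circle` is
#' the one odd-length shape: `[cx, cy, r]`.
#'
#' @param annotation_id Identifier (kept as character).
#' @param image_filename Image the annotation was made on.
#' @param shape One of `"Point"`, `"Polygon"`, `"Rectangle"`, `"Circle"`,
#'   `"LineString"`.
#' @param points Flat numeric coordinate list.
#' @param label Label (taxon/feature) name.
#' @param annotated_image_size Optional length-2 (width, height) of the
#'   annotated image, in pixels.
#' @return An object of class `annotation2d`.
#' @export
annotation2d <- function(annotation_id, image_filename, shape, points, label,
                         annotated_image_size = NULL) {
  shape <- match.arg(shape,
                     c("Point", "Polygon", "Rectangle", "Circle", "LineString"))
  points <- as.numeric(points)
  if (any(!is.finite(points))) stop("annotation points must be finite")
  np <- length(points)
  ok <- switch(shape,
               Point = np == 2L,
               Circle = np == 3L && points[3] > 0,
               Polygon = np >= 6L && np %% 2L == 0L,
               Rectangle = np == 8L,
               LineString = np >= 4L && np %% 2L == 0L)
  if (!ok)
    stop(sprintf("annotation %s: %d coordinates is invalid for shape %s",
                 annotation_id, np, shape))
  structure(list(annotation_id = as.character(annotation_id),
                 image_filename = as.character(image_filename),
                 shape = shape, points = points, label = as.character(label),
                 annotated_image_size =
                   if (is.null(annotated_image_size)) NULL
                   else as.numeric(annotated_image_size)),
            class = "annotation2d")
}

ann_vertices <- function(a) {
  if (a$shape == "Circle") matrix(a$points[1:2], 1L, 2L)
  else matrix(a$points, ncol = 2L, byrow = TRUE)
}

#' Parse a camera file (JSON)
#'
#' The schema mirrors structure-from-motion exports: a top-level
#' `"intrinsics"` object mapping intrinsic ids to
#' `{focal, cx, cy, width, height, k1, k2, k3}` and a `"views"` object
#' mapping image filenames to
#' `{intrinsic_id, rotation: [9 numbers, row-major world->camera],
#' center: [3 numbers]}`.  An optional top-level `"anchor"`
#' (`{lat, lon, height}`) georeferences the local frame.
#'
#' @param path Path to the camera JSON file.
#' @return An object of class `camera_set`: a list of cameras, each a list
#'   with `intrinsics`, `pose` and `filename`; the anchor (or NULL) is in
#'   `attr(, "anchor")`.
#' @export
parse_camera_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("camera file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$intrinsics) || is.null(doc$views))
    stop(sprintf("camera file %s must contain 'intrinsics' and 'views'", path))
  intr <- lapply(doc$intrinsics, function(it) {
    if (!is.null(it$t1) || !is.null(it$t2) || !is.null(it$p1) || !is.null(it$p2))
      stop("tangential distortion coefficients are not supported (radial K3 only)")
    camera_intrinsics(it$focal, c(it$cx, it$cy), c(it$width, it$height),
                      c(val_or(it$k1, 0), val_or(it$k2, 0), val_or(it$k3, 0)))
  })
  fns <- names(doc$views)
  if (anyDuplicated(fns))
    stop(sprintf("duplicate view filename(s) in %s: %s", path,
                 paste(unique(fns[duplicated(fns)]), collapse = ", ")))
  cams <- vector("list", length(fns))
  for (i in seq_along(fns)) {
    v <- doc$views[[i]]
    iid <- as.character(v$intrinsic_id)
    if (is.null(intr[[iid]]))
      stop(sprintf("view '%s' references unknown intrinsic_id '%s'",
                   fns[i], iid))
    R <- matrix(as.numeric(unlist(v$rotation)), 3L, 3L, byrow = TRUE)
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
      stop(sprintf("view '%s': rotation is not a proper orthonormal matrix (tolerance 1e-6)",
                   fns[i]))
    pose <- camera_pose(project_to_so3(R), as.numeric(unlist(v$center)),
                        image_id = fns[i])
    cams[[i]] <- list(intrinsics = intr[[iid]], pose = pose,
                      filename = fns[i])
  }
  names(cams) <- fns
  anchor <- NULL
  if (!is.null(doc$anchor))
    anchor <- geo_anchor(doc$anchor$lat, doc$anchor$lon,
                         val_or(doc$anchor$height, 0))
  structure(cams, class = "camera_set", anchor = anchor)
}

val_or <- function(x, default) if (is.null(x)) default else x

# snap a near-orthonormal matrix onto SO(3) (polar decomposition via SVD)
project_to_so3 <- function(R) {
  s <- svd(R)
  Q <- s$u %*% t(s$v)
  if (det(Q) < 0) Q <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  Q
}

#' Write a camera set to the camera JSON schema
#'
#' Inverse of [parse_camera_file()]; identical intrinsics are pooled under
#' one intrinsic id.
#'
#' @param cameras A `camera_set` or plain list of camera entries.
#' @param path Output path.
#' @param anchor Optional [geo_anchor()] stored at the top level.
#' @return `path`, invisibly.
#' @export
write_camera_file <- function(cameras, path, anchor = NULL) {
  keys <- vapply(cameras, function(cm)
    paste(c(cm$intrinsics$focal_px, cm$intrinsics$principal_point,
            cm$intrinsics$image_size, cm$intrinsics$distortion),
          collapse = "|"), "")
  uk <- unique(keys)
  intr <- list()
  for (i in seq_along(uk)) {
    it <- cameras[[match(uk[i], keys)]]$intrinsics
    intr[[as.character(i - 1L)]] <-
      list(focal = it$focal_px, cx = it$principal_point[1],
           cy = it$principal_point[2], width = it$image_size[1],
           height = it$image_size[2], k1 = it$distortion[1],
           k2 = it$distortion[2], k3 = it$distortion[3])
  }
  views <- list()
  for (i in seq_along(cameras)) {
    cm <- cameras[[i]]
    views[[cm$filename]] <-
      list(intrinsic_id = as.character(match(keys[i], uk) - 1L),
           rotation = as.numeric(t(cm$pose$rotation)),
           center = cm$pose$center)
  }
  doc <- list(intrinsics = intr, views = views)
  if (!is.null(anchor))
    doc$anchor <- list(lat = anchor$lat0, lon = anchor$lon0,
                       height = anchor$h0)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Convert an OpenMVG sfm_data.json export to a camera set
#'
#' Thin adapter for the `sfm_data.json` produced by OpenMVG's SfM pipelines
#' (as embedded in Matisse3D): reads `views`, `intrinsics`
#' (`pinhole_radial_k3`) and `extrinsics` and returns the same structure as
#' [parse_camera_file()].  Views without a reconstructed pose are skipped.
#'
#' @param path Path to sfm_data.json.
#' @return A `camera_set`.
#' @export
convert_sfm_data <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  unwrap <- function(x) if (!is.null(x$ptr_wrapper)) x$ptr_wrapper$data else x
  intr <- list()
  for (it in doc$intrinsics) {
    d <- unwrap(it$value)
    k <- as.numeric(unlist(d$disto_k3))
    if (is.null(k) || length(k) == 0L) k <- c(0, 0, 0)
    intr[[as.character(it$key)]] <-
      camera_intrinsics(d$focal_length,
                        as.numeric(unlist(d$principal_point)),
                        c(d$width, d$height), k)
  }
  poses <- list()
  for (ex in doc$extrinsics) {
    d <- ex$value
    R <- do.call(rbind, lapply(d$rotation, function(r) as.numeric(unlist(r))))
    poses[[as.character(ex$key)]] <-
      list(rotation = R, center = as.numeric(unlist(d$center)))
  }
  cams <- list()
  for (v in doc$views) {
    d <- unwrap(v$value)
    pid <- as.character(d$id_pose)
    iid <- as.character(d$id_intrinsic)
    if (is.null(poses[[pid]]) || is.null(intr[[iid]])) next
    pose <- camera_pose(project_to_so3(poses[[pid]]$rotation),
                        poses[[pid]]$center, image_id = d$filename)
    cams[[d$filename]] <- list(intrinsics = intr[[iid]], pose = pose,
                               filename = d$filename)
  }
  structure(cams, class = "camera_set", anchor = NULL)
}

biigle_col <- function(headers, synonyms, what, path) {
  hit <- intersect(synonyms, headers)
  if (length(hit) == 0L)
    stop(sprintf("annotation CSV %s lacks a %s column (expected one of: %s; found: %s)",
                 path, what, paste(synonyms, collapse = ", "),
                 paste(headers, collapse = ", ")))
  hit[1L]
}

parse_points_field <- function(s) {
  s <- gsub("[][]", "", s)
  as.numeric(strsplit(s, ",")[[1]])
}

#' Read a BIIGLE-style annotation CSV report
#'
#' Expects a header with (synonyms accepted) `annotation_id`/`id`,
#' `filename`/`image_filename`, `shape_name`/`shape`, `points` (a bracketed
#' numeric list, e.g. `"[512.5,384.0]"`) and `label_name`/`label`.  An
#' optional `attributes` column holding JSON with `width`/`height` supplies
#' the annotated image size.  Rows with unknown shape names are skipped with
#' a warning and counted; row conservation (`n_rows = n_parsed + n_skipped`)
#' always holds.
#'
#' @param path Path to the CSV file.
#' @return An object of class `annotation_set`: list with `annotations`
#'   (list of [annotation2d()]), `n_rows`, `n_parsed`, `n_skipped`.
#' @export
read_biigle_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation CSV not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_c <- biigle_col(names(df), c("annotation_id", "id"), "annotation id", path)
  fn_c <- biigle_col(names(df), c("filename", "image_filename"), "filename", path)
  sh_c <- biigle_col(names(df), c("shape_name", "shape"), "shape", path)
  pt_c <- biigle_col(names(df), "points", "points", path)
  lb_c <- biigle_col(names(df), c("label_name", "label"), "label", path)
  at_c <- intersect("attributes", names(df))
  known <- c("Point", "Polygon", "Rectangle", "Circle", "LineString")
  anns <- list()
  skipped <- 0L
  for (i in seq_len(nrow(df))) {
    shape <- df[[sh_c]][i]
    if (!shape %in% known) {
      warning(sprintf("row %d: unknown shape '%s' skipped", i, shape),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    size <- NULL
    if (length(at_c) == 1L && nzchar(df[[at_c]][i])) {
      att <- tryCatch(jsonlite::fromJSON(df[[at_c]][i]),
                      error = function(e) NULL)
      if (!is.null(att$width) && !is.null(att$height))
        size <- c(att$width, att$height)
    }
    anns[[length(anns) + 1L]] <-
      annotation2d(df[[id_c]][i], df[[fn_c]][i], shape,
                   parse_points_field(df[[pt_c]][i]), df[[lb_c]][i],
                   annotated_image_size = size)
  }
  structure(list(annotations = anns, n_rows = nrow(df),
                 n_parsed = length(anns), n_skipped = skipped),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d rows, %d parsed, %d skipped\n",
              x$n_rows, x$n_parsed, x$n_skipped))
  invisible(x)
}

geojson_geometry <- function(a) {
  if (is.null(a$vertices_geo) || nrow(a$vertices_geo) == 0L) return(NULL)
  coords <- lapply(seq_len(nrow(a$vertices_geo)), function(i)
    c(a$vertices_geo[i, 2], a$vertices_geo[i, 1], a$vertices_geo[i, 3]))
  shape <- val_or(a$shape, if (length(coords) == 1L) "Point" else "Polygon")
  if (shape %in% c("Point", "Circle") || length(coords) == 1L) {
    list(type = "Point", coordinates = coords[[1L]])
  } else if (shape == "LineString") {
    list(type = "LineString", coordinates = coords)
  } else {
    list(type = "Polygon", coordinates = list(c(coords, coords[1L])))
  }
}

#' Write reprojected annotations (and footprints) to GeoJSON and CSV
#'
#' Writes `<prefix>_annotations.geojson` (RFC 7946 FeatureCollection,
#' coordinates `[lon, lat, height]`) plus a flat CSV twin
#' `<prefix>_annotations.csv` with one row per vertex.  Discarded annotations
#' appear only in the CSV, with empty geometry.  If footprints are given they
#' are written to `<prefix>_footprints.geojson` the same way.
#'
#' @param annotations List of `annotation3d` objects (see
#'   [reproject_annotation()]); must already be georeferenced.
#' @param footprints Optional list of georeferenced footprints, each with
#'   `image_filename`, `status`, `vertices_geo`.
#' @param path_prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(annotations, footprints = NULL, path_prefix) {
  feats <- list()
  rows <- list()
  for (a in annotations) {
    geom <- geojson_geometry(a)
    props <- list(annotation_id = a$annotation_id, label = a$label,
                  status = a$status, source_image = a$source_image)
    if (!is.null(geom))
      feats[[length(feats) + 1L]] <-
        list(type = "Feature", geometry = geom, properties = props)
    nv <- if (is.null(a$vertices_local)) 0L else nrow(a$vertices_local)
    if (nv == 0L) {
      rows[[length(rows) + 1L]] <-
        data.frame(annotation_id = a$annotation_id, label = a$label,
                   status = a$status, source_image = a$source_image,
                   vertex = NA_integer_, x = NA_real_, y = NA_real_,
                   z = NA_real_, lat = NA_real_, lon = NA_real_,
                   height = NA_real_)
    } else {
      geo <- if (is.null(a$vertices_geo)) matrix(NA_real_, nv, 3L) else a$vertices_geo
      rows[[length(rows) + 1L]] <-
        data.frame(annotation_id = a$annotation_id, label = a$label,
                   status = a$status, source_image = a$source_image,
                   vertex = seq_len(nv), x = a$vertices_local[, 1],
                   y = a$vertices_local[, 2], z = a$vertices_local[, 3],
                   lat = geo[, 1], lon = geo[, 2], height = geo[, 3])
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  gj_path <- paste0(path_prefix, "_annotations.geojson")
  csv_path <- paste0(path_prefix, "_annotations.csv")
  jsonlite::write_json(fc, gj_path, auto_unbox = TRUE, digits = NA)
  csv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(annotation_id = character(0), label = character(0),
               status = character(0), source_image = character(0),
               vertex = integer(0), x = numeric(0), y = numeric(0),
               z = numeric(0), lat = numeric(0), lon = numeric(0),
               height = numeric(0))
  utils::write.csv(csv, csv_path, row.names = FALSE)
  written <- c(gj_path, csv_path)
  if (!is.null(footprints)) {
    ffeats <- list()
    for (fp in footprints) {
      if (is.null(fp$vertices_geo) || nrow(fp$vertices_geo) < 3L) next
      coords <- lapply(seq_len(nrow(fp$vertices_geo)), function(i)
        c(fp$vertices_geo[i, 2], fp$vertices_geo[i, 1], fp$vertices_geo[i, 3]))
      ffeats[[length(ffeats) + 1L]] <-
        list(type = "Feature",
             geometry = list(type = "Polygon",
                             coordinates = list(c(coords, coords[1L]))),
             properties = list(image = fp$image_filename,
                               status = fp$status))
    }
    fp_path <- paste0(path_prefix, "_footprints.geojson")
    jsonlite::write_json(list(type = "FeatureCollection", features = ffeats),
                         fp_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, fp_path)
  }
  invisible(written)
}

#' Read back a GeoJSON FeatureCollection written by [write_outputs()]
#'
#' @param path Path to the GeoJSON file.
#' @return The parsed FeatureCollection as a list.
#' @export
read_geojson <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}
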