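#' Specification of a synthetic survey scene
#'
#' Describes a fully synthetic seafloor survey: a height-field terrain, a
#' fixed-altitude serpentine ("lawnmower") trajectory of nadir cameras,
#' ground-truth surface features, and optionally a noisy navigation track
#' caricaturing dead reckoning with periodic acoustic resets.  Every random
#' quantity flows from `seed`.
#'
#' Defaults emulate a small deep-sea photo survey: 5 m altitude, one frame
#' per metre along track, 3 m line spacing, a 4 Mpx-style calibrated camera
#' with mild radial distortion, annotations made at twice the calibrated
#' resolution.
#'
#' @param terrain List: `type` one of `"flat"`, `"sinusoidal"` (fields
#'   `amplitude` m, `wavelength` m) or `"random_field"` (fields `amplitude`
#'   m, `smoothness` in grid cells).
#' @param extent Length-2 (x, y) extent in metres.
#' @param grid_step Terrain grid step in metres.
#' @param trajectory List: `altitude` (m, must exceed the terrain maximum),
#'   `line_spacing` (m), `shot_spacing` (m).
#' @param camera A [camera_intrinsics()].
#' @param n_features Number of ground-truth surface features.
#' @param nav_noise NULL, or list `drift` (m of random-walk step per metre
#'   travelled), `reset_interval` (m of travel between resets),
#'   `reset_sigma` (m, sd of position after a reset).
#' @param annotated_scale Annotated-image resolution as a multiple of the
#'   calibrated resolution.
#' @param seed Integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(terrain = list(type = "sinusoidal", amplitude = 0.5,
                                      wavelength = 8),
                       extent = c(40, 30), grid_step = 0.25,
                       trajectory = list(altitude = 5, line_spacing = 3,
                                         shot_spacing = 1),
                       camera = camera_intrinsics(1400, c(1000, 750),
                                                  c(2000, 1500),
                                                  c(-0.05, 0, 0)),
                       n_features = 60, nav_noise = NULL,
                       annotated_scale = 2, seed = 1L) {
  terrain$type <- match.arg(terrain$type,
                            c("flat", "sinusoidal", "random_field"))
  if (terrain$type == "sinusoidal" &&
      (is.null(terrain$amplitude) || is.null(terrain$wavelength)))
    stop("sinusoidal terrain requires fields 'amplitude' and 'wavelength'")
  if (terrain$type == "random_field" && is.null(terrain$amplitude))
    stop("random_field terrain requires field 'amplitude'")
  if (is.null(terrain$smoothness)) terrain$smoothness <- 8
  if (length(extent) != 2L || any(extent <= 0))
    stop("invalid field 'extent': need two positive lengths")
  if (grid_step <= 0) stop("invalid field 'grid_step': must be > 0")
  for (f in c("altitude", "line_spacing", "shot_spacing"))
    if (is.null(trajectory[[f]]) || trajectory[[f]] <= 0)
      stop(sprintf("invalid trajectory field '%s'", f))
  stopifnot(inherits(camera, "camera_intrinsics"))
  if (n_features < 1) stop("invalid field 'n_features': must be >= 1")
  if (!is.null(nav_noise))
    for (f in c("drift", "reset_interval", "reset_sigma"))
      if (is.null(nav_noise[[f]]) || nav_noise[[f]] < 0)
        stop(sprintf("invalid nav_noise field '%s'", f))
  if (annotated_scale <= 0) stop("invalid field 'annotated_scale'")
  structure(list(terrain = terrain, extent = as.numeric(extent),
                 grid_step = grid_step, trajectory = trajectory,
                 camera = camera, n_features = as.integer(n_features),
                 nav_noise = nav_noise, annotated_scale = annotated_scale,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# separable moving-average smoothing of a matrix (reflecting edges)
smooth_matrix <- function(m, half_width) {
  k <- max(1L, as.integer(half_width))
  w <- stats::dnorm(seq(-k, k), sd = k / 2 + 0.5)
  w <- w / sum(w)
  pad_filter <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(k)]), v, rev(v[n - seq_len(k) + 1L]))
    stats::filter(vp, w, sides = 2)[(k + 1L):(k + n)]
  }
  m <- apply(m, 2L, pad_filter)
  t(apply(t(m), 2L, pad_filter))
}

terrain_height_grid <- function(spec, x, y) {
  switch(spec$terrain$type,
         flat = matrix(0, length(x), length(y)),
         sinusoidal = outer(x, y, function(xx, yy)
           spec$terrain$amplitude *
             sin(2 * pi * xx / spec$terrain$wavelength) *
             cos(2 * pi * yy / spec$terrain$wavelength)),
         random_field = {
           z <- matrix(stats::rnorm(length(x) * length(y)),
                       length(x), length(y))
           z <- smooth_matrix(z, spec$terrain$smoothness)
           z <- z - mean(z)
           z * spec$terrain$amplitude / max(abs(z))
         })
}

# piecewise-linear height of the triangulated grid at (px, py), consistent
# with the (ll, lr, ur) / (ll, ur, ul) cell split used by generate_scene
grid_mesh_height <- function(px, py, x, y, zg) {
  step_x <- x[2] - x[1]
  step_y <- y[2] - y[1]
  i <- pmin(pmax(findInterval(px, x), 1L), length(x) - 1L)
  j <- pmin(pmax(findInterval(py, y), 1L), length(y) - 1L)
  fx <- (px - x[i]) / step_x
  fy <- (py - y[j]) / step_y
  zll <- zg[cbind(i, j)]; zlr <- zg[cbind(i + 1L, j)]
  zul <- zg[cbind(i, j + 1L)]; zur <- zg[cbind(i + 1L, j + 1L)]
  # lower triangle (fx >= fy): ll, lr, ur; upper: ll, ur, ul
  ifelse(fx >= fy,
         zll + fx * (zlr - zll) + fy * (zur - zlr),
         zll + fy * (zul - zll) + fx * (zur - zul))
}

#' Generate a synthetic survey scene
#'
#' Builds the triangulated height-field mesh, the nadir camera trajectory,
#' ground-truth features sampled on the mesh surface, and the 2D annotations
#' each feature produces in every camera that sees it (in-bounds, in front,
#' unoccluded).  When `nav_noise` is set, a noisy navigation track is
#' attached: true camera centers plus cumulative random-walk drift, reset to
#' truth (plus `reset_sigma` noise) after every `reset_interval` metres of
#' travel.  Deterministic given `spec$seed`.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene`: `mesh`, `cameras`
#'   (`camera_set`), `features` (data.frame id/label/x/y/z), `annotations`
#'   (`annotation_set`), `track` (data.frame, NULL without nav_noise),
#'   `anchor`, `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv())
  else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  ex <- spec$extent
  x <- seq(0, ex[1], by = spec$grid_step)
  y <- seq(0, ex[2], by = spec$grid_step)
  zg <- terrain_height_grid(spec, x, y)
  if (spec$trajectory$altitude <= max(zg))
    stop("trajectory altitude must exceed the maximum terrain height")

  nx <- length(x); ny <- length(y)
  verts <- cbind(rep(x, times = ny), rep(y, each = nx), as.numeric(zg))
  vid <- function(i, j) (j - 1L) * nx + i
  ii <- rep(seq_len(nx - 1L), times = ny - 1L)
  jj <- rep(seq_len(ny - 1L), each = nx - 1L)
  ll <- vid(ii, jj); lr <- vid(ii + 1L, jj)
  ul <- vid(ii, jj + 1L); ur <- vid(ii + 1L, jj + 1L)
  faces <- rbind(cbind(ll, lr, ur), cbind(ll, ur, ul))
  # interleave so lower/upper triangle of each cell are adjacent
  ord <- as.vector(rbind(seq_along(ll), seq_along(ll) + length(ll)))
  mesh <- triangle_mesh(verts, faces[ord, ])

  tr <- spec$trajectory
  margin_x <- 0.05 * ex[1]
  margin_y <- 0.05 * ex[2]
  line_y <- seq(margin_y, ex[2] - margin_y, by = tr$line_spacing)
  xs <- seq(margin_x, ex[1] - margin_x, by = tr$shot_spacing)
  R_nadir <- diag(c(1, -1, -1))  # +x_cam east, +y_cam south, +z_cam down
  cams <- list()
  centers <- NULL
  for (li in seq_along(line_y)) {
    xs_line <- if (li %% 2L == 1L) xs else rev(xs)  # serpentine
    for (xc in xs_line) {
      fn <- sprintf("img_%04d.jpg", length(cams) + 1L)
      pose <- camera_pose(R_nadir, c(xc, line_y[li], tr$altitude),
                         image_id = fn)
      cams[[fn]] <- list(intrinsics = spec$camera, pose = pose,
                         filename = fn)
      centers <- rbind(centers, c(xc, line_y[li], tr$altitude))
    }
  }
  cameras <- structure(cams, class = "camera_set", anchor = NULL)
  bvh <- build_bvh(mesh)

  labels <- c("coral", "sponge", "anemone", "crinoid", "urchin")
  n_feat <- spec$n_features
  feats <- NULL
  attempts <- 0L
  while (is.null(feats) || nrow(feats) < n_feat) {
    need <- n_feat - if (is.null(feats)) 0L else nrow(feats)
    fx <- stats::runif(need, margin_x, ex[1] - margin_x)
    fy <- stats::runif(need, margin_y, ex[2] - margin_y)
    fz <- grid_mesh_height(fx, fy, x, y, zg)
    cand <- data.frame(x = fx, y = fy, z = fz)
    seen <- vapply(seq_len(nrow(cand)), function(i) {
      any(feature_views(as.numeric(cand[i, ]), cameras, bvh)$visible)
    }, TRUE)
    if (!all(seen) && attempts == 0L)
      warning(sprintf("%d feature draw(s) not visible from any camera; resampling",
                      sum(!seen)), call. = FALSE)
    feats <- rbind(feats, cand[seen, , drop = FALSE])
    attempts <- attempts + 1L
    if (attempts > 50L)
      stop("could not place all features in view of the trajectory")
  }
  feats <- feats[seq_len(n_feat), ]
  features <- data.frame(feature_id = sprintf("F%03d", seq_len(n_feat)),
                         label = sample(labels, n_feat, replace = TRUE),
                         x = feats$x, y = feats$y, z = feats$z,
                         stringsAsFactors = FALSE)

  asize <- spec$camera$image_size * spec$annotated_scale
  anns <- list()
  ann_feature <- character(0)
  for (i in seq_len(n_feat)) {
    p <- c(features$x[i], features$y[i], features$z[i])
    vis <- feature_views(p, cameras, bvh)
    for (r in which(vis$visible)) {
      px_ann <- c(vis$u[r], vis$v[r]) * spec$annotated_scale
      anns[[length(anns) + 1L]] <-
        annotation2d(sprintf("A%05d", length(anns) + 1L), vis$image[r],
                     "Point", px_ann, features$label[i],
                     annotated_image_size = asize)
      ann_feature <- c(ann_feature, features$feature_id[i])
    }
  }
  annotations <- structure(list(annotations = anns, n_rows = length(anns),
                                n_parsed = length(anns), n_skipped = 0L),
                           class = "annotation_set")

  track <- NULL
  if (!is.null(spec$nav_noise)) {
    nn <- spec$nav_noise
    n_cam <- nrow(centers)
    off <- matrix(0, n_cam, 2L)
    cur <- c(0, 0)
    since_reset <- 0
    for (i in seq_len(n_cam)) {
      if (i > 1L) {
        ds <- sqrt(sum((centers[i, 1:2] - centers[i - 1L, 1:2])^2))
        since_reset <- since_reset + ds
        if (nn$reset_interval > 0 && since_reset >= nn$reset_interval) {
          cur <- stats::rnorm(2L, 0, nn$reset_sigma)
          since_reset <- 0
        } else {
          cur <- cur + stats::rnorm(2L, 0, nn$drift * ds)
        }
      }
      off[i, ] <- cur
    }
    track <- data.frame(image = names(cams),
                        x_true = centers[, 1], y_true = centers[, 2],
                        z_true = centers[, 3],
                        x_nav = centers[, 1] + off[, 1],
                        y_nav = centers[, 2] + off[, 2],
                        z_nav = centers[, 3], stringsAsFactors = FALSE)
  }

  # anchor: a deep-sea back-arc basin setting; local frame is ENU here
  anchor <- geo_anchor(-21.98905, -176.56844, -1850)
  structure(list(mesh = mesh, cameras = cameras, features = features,
                 annotations = annotations, annotation_feature = ann_feature,
                 track = track, anchor = anchor, bvh = bvh, spec = spec),
            class = "synthetic_scene")
}

# project a point into all cameras; visibility = in-bounds, in front, and
# the viewing ray's first mesh hit is within 1 mm of the point
feature_views <- function(p, cameras, bvh) {
  locate_in_images(p, cameras, bvh, epsilon = 1e-3)
}

#' Write a synthetic scene to pipeline-native files
#'
#' Writes `mesh.ply` (ASCII PLY), `cameras.json` (camera schema, with the
#' scene anchor), `annotations.csv` (BIIGLE-style report),
#' `groundtruth.csv` (feature positions) and, when present,
#' `navigation.csv` (true and noisy camera track) — exactly the formats the
#' reprojection pipeline consumes.
#'
#' @param scene A [generate_scene()] result.
#' @param directory Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_scene <- function(scene, directory) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory %s", directory))
  mesh_path <- file.path(directory, "mesh.ply")
  cam_path <- file.path(directory, "cameras.json")
  ann_path <- file.path(directory, "annotations.csv")
  gt_path <- file.path(directory, "groundtruth.csv")
  write_mesh_ply(scene$mesh, mesh_path)
  write_camera_file(scene$cameras, cam_path, anchor = scene$anchor)
  anns <- scene$annotations$annotations
  df <- data.frame(
    annotation_id = vapply(anns, `[[`, "", "annotation_id"),
    filename = vapply(anns, `[[`, "", "image_filename"),
    shape_name = vapply(anns, `[[`, "", "shape"),
    points = vapply(anns, function(a)
      paste0("[", paste(sprintf("%.10f", a$points), collapse = ","), "]"), ""),
    label_name = vapply(anns, `[[`, "", "label"),
    attributes = vapply(anns, function(a)
      sprintf('{"width":%d,"height":%d}',
              as.integer(a$annotated_image_size[1]),
              as.integer(a$annotated_image_size[2])), ""),
    feature_id = scene$annotation_feature,
    stringsAsFactors = FALSE)
  utils::write.csv(df, ann_path, row.names = FALSE)
  utils::write.csv(scene$features, gt_path, row.names = FALSE)
  files <- c(mesh = mesh_path, cameras = cam_path, annotations = ann_path,
             groundtruth = gt_path)
  if (!is.null(scene$track)) {
    nav_path <- file.path(directory, "navigation.csv")
    utils::write.csv(scene$track, nav_path, row.names = FALSE)
    files <- c(files, navigation = nav_path)
  }
  invisible(files)
}

#' Naive flat-projection georeferencing from the navigation track
#'
#' The baseline this pipeline replaces: place each annotation by taking the
#' vehicle's (noisy) navigation position for the image, assuming a flat
#' seafloor directly below, and offsetting the annotated pixel by
#' altitude-scaled normalized image coordinates.  No mesh, no distortion
#' model.  Used to reproduce the hybrid-vs-optical navigation mismatch on
#' synthetic surveys.
#'
#' @param annotation_set Annotations (set or list of [annotation2d()]).
#' @param cameras A `camera_set` (for intrinsics and orientation).
#' @param track Navigation data.frame from [generate_scene()]
#'   (`image`, `x_nav`, `y_nav`, `z_nav`).
#' @param ground_z Assumed flat seafloor height (local frame), default 0.
#' @return data.frame `annotation_id`, `label`, `source_image`, `x`, `y`,
#'   `z`.
#' @export
naive_georeference <- function(annotation_set, cameras, track,
                               ground_z = 0) {
  anns <- if (inherits(annotation_set, "annotation_set"))
    annotation_set$annotations else annotation_set
  out <- vector("list", length(anns))
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    cam <- cameras[[a$image_filename]]
    if (is.null(cam)) stop(sprintf("no camera for image %s", a$image_filename))
    ti <- match(a$image_filename, track$image)
    if (is.na(ti)) stop(sprintf("no navigation for image %s", a$image_filename))
    px <- a$points[1:2]
    if (!is.null(a$annotated_image_size))
      px <- scale_annotation_pixel(px, a$annotated_image_size,
                                   cam$intrinsics)
    xn <- (px[1] - cam$intrinsics$principal_point[1]) / cam$intrinsics$focal_px
    yn <- (px[2] - cam$intrinsics$principal_point[2]) / cam$intrinsics$focal_px
    alt <- track$z_nav[ti] - ground_z
    # nadir assumption: +u = east, +v = south
    out[[i]] <- data.frame(annotation_id = a$annotation_id, label = a$label,
                           source_image = a$image_filename,
                           x = track$x_nav[ti] + xn * alt,
                           y = track$y_nav[ti] - yn * alt,
                           z = ground_z, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
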