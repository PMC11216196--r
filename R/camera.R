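#' Camera intrinsics: pinhole with radial (Brown k1,k2,k3) distortion
#'
#' Describes the optics of the calibrated (reconstruction-resolution) camera:
#' a single focal length in pixels, a principal point, the image size in
#' pixels, and up to three radial distortion coefficients.  Tangential
#' distortion is not supported: structure-from-motion exports consumed by this
#' pipeline use the radial-K3 model.
#'
#' Pixel convention: (0,0) is the top-left image corner, u grows right and v
#' grows down; coordinates are continuous (no half-pixel shift), matching
#' BIIGLE exports.  The camera frame is +x right, +y down, +z forward
#' (OpenCV/OpenMVG convention).
#'
#' @param focal_px Focal length in pixels (> 0).
#' @param principal_point Numeric length-2, (cx, cy) in pixels.
#' @param image_size Integer-ish length-2, (width, height) in pixels of the
#'   images the camera was calibrated on.
#' @param distortion Numeric length-3, (k1, k2, k3); all zero allowed.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(focal_px, principal_point, image_size,
                              distortion = c(0, 0, 0)) {
  stopifnot(is.numeric(focal_px), length(focal_px) == 1L,
            is.numeric(principal_point), length(principal_point) == 2L,
            is.numeric(image_size), length(image_size) == 2L,
            is.numeric(distortion), length(distortion) == 3L)
  if (!is.finite(focal_px) || focal_px <= 0)
    stop("focal_px must be a positive finite number")
  if (any(!is.finite(principal_point)))
    stop("principal point must be finite")
  if (any(!is.finite(image_size)) || any(image_size <= 0))
    stop("image_size must be positive")
  if (any(!is.finite(distortion)))
    stop("distortion coefficients must be finite")
  structure(list(focal_px = as.numeric(focal_px),
                 principal_point = as.numeric(principal_point),
                 image_size = as.numeric(image_size),
                 distortion = as.numeric(distortion)),
            class = "camera_intrinsics")
}

#' Camera pose (extrinsics)
#'
#' World-to-camera rotation and the camera optical center in the local model
#' frame, i.e. a camera-frame point is `x_c = R %*% (X - C)`.
#'
#' @param rotation 3x3 matrix mapping world to camera coordinates; must be
#'   orthonormal with determinant +1 (tolerance 1e-8).
#' @param center Numeric length-3 camera center in the local frame (metres).
#' @param image_id Identifier linking the pose to an image filename.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(rotation, center, image_id = NA_character_) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  if (any(!is.finite(rotation)) || any(!is.finite(center)))
    stop("rotation and center must be finite")
  if (length(center) != 3L) stop("center must have length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal (tolerance 1e-8)")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation determinant is not +1 (reflections are not valid poses)")
  structure(list(rotation = rotation, center = as.numeric(center),
                 image_id = as.character(image_id)),
            class = "camera_pose")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: f=%.6g px, pp=(%.6g, %.6g), %gx%g px, k=(%g, %g, %g)\n",
              x$focal_px, x$principal_point[1], x$principal_point[2],
              x$image_size[1], x$image_size[2],
              x$distortion[1], x$distortion[2], x$distortion[3]))
  invisible(x)
}

#' @export
print.camera_pose <- function(x, ...) {
  cat(sprintf("camera_pose [%s]: center=(%.6g, %.6g, %.6g)\n",
              x$image_id, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# radial distortion factor 1 + k1 r^2 + k2 r^4 + k3 r^6 for normalized coords
radial_factor <- function(r2, k) {
  1 + k[1] * r2 + k[2] * r2^2 + k[3] * r2^3
}

#' Project a 3D point into a camera
#'
#' Transforms a local-frame point into the camera frame, applies radial
#' distortion and maps to pixel coordinates.  Points with non-positive depth
#' (on or behind the image plane) return `c(NA, NA)`; the caller decides
#' whether an in-front pixel outside the image bounds is usable.
#'
#' @param point Numeric length-3 point in the local model frame (metres), or
#'   an n x 3 matrix of points.
#' @param intrinsics A [camera_intrinsics()].
#' @param pose A [camera_pose()].
#' @return Length-2 pixel (u, v), or an n x 2 matrix for matrix input; NA for
#'   behind-camera points.
#' @export
project_point <- function(point, intrinsics, pose) {
  single <- is.null(dim(point))
  p <- if (single) matrix(point, 1L, 3L) else as.matrix(point)
  if (ncol(p) != 3L) stop("point must have 3 coordinates")
  if (any(!is.finite(p))) stop("non-finite point passed to project_point")
  pc <- sweep(p, 2L, pose$center) %*% t(pose$rotation)
  z <- pc[, 3L]
  ok <- z > 0
  xn <- pc[, 1L] / z
  yn <- pc[, 2L] / z
  r2 <- xn^2 + yn^2
  fac <- radial_factor(r2, intrinsics$distortion)
  u <- intrinsics$principal_point[1] + intrinsics$focal_px * xn * fac
  v <- intrinsics$principal_point[2] + intrinsics$focal_px * yn * fac
  u[!ok] <- NA_real_
  v[!ok] <- NA_real_
  out <- cbind(u = u, v = v)
  if (single) out[1L, ] else out
}

#' Undistort a pixel to normalized camera coordinates
#'
#' Inverts the radial distortion model by damped fixed-point iteration
#' starting from the distorted normalized coordinates.  Convergence is
#' checked by re-distorting the candidate: the residual against the observed
#' distorted coordinates must fall below `tol` (normalized units; the
#' default keeps sub-1e-9-pixel accuracy at typical focal lengths).
#'
#' @param pixel Length-2 (u, v) in calibrated-image pixels.
#' @param intrinsics A [camera_intrinsics()].
#' @param tol Convergence tolerance on the re-distorted residual.
#' @param max_iter Iteration cap; non-convergence is an error naming the pixel.
#' @return Length-2 normalized coordinates (x_n, y_n).
#' @export
undistort_pixel <- function(pixel, intrinsics, tol = 1e-13, max_iter = 100L) {
  stopifnot(length(pixel) == 2L, all(is.finite(pixel)))
  k <- intrinsics$distortion
  xd <- (pixel[1] - intrinsics$principal_point[1]) / intrinsics$focal_px
  yd <- (pixel[2] - intrinsics$principal_point[2]) / intrinsics$focal_px
  if (all(k == 0)) return(c(xd, yd))
  x <- xd
  y <- yd
  for (i in seq_len(max_iter)) {
    fac <- radial_factor(x^2 + y^2, k)
    if (!is.finite(fac) || fac <= 0)
      stop(sprintf("undistortion diverged at pixel (%g, %g): the distortion model is not invertible there",
                   pixel[1], pixel[2]))
    x_new <- xd / fac
    y_new <- yd / fac
    # damping stabilises strong distortion near the image corners
    x <- 0.5 * (x + x_new)
    y <- 0.5 * (y + y_new)
    fac <- radial_factor(x^2 + y^2, k)
    if (max(abs(x * fac - xd), abs(y * fac - yd)) < tol) return(c(x, y))
  }
  stop(sprintf("undistortion did not converge after %d iterations at pixel (%g, %g)",
               max_iter, pixel[1], pixel[2]))
}

#' Construct the world-frame viewing ray through a pixel
#'
#' The ray originates at the camera center and passes through the undistorted
#' image point, i.e. `direction = normalize(t(R) %*% c(x_n, y_n, 1))`.
#' Out-of-bounds pixels are allowed (the caller may be densifying an image
#' boundary); non-finite pixels are an error.
#'
#' @inheritParams undistort_pixel
#' @param pose A [camera_pose()].
#' @return A list with class `ray`: `origin` (camera center) and unit-norm
#'   `direction`, both length-3.
#' @export
pixel_to_ray <- function(pixel, intrinsics, pose) {
  n <- undistort_pixel(pixel, intrinsics)
  d <- as.numeric(t(pose$rotation) %*% c(n[1], n[2], 1))
  d <- d / sqrt(sum(d^2))
  structure(list(origin = pose$center, direction = d), class = "ray")
}

#' Rescale an annotation pixel to the calibrated image resolution
#'
#' Annotations are typically made on full-resolution images while cameras are
#' calibrated on downscaled reconstruction images; this maps annotated pixels
#' into the calibrated frame.  The aspect ratios must agree within 0.5%
#' (a mismatch usually means the annotation was paired with the wrong image).
#'
#' @param pixel Length-2 (u, v) in annotated-image pixels, or an n x 2 matrix.
#' @param annotated_size Length-2 (width, height) of the annotated image.
#' @param intrinsics A [camera_intrinsics()] giving the calibrated size.
#' @return Pixel(s) in calibrated-image coordinates.
#' @export
scale_annotation_pixel <- function(pixel, annotated_size, intrinsics) {
  stopifnot(length(annotated_size) == 2L, all(annotated_size > 0))
  w <- intrinsics$image_size[1]
  h <- intrinsics$image_size[2]
  ar_ann <- annotated_size[1] / annotated_size[2]
  ar_rec <- w / h
  if (abs(ar_ann - ar_rec) / ar_rec > 0.005)
    stop(sprintf("aspect ratio mismatch: annotated %gx%g (%.5f) vs calibrated %gx%g (%.5f); likely wrong image pairing",
                 annotated_size[1], annotated_size[2], ar_ann, w, h, ar_rec))
  if (is.null(dim(pixel))) {
    c(pixel[1] * w / annotated_size[1], pixel[2] * h / annotated_size[2])
  } else {
    cbind(pixel[, 1] * w / annotated_size[1], pixel[, 2] * h / annotated_size[2])
  }
}
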