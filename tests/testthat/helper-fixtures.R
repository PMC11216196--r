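# Shared fixture builders (all generated in code; no binary data on disk).

# two-triangle horizontal square spanning [-half, half]^2 at height z
flat_square_mesh <- function(half = 6, z = 0) {
  triangle_mesh(rbind(c(-half, -half, z), c(half, -half, z),
                      c(half, half, z), c(-half, half, z)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
}

# nadir camera looking straight down (+z_cam = -z_world, +u = east, +v = south)
nadir_camera <- function(center = c(0, 0, 10), f = 1000,
                         size = c(1000, 1000), k = c(0, 0, 0),
                         filename = "img_001.jpg") {
  list(intrinsics = camera_intrinsics(f, size / 2, size, k),
       pose = camera_pose(diag(c(1, -1, -1)), center, filename),
       filename = filename)
}

# random triangle soup: n triangles with centers in [-s, s]^3, edge scale e
random_soup_mesh <- function(n, s = 5, e = 1) {
  ctr <- matrix(stats::runif(3 * n, -s, s), n, 3L)
  v1 <- ctr + matrix(stats::rnorm(3 * n, sd = e), n, 3L)
  v2 <- ctr + matrix(stats::rnorm(3 * n, sd = e), n, 3L)
  v3 <- ctr + matrix(stats::rnorm(3 * n, sd = e), n, 3L)
  triangle_mesh(rbind(v1, v2, v3),
                cbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n))
}

# rotation matrix aiming camera +z at `target` from `center`, with roll
look_at_rotation <- function(center, target, roll = 0) {
  zc <- target - center
  zc <- zc / sqrt(sum(zc^2))
  up <- if (abs(zc[3]) > 0.99) c(0, 1, 0) else c(0, 0, 1)
  xc <- c(zc[2] * up[3] - zc[3] * up[2],
          zc[3] * up[1] - zc[1] * up[3],
          zc[1] * up[2] - zc[2] * up[1])
  xc <- xc / sqrt(sum(xc^2))
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  R <- rbind(xc, yc, zc)
  cr <- cos(roll); sr <- sin(roll)
  rbind(cr * R[1, ] + sr * R[2, ], -sr * R[1, ] + cr * R[2, ], R[3, ])
}

# small survey spec used by end-to-end tests (3 transect lines)
small_survey_spec <- function(terrain, n_features = 60, nav_noise = NULL,
                              seed = 1L) {
  scene_spec(terrain = terrain, extent = c(40, 8), grid_step = 0.25,
             trajectory = list(altitude = 5, line_spacing = 3,
                               shot_spacing = 1),
             n_features = n_features, nav_noise = nav_noise, seed = seed)
}

# per-annotation ground-truth recovery errors for a reprojected scene
recovery_errors <- function(scene, result) {
  vapply(seq_along(result$annotations), function(i) {
    a <- result$annotations[[i]]
    if (a$status != "reprojected") return(NA_real_)
    f <- scene$features[scene$features$feature_id ==
                          scene$annotation_feature[i], ]
    sqrt(sum((a$vertices_local[1, ] - c(f$x, f$y, f$z))^2))
  }, 0)
}

crossprod_3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
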