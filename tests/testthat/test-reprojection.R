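test_that("single-vertex reprojection inverts nadir projection geometry", {
  cam <- nadir_camera()
  bvh <- build_bvh(flat_square_mesh(6))
  expect_equal(reproject_vertex(c(500, 500), cam, bvh), c(0, 0, 0),
               tolerance = 1e-12)
  # 100 px / f 1000 at 10 m altitude = 1 m on the ground
  expect_equal(reproject_vertex(c(600, 500), cam, bvh), c(1, 0, 0),
               tolerance = 1e-9)
  # annotated at double resolution: same ground point
  expect_equal(reproject_vertex(c(1200, 1000), cam, bvh,
                                annotated_size = c(2000, 2000)),
               c(1, 0, 0), tolerance = 1e-9)
})

test_that("reprojection over rough terrain equals the exhaustive scan", {
  set.seed(31)
  sp <- scene_spec(terrain = list(type = "sinusoidal", amplitude = 0.8,
                                  wavelength = 4),
                   extent = c(12, 8), grid_step = 0.5, n_features = 5,
                   seed = 31)
  scene <- generate_scene(sp)
  cam <- scene$cameras[[3L]]
  for (i in 1:25) {
    px <- c(runif(1, 0, 2000), runif(1, 0, 1500))
    ray <- pixel_to_ray(px, cam$intrinsics, cam$pose)
    mine <- intersect_first_hit(ray, scene$bvh)
    ref <- brute_force_first_hit(scene$mesh, ray$origin, ray$direction)
    if (is.null(ref)) {
      expect_null(mine)
    } else {
      expect_equal(mine$face, ref$face)
      expect_lt(abs(mine$t - ref$t), 1e-9)
    }
  }
})

test_that("point annotations reproject or are discarded on a miss", {
  cam <- nadir_camera()
  bvh <- build_bvh(flat_square_mesh(2))  # small plane: corner rays overshoot
  on_mesh <- annotation2d("1", "img_001.jpg", "Point", c(500, 500), "coral")
  a <- reproject_annotation(on_mesh, cam, bvh)
  expect_equal(a$status, "reprojected")
  expect_equal(nrow(a$vertices_local), 1L)
  # the ray exits past the mesh boundary: annotation is discarded
  off_mesh <- annotation2d("2", "img_001.jpg", "Point", c(990, 990), "coral")
  d <- reproject_annotation(off_mesh, cam, bvh)
  expect_equal(d$status, "discarded")
  expect_null(d$vertices_local)
})

test_that("polygon misses follow strict/lenient semantics", {
  # two squares with a hole between x in (-1, 1)
  v <- rbind(c(-5, -5, 0), c(-1, -5, 0), c(-1, 5, 0), c(-5, 5, 0),
             c(1, -5, 0), c(5, -5, 0), c(5, 5, 0), c(1, 5, 0))
  mesh <- triangle_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4),
                                 c(5, 6, 7), c(5, 7, 8)))
  bvh <- build_bvh(mesh)
  cam <- nadir_camera()
  # vertices at ground x = -3, +3, +3, and 0 (the last over the hole)
  poly <- annotation2d("3", "img_001.jpg", "Polygon",
                       c(200, 400, 800, 400, 800, 600, 500, 600), "patch")
  strict <- reproject_annotation(poly, cam, bvh, mode = "strict")
  expect_equal(strict$status, "discarded")
  lenient <- reproject_annotation(poly, cam, bvh, mode = "lenient")
  expect_equal(lenient$status, "partial")
  expect_equal(nrow(lenient$vertices_local), 3L)
  # lenient still discards below three surviving vertices
  line <- annotation2d("4", "img_001.jpg", "LineString",
                       c(400, 500, 500, 500), "scar")
  expect_equal(reproject_annotation(line, cam, bvh, mode = "lenient")$status,
               "discarded")
})

test_that("circles reproject their center and estimate a metric radius", {
  cam <- nadir_camera()
  bvh <- build_bvh(flat_square_mesh(6))
  circ <- annotation2d("5", "img_001.jpg", "Circle", c(500, 500, 100),
                       "anemone")
  a <- reproject_annotation(circ, cam, bvh)
  expect_equal(a$status, "reprojected")
  expect_equal(a$vertices_local[1, ], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(a$radius_m, 1, tolerance = 1e-9)  # 100 px at 10 m / f 1000
})

test_that("batch reprojection enforces camera matching and conservation", {
  cam <- nadir_camera()
  cameras <- structure(list(img_001.jpg = cam), class = "camera_set",
                       anchor = NULL)
  bvh <- build_bvh(flat_square_mesh(2))
  anns <- list(annotation2d("1", "img_001.jpg", "Point", c(500, 500), "a"),
               annotation2d("2", "img_001.jpg", "Point", c(990, 990), "a"),
               annotation2d("3", "img_001.jpg", "Polygon",
                            c(450, 450, 550, 450, 550, 550), "b"))
  res <- reproject_annotations(anns, cameras, bvh)
  expect_equal(unname(res$counts["input"]), 3L)
  expect_equal(sum(res$counts[c("reprojected", "partial", "discarded")]),
               res$counts[["input"]])
  bad <- list(annotation2d("9", "IMG_001.JPG", "Point", c(1, 1), "x"))
  expect_error(reproject_annotations(bad, cameras, bvh), "IMG_001.JPG")
  # case-insensitive stem fallback is opt-in
  res2 <- reproject_annotations(bad, cameras, bvh, fuzzy_match = TRUE)
  expect_equal(unname(res2$counts["input"]), 1L)
})

test_that("flat-plane footprint matches the closed-form geometry", {
  cam <- nadir_camera()
  fp <- compute_footprint(cam, build_bvh(flat_square_mesh(20)))
  expect_equal(fp$status, "complete")
  got <- fp$vertices_local[order(fp$vertices_local[, 1],
                                 fp$vertices_local[, 2]), ]
  want <- rbind(c(-5, -5, 0), c(-5, 5, 0), c(5, -5, 0), c(5, 5, 0))
  expect_equal(unname(got), want, tolerance = 1e-9)
  # corner order: top-left of the image is (-5, +5) on the ground
  expect_equal(fp$vertices_local[1, 1:2], c(-5, 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # all rays skyward: discarded
  up <- list(intrinsics = cam$intrinsics,
             pose = camera_pose(diag(3), c(0, 0, 10), "up.jpg"),
             filename = "up.jpg")
  expect_equal(compute_footprint(up, build_bvh(flat_square_mesh(20)))$status,
               "discarded")
})

test_that("densified footprints stay on the mesh over rough terrain", {
  sp <- scene_spec(terrain = list(type = "sinusoidal", amplitude = 0.6,
                                  wavelength = 5),
                   extent = c(20, 10), grid_step = 0.25, n_features = 3,
                   seed = 13)
  scene <- generate_scene(sp)
  # a mid-survey camera whose whole footprint lies over modelled terrain
  cam <- scene$cameras[[29L]]
  expect_equal(cam$pose$center[1:2], c(10, 3.5))
  fp <- compute_footprint(cam, scene$bvh, densify_n = 10L)
  expect_equal(fp$n_rays, 44L)
  expect_equal(fp$status, "complete")
  # each vertex is on the surface: a vertical probe from 5 m above it must
  # hit the mesh at exactly that depth
  for (i in seq_len(nrow(fp$vertices_local))) {
    v <- fp$vertices_local[i, ]
    ref <- brute_force_first_hit(scene$mesh, v + c(0, 0, 5), c(0, 0, -1))
    expect_lt(abs(ref$t - 5), 1e-6)
  }
})

test_that("annotations fall inside their image's densified footprint", {
  sp <- scene_spec(terrain = list(type = "sinusoidal", amplitude = 0.5,
                                  wavelength = 8),
                   extent = c(20, 10), grid_step = 0.25, n_features = 15,
                   seed = 17)
  scene <- generate_scene(sp)
  res <- reproject_annotations(scene$annotations, scene$cameras, scene$bvh)
  fns <- vapply(res$annotations, `[[`, "", "source_image")
  for (fn in unique(fns)[1:5]) {
    fp <- compute_footprint(scene$cameras[[fn]], scene$bvh, densify_n = 8L)
    if (fp$status != "complete") next
    hull <- fp$vertices_local[grDevices::chull(fp$vertices_local[, 1:2]),
                              1:2]
    for (a in res$annotations[fns == fn]) {
      if (a$status != "reprojected") next
      p <- a$vertices_local[1, 1:2]
      # within the hull grown by 1 mm
      grown <- sweep(sweep(hull, 2L, colMeans(hull)) * 1.001, 2L,
                     colMeans(hull), `+`)
      expect_true(all(points_in_poly(p[1], p[2], grown)))
    }
  }
})

test_that("locate_in_images finds features and respects occlusion", {
  cam <- nadir_camera()
  cameras <- structure(list(img_001.jpg = cam), class = "camera_set")
  bvh <- build_bvh(flat_square_mesh(6))
  res <- locate_in_images(c(0, 0, 0), cameras, bvh)
  expect_true(res$visible[1])
  expect_equal(c(res$u[1], res$v[1]), c(500, 500), tolerance = 1e-9)
  # a vertical wall hides the ground point from an oblique camera
  wall <- rbind(c(-0.5, -3, 0), c(-0.5, 3, 0), c(-0.5, 3, 4),
                c(-0.5, -3, 4))
  mesh2 <- triangle_mesh(rbind(flat_square_mesh(6)$vertices, wall),
                         rbind(flat_square_mesh(6)$faces,
                               c(5, 6, 7), c(5, 7, 8)))
  bvh2 <- build_bvh(mesh2)
  oblique <- list(intrinsics = cam$intrinsics,
                  pose = camera_pose(look_at_rotation(c(-4, 0, 2),
                                                      c(1, 0, 0)),
                                     c(-4, 0, 2), "obl.jpg"),
                  filename = "obl.jpg")
  res2 <- locate_in_images(c(1, 0, 0),
                           structure(list(obl.jpg = oblique),
                                     class = "camera_set"), bvh2)
  expect_true(res2$candidate[1])
  expect_false(res2$visible[1])
})

test_that("synthetic features relocate at their annotation pixel", {
  sp <- scene_spec(terrain = list(type = "flat"), extent = c(15, 8),
                   grid_step = 0.5, n_features = 8, seed = 23)
  scene <- generate_scene(sp)
  anns <- scene$annotations$annotations
  for (i in seq_along(anns)[1:10]) {
    a <- anns[[i]]
    f <- scene$features[scene$features$feature_id ==
                          scene$annotation_feature[i], ]
    res <- locate_in_images(c(f$x, f$y, f$z), scene$cameras, scene$bvh)
    row <- res[res$image == a$image_filename, ]
    expect_true(row$visible)
    px_rec <- scale_annotation_pixel(a$points[1:2], a$annotated_image_size,
                                     scene$cameras[[a$image_filename]]$intrinsics)
    expect_lt(max(abs(c(row$u, row$v) - px_rec)), 0.5)
  }
})
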