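make_camera_json <- function(rotation = diag(3), center = c(0, 0, 10),
                             extra_view = NULL, intrinsic_id = "0") {
  doc <- list(
    intrinsics = list("0" = list(focal = 1000, cx = 500, cy = 500,
                                 width = 1000, height = 1000,
                                 k1 = -0.05, k2 = 0, k3 = 0)),
    views = c(list("img_001.jpg" = list(intrinsic_id = intrinsic_id,
                                        rotation = as.numeric(t(rotation)),
                                        center = center)),
              extra_view))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("camera JSON parses, resolves intrinsics and validates rotations", {
  cams <- parse_camera_file(make_camera_json())
  expect_length(cams, 1L)
  expect_equal(cams[["img_001.jpg"]]$pose$center, c(0, 0, 10))
  expect_equal(cams[["img_001.jpg"]]$intrinsics$distortion, c(-0.05, 0, 0))
  # reflection (det = -1) rejected
  expect_error(parse_camera_file(make_camera_json(diag(c(1, 1, -1)))),
               "orthonormal|proper")
  # dangling intrinsic reference names the view
  expect_error(parse_camera_file(make_camera_json(intrinsic_id = "7")),
               "img_001.jpg")
})

test_that("camera set write-then-parse is the identity", {
  set.seed(3)
  cams <- lapply(1:5, function(i) {
    R <- look_at_rotation(c(i, -i, 10), c(0, 0, 0), roll = i / 3)
    list(intrinsics = camera_intrinsics(900 + 50 * i, c(500, 400),
                                        c(1000, 800), c(-0.02 * i, 0, 0)),
         pose = camera_pose(R, c(i, 2 * i, 10), sprintf("im%02d.jpg", i)),
         filename = sprintf("im%02d.jpg", i))
  })
  path <- tempfile(fileext = ".json")
  anchor <- geo_anchor(47.61116, -7.53664, -800)
  write_camera_file(cams, path, anchor = anchor)
  back <- parse_camera_file(path)
  expect_length(back, 5L)
  for (i in 1:5) {
    expect_equal(back[[i]]$pose$rotation, cams[[i]]$pose$rotation,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(back[[i]]$pose$center, cams[[i]]$pose$center)
    expect_equal(back[[i]]$intrinsics$focal_px, cams[[i]]$intrinsics$focal_px)
    expect_equal(back[[i]]$intrinsics$distortion,
                 cams[[i]]$intrinsics$distortion)
  }
  expect_equal(attr(back, "anchor")$lat0, anchor$lat0)
})

test_that("BIIGLE CSV reading parses shapes and conserves rows", {
  path <- system.file("extdata", "annotations_sample.csv",
                      package = "reproj3d")
  set <- suppressWarnings(read_biigle_csv(path))
  expect_equal(set$n_rows, 5L)
  expect_equal(set$n_parsed, 4L)
  expect_equal(set$n_skipped, 1L)
  expect_equal(set$n_rows, set$n_parsed + set$n_skipped)
  expect_warning(read_biigle_csv(path), "Ellipse")
  a1 <- set$annotations[[1]]
  expect_equal(a1$shape, "Point")
  expect_equal(a1$points, c(512.5, 384))
  expect_equal(a1$annotated_image_size, c(4000, 3000))
  a2 <- set$annotations[[2]]
  expect_equal(a2$shape, "Circle")
  expect_equal(a2$points, c(100, 100, 25))
  # missing required column: error lists found vs expected headers
  bad <- write_lines_tmp(c("annotation_id,filename,points,label_name",
                           '1,a.jpg,"[1,2]",coral'), ".csv")
  expect_error(read_biigle_csv(bad), "shape")
})

test_that("annotation validation enforces per-shape coordinate counts", {
  expect_error(annotation2d(1, "a.jpg", "Point", c(1, 2, 3), "x"), "invalid")
  expect_error(annotation2d(1, "a.jpg", "Polygon", c(1, 2, 3, 4), "x"),
               "invalid")
  expect_silent(annotation2d(1, "a.jpg", "Circle", c(5, 5, 2), "x"))
  expect_error(annotation2d(1, "a.jpg", "Blob", c(1, 2), "x"))
})

test_that("GeoJSON output is RFC 7946 lon/lat/height and round-trips", {
  a_ok <- annotation3d("7", "coral", "img_001.jpg", "reprojected",
                       matrix(c(1, 2, 0.5), 1L, 3L),
                       matrix(c(-21.989123456789, -176.568987654321, -1849.5),
                              1L, 3L),
                       shape = "Point")
  a_disc <- annotation3d("8", "sponge", "img_002.jpg", "discarded")
  prefix <- file.path(tempdir(), "out1")
  files <- write_outputs(list(a_ok, a_disc), path_prefix = prefix)
  gj <- read_geojson(paste0(prefix, "_annotations.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 1L)  # discarded has no geometry feature
  feat <- gj$features[[1L]]
  expect_equal(feat$geometry$type, "Point")
  coords <- unlist(feat$geometry$coordinates)
  expect_equal(coords[1], -176.568987654321, tolerance = 1e-9)
  expect_equal(coords[2], -21.989123456789, tolerance = 1e-9)
  # CSV twin carries the same coordinates, and the discarded row
  csv <- utils::read.csv(paste0(prefix, "_annotations.csv"))
  expect_equal(nrow(csv), 2L)
  expect_equal(csv$lon[csv$annotation_id == 7], coords[1])
  expect_true(is.na(csv$x[csv$annotation_id == 8]))
  expect_equal(csv$status[csv$annotation_id == 8], "discarded")
  # empty input: still a valid, empty FeatureCollection
  prefix2 <- file.path(tempdir(), "out2")
  write_outputs(list(), path_prefix = prefix2)
  gj2 <- read_geojson(paste0(prefix2, "_annotations.geojson"))
  expect_equal(gj2$type, "FeatureCollection")
  expect_length(gj2$features, 0L)
})

test_that("polygons close their GeoJSON ring", {
  a <- annotation3d("9", "patch", "img.jpg", "reprojected",
                    matrix(1:9, 3L, 3L),
                    matrix(c(10, 11, 12, 20, 21, 22, 1, 2, 3), 3L, 3L),
                    shape = "Polygon")
  prefix <- file.path(tempdir(), "out3")
  write_outputs(list(a), path_prefix = prefix)
  gj <- read_geojson(paste0(prefix, "_annotations.geojson"))
  ring <- gj$features[[1L]]$geometry$coordinates[[1L]]
  expect_length(ring, 4L)
  expect_equal(unlist(ring[[1L]]), unlist(ring[[4L]]))
})

test_that("OpenMVG sfm_data.json adapts into a camera set", {
  R <- look_at_rotation(c(0, 0, 8), c(1, 1, 0), 0.2)
  doc <- list(
    views = list(list(key = 0, value = list(ptr_wrapper = list(data = list(
      filename = "dsc_0001.jpg", id_intrinsic = 0, id_pose = 0)))),
      list(key = 1, value = list(ptr_wrapper = list(data = list(
        filename = "dsc_0002.jpg", id_intrinsic = 0, id_pose = 99))))),
    intrinsics = list(list(key = 0, value = list(ptr_wrapper = list(data =
      list(focal_length = 1234.5, principal_point = c(980, 540),
           width = 1960, height = 1080,
           disto_k3 = c(-0.03, 0.002, 0)))))),
    extrinsics = list(list(key = 0, value = list(
      rotation = lapply(1:3, function(i) R[i, ]),
      center = c(0, 0, 8)))))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  cams <- convert_sfm_data(path)
  expect_length(cams, 1L)  # view without a reconstructed pose is skipped
  cm <- cams[["dsc_0001.jpg"]]
  expect_equal(cm$intrinsics$focal_px, 1234.5)
  expect_equal(cm$intrinsics$distortion, c(-0.03, 0.002, 0))
  expect_equal(cm$pose$rotation, R, tolerance = 1e-12, ignore_attr = TRUE)
})
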