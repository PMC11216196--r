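Package: reproj3d
Title: Reproject 2D Image Annotations onto Georeferenced 3D Terrain Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A processing pipeline for underwater photogrammetry surveys that
    casts a ray per annotated image pixel from its calibrated camera onto a 3D
    terrain mesh and takes the first intersection, turning 2D image annotations
    into georeferenced 3D positions (WGS84). Includes a pinhole camera model
    with radial distortion, a bounding-volume-hierarchy ray caster, readers for
    OBJ/PLY meshes, structure-from-motion camera exports and BIIGLE-style
    annotation CSVs, GeoJSON/CSV writers, image-footprint computation,
    duplicate-annotation detection, disjoint-image selection, reprojection
    accuracy statistics, and a synthetic-survey generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
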