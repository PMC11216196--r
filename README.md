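# reproj3d

Georeference 2D image annotations by reprojecting them onto 3D
photogrammetry models.

## The problem

Deep-sea imaging surveys produce two data streams that do not line up.
Biologists annotate raw 2D images (points on individual organisms, polygons
around faunal patches) in web tools such as BIIGLE, and those annotations are
georeferenced with the vehicle's *hybrid navigation* (inertial dead reckoning
reset by acoustic USBL fixes) — accurate to metres at best. Meanwhile,
structure-from-motion photogrammetry turns the same images into a 3D terrain
mesh whose *optical navigation* (bundle-adjusted camera poses) is internally
consistent to centimetres. Mapping metre-accurate annotations onto a
centimetre-resolution model double-counts organisms where supposedly disjoint
images actually overlap, and scrambles fine-scale spatial structure.

`reproj3d` closes the gap by ray casting. For an annotated pixel
$(u, v)$ in image $i$ with calibrated intrinsics (focal $f$, principal point
$(c_x, c_y)$, radial distortion $k_1, k_2, k_3$) and pose
$(R_i, C_i)$ (world-to-camera rotation, camera center), the viewing ray is

$$\mathbf{d} = R_i^{\top} \, (x_n, y_n, 1)^{\top}, \qquad
  \mathbf{r}(t) = C_i + t\,\mathbf{d},$$

where $(x_n, y_n)$ are the undistorted normalized image coordinates of
$(u, v)$. The annotation's 3D position is the **first intersection** of this
ray with the scene mesh (found through a bounding-volume hierarchy with
Möller–Trumbore triangle tests); rays that miss the model (unreconstructed
holes, image borders beyond the mesh) mark the annotation as discarded.
Positions in the local model frame are converted to WGS84 via an east-north-up
tangent frame at a geodetic anchor.

On top of the reprojection core the package provides the survey analyses
built from it:

- **image footprints** — the on-mesh polygon covered by an image, from rays
  through its (densified) boundary pixels;
- **duplicate detection** — connected components of same-label,
  cross-image annotation pairs within a linkage radius, with the duplicate
  percentage;
- **disjoint-image selection** — a greedy pass over footprint overlap
  fractions (plus an exhaustive reference solver for small sets);
- **accuracy evaluation** — median and IQR of 3D Euclidean distances between
  reprojected control points and reference positions;
- **a synthetic-survey generator** — terrain, serpentine camera trajectory,
  planted features, their 2D annotations, and a drifting navigation track,
  so the whole pipeline is testable end to end with no external data.

## Worked example

```r
library(reproj3d)

# 1. simulate a survey: sinusoidal terrain, 3 transects, 30 seabed features
spec  <- scene_spec(terrain = list(type = "sinusoidal", amplitude = 0.5,
                                   wavelength = 8),
                    extent = c(40, 8), n_features = 30, seed = 42)
scene <- generate_scene(spec)
dir   <- file.path(tempdir(), "survey")
write_scene(scene, dir)   # mesh.ply, cameras.json, annotations.csv, ...

# 2. reproject the BIIGLE-style annotations onto the mesh
cameras <- parse_camera_file(file.path(dir, "cameras.json"))
mesh    <- read_mesh(file.path(dir, "mesh.ply"))
anns    <- read_biigle_csv(file.path(dir, "annotations.csv"))
bvh     <- build_bvh(mesh)
res     <- reproject_annotations(anns, cameras, bvh,
                                 anchor = attr(cameras, "anchor"))
res$counts
#>       input reprojected     partial   discarded
#>         331         331           0           0

# 3. error against the planted ground truth
truth   <- read.csv(file.path(dir, "groundtruth.csv"))
pos     <- t(sapply(res$annotations, function(a) a$vertices_local[1, ]))
nearest <- apply(pos, 1, function(p)
  min(sqrt((truth$x - p[1])^2 + (truth$y - p[2])^2 + (truth$z - p[3])^2)))
evaluate_accuracy(cbind(nearest, 0, 0), matrix(0, length(nearest), 3),
                  "synthetic survey")
#> accuracy_report [synthetic survey]: n=331, median=4.243e-13 m, IQR=1.732e-13 m

# 4. duplicates among the reprojected points at a 5 cm linkage radius
pts <- do.call(rbind, lapply(res$annotations, function(a)
  data.frame(annotation_id = a$annotation_id, label = a$label,
             source_image = a$source_image, x = a$vertices_local[1, 1],
             y = a$vertices_local[1, 2], z = a$vertices_local[1, 3])))
dup <- detect_duplicates(pts, radius_m = 0.05)
sprintf("%d duplicate groups, %.1f%% of annotations are duplicates",
        length(dup$groups), dup$duplicate_pct)
#> "30 duplicate groups, 90.9% of annotations are duplicates"

# 5. the first annotation in WGS84 (lat, lon, ellipsoidal height)
round(res$annotations[[1]]$vertices_geo, 6)
#>          lat       lon         h
#> [1,] -21.989 -176.5681 -1850.084
```

The 331 annotations are the 30 features seen from every camera that images
them — with overlapping survey images each feature is annotated ~11 times,
which is exactly why duplicate detection matters. Reprojection with exact
cameras recovers the planted positions to sub-picometre-of-survey precision
(the residual is floating-point noise), and every cross-image sighting
collapses into one duplicate group.

A command-line interface wraps the same stages
(`simulate`, `reproject`, `footprints`, `duplicates`, `disjoint`,
`evaluate`); see `inst/cli/reproj3d --help` after installation.

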