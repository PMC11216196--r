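#' Detect duplicate annotations among reprojected points
#'
#' Two reprojected annotations are duplicate candidates when they carry the
#' same label, come from different source images, and lie within `radius_m`
#' of each other in 3D.  Duplicate groups are the connected components of the
#' candidate-pair graph; within each group the member with the lowest
#' annotation id is kept as the representative.  The duplicate percentage
#' counts one representative per group:
#' `100 * sum(group_size - 1) / n_total`, so two coincident annotations give
#' 50%.
#'
#' @param annotations List of [annotation3d()] point annotations
#'   (status `"reprojected"`), or a data.frame with columns
#'   `annotation_id`, `label`, `source_image`, `x`, `y`, `z`.
#' @param radius_m Linkage radius in metres (> 0).  The default 0.05 m is
#'   roughly ten times a typical photogrammetric model resolution.
#' @return List with `groups` (each: `label`, `member_ids`,
#'   `representative`), `duplicate_pct`, `n_total` and the candidate `pairs`
#'   data.frame.
#' @export
detect_duplicates <- function(annotations, radius_m = 0.05) {
  if (!is.numeric(radius_m) || radius_m <= 0)
    stop("radius_m must be positive")
  df <- duplicates_frame(annotations)
  n <- nrow(df)
  if (n == 0L)
    return(list(groups = list(), duplicate_pct = 0, n_total = 0L,
                pairs = data.frame(i = integer(0), j = integer(0))))
  d <- as.matrix(stats::dist(df[, c("x", "y", "z")]))
  same_label <- outer(df$label, df$label, `==`)
  diff_image <- outer(df$source_image, df$source_image, `!=`)
  adj <- d <= radius_m & same_label & diff_image
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  pairs <- data.frame(i = idx[, 1], j = idx[, 2])
  groups <- list()
  if (nrow(pairs) > 0L) {
    g <- igraph::graph_from_edgelist(as.matrix(pairs), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    for (k in unique(comp)) {
      members <- which(comp == k)
      if (length(members) < 2L) next
      ids <- df$annotation_id[members]
      groups[[length(groups) + 1L]] <-
        list(label = df$label[members[1L]],
             member_ids = ids,
             representative = sort(ids)[1L])
    }
  }
  dup <- sum(vapply(groups, function(g) length(g$member_ids) - 1L, 0L))
  list(groups = groups, duplicate_pct = 100 * dup / n, n_total = n,
       pairs = pairs)
}

duplicates_frame <- function(annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("annotation_id", "label", "source_image",
                    "x", "y", "z") %in% names(annotations)))
    return(annotations)
  }
  keep <- Filter(function(a) a$status == "reprojected" &&
                   !is.null(a$vertices_local), annotations)
  do.call(rbind, lapply(keep, function(a)
    data.frame(annotation_id = a$annotation_id, label = a$label,
               source_image = a$source_image,
               x = a$vertices_local[1, 1], y = a$vertices_local[1, 2],
               z = a$vertices_local[1, 3], stringsAsFactors = FALSE)))
}

#' Select images with (near-)disjoint optical footprints
#'
#' Projects each footprint to the horizontal plane and greedily accepts
#' images in acquisition order: an image is selected iff its overlap
#' fraction (intersection area over its own footprint area) with every
#' already-selected footprint is at most `max_overlap_frac`.  This mirrors a
#' one-pass survey workflow; [select_disjoint_exhaustive()] provides the
#' optimal reference for small image sets.
#'
#' @param footprints List of `footprint` objects (complete or partial;
#'   discarded ones are skipped with a warning).
#' @param max_overlap_frac Maximum tolerated overlap fraction in `[0, 1]`.
#' @return List with `selected` (image filenames), `selected_idx`, and
#'   `overlap` (pairwise overlap-fraction matrix over usable footprints,
#'   `overlap[i, j]` = intersection / area of i).
#' @export
select_disjoint <- function(footprints, max_overlap_frac = 0) {
  stopifnot(max_overlap_frac >= 0)
  ov <- footprint_overlap_matrix(footprints)
  usable <- which(vapply(footprints, function(fp)
    fp$status != "discarded", TRUE))
  if (length(usable) < length(footprints))
    warning(sprintf("%d discarded footprint(s) skipped",
                    length(footprints) - length(usable)))
  selected <- integer(0)
  for (i in usable) {
    if (all(ov[i, selected] <= max_overlap_frac)) {
      selected <- c(selected, i)
    }
  }
  list(selected = rownames(ov)[selected], selected_idx = selected,
       overlap = ov)
}

#' Pairwise footprint overlap-fraction matrix
#'
#' `overlap[i, j]` is the horizontal-plane overlap fraction of footprint `i`
#' with footprint `j`, relative to `i`'s own area; rows/columns of discarded
#' footprints are NA, the diagonal is 0.  Indices match the input list.
#'
#' @param footprints List of `footprint` objects.
#' @return Square numeric matrix with image filenames as dimnames.
#' @export
footprint_overlap_matrix <- function(footprints) {
  n <- length(footprints)
  names_ <- vapply(footprints, `[[`, "", "image_filename")
  polys <- lapply(footprints, footprint_poly2d)
  usable <- which(vapply(footprints, function(fp)
    fp$status != "discarded", TRUE))
  ov <- matrix(NA_real_, n, n, dimnames = list(names_, names_))
  for (i in usable) {
    ov[i, i] <- 0
    for (j in usable) {
      if (i == j) next
      ov[i, j] <- poly_overlap_frac(polys[[i]], polys[[j]])
    }
  }
  ov
}

#' Exhaustive disjoint-image selection (small sets)
#'
#' Finds a maximum-size subset of footprints in which every pair is
#' admissible under the symmetric rule
#' `max(overlap[i, j], overlap[j, i]) <= max_overlap_frac`.  Exponential in
#' the number of images; intended as a testing reference for <= 20 images.
#'
#' @inheritParams select_disjoint
#' @return List with `selected`, `selected_idx`, `overlap`.
#' @export
select_disjoint_exhaustive <- function(footprints, max_overlap_frac = 0) {
  ov <- footprint_overlap_matrix(footprints)
  usable <- which(vapply(footprints, function(fp)
    fp$status != "discarded", TRUE))
  if (length(usable) > 20L)
    stop("exhaustive selection supported for <= 20 footprints")
  admis <- pmax(ov, t(ov)) <= max_overlap_frac
  n <- length(usable)
  best <- integer(0)
  recurse <- function(k, chosen) {
    if (length(chosen) + (n - k + 1L) <= length(best)) return()
    if (k > n) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    i <- usable[k]
    if (all(admis[i, chosen])) recurse(k + 1L, c(chosen, i))
    recurse(k + 1L, chosen)
  }
  recurse(1L, integer(0))
  list(selected = rownames(ov)[best], selected_idx = best, overlap = ov)
}

#' Reprojection accuracy statistics
#'
#' Compares reprojected control points with their reference positions on the
#' model using the 3D Euclidean distance (preferred over horizontal distance:
#' on vertical structure two stacked features have zero horizontal
#' separation but a large along-surface one).  Reports the median and the
#' interquartile range (Q3 - Q1, linear-interpolation quantiles).
#'
#' @param reprojected n x 3 matrix of reprojected positions (metres).
#' @param reference n x 3 matrix of reference positions.
#' @param site Site name carried into the report.
#' @return An object of class `accuracy_report`: `site`, `n_pairs`,
#'   `median_m`, `iqr_m`, `q1_m`, `q3_m`, `distances_m`,
#'   `quantile_method = "linear"`.
#' @export
evaluate_accuracy <- function(reprojected, reference, site = "site") {
  reprojected <- matrix(as.numeric(reprojected), ncol = 3L)
  reference <- matrix(as.numeric(reference), ncol = 3L)
  if (nrow(reprojected) == 0L) stop("no control-point pairs supplied")
  if (nrow(reprojected) != nrow(reference))
    stop("reprojected and reference must have the same number of rows")
  d <- sqrt(rowSums((reprojected - reference)^2))
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(site = site, n_pairs = length(d), median_m = q[2],
                 iqr_m = q[3] - q[1], q1_m = q[1], q3_m = q[3],
                 distances_m = d, quantile_method = "linear"),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy_report [%s]: n=%d, median=%.4g m, IQR=%.4g m\n",
              x$site, x$n_pairs, x$median_m, x$iqr_m))
  invisible(x)
}
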