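#' Triangle mesh in the local model frame
#'
#' A triangle soup: vertices in metres plus faces as 1-based vertex index
#' triples.  Degenerate faces (area < `degenerate_area`) are flagged invalid
#' and excluded from ray casting rather than rejected — Poisson-reconstructed
#' photogrammetry meshes routinely contain slivers.  Watertightness is not
#' required; a ray missing the mesh is an expected outcome.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (metres).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param degenerate_area Faces with area below this (m^2) are flagged invalid.
#' @return An object of class `triangle_mesh` with fields `vertices`, `faces`,
#'   `valid` (logical per face) and `areas`.
#' @export
triangle_mesh <- function(vertices, faces, degenerate_area = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(faces) != 3L) stop("faces must be m x 3 (triangles)")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop(sprintf("face vertex index out of range [1, %d]", nrow(vertices)))
  areas <- face_areas(vertices, faces)
  structure(list(vertices = vertices, faces = faces,
                 areas = areas, valid = areas >= degenerate_area),
            class = "triangle_mesh")
}

face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces (%d valid)\n",
              nrow(x$vertices), nrow(x$faces), sum(x$valid)))
  invisible(x)
}

#' Load a triangle mesh from OBJ or PLY
#'
#' Reads Wavefront OBJ (`v`/`f` records, 1-based indices, `v/vt/vn` face
#' syntax accepted) or PLY (ASCII or binary little-endian).  Quad faces are
#' triangulated by the (1,2,3),(1,3,4) split; texture coordinates and normals
#' are ignored.
#'
#' @param path Path to a `.obj` or `.ply` file.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stop(sprintf("unknown mesh extension '.%s' (expected .obj or .ply): %s",
                      ext, path)))
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grepl("^v\\s", lines)
  flines <- grepl("^f\\s", lines)
  verts <- matrix(0, sum(vlines), 3L)
  vi <- which(vlines)
  for (i in seq_along(vi)) {
    parts <- strsplit(trimws(lines[vi[i]]), "\\s+")[[1]]
    xyz <- suppressWarnings(as.numeric(parts[2:4]))
    if (length(parts) < 4L || any(is.na(xyz)))
      stop(sprintf("malformed OBJ vertex at line %d of %s", vi[i], path))
    verts[i, ] <- xyz
  }
  fi <- which(flines)
  tris <- vector("list", length(fi))
  for (i in seq_along(fi)) {
    parts <- strsplit(trimws(lines[fi[i]]), "\\s+")[[1]][-1L]
    idx <- suppressWarnings(as.integer(vapply(strsplit(parts, "/"),
                                              `[[`, "", 1L)))
    if (length(idx) < 3L || any(is.na(idx)))
      stop(sprintf("malformed OBJ face at line %d of %s", fi[i], path))
    if (any(idx < 1L | idx > nrow(verts)))
      stop(sprintf("OBJ face index out of range at line %d of %s (mesh has %d vertices)",
                   fi[i], path, nrow(verts)))
    tris[[i]] <- if (length(idx) == 3L) {
      matrix(idx, 1L, 3L)
    } else if (length(idx) == 4L) {
      rbind(idx[c(1L, 2L, 3L)], idx[c(1L, 3L, 4L)])
    } else {
      # fan-triangulate larger polygons
      do.call(rbind, lapply(2:(length(idx) - 1L),
                            function(j) idx[c(1L, j, j + 1L)]))
    }
  }
  faces <- if (length(tris)) do.call(rbind, tris) else matrix(integer(0), 0L, 3L)
  triangle_mesh(verts, faces)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (is.null(sz)) stop(sprintf("unsupported PLY property type '%s'", type))
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(con, "double", 1L, size = sz, endian = "little")
  } else {
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1L)
  if (!identical(trimws(magic), "ply"))
    stop(sprintf("not a PLY file (bad magic '%s'): %s", magic, path))
  fmt <- NULL
  elements <- list()  # list of list(name, n, props = list(list(name,type,list,count_type)))
  cur <- NULL
  repeat {
    line <- readLines(con, 1L)
    if (length(line) == 0L) stop(sprintf("unterminated PLY header in %s", path))
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian"))
        stop(sprintf("unsupported PLY format '%s' in %s", fmt, path))
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], n = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop(sprintf("PLY property before element in %s", path))
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop(sprintf("PLY file lacks vertex or face element: %s", path))

  verts <- NULL
  faces_list <- NULL
  if (fmt == "ascii") {
    rest <- readLines(con)
    pos <- 1L
    for (el in elements) {
      pnames <- vapply(el$props, `[[`, "", "name")
      if (el$name == "vertex") {
        vals <- matrix(0, el$n, length(pnames))
        for (i in seq_len(el$n)) {
          vals[i, ] <- as.numeric(strsplit(trimws(rest[pos]), "\\s+")[[1]][seq_along(pnames)])
          pos <- pos + 1L
        }
        colnames(vals) <- pnames
        verts <- vals[, c("x", "y", "z"), drop = FALSE]
      } else if (el$name == "face") {
        faces_list <- vector("list", el$n)
        for (i in seq_len(el$n)) {
          nums <- as.numeric(strsplit(trimws(rest[pos]), "\\s+")[[1]])
          pos <- pos + 1L
          cnt <- nums[1]
          faces_list[[i]] <- as.integer(nums[2:(1 + cnt)]) + 1L
        }
      } else {
        pos <- pos + el$n
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        pnames <- vapply(el$props, `[[`, "", "name")
        vals <- matrix(0, el$n, length(el$props))
        for (i in seq_len(el$n))
          for (j in seq_along(el$props))
            vals[i, j] <- ply_read_scalar(con, el$props[[j]]$type)
        colnames(vals) <- pnames
        verts <- vals[, c("x", "y", "z"), drop = FALSE]
      } else if (el$name == "face") {
        faces_list <- vector("list", el$n)
        lp <- el$props[[1L]]
        if (!lp$list)
          stop(sprintf("PLY face element lacks a list property in %s", path))
        for (i in seq_len(el$n)) {
          cnt <- ply_read_scalar(con, lp$count_type)
          idx <- integer(cnt)
          for (j in seq_len(cnt)) idx[j] <- ply_read_scalar(con, lp$type)
          faces_list[[i]] <- idx + 1L
        }
      } else {
        for (i in seq_len(el$n))
          for (p in el$props) {
            if (isTRUE(p$list)) {
              cnt <- ply_read_scalar(con, p$count_type)
              for (j in seq_len(cnt)) ply_read_scalar(con, p$type)
            } else ply_read_scalar(con, p$type)
          }
      }
    }
  }
  tris <- lapply(faces_list, function(idx) {
    if (length(idx) == 3L) matrix(idx, 1L, 3L)
    else if (length(idx) == 4L) rbind(idx[c(1L, 2L, 3L)], idx[c(1L, 3L, 4L)])
    else do.call(rbind, lapply(2:(length(idx) - 1L),
                               function(j) idx[c(1L, j, j + 1L)]))
  })
  faces <- if (length(tris)) do.call(rbind, tris) else matrix(integer(0), 0L, 3L)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(verts)))
    stop(sprintf("PLY face index out of range in %s", path))
  triangle_mesh(verts, faces)
}

#' Write a triangle mesh to PLY
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path (`.ply`).
#' @param binary Write `binary_little_endian` (TRUE) or ASCII (FALSE).
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 8L, endian = "little")
    f0 <- mesh$faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    vtxt <- sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                    mesh$vertices[, 2], mesh$vertices[, 3])
    f0 <- mesh$faces - 1L
    ftxt <- sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])
    writeLines(c(header, vtxt, ftxt), path)
  }
  invisible(path)
}
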