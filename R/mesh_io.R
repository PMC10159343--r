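#' Read a mesh from a standard file format
#'
#' Supports ASCII and binary STL and ASCII PLY for surfaces, and legacy-VTK
#' unstructured grids for tetrahedral volume meshes. STL files carry no
#' shared-vertex information, so vertices closer than 1e-9 mm are merged on
#' read. Boundary-ring tags and lineage are not representable in these
#' formats and come back empty.
#'
#' @param path file path.
#' @param format one of `"stl"`, `"ply"`, `"vtk"`; inferred from the file
#'   extension when `NULL`.
#' @return A [surface_mesh()] (STL/PLY) or [volume_mesh()] (VTK).
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    stl = read_stl(path),
    ply = read_ply(path),
    vtk = read_vtk(path),
    stop("unsupported mesh format: ", format)
  )
}

#' Write a mesh to a standard file format
#'
#' @param mesh a [surface_mesh()] or [volume_mesh()].
#' @param path output file path.
#' @param format `"stl"`, `"ply"` (surfaces) or `"vtk"` (volumes); inferred
#'   from the extension when `NULL`.
#' @param binary write binary STL instead of ASCII (STL only).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = FALSE) {
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    stl = write_stl(mesh, path, binary = binary),
    ply = write_ply(mesh, path),
    vtk = write_vtk(mesh, path),
    stop("unsupported mesh format: ", format)
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || identical(a, "")) b else a

parse_fail <- function(path, line, msg) {
  stop(sprintf("parse error in %s at line %d: %s", path, line, msg),
       call. = FALSE)
}

# merge vertices closer than `tol` and return a deduplicated surface mesh
merge_vertices <- function(vertices, triangles, tol = 1e-9) {
  key <- apply(round(vertices / tol), 1L, paste, collapse = "/")
  ukey <- unique(key)
  compact <- match(key, ukey)
  newv <- vertices[match(ukey, key), , drop = FALSE]
  tri <- matrix(compact[as.vector(triangles)], ncol = 3L)
  surface_mesh(newv, tri)
}

# --- STL --------------------------------------------------------------------

is_binary_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 84L)
  if (length(head) < 84L) return(FALSE)
  ntri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  isTRUE(all.equal(expected, file.size(path)))
}

read_stl <- function(path) {
  if (file.size(path) == 0) parse_fail(path, 1L, "empty file")
  if (is_binary_stl(path)) return(read_stl_binary(path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1L])) {
    parse_fail(path, 1L, "expected 'solid' header")
  }
  vlines <- grep("^\\s*vertex\\s", lines)
  if (!length(vlines)) parse_fail(path, length(lines), "no vertex records")
  if (length(vlines) %% 3L != 0L) {
    parse_fail(path, vlines[length(vlines)],
               "vertex count not a multiple of 3")
  }
  coords <- t(vapply(vlines, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]][-1L]
    v <- suppressWarnings(as.numeric(toks))
    if (length(v) != 3L || anyNA(v)) parse_fail(path, i, "bad vertex record")
    v
  }, numeric(3)))
  tri <- matrix(seq_len(nrow(coords)), ncol = 3L, byrow = TRUE)
  merge_vertices(coords, tri)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", size = 4L, endian = "little")
  coords <- matrix(0, nrow = 3L * ntri, ncol = 3L)
  for (t in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    if (length(rec) < 12L) parse_fail(path, t, "truncated binary facet")
    coords[(3L * t - 2L):(3L * t), ] <- matrix(rec[4:12], ncol = 3L,
                                               byrow = TRUE)
    readBin(con, "raw", 2L)
  }
  tri <- matrix(seq_len(nrow(coords)), ncol = 3L, byrow = TRUE)
  merge_vertices(coords, tri)
}

write_stl <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles
  n <- normalize_rows(tri_normals(v, tr))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
    for (t in seq_len(nrow(tr))) {
      rec <- c(n[t, ], t(v[tr[t, ], ]))
      writeBin(rec, con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    out <- c("solid shapeflow",
             unlist(lapply(seq_len(nrow(tr)), function(t) {
               vv <- v[tr[t, ], , drop = FALSE]
               c(sprintf("  facet normal %.9e %.9e %.9e",
                         n[t, 1], n[t, 2], n[t, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9e %.9e %.9e",
                         vv[, 1], vv[, 2], vv[, 3]),
                 "    endloop", "  endfacet")
             })),
             "endsolid shapeflow")
    writeLines(out, path)
  }
}

tri_normals <- function(v, tr) {
  a <- v[tr[, 1L], , drop = FALSE]
  u <- v[tr[, 2L], , drop = FALSE] - a
  w <- v[tr[, 3L], , drop = FALSE] - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# --- PLY (ASCII) ------------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) parse_fail(path, 1L, "empty file")
  if (trimws(lines[1L]) != "ply") parse_fail(path, 1L, "missing 'ply' magic")
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) parse_fail(path, length(lines), "missing end_header")
  header <- trimws(lines[seq_len(hdr_end)])
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1L]))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", header, value = TRUE)[1L]))
  if (is.na(nv) || is.na(nf)) parse_fail(path, 1L, "missing element counts")
  body <- lines[(hdr_end + 1L):length(lines)]
  if (length(body) < nv + nf) {
    parse_fail(path, length(lines), "truncated body")
  }
  verts <- t(vapply(seq_len(nv), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1L]]))
    if (length(v) < 3L || anyNA(v[1:3])) {
      parse_fail(path, hdr_end + i, "bad vertex line")
    }
    v[1:3]
  }, numeric(3)))
  faces <- t(vapply(seq_len(nf), function(i) {
    toks <- suppressWarnings(
      as.integer(strsplit(trimws(body[nv + i]), "\\s+")[[1L]]))
    if (length(toks) < 4L || toks[1L] != 3L || anyNA(toks)) {
      parse_fail(path, hdr_end + nv + i, "only triangular faces supported")
    }
    toks[2:4] + 1L
  }, integer(3)))
  surface_mesh(verts, faces)
}

write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles - 1L
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(tr)),
    "property list uchar int vertex_indices",
    "end_header",
    sprintf("%.9e %.9e %.9e", v[, 1], v[, 2], v[, 3]),
    sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3])
  ), path)
}

# --- legacy VTK unstructured grid ------------------------------------------

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) parse_fail(path, 1L, "empty file")
  if (!grepl("^# vtk DataFile", lines[1L])) {
    parse_fail(path, 1L, "missing VTK header")
  }
  ip <- grep("^POINTS", lines)[1L]
  if (is.na(ip)) parse_fail(path, length(lines), "no POINTS section")
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  nums <- scan_numbers(lines, ip + 1L, 3L * np, path)
  pts <- matrix(nums$values, ncol = 3L, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1L]
  if (is.na(ic)) parse_fail(path, length(lines), "no CELLS section")
  nc <- as.integer(strsplit(lines[ic], "\\s+")[[1L]][2L])
  cells <- scan_numbers(lines, ic + 1L, 5L * nc, path)
  cm <- matrix(as.integer(cells$values), ncol = 5L, byrow = TRUE)
  if (any(cm[, 1L] != 4L)) {
    parse_fail(path, ic, "only tetrahedral cells (4 points) supported")
  }
  volume_mesh(pts, cm[, 2:5] + 1L)
}

scan_numbers <- function(lines, from, n, path) {
  vals <- numeric(0)
  i <- from
  while (length(vals) < n && i <= length(lines)) {
    ln <- trimws(lines[i])
    if (nzchar(ln)) {
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (anyNA(v)) parse_fail(path, i, "non-numeric data")
      vals <- c(vals, v)
    }
    i <- i + 1L
  }
  if (length(vals) < n) parse_fail(path, i - 1L, "truncated numeric block")
  list(values = vals[seq_len(n)], next_line = i)
}

write_vtk <- function(mesh, path, point_data = NULL) {
  stopifnot(inherits(mesh, "volume_mesh"))
  nd <- mesh$nodes
  tt <- mesh$tets - 1L
  out <- c("# vtk DataFile Version 3.0", "shapeflow volume mesh", "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           sprintf("POINTS %d double", nrow(nd)),
           sprintf("%.9e %.9e %.9e", nd[, 1], nd[, 2], nd[, 3]),
           sprintf("CELLS %d %d", nrow(tt), 5L * nrow(tt)),
           sprintf("4 %d %d %d %d", tt[, 1], tt[, 2], tt[, 3], tt[, 4]),
           sprintf("CELL_TYPES %d", nrow(tt)),
           rep("10", nrow(tt)))
  if (!is.null(point_data)) {
    out <- c(out, sprintf("POINT_DATA %d", nrow(nd)))
    for (nm in names(point_data)) {
      out <- c(out,
               sprintf("SCALARS %s double 1", nm),
               "LOOKUP_TABLE default",
               sprintf("%.9e", point_data[[nm]]))
    }
  }
  writeLines(out, path)
}

#' Export a flow field as legacy-VTK point data
#'
#' Writes the volume mesh together with its per-node pressure (Pa) and
#' velocity magnitude (m/s) so the field can be inspected in ParaView.
#'
#' @param volume a [volume_mesh()].
#' @param field a [flow_field()] on the same mesh.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(volume, field, path) {
  stopifnot(inherits(field, "flow_field"))
  if (length(field$pressure) != nrow(volume$nodes)) {
    stop("field and mesh node counts differ")
  }
  write_vtk(volume, path,
            point_data = list(pressure = field$pressure,
                              velocity = field$velocity))
  invisible(path)
}
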