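#' Triangulated surface mesh
#'
#' Container for a closed triangulated vessel surface. Coordinates are in
#' millimetres throughout the geometry layer. Meshes produced by the cohort
#' generator carry boundary-ring tags (inlet/outlet vertex indices) and a
#' per-vertex axial station map; meshes shot from a template carry a
#' `lineage_id` so that point correspondence can be asserted downstream.
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @param triangles integer matrix, one row per triangle, 1-based vertex
#'   indices.
#' @param inlet_ring,outlet_ring integer vectors of vertex indices forming the
#'   open boundary rings (empty when untagged).
#' @param stations optional integer vector, axial station index per vertex
#'   (`NA` for cap centres is allowed).
#' @param lineage_id template lineage tag; `""` when the mesh is not in point
#'   correspondence with any template.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, inlet_ring = integer(),
                         outlet_ring = integer(), stations = NULL,
                         lineage_id = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (nrow(vertices) <= 3L) stop("a surface mesh needs more than 3 vertices")
  if (anyNA(vertices) || any(!is.finite(vertices))) {
    stop("vertices contain non-finite values")
  }
  if (min(triangles) < 1L || max(triangles) > nrow(vertices)) {
    stop("triangle indices out of range")
  }
  areas <- triangle_areas(vertices, triangles)
  if (any(areas <= 0)) {
    stop(sprintf("%d degenerate (zero-area) triangles", sum(areas <= 0)))
  }
  structure(
    list(vertices = vertices, triangles = triangles,
         inlet_ring = as.integer(inlet_ring),
         outlet_ring = as.integer(outlet_ring),
         stations = stations, lineage_id = lineage_id),
    class = "surface_mesh")
}

#' Tetrahedral volume mesh
#'
#' @param nodes numeric matrix of node coordinates (mm), one row per node.
#' @param tets integer matrix, one row per tetrahedron (1-based node indices).
#' @param lineage_id template lineage tag (see [surface_mesh()]).
#' @param stations optional integer vector, axial station per node.
#' @param layers optional integer vector, radial layer per node (0 = on the
#'   centerline, max = vessel wall).
#' @return An object of class `volume_mesh`.
#' @export
volume_mesh <- function(nodes, tets, lineage_id = "", stations = NULL,
                        layers = NULL) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(tets) != 4L) stop("tets must be an m x 4 matrix")
  if (min(tets) < 1L || max(tets) > nrow(nodes)) {
    stop("tetrahedron indices out of range")
  }
  vols <- tet_volumes(nodes, tets)
  if (any(abs(vols) <= 0)) {
    stop(sprintf("%d degenerate (zero-volume) tetrahedra", sum(abs(vols) <= 0)))
  }
  structure(
    list(nodes = nodes, tets = tets, lineage_id = lineage_id,
         stations = stations, layers = layers),
    class = "volume_mesh")
}

#' Vessel centerline
#'
#' Ordered polyline from the aortic root to the outlet with a local lumen
#' radius at every point. Arc length is recomputed from the points.
#'
#' @param points numeric matrix of ordered centerline points (mm).
#' @param radius numeric vector of local lumen radii (mm, > 0).
#' @return An object of class `centerline` with fields `points`,
#'   `arc_length` (cumulative, starts at 0) and `radius`.
#' @export
centerline <- function(points, radius) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  radius <- as.numeric(radius)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(points) != length(radius)) {
    stop("points and radius must have equal length")
  }
  if (any(radius <= 0)) stop("centerline radius must be positive everywhere")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("coincident consecutive centerline points")
  arc <- c(0, cumsum(seg))
  structure(list(points = points, arc_length = arc, radius = radius),
            class = "centerline")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (nzchar(x$lineage_id)) paste0(" [lineage ", x$lineage_id, "]")
              else ""))
  invisible(x)
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("volume_mesh: %d nodes, %d tets%s\n",
              nrow(x$nodes), nrow(x$tets),
              if (nzchar(x$lineage_id)) paste0(" [lineage ", x$lineage_id, "]")
              else ""))
  invisible(x)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, length %.1f mm, radius %.2f-%.2f mm\n",
              nrow(x$points), max(x$arc_length), min(x$radius), max(x$radius)))
  invisible(x)
}

# --- geometric helpers ------------------------------------------------------

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c_ <- vertices[triangles[, 3L], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  u <- nodes[tets[, 2L], , drop = FALSE] - a
  v <- nodes[tets[, 3L], , drop = FALSE] - a
  w <- nodes[tets[, 4L], , drop = FALSE] - a
  det3 <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
    u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
    u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  det3 / 6
}

# nearest-neighbour index and distance of each query row in ref
nn_ref <- function(query, ref) {
  res <- FNN::get.knnx(ref, query, k = 1L)
  list(index = as.integer(res$nn.index[, 1L]),
       dist = as.numeric(res$nn.dist[, 1L]))
}

mesh_points <- function(x) {
  if (inherits(x, "surface_mesh")) x$vertices
  else if (inherits(x, "volume_mesh")) x$nodes
  else if (inherits(x, "centerline")) x$points
  else as.matrix(x)
}
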