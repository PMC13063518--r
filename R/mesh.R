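#' Triangulated surface mesh
#'
#' Articular-surface container: vertices in mm, 1-based triangular faces,
#' optional per-vertex outward normals. Construction validates index ranges
#' and rejects degenerate (zero-area) faces; the mean edge length is checked
#' against the 0.3 mm analysis density and a warning is issued above
#' 0.45 mm when `analysis = TRUE`.
#'
#' @param vertices Numeric n x 3 matrix (mm).
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @param normals Optional n x 3 matrix of per-vertex outward unit normals.
#' @param analysis If `TRUE`, warn when the mean edge length exceeds
#'   0.45 mm (too coarse for gap/congruency mapping).
#' @return An object of class `triangle_mesh` with fields `vertices`,
#'   `faces`, `normals`, `mean_edge`, `n_components`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL, analysis = FALSE) {
  v <- as.matrix(vertices); storage.mode(v) <- "double"
  f <- as.matrix(faces); storage.mode(f) <- "integer"
  if (ncol(v) != 3 || nrow(v) < 3) stop("vertices must be an n x 3 matrix, n >= 3")
  if (!all(is.finite(v))) stop("vertex coordinates must be finite")
  if (ncol(f) != 3 || nrow(f) < 1) stop("faces must be an m x 3 matrix")
  if (min(f) < 1 || max(f) > nrow(v)) stop("face indices out of range")
  areas <- face_areas(v, f)
  if (any(areas <= 1e-12))
    stop(sprintf("%d degenerate (zero-area) faces", sum(areas <= 1e-12)))
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(v))) stop("normals must match vertices")
  }
  me <- mean_edge_length(v, f)
  if (analysis && me > 0.45)
    warning(sprintf("mean edge length %.3f mm exceeds 0.45 mm; gap/congruency analysis expects ~0.3 mm meshes", me))
  structure(list(vertices = v, faces = f, normals = normals,
                 mean_edge = me, n_components = mesh_component_count(v, f)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, mean edge %.3f mm, %d component(s)%s\n",
              nrow(x$vertices), nrow(x$faces), x$mean_edge, x$n_components,
              if (is.null(x$normals)) "" else ", with normals"))
  invisible(x)
}

face_areas <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_unique_edges <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

mean_edge_length <- function(v, f) {
  e <- mesh_unique_edges(f)
  d <- v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

mesh_component_count <- function(v, f) {
  g <- igraph::graph_from_edgelist(mesh_unique_edges(f), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(v) - igraph::vcount(g)))
  igraph::components(g)$no
}

#' Per-face and area-weighted per-vertex normals
#'
#' Face normals follow the face winding (counter-clockwise = normal toward
#' the viewer); vertex normals are area-weighted averages of incident face
#' normals, normalized to unit length.
#'
#' @param mesh A [triangle_mesh()].
#' @return An n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) # 2*area-weighted
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    vn[, 1] <- vn[, 1] + tabulate2(f[, k], fn[, 1], nrow(v))
    vn[, 2] <- vn[, 2] + tabulate2(f[, k], fn[, 2], nrow(v))
    vn[, 3] <- vn[, 3] + tabulate2(f[, k], fn[, 3], nrow(v))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' Per-vertex scalar field on a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @param values One numeric value per vertex (NA marks vertices where the
#'   quantity is undefined, e.g. failed curvature fits).
#' @param name,units Metadata labels.
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(mesh, values, name = "field", units = "") {
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  values <- as.numeric(values)
  if (length(values) != nrow(mesh$vertices))
    stop("one value per vertex required")
  if (any(is.infinite(values))) stop("field values must be finite or NA")
  structure(list(mesh = mesh, values = values, name = name, units = units),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf("<scalar_field> '%s'%s on %d vertices (%d defined): range [%.4g, %.4g]\n",
              x$name, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              length(x$values), sum(ok),
              if (any(ok)) min(x$values[ok]) else NA,
              if (any(ok)) max(x$values[ok]) else NA))
  invisible(x)
}
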