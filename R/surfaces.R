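#' Joint-gap field between two articular surfaces
#'
#' For every vertex of `surface_a`, the minimum Euclidean distance to the
#' opposing surface `surface_b`, computed as exact point-to-triangle
#' distance (vertex-to-vertex distance would bias high by the order of the
#' edge length). Values are nonnegative; on 0.3 mm meshes the field tracks
#' the continuum joint space width.
#'
#' @param surface_a,surface_b [triangle_mesh()] objects (mm).
#' @param detail If `TRUE`, return the full correspondence (closest faces,
#'   points and barycentric coordinates) instead of just the field.
#' @return A [scalar_field()] on `surface_a` (mm), or a list when
#'   `detail = TRUE`.
#' @export
joint_gap <- function(surface_a, surface_b, detail = FALSE) {
  for (m in list(surface_a, surface_b))
    if (!inherits(m, "triangle_mesh")) stop("inputs must be triangle_mesh")
  res <- .mesh_closest_cpp(surface_a$vertices, surface_b$vertices,
                           surface_b$faces)
  field <- scalar_field(surface_a, res$distance, name = "joint_gap",
                        units = "mm")
  if (!detail) return(field)
  list(field = field, face = res$face, point = res$point, bary = res$bary)
}

#' Per-vertex principal curvatures by local quadric fitting
#'
#' Estimates the two principal curvatures at every vertex from a
#' second-order polynomial (quadric) fitted by least squares to the n-ring
#' neighborhood expressed in the vertex tangent frame. Sign convention:
#' surfaces convex with respect to the outward normal have positive
#' curvature (a convex condyle is positive, a concave fossa negative).
#' Vertices whose neighborhood stays below 6 points even after enlarging
#' the ring are flagged `NA`.
#'
#' @param mesh A [triangle_mesh()] with consistent outward orientation;
#'   `mesh$normals` is used when present, otherwise area-weighted vertex
#'   normals of the face winding.
#' @param neighborhood_rings Ring order of the neighborhood (default 2).
#' @return A list of class `curvature_field` with per-vertex `k_max`,
#'   `k_min` (1/mm) and `dir_max` (unit 3-vectors, rows; NA where
#'   undefined).
#' @export
principal_curvatures <- function(mesh, neighborhood_rings = 2) {
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  v <- mesh$vertices
  nv <- nrow(v)
  nrm <- if (!is.null(mesh$normals)) mesh$normals else vertex_normals(mesh)
  adj <- vertex_adjacency(mesh)
  k_max <- k_min <- rep(NA_real_, nv)
  dir_max <- matrix(NA_real_, nv, 3)
  for (i in seq_len(nv)) {
    nb <- ring_neighborhood(adj, i, neighborhood_rings)
    r <- neighborhood_rings
    while (length(nb) < 6 && r < neighborhood_rings + 3) {
      r <- r + 1
      nb <- ring_neighborhood(adj, i, r)
    }
    if (length(nb) < 6) next
    n <- nrm[i, ]
    # tangent frame (t1, t2, n)
    t1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- t1 - sum(t1 * n) * n
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(n[2] * t1[3] - n[3] * t1[2],
            n[3] * t1[1] - n[1] * t1[3],
            n[1] * t1[2] - n[2] * t1[1])
    d <- sweep(v[nb, , drop = FALSE], 2, v[i, ])
    u <- d %*% t1
    w <- d %*% t2
    h <- d %*% n
    X <- cbind(u^2, u * w, w^2, u, w, 1)
    fit <- tryCatch(stats::lm.fit(X, h), error = function(e) NULL)
    if (is.null(fit) || fit$rank < 6) next
    cf <- fit$coefficients
    # height function h(u,w): gradient (p,q) and hessian at the origin
    p <- cf[4]; q <- cf[5]
    huu <- 2 * cf[1]; huw <- cf[2]; hww <- 2 * cf[3]
    W <- sqrt(1 + p^2 + q^2)
    E <- 1 + p^2; F <- p * q; G <- 1 + q^2
    L <- huu / W; M <- huw / W; N <- hww / W
    # shape operator = I^-1 II; flip sign so convex w.r.t. outward normal > 0
    I1 <- matrix(c(E, F, F, G), 2, 2)
    II <- matrix(c(L, M, M, N), 2, 2)
    S <- -solve(I1, II)
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE)
    k_max[i] <- ev$values[1]
    k_min[i] <- ev$values[2]
    dmax2 <- ev$vectors[, 1]
    d3 <- dmax2[1] * t1 + dmax2[2] * t2
    dir_max[i, ] <- d3 / sqrt(sum(d3^2))
  }
  structure(list(mesh = mesh, k_max = k_max, k_min = k_min,
                 dir_max = dir_max),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  ok <- is.finite(x$k_max)
  cat(sprintf("<curvature_field> %d vertices (%d defined), k_max median %.4g, k_min median %.4g 1/mm\n",
              length(x$k_max), sum(ok),
              stats::median(x$k_max[ok]), stats::median(x$k_min[ok])))
  invisible(x)
}

vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- mesh_unique_edges(f)
  split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]),
                                  levels = seq_len(nrow(mesh$vertices))))
}

ring_neighborhood <- function(adj, i, rings) {
  seen <- i
  frontier <- i
  for (r in seq_len(rings)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    if (length(frontier) == 0) break
    seen <- c(seen, frontier)
  }
  setdiff(seen, i)
}

#' Equivalent-surface principal curvatures
#'
#' Combines the principal curvatures of two contacting surfaces into the
#' principal curvatures of the single equivalent surface:
#' `k_e = A_S1 + A_S2 +/- sqrt(D_S1^2 + D_S2^2 - 2 D_S1 D_S2)` with
#' `D_Si = k_min_i - k_max_i` and `A_Si = (k_min_i + k_max_i)/2`. The
#' radicand equals `(D_S1 - D_S2)^2` and is clamped at zero against
#' rounding. No relative-orientation (principal-direction angle) term is
#' included by default; see `orientation_aware` and the methods vignette.
#'
#' @param k1max,k1min,k2max,k2min Principal curvatures of the two surfaces
#'   (1/mm); vectors are accepted. Requires `k_max >= k_min` elementwise.
#' @param orientation_aware If `TRUE`, include the classical `cos(2*alpha)`
#'   coupling between the surfaces' principal directions; `alpha` is the
#'   angle between the `k_max` directions.
#' @param alpha Angle in radians between the two `k_max` principal
#'   directions (only used when `orientation_aware = TRUE`).
#' @return A list with vectors `k_e_max`, `k_e_min` (1/mm).
#' @export
equivalent_curvatures <- function(k1max, k1min, k2max, k2min,
                                  orientation_aware = FALSE, alpha = 0) {
  if (any(k1max < k1min - 1e-12, na.rm = TRUE) ||
      any(k2max < k2min - 1e-12, na.rm = TRUE))
    stop("curvature ordering violated: need k_max >= k_min")
  D1 <- k1min - k1max
  D2 <- k2min - k2max
  A <- (k1min + k1max) / 2 + (k2min + k2max) / 2
  rad <- if (orientation_aware) {
    D1^2 + D2^2 + 2 * D1 * D2 * cos(2 * alpha)
  } else {
    D1^2 + D2^2 - 2 * D1 * D2
  }
  root <- sqrt(pmax(rad, 0))
  list(k_e_max = A + root, k_e_min = A - root)
}

#' Point congruency from equivalent curvatures
#'
#' Root-mean-square of the two equivalent principal curvatures,
#' `C = sqrt((k_e_max^2 + k_e_min^2) / 2)`. `C = 0` indicates a perfect
#' local match of the two surfaces; larger values indicate curvature
#' mismatch.
#'
#' @param k_e_max,k_e_min Equivalent principal curvatures (1/mm).
#' @return Congruency value(s) in 1/mm.
#' @export
congruency <- function(k_e_max, k_e_min) {
  sqrt((k_e_max^2 + k_e_min^2) / 2)
}

#' Per-vertex congruency map between two articular surfaces
#'
#' For each vertex of `surface_a`: find the closest point on `surface_b`
#' (the joint-gap correspondence), interpolate `surface_b`'s per-vertex
#' principal curvatures barycentrically at that point, and evaluate the
#' equivalent-surface congruency. Vertices where either curvature is
#' undefined are flagged `NA` and excluded from summaries.
#'
#' @param surface_a,surface_b Oriented [triangle_mesh()] objects.
#' @param neighborhood_rings Passed to [principal_curvatures()].
#' @param orientation_aware Passed to [equivalent_curvatures()]; when
#'   `TRUE`, the angle between interpolated principal directions is used.
#' @return A [scalar_field()] on `surface_a` (1/mm).
#' @export
congruency_map <- function(surface_a, surface_b, neighborhood_rings = 2,
                           orientation_aware = FALSE) {
  ca <- principal_curvatures(surface_a, neighborhood_rings)
  cb <- principal_curvatures(surface_b, neighborhood_rings)
  corr <- joint_gap(surface_a, surface_b, detail = TRUE)
  fb <- surface_b$faces[corr$face, , drop = FALSE]
  interp <- function(vals) {
    m <- cbind(vals[fb[, 1]], vals[fb[, 2]], vals[fb[, 3]])
    rowSums(m * corr$bary)
  }
  k2max <- interp(cb$k_max)
  k2min <- interp(cb$k_min)
  ok <- is.finite(ca$k_max) & is.finite(ca$k_min) &
    is.finite(k2max) & is.finite(k2min)
  vals <- rep(NA_real_, nrow(surface_a$vertices))
  if (any(ok)) {
    alpha <- 0
    if (orientation_aware) {
      da <- ca$dir_max[ok, , drop = FALSE]
      db <- interp_dirs(cb$dir_max, fb, corr$bary)[ok, , drop = FALSE]
      dots <- pmin(1, pmax(-1, abs(rowSums(da * db))))
      alpha <- acos(dots)
    }
    eq <- equivalent_curvatures(ca$k_max[ok], ca$k_min[ok],
                                k2max[ok], k2min[ok],
                                orientation_aware = orientation_aware,
                                alpha = alpha)
    vals[ok] <- congruency(eq$k_e_max, eq$k_e_min)
  }
  scalar_field(surface_a, vals, name = "congruency", units = "1/mm")
}

interp_dirs <- function(dirs, fb, bary) {
  m <- bary[, 1] * dirs[fb[, 1], , drop = FALSE] +
    bary[, 2] * dirs[fb[, 2], , drop = FALSE] +
    bary[, 3] * dirs[fb[, 3], , drop = FALSE]
  len <- sqrt(rowSums(m^2))
  len[!is.finite(len) | len == 0] <- 1
  m / len
}
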