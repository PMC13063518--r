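test_that("joint gap between parallel planes is the separation", {
  pp <- make_plane_pair(gap = 1.25)
  g <- joint_gap(pp$a, pp$b)
  expect_true(all(abs(g$values - 1.25) < 1e-9))
  # coincident meshes: zero everywhere
  g0 <- joint_gap(pp$b, pp$b)
  expect_true(all(g0$values < 1e-12))
  expect_true(all(g$values >= 0))
})

test_that("joint gap from a plane to a sphere approaches the analytic closest distance", {
  plane <- gen_surface("plane", list(extent = 2), edge_length = 0.3)
  r <- 5; d <- 7
  # sphere cap (lower side toward the plane) centered at height d
  cap <- gen_surface("sphere", list(radius = r, extent = 2), edge_length = 0.3)
  cap$vertices[, 3] <- d - r - cap$vertices[, 3] # lower cap, apex at d - r
  cap$faces <- cap$faces[, c(1, 3, 2)]
  g <- joint_gap(plane, cap)
  apex_idx <- which.min(rowSums(plane$vertices[, 1:2]^2))
  expect_equal(g$values[apex_idx], d - r, tolerance = 1e-3)
  expect_true(all(g$values >= d - r - 1e-9))
})

test_that("quadric-fit principal curvatures match plane, sphere and cylinder", {
  plane <- gen_surface("plane", list(extent = 2), edge_length = 0.3)
  pc <- principal_curvatures(plane)
  interior <- rowSums(plane$vertices[, 1:2]^2) < 1.2^2
  expect_lt(max(abs(pc$k_max[interior]), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(pc$k_min[interior]), na.rm = TRUE), 1e-6)

  sph <- gen_surface("sphere", list(radius = 10, extent = 3), edge_length = 0.3)
  pcs <- principal_curvatures(sph)
  interior <- rowSums(sph$vertices[, 1:2]^2) < 2^2
  expect_equal(median(pcs$k_max[interior]), 0.1, tolerance = 0.005)
  expect_equal(median(pcs$k_min[interior]), 0.1, tolerance = 0.005)
  expect_true(all(pcs$k_max >= pcs$k_min - 1e-12, na.rm = TRUE))

  cyl <- gen_surface("cylinder", list(radius = 5, extent = 2), edge_length = 0.3)
  pcc <- principal_curvatures(cyl)
  interior <- rowSums(cyl$vertices[, 1:2]^2) < 1.2^2
  expect_equal(median(pcc$k_max[interior]), 0.2, tolerance = 0.01)
  expect_equal(median(abs(pcc$k_min[interior])), 0, tolerance = 0.01)
})

test_that("estimated curvatures track the attached analytic ground truth on an ellipsoid", {
  el <- gen_surface("ellipsoid", list(a = 12, b = 9, c = 7, extent = 2.5),
                    edge_length = 0.3)
  pc <- principal_curvatures(el)
  interior <- rowSums(el$vertices[, 1:2]^2) < 1.5^2
  ok <- interior & is.finite(pc$k_max)
  expect_gt(mean(ok[interior]), 0.95)
  expect_lt(median(abs(pc$k_max[ok] - attr(el, "k_max_true")[ok]) /
                     attr(el, "k_max_true")[ok]), 0.05)
  expect_lt(median(abs(pc$k_min[ok] - attr(el, "k_min_true")[ok]) /
                     attr(el, "k_min_true")[ok]), 0.05)
})

test_that("equivalent curvatures follow the printed formula on hand-computed cases", {
  expect_equal(equivalent_curvatures(0, 0, 0, 0),
               list(k_e_max = 0, k_e_min = 0))
  # convex sphere k = 0.1 against concave sphere k = -1/12
  eq <- equivalent_curvatures(0.1, 0.1, -1 / 12, -1 / 12)
  expect_equal(eq$k_e_max, 0.1 - 1 / 12, tolerance = 1e-12)
  expect_equal(eq$k_e_min, 0.1 - 1 / 12, tolerance = 1e-12)
  # sphere k = 0.1 against cylinder (0.2, 0): A = 0.2, |D1 - D2| = 0.2
  eq2 <- equivalent_curvatures(0.1, 0.1, 0.2, 0)
  expect_equal(eq2$k_e_max, 0.4, tolerance = 1e-12)
  expect_equal(eq2$k_e_min, 0.0, tolerance = 1e-12)
  expect_error(equivalent_curvatures(0, 0.1, 0, 0), "ordering")
})

test_that("equivalent curvatures and congruency are symmetric in the two surfaces", {
  set.seed(10)
  for (i in 1:20) {
    k1 <- sort(rnorm(2, sd = 0.2)); k2 <- sort(rnorm(2, sd = 0.2))
    a <- equivalent_curvatures(k1[2], k1[1], k2[2], k2[1])
    b <- equivalent_curvatures(k2[2], k2[1], k1[2], k1[1])
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(congruency(a$k_e_max, a$k_e_min),
                 congruency(b$k_e_max, b$k_e_min), tolerance = 1e-12)
  }
})

test_that("congruency is the RMS of the equivalent curvatures", {
  expect_equal(congruency(0, 0), 0)
  expect_equal(congruency(0.37, 0.37), 0.37)
  expect_equal(congruency(-0.37, -0.37), 0.37)
  expect_equal(congruency(0.4, 0.0), sqrt(0.16 / 2), tolerance = 1e-12)
  expect_equal(congruency(0.4, 0.0), 0.2828, tolerance = 1e-3)
})

test_that("congruency map matches the analytic sphere-in-socket mismatch", {
  pr <- gen_condyle_fossa_pair(condyle_r = 10, socket_r = 12,
                               clearance = 0.3, edge_length = 0.3)
  cm <- congruency_map(pr$condyle, pr$fossa)
  interior <- rowSums(pr$condyle$vertices[, 1:2]^2) < 2.5^2
  vals <- cm$values[interior & is.finite(cm$values)]
  expect_equal(median(vals), 1 / 10 - 1 / 12, tolerance = 0.1) # within 10 %
  # congruent pair (equal radii, coincident): congruency ~ 0
  pr0 <- gen_condyle_fossa_pair(condyle_r = 10, socket_r = 10,
                                clearance = 0, edge_length = 0.3)
  cm0 <- congruency_map(pr0$condyle, pr0$fossa)
  vals0 <- cm0$values[interior & is.finite(cm0$values)]
  expect_lt(median(vals0), 0.002) # ~10x the curvature-estimation error
  # plane against plane: exactly congruent
  pp <- make_plane_pair(gap = 0.4, edge = 0.3)
  cmp <- congruency_map(pp$a, pp$b)
  expect_lt(max(abs(cmp$values), na.rm = TRUE), 1e-6)
})

test_that("congruency map is invariant under a joint rigid transformation", {
  pr <- gen_condyle_fossa_pair(condyle_r = 8, socket_r = 9.5,
                               clearance = 0.4, edge_length = 0.4)
  set.seed(11)
  R <- random_rotation(); t0 <- c(5, -3, 11)
  mv <- function(m) {
    m$vertices <- sweep(m$vertices %*% t(R), 2, t0, `+`)
    if (!is.null(m$normals)) m$normals <- m$normals %*% t(R)
    m
  }
  a <- congruency_map(pr$condyle, pr$fossa)
  b <- congruency_map(mv(pr$condyle), mv(pr$fossa))
  ok <- is.finite(a$values) & is.finite(b$values)
  expect_equal(a$values[ok], b$values[ok], tolerance = 1e-6)
})

test_that("gap values are bounded by the bounding-box diameter and are nonnegative", {
  pr <- gen_condyle_fossa_pair(condyle_r = 10, socket_r = 12,
                               clearance = 0.5, edge_length = 0.4)
  g <- joint_gap(pr$condyle, pr$fossa)
  allv <- rbind(pr$condyle$vertices, pr$fossa$vertices)
  diam <- sqrt(sum((apply(allv, 2, max) - apply(allv, 2, min))^2))
  expect_true(all(g$values >= 0))
  expect_true(all(g$values <= diam))
})
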