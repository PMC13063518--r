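test_that("the bite plane passes through its landmarks with a superior normal", {
  bp <- build_bite_plane(c(-22, 70, -25), c(22, 70, -25), c(0, 92, -25))
  expect_equal(bp$normal, c(0, 0, 1))
  bp2 <- build_bite_plane(c(-22, 70, -25) + 5, c(22, 70, -25) + 5,
                          c(0, 92, -25) + 5)
  expect_equal(bp2$normal, bp$normal)
  set.seed(30)
  for (i in 1:10) {
    P <- matrix(rnorm(9, sd = 20), 3)
    bp3 <- try(build_bite_plane(P[1, ], P[2, ], P[3, ]), silent = TRUE)
    if (inherits(bp3, "try-error")) next
    res <- apply(P, 1, function(p) sum(bp3$normal * (p - bp3$point)))
    expect_lt(max(abs(res)), 1e-9)
    expect_gte(bp3$normal[3], 0)
  }
  expect_error(build_bite_plane(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("a single vertical muscle through the bite point transmits its full strength", {
  model <- make_lever_model(m_arm = 35, b_arm = 70)
  # move the one strong muscle pair onto the premolars, pulling straight up
  model$muscles <- lapply(model$muscles, function(m) {
    if (m$name == "masseter_superficial") {
      sgn <- if (m$side == "right") 1 else -1
      m$insertion <- c(sgn * 22, 70, -25)
      m$origin <- c(sgn * 22, 70, 40)
    }
    m
  })
  sim <- build_sim(tmj_model(model$muscles, model$ligaments,
                             model$joint_sites, model$bite_points,
                             model$landmarks, mass_kg = model$mass_kg,
                             com = model$com, gravity = FALSE,
                             damping = model$damping))
  er <- excitation_response(sim)
  h_left <- er$H[["left_masseter_superficial"]]
  expect_equal(h_left, 400, tolerance = 400 * 1e-6)
  # doubling F_max doubles the column
  model2 <- model
  model2$muscles <- lapply(model$muscles, function(m) {
    if (m$name == "masseter_superficial") m$f_max <- 800
    m
  })
  sim2 <- build_sim(tmj_model(model2$muscles, model2$ligaments,
                              model2$joint_sites, model2$bite_points,
                              model2$landmarks, mass_kg = model2$mass_kg,
                              com = model2$com, gravity = FALSE,
                              damping = model2$damping))
  expect_equal(excitation_response(sim2)$H[["left_masseter_superficial"]],
               2 * h_left, tolerance = 1e-6 * h_left)
})

test_that("the excitation response follows the planar lever balance", {
  # vertical muscle at arm m, bite at arm b, condyles as fulcrum:
  # the sagittal lever transmits F_max * m / b per unit activation, split
  # between the paired task-side-loaded geometry; use both sides activated
  # equally via the H sum to compare against the 2-D closed form
  m_arm <- 30; b_arm <- 75
  model <- make_lever_model(m_arm = m_arm, b_arm = b_arm, f_max = 300)
  sim <- build_sim(model)
  # settle into joint contact first so the condyles act as a fulcrum
  res <- simulate_task(model, gen_force_curve(20, n = 120),
                       n_substeps = 10)
  er <- excitation_response(sim, res$final_state)
  h_pair <- er$H[["left_masseter_superficial"]] +
    er$H[["right_masseter_superficial"]]
  expect_equal(h_pair, 300 * m_arm / b_arm, tolerance = 0.04 * h_pair)
})

test_that("step leaves an equilibrium state unchanged and respects the constraint", {
  model <- gen_toy_mandible()
  model$gravity <- FALSE
  sim <- build_sim(model)
  st <- sim$state0
  new <- step(sim, st, numeric(12), 1e-3)
  expect_equal(new$p, st$p, tolerance = 1e-12)
  expect_equal(new$v, st$v, tolerance = 1e-12)
  # with gravity and muscles on, the constraint residual stays tiny
  res <- simulate_task(gen_toy_mandible(), gen_force_curve(50, n = 60),
                       n_substeps = 5)
  sim2 <- build_sim(gen_toy_mandible())
  resid <- abs(tmjmech:::constraint_values(sim2, res$final_state))
  expect_lt(resid / 1e-3, 1e-8) # < 1e-8 mm, state in m
})

test_that("the passive integrator conserves energy on a soft elastic pendulum", {
  # gravity in the constraint plane (vertical bite plane), one soft cable,
  # damping off: symplectic Euler should hold the energy drift under 1 %
  model <- gen_toy_mandible()
  model$muscles <- lapply(model$muscles, function(m) { m$f_max <- 1e-9; m })
  model$ligaments <- lapply(model$ligaments, function(l) {
    l$stiffness <- 0; l
  })
  model$ligaments[[1]]$stiffness <- 2    # soft cable pendulum
  model$ligaments[[1]]$slack_length <- 0
  sites <- lapply(model$joint_sites, function(s) {
    s$socket_radius <- 500 # joints far open: a pure pendulum
    s
  })
  model <- tmj_model(model$muscles, model$ligaments, sites,
                     bite_points = list(premolar_left = c(-22, 70, -25),
                                        premolar_right = c(22, 70, -28),
                                        incisor = c(0, 92, -40)),
                     landmarks = model$landmarks, mass_kg = model$mass_kg,
                     com = model$com, gravity = TRUE,
                     damping = list(translational = 0, rotational = 0))
  sim <- build_sim(model)
  st <- sim$state0
  st$v <- c(0, 0.003, 0.004) # gentle in-plane push, m/s
  lig <- sim$ligaments[[1]]
  energy <- function(s) {
    ke <- 0.5 * sim$mass * sum(s$v^2) +
      0.5 * sum(s$w * (s$R %*% sim$I_body %*% crossprod(s$R, s$w)))
    pe <- sim$mass * 9.81 * s$p[3]
    x <- s$p + drop(s$R %*% lig$insertion_b)
    l_mm <- sqrt(sum((lig$origin_w - x)^2)) / 1e-3
    L0 <- lig$params$initial_length + lig$params$slack_length
    stretch_mm <- max(0, l_mm - L0)
    # cable PE: 0.5 * (stiffness / L0) * stretch^2, in N mm -> J
    pe_cable <- 0.5 * (lig$params$stiffness / L0) * stretch_mm^2 * 1e-3
    ke + pe + pe_cable
  }
  e0 <- energy(st)
  states <- st
  for (k in 1:250) states <- step(sim, states, numeric(12), 1e-3)
  drift <- abs(energy(states) - e0) / abs(e0)
  expect_lt(drift, 0.01)
})

test_that("joint contact force is zero when open and scales linearly with the modulus", {
  model <- gen_toy_mandible()
  sim <- build_sim(model)
  cf0 <- joint_contact_force(sim)
  expect_equal(cf0$left, c(0, 0, 0))  # reference pose has clearance
  expect_equal(cf0$right, c(0, 0, 0))
  # push the mandible up into the sockets
  st <- sim$state0
  st$p <- st$p + c(0, 0, 0.1e-3)
  cf1 <- joint_contact_force(sim, st)
  expect_gt(sqrt(sum(cf1$left^2)), 0)
  expect_lt(cf1$left[3], 0) # fossa pushes the condyle down
  model2 <- gen_toy_mandible()
  for (s in names(model2$joint_sites))
    model2$joint_sites[[s]]$ef <- ef_params(elastic_modulus = 5.4)
  cf2 <- joint_contact_force(build_sim(model2), st)
  expect_equal(cf2$left, 2 * cf1$left, tolerance = 1e-9)
  expect_equal(cf2$right, 2 * cf1$right, tolerance = 1e-9)
})

test_that("uniform penetration of a conforming patch integrates to pressure times area", {
  # equal radii and a small interference: every quadrature node penetrates
  # by the same depth, so |F| = p(d) * projected patch area
  model <- gen_toy_mandible()
  d_mm <- 0.1
  for (s in names(model$joint_sites)) {
    model$joint_sites[[s]]$socket_radius <- 8 - d_mm # interference fit
    model$joint_sites[[s]]$socket_center <- model$joint_sites[[s]]$condyle_center
    model$joint_sites[[s]]$patch_half_angle <- 12 # narrow, near-flat patch
    model$joint_sites[[s]]$n_rings <- 40
  }
  sim <- build_sim(model)
  cf <- joint_contact_force(sim)
  p_pa <- ef_pressure(d_mm, ef_params()) * 1e6
  r <- 8e-3
  th <- 12 * pi / 180
  area_proj <- pi * (r * sin(th))^2 # projected area of the cap
  expect_equal(sqrt(sum(cf$left^2)), p_pa * area_proj,
               tolerance = 0.02 * p_pa * area_proj)
})

test_that("simulate_task tracks the target and enforces the IC ratios exactly", {
  model <- gen_toy_mandible()
  res <- simulate_task(model, gen_force_curve(50),
                       ratios = list(temporalis = 2, masseter = 2))
  n <- length(res$bite_force)
  expect_false(any(res$saturated))
  expect_equal(res$bite_force[n], 50, tolerance = 1)
  a <- res$activations
  for (nm in c("temporalis_anterior", "temporalis_middle",
               "temporalis_posterior", "masseter_superficial",
               "masseter_deep")) {
    expect_equal(a[, paste0("left_", nm)], 2 * a[, paste0("right_", nm)],
                 tolerance = 1e-12)
  }
  expect_true(all(a >= 0 & a <= 1))
})

test_that("a zero-amplitude target leaves activations at the regularized floor", {
  model <- gen_toy_mandible()
  model$gravity <- FALSE # with gravity on, holding zero bite needs tone
  curve <- uniform_series(rep(0, 60), 240)
  res <- simulate_task(model, curve, n_substeps = 5)
  expect_lt(max(res$activations), 1e-6)
})

test_that("an unreachable target is flagged saturated, not an error", {
  model <- gen_toy_mandible()
  res <- simulate_task(model, gen_force_curve(5000, n = 40), n_substeps = 5)
  expect_true(any(res$saturated))
})

test_that("terminal state is in static equilibrium", {
  model <- gen_toy_mandible()
  res <- simulate_task(model, gen_force_curve(50))
  sim <- build_sim(model)
  st <- res$final_state
  n <- length(res$bite_force)
  wr <- tmjmech:::sim_wrench(sim, st, res$activations[n, ])
  J <- tmjmech:::constraint_jacobian(sim, st)
  lam <- attr(st, "lambda")
  net <- c(wr$F, wr$T) + drop(t(J) * lam) - c(sim$c_trans * st$v,
                                              sim$c_rot * st$w)
  # forces in N, torques in N m; 1e-3 N and 1e-3 N mm = 1e-6 N m
  expect_lt(max(abs(net[1:3])), 1e-3)
  expect_lt(max(abs(net[4:6])) / 1e-3, 1e-3 + 1e-9) # N mm
})

test_that("simulation results are bit-identical across repeated runs", {
  model <- gen_toy_mandible()
  r1 <- simulate_task(model, gen_force_curve(50, n = 50), n_substeps = 5)
  r2 <- simulate_task(model, gen_force_curve(50, n = 50), n_substeps = 5)
  expect_identical(r1$bite_force, r2$bite_force)
  expect_identical(r1$activations, r2$activations)
  expect_identical(r1$joint_force_left, r2$joint_force_left)
})

test_that("mirroring the model and task mirrors the simulation result", {
  model <- gen_toy_mandible()
  mm <- mirror_model(model)
  r1 <- simulate_task(model, gen_force_curve(40, n = 80), n_substeps = 5)
  r2 <- simulate_task(mm, gen_force_curve(40, n = 80), n_substeps = 5)
  n <- length(r1$bite_force)
  expect_equal(r2$bite_force, r1$bite_force, tolerance = 1e-9)
  expect_equal(r2$joint_mag_left, r1$joint_mag_right, tolerance = 1e-8)
  expect_equal(r2$joint_mag_right, r1$joint_mag_left, tolerance = 1e-8)
})

test_that("joint loading summary divides terminal joint force by bite force", {
  model <- gen_toy_mandible()
  res <- simulate_task(model, gen_force_curve(50, n = 100), n_substeps = 5)
  s <- summarize_joint_loading(res, digits = NA)
  n <- length(res$bite_force)
  expect_equal(s$left_pct, 100 * res$joint_mag_left[n] / res$bite_force[n])
  expect_equal(s$right_pct, 100 * res$joint_mag_right[n] / res$bite_force[n])
  # arithmetic check of the percentage convention: 18 N on 50 N -> 36.0
  fake <- res
  fake$joint_mag_left[n] <- 18 * res$bite_force[n] / 50
  expect_equal(summarize_joint_loading(fake)$left_pct,
               round_half_up(100 * 18 / 50, 1))
})
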