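# Forward dynamics of the rigid mandible: SI internals (m, N, kg, s),
# converted once from the model's mm-N-MPa convention at build time.

MM <- 1e-3

#' Compile a model for simulation
#'
#' Converts the mm-based [tmj_model()] once into SI internals: body-frame
#' coordinates of all mandible-fixed points relative to the center of mass,
#' contact-patch quadrature nodes, reference muscle/ligament lengths, and
#' the bite-plane constraint rows. The returned object carries the
#' reference state (`sim$state0`).
#'
#' @param model A [tmj_model()].
#' @return An object of class `tmj_sim`.
#' @export
build_sim <- function(model) {
  if (!inherits(model, "tmj_model")) stop("model must be a tmj_model")
  com <- model$com * MM
  b <- function(x_mm) as.numeric(x_mm) * MM - com # mandible point -> body frame
  w <- function(x_mm) as.numeric(x_mm) * MM       # cranium point -> world

  muscles <- lapply(model$muscles, function(m) {
    ins_b <- b(m$insertion)
    org_w <- w(m$origin)
    ref_len_mm <- sqrt(sum((as.numeric(m$origin) - as.numeric(m$insertion))^2))
    lopt <- if (is.null(m$optimal_length) || is.na(m$optimal_length))
      ref_len_mm else m$optimal_length
    list(name = m$name, side = m$side, group = m$group,
         origin_w = org_w, insertion_b = ins_b, active = isTRUE(m$active),
         params = hill_params(m$f_max, lopt))
  })
  ligaments <- lapply(model$ligaments, function(l) {
    ref_len_mm <- sqrt(sum((as.numeric(l$origin) - as.numeric(l$insertion))^2))
    list(name = l$name, side = l$side, origin_w = w(l$origin),
         insertion_b = b(l$insertion),
         params = ligament_params(l$stiffness, ref_len_mm, l$slack_length))
  })
  sites <- lapply(model$joint_sites, function(s) {
    quad <- cap_quadrature(s$condyle_radius * MM,
                           s$patch_half_angle %||% 60,
                           s$n_rings %||% 8)
    list(side = s$side, condyle_b = b(s$condyle_center),
         socket_w = w(s$socket_center),
         r_condyle = s$condyle_radius * MM, r_socket = s$socket_radius * MM,
         ef = s$ef, nodes_b = quad$nodes, areas = quad$areas)
  })
  bp <- model$bite_plane
  active_idx <- which(vapply(muscles, `[[`, logical(1), "active"))
  sim <- structure(list(
    model = model,
    mass = model$mass_kg,
    I_body = model$inertia_kgm2,
    I_body_inv = solve(model$inertia_kgm2),
    com0 = com,
    muscles = muscles,
    ligaments = ligaments,
    sites = sites,
    plane_point = bp$point * MM,
    plane_normal = bp$normal,
    # the bite constraint attaches the task-side premolar to the plane;
    # the other occlusal landmarks only define the plane's orientation
    cpoint_b = b(if (model$task_side == "left") model$bite_points$premolar_left
                 else model$bite_points$premolar_right),
    landmarks_b = t(apply(bp$landmarks, 1, b)),
    active_idx = active_idx,
    gravity = if (isTRUE(model$gravity)) c(0, 0, -9.81) else c(0, 0, 0),
    c_trans = model$damping$translational,
    c_rot = model$damping$rotational
  ), class = "tmj_sim")
  sim$state0 <- list(p = com, R = diag(3), v = c(0, 0, 0), w = c(0, 0, 0))
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ring quadrature of a spherical cap of half-angle (deg) about body +z,
# scaled to radius r; nodes are unit directions, areas sum to the cap area
cap_quadrature <- function(r, half_angle_deg, n_rings) {
  th_max <- half_angle_deg * pi / 180
  dth <- th_max / n_rings
  nodes <- NULL
  areas <- NULL
  for (j in seq_len(n_rings)) {
    th <- (j - 0.5) * dth
    n_phi <- max(6L, 2L * ceiling(pi * sin(th) / dth)) # even count
    phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
    ring <- cbind(sin(th) * cos(phi), sin(th) * sin(phi),
                  rep(cos(th), n_phi))
    nodes <- rbind(nodes, ring)
    areas <- c(areas, rep(r^2 * sin(th) * dth * (2 * pi / n_phi), n_phi))
  }
  list(nodes = nodes, areas = areas)
}

rot_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew(w))
  k <- w / th
  K <- skew(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

skew <- function(a) {
  matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
}

orthonormalize <- function(R) {
  s <- svd(R)
  s$u %*% t(s$v)
}

# total applied wrench (force, torque about COM) at a state, activations `a`
# over the active muscles; also returns per-side contact force (N, world)
sim_wrench <- function(sim, state, a, include_damping = FALSE) {
  p <- state$p; R <- state$R
  F <- sim$mass * sim$gravity
  Tq <- -cross3(state$w, drop(R %*% sim$I_body %*% crossprod(R, state$w)))
  if (include_damping) {
    F <- F - sim$c_trans * state$v
    Tq <- Tq - sim$c_rot * state$w
  }
  ai <- 0L
  for (m in sim$muscles) {
    x <- p + drop(R %*% m$insertion_b)
    vec <- m$origin_w - x
    l <- sqrt(sum(vec^2))
    act <- if (m$active) { ai <- ai + 1L; a[ai] } else 0
    fmag <- hill_static_force(act, l / MM, m$params)
    if (fmag > 0) {
      f <- fmag * vec / l
      F <- F + f
      Tq <- Tq + cross3(x - p, f)
    }
  }
  for (lg in sim$ligaments) {
    x <- p + drop(R %*% lg$insertion_b)
    vec <- lg$origin_w - x
    l <- sqrt(sum(vec^2))
    fmag <- ligament_force(l / MM, lg$params)
    if (fmag > 0) {
      f <- fmag * vec / l
      F <- F + f
      Tq <- Tq + cross3(x - p, f)
    }
  }
  contact <- vector("list", length(sim$sites))
  names(contact) <- vapply(sim$sites, `[[`, character(1), "side")
  for (k in seq_along(sim$sites)) {
    s <- sim$sites[[k]]
    cc <- p + drop(R %*% s$condyle_b)
    nd <- sweep(s$nodes_b %*% t(R) * s$r_condyle, 2, cc, `+`)
    rel <- sweep(nd, 2, s$socket_w)
    rho <- sqrt(rowSums(rel^2))
    pen_mm <- (rho - s$r_socket) / MM
    fi <- c(0, 0, 0)
    ti <- c(0, 0, 0)
    # the socket is the superior cap of its sphere: only nodes pressing
    # into that cap (radial direction with an upward component) contact
    axis_w <- R[, 3]
    hit <- which(pen_mm > 0 & (rel %*% axis_w) > 0)
    if (length(hit) > 0) {
      pr <- ef_pressure(pen_mm[hit], s$ef) * 1e6 # MPa -> Pa
      fvec <- -rel[hit, , drop = FALSE] / rho[hit] * (pr * s$areas[hit])
      fi <- colSums(fvec)
      arm <- sweep(nd[hit, , drop = FALSE], 2, p)
      ti <- colSums(cbind(arm[, 2] * fvec[, 3] - arm[, 3] * fvec[, 2],
                          arm[, 3] * fvec[, 1] - arm[, 1] * fvec[, 3],
                          arm[, 1] * fvec[, 2] - arm[, 2] * fvec[, 1]))
    }
    contact[[k]] <- fi
    F <- F + fi
    Tq <- Tq + ti
  }
  list(F = F, T = Tq, contact = contact)
}

# constraint Jacobian (1 x 6) of the point-on-plane bite constraint
constraint_jacobian <- function(sim, state) {
  n <- sim$plane_normal
  r <- drop(state$R %*% sim$cpoint_b)
  matrix(c(n, cross3(r, n)), 1, 6)
}

constraint_values <- function(sim, state) {
  n <- sim$plane_normal
  x <- state$p + drop(state$R %*% sim$cpoint_b)
  sum(n * (x - sim$plane_point))
}

# effective inverse mass matrix (implicit damping folded in): 6x6 block diag
minv6 <- function(sim, state, dt, damped = TRUE) {
  ct <- if (damped) sim$c_trans else 0
  cr <- if (damped) sim$c_rot else 0
  Mt <- diag(sim$mass + dt * ct, 3)
  Iw <- state$R %*% sim$I_body %*% t(state$R) + diag(dt * cr, 3)
  rbindblock(solve(Mt), solve(Iw))
}

rbindblock <- function(A, B) {
  out <- matrix(0, 6, 6)
  out[1:3, 1:3] <- A
  out[4:6, 4:6] <- B
  out
}

#' Advance the mandible state by one time step
#'
#' Semi-implicit Euler update of the 6-DOF rigid-mandible state under
#' muscle, ligament, elastic-foundation contact, gravity and damping
#' forces, with the point-on-plane bite constraint (task-side premolar on
#' the occlusal plane) enforced at the velocity level by a Lagrange
#' multiplier and at the position level by Newton projection (residual
#' below 1e-8 mm). Damping is treated implicitly for stability; the
#' multiplier is returned as a force, so the bite reaction can be read
#' directly.
#'
#' @param sim A [build_sim()] object.
#' @param state State list (`p`, `R`, `v`, `w`).
#' @param activations Activation vector over the active muscles (model
#'   order), each in \[0, 1\].
#' @param dt Time step in seconds.
#' @return The new state, with attributes `lambda` (constraint force, N),
#'   `contact` (per-side contact force vectors, N), and `bite_force` (N,
#'   reaction at the task-side premolar normal to the bite plane).
#' @export
step <- function(sim, state, activations, dt) {
  if (!inherits(sim, "tmj_sim")) stop("sim must come from build_sim()")
  if (dt <= 0) stop("dt must be positive")
  na <- length(sim$active_idx)
  if (length(activations) != na)
    stop(sprintf("activations must have length %d", na))
  wr <- sim_wrench(sim, state, activations, include_damping = FALSE)
  # damping force at current velocity enters implicitly through minv6;
  # the explicit part of the damping wrench is -C v (kept implicit), so g6
  # holds only the applied forces
  g6 <- c(wr$F, wr$T)
  J <- constraint_jacobian(sim, state)
  Mi <- minv6(sim, state, dt, damped = TRUE)
  v6 <- c(state$v, state$w)
  # implicit damping: M_eff (v+ - v)/dt = g - C v+ + Jt lambda  =>
  # v+ = Mi (M v + dt g + dt Jt lambda), with Mi = (M + dt C)^-1
  Mv <- c(sim$mass * state$v,
          drop(state$R %*% sim$I_body %*% crossprod(state$R, state$w)))
  vfree <- drop(Mi %*% (Mv + dt * g6))
  S <- J %*% Mi %*% t(J)
  lambda <- drop(-(J %*% vfree) / dt) / drop(S)
  v6p <- vfree + dt * drop(Mi %*% (t(J) %*% lambda))
  new <- state
  new$v <- v6p[1:3]
  new$w <- v6p[4:6]
  new$p <- state$p + dt * new$v
  new$R <- orthonormalize(rot_exp(new$w * dt) %*% state$R)
  # position projection to kill constraint drift
  for (it in 1:10) {
    cval <- constraint_values(sim, new)
    if (abs(cval) < 1e-11) break
    Jp <- constraint_jacobian(sim, new)
    dq <- -drop(t(Jp)) * (cval / drop(Jp %*% t(Jp)))
    new$p <- new$p + dq[1:3]
    new$R <- orthonormalize(rot_exp(dq[4:6]) %*% new$R)
  }
  attr(new, "lambda") <- lambda
  attr(new, "contact") <- wr$contact
  attr(new, "bite_force") <- -lambda
  new
}

#' Excitation response of the bite force to muscle activations
#'
#' The row vector `H` mapping unit activations of the active muscles to the
#' bite force generated at the task-side premolar normal to the bite plane,
#' computed by unit-activation perturbation at the current state: column j
#' is the constraint-reaction change produced by muscle j at full
#' activation with all others passive (the reaction is affine in the
#' activations at fixed state, so the perturbation is exact). The passive
#' bite force (gravity, ligaments, contact, passive muscle tension, and the
#' momentum term of the discrete solve) is returned alongside.
#'
#' @param sim A [build_sim()] object (a [tmj_model()] is accepted and
#'   compiled on the fly).
#' @param state State list; default the reference state.
#' @param dt Time step used for the discrete constraint solve (s).
#' @return List with `H` (named vector over active muscles) and
#'   `passive_bite` (N).
#' @export
excitation_response <- function(sim, state = NULL, dt = 1e-3) {
  if (inherits(sim, "tmj_model")) sim <- build_sim(sim)
  if (is.null(state)) state <- sim$state0
  na <- length(sim$active_idx)
  J <- constraint_jacobian(sim, state)
  Mi <- minv6(sim, state, dt, damped = TRUE)
  Sc <- drop(J %*% Mi %*% t(J))
  wr0 <- sim_wrench(sim, state, numeric(na))
  Mv <- c(sim$mass * state$v,
          drop(state$R %*% sim$I_body %*% crossprod(state$R, state$w)))
  lam0 <- drop(-(J %*% (Mi %*% (Mv + dt * c(wr0$F, wr0$T)))) / dt) / Sc
  H <- numeric(na)
  nm <- character(na)
  p <- state$p; R <- state$R
  for (k in seq_len(na)) {
    m <- sim$muscles[[sim$active_idx[k]]]
    x <- p + drop(R %*% m$insertion_b)
    vec <- m$origin_w - x
    l <- sqrt(sum(vec^2))
    fl <- m$params$active_fl(l / MM / m$params$optimal_length)
    df <- m$params$max_isometric_force * fl * vec / l
    dg6 <- c(df, cross3(x - p, df))
    dlam <- drop(-(J %*% (Mi %*% dg6))) / Sc
    H[k] <- -dlam
    nm[k] <- paste(m$side, m$name, sep = "_")
  }
  names(H) <- nm
  list(H = H, passive_bite = -lam0)
}

#' Per-side joint contact force
#'
#' Integrates the elastic-foundation pressure over the penetrating part of
#' each condylar contact patch (ring quadrature of the spherical cap
#' against the socket surface) and returns the total force each joint
#' transmits to the mandible. Zero when the joint is open.
#'
#' @param sim A [build_sim()] object (or a [tmj_model()]).
#' @param state State list; default the reference state.
#' @return Named list of per-side world force 3-vectors (N).
#' @export
joint_contact_force <- function(sim, state = NULL) {
  if (inherits(sim, "tmj_model")) sim <- build_sim(sim)
  if (is.null(state)) state <- sim$state0
  sim_wrench(sim, state, numeric(length(sim$active_idx)))$contact
}
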