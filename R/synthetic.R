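# Deterministic synthetic-data generators: every generator is a pure
# function of its parameters and seed (RNG state is saved and restored).

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic unilateral-bite recording with known ground truth
#'
#' Emulates the function-assessment acquisition: five consecutive static
#' bites at the 10/20/30/40/50 N target staircase (scaled so the top bite
#' plateaus at `plateau_N`), recorded at `fs` together with four EMG
#' channels. Each EMG channel is a constant-envelope frequency-modulated
#' carrier wandering inside the 20-450 Hz surface-EMG band,
#' amplitude-modulated by a power law of the force level chosen so that
#' after 20 N-baseline normalization the ipsilateral/contralateral envelope
#' ratios equal the prescribed IC ratios at the top bite. Optional additive
#' Gaussian noise (`noise_sd`, relative to the baseline envelope) degrades
#' the recovery realistically.
#'
#' @param plateau_N Plateau force of the strongest bite (N, > 0).
#' @param ic_temporalis,ic_masseter Prescribed IC ratios (> 0).
#' @param task_side `"left"` or `"right"`.
#' @param fs Sampling frequency, Hz (default 2000).
#' @param noise_sd Additive noise standard deviation relative to the
#'   baseline envelope (default 0).
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @return A list with `recording` (a [bite_recording()]) and `truth`
#'   (prescribed ratios and plateau plus the `bite_window`,
#'   `baseline_window` and `rest_window` to feed [process_recording()]).
#' @export
gen_bite_recording <- function(plateau_N = 50, ic_temporalis = 1.5,
                               ic_masseter = 1.4, task_side = "left",
                               fs = 2000, noise_sd = 0, seed = 1) {
  if (plateau_N <= 0) stop("plateau must be positive")
  if (ic_temporalis <= 0 || ic_masseter <= 0) stop("ratios must be positive")
  task_side <- match.arg(task_side, c("left", "right"))
  with_seed(seed, {
    ramp <- 0.3; hold <- 1.6; rest <- 0.6
    levels <- c(10, 20, 30, 40, 50) / 50 * plateau_N
    dt <- 1 / fs
    seg_force <- function(level) {
      c(seq(0, level, length.out = round(ramp * fs)),
        rep(level, round(hold * fs)),
        seq(level, 0, length.out = round(ramp * fs)),
        rep(0, round(rest * fs)))
    }
    force <- c(rep(0, round(rest * fs)), unlist(lapply(levels, seg_force)))
    n <- length(force)
    tt <- (seq_len(n) - 1) * dt
    bite_len <- 2 * ramp + hold + rest
    hold_window <- function(k) {
      t0 <- rest + (k - 1) * bite_len + ramp
      c(t0 + 0.3 * hold, t0 + 0.95 * hold)
    }
    baseline_window <- hold_window(2) # the 20 N bite
    bite_window <- hold_window(5)     # the top bite
    rest_window <- c(0.05, rest - 0.05)
    # per-channel envelope: power law of force level, equal at the 20 N
    # baseline, prescribed ratio at the top bite after normalization
    f20 <- levels[2]
    rel <- pmax(force, 0.05 * f20) / f20
    p_contra <- 1
    expo <- function(r) p_contra + log(r) / log(levels[5] / f20)
    side_is_left <- task_side == "left"
    exps <- c(
      LT = if (side_is_left) expo(ic_temporalis) else p_contra,
      RT = if (side_is_left) p_contra else expo(ic_temporalis),
      LM = if (side_is_left) expo(ic_masseter) else p_contra,
      RM = if (side_is_left) p_contra else expo(ic_masseter)
    )
    fm_carrier <- function() {
      f_inst <- 150 + 100 * as.numeric(
        stats::filter(stats::rnorm(n), rep(1 / 50, 50), sides = 1))
      f_inst[is.na(f_inst)] <- 150
      f_inst <- pmin(450, pmax(20, f_inst))
      sin(2 * pi * cumsum(f_inst) * dt + stats::runif(1, 0, 2 * pi))
    }
    emg <- lapply(exps, function(p) {
      env <- rel^p
      x <- env * fm_carrier()
      if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
      uniform_series(x, fs, 0)
    })
    rec <- bite_recording(uniform_series(force, fs, 0, units = "N"),
                          emg, task_side)
    list(recording = rec,
         truth = list(ic_temporalis = ic_temporalis,
                      ic_masseter = ic_masseter,
                      plateau_N = plateau_N,
                      bite_window = bite_window,
                      baseline_window = baseline_window,
                      rest_window = rest_window))
  })
}

# equilateral-ish triangulated grid over [-hx, hx] x [-hy, hy] with target
# edge length e; returns 2D vertices and faces (CCW seen from +z)
tri_grid <- function(hx, hy, e) {
  dy <- e * sqrt(3) / 2
  ny <- max(2L, round(2 * hy / dy))
  nx <- max(2L, round(2 * hx / e)) + 1L
  verts <- NULL
  for (i in 0:ny) {
    x <- (seq_len(nx) - 1) * e + (i %% 2) * e / 2 - hx
    verts <- rbind(verts, cbind(x, i * dy - hy))
  }
  idx <- function(i, j) i * nx + j + 1L # i row (0-based), j col (0-based)
  faces <- vector("list", ny)
  for (i in 0:(ny - 1)) {
    j <- 0:(nx - 2)
    if (i %% 2 == 0) {
      f1 <- cbind(idx(i, j), idx(i, j + 1), idx(i + 1, j))
      f2 <- cbind(idx(i, j + 1), idx(i + 1, j + 1), idx(i + 1, j))
    } else {
      f1 <- cbind(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1))
      f2 <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j))
    }
    faces[[i + 1]] <- rbind(f1, f2)
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

# analytic curvatures of a height surface z = f(x, y) from closed-form
# gradient (p, q) and hessian (r, s, t); sign convention: convex w.r.t.
# the chosen outward normal is positive
graph_curvatures <- function(p, q, r, s, t, normal_up = TRUE) {
  W <- sqrt(1 + p^2 + q^2)
  E <- 1 + p^2; F <- p * q; G <- 1 + q^2
  L <- r / W; M <- s / W; N <- t / W
  k <- matrix(NA_real_, length(p), 2)
  for (i in seq_along(p)) {
    I1 <- matrix(c(E[i], F[i], F[i], G[i]), 2, 2)
    II <- matrix(c(L[i], M[i], M[i], N[i]), 2, 2)
    S <- -solve(I1, II)
    if (!normal_up) S <- -S
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    k[i, ] <- ev
  }
  list(k_max = k[, 1], k_min = k[, 2])
}

#' Generate an analytic surface patch as a triangulated mesh
#'
#' Meshes a height surface z = f(x, y) on an equilateral planar grid at the
#' requested edge length (0.3 mm default, the analysis density) and
#' attaches the analytic principal curvatures per vertex as ground truth.
#' Kinds: `plane` (`params$extent`), `sphere` (`radius`, `extent`),
#' `cylinder` (`radius`, axis along y, `extent`), `ellipsoid` (`a`, `b`,
#' `c` semi-axes, `extent`), `saddle` (`radius` scale, `extent`). The patch
#' is centered on the apex; `extent` is the half-width of the meshed square
#' (mm). `convex = TRUE` (default) builds the cap bulging toward +z with
#' outward normal up; `convex = FALSE` builds the mirrored concave socket
#' with outward normal down (into the joint space).
#'
#' @param kind Surface kind.
#' @param params Named list of kind parameters (see above).
#' @param edge_length Target mean edge length in mm (default 0.3).
#' @param convex Orientation of the patch (see above).
#' @return A [triangle_mesh()] with attributes `k_max_true`, `k_min_true`
#'   (1/mm per vertex).
#' @export
gen_surface <- function(kind = c("plane", "sphere", "ellipsoid", "cylinder",
                                 "saddle"),
                        params = list(), edge_length = 0.3, convex = TRUE) {
  kind <- match.arg(kind)
  ext <- params$extent %||% switch(kind, plane = 3, sphere = 0.45 * (params$radius %||% 10),
                                   cylinder = 0.45 * (params$radius %||% 10),
                                   ellipsoid = 0.35 * min(params$a %||% 10, params$b %||% 10),
                                   saddle = 3)
  g <- tri_grid(ext, ext, edge_length)
  x <- g$vertices[, 1]; y <- g$vertices[, 2]
  fun <- switch(kind,
    plane = function(x, y) {
      list(z = 0 * x, p = 0 * x, q = 0 * x, r = 0 * x, s = 0 * x, t = 0 * x)
    },
    sphere = {
      R <- params$radius %||% 10
      if (ext >= R) stop("extent must be smaller than the sphere radius")
      function(x, y) {
        w <- sqrt(R^2 - x^2 - y^2)
        list(z = w - R, p = -x / w, q = -y / w,
             r = -(1 / w + x^2 / w^3), s = -(x * y / w^3),
             t = -(1 / w + y^2 / w^3))
      }
    },
    cylinder = {
      R <- params$radius %||% 10
      if (ext >= R) stop("extent must be smaller than the cylinder radius")
      function(x, y) {
        w <- sqrt(R^2 - x^2)
        list(z = w - R, p = -x / w, q = 0 * y,
             r = -(1 / w + x^2 / w^3), s = 0 * x, t = 0 * x)
      }
    },
    ellipsoid = {
      a <- params$a %||% 10; bb <- params$b %||% 8; cc <- params$c %||% 6
      function(x, y) {
        u <- 1 - x^2 / a^2 - y^2 / bb^2
        if (any(u <= 0)) stop("extent must stay inside the ellipsoid")
        w <- sqrt(u)
        z <- cc * w - cc
        p <- -cc * x / (a^2 * w)
        q <- -cc * y / (bb^2 * w)
        r <- -cc / (a^2 * w) - cc * x^2 / (a^4 * w^3)
        s <- -cc * x * y / (a^2 * bb^2 * w^3)
        t <- -cc / (bb^2 * w) - cc * y^2 / (bb^4 * w^3)
        list(z = z, p = p, q = q, r = r, s = s, t = t)
      }
    },
    saddle = {
      R <- params$radius %||% 10
      function(x, y) {
        list(z = (x^2 - y^2) / (2 * R), p = x / R, q = -y / R,
             r = rep(1 / R, length(x)), s = 0 * x, t = rep(-1 / R, length(x)))
      }
    })
  fz <- fun(x, y)
  z <- fz$z
  faces <- g$faces
  verts <- cbind(x, y, z)
  W <- sqrt(1 + fz$p^2 + fz$q^2)
  normals <- cbind(-fz$p, -fz$q, 1) / W
  kk <- graph_curvatures(fz$p, fz$q, fz$r, fz$s, fz$t, normal_up = TRUE)
  if (!convex) {
    # same dome used as the overlying socket: outward normal (into the
    # joint space) points down, the winding is reversed to match, and the
    # surface is concave w.r.t. that normal (curvature signs negate)
    normals <- -normals
    faces <- faces[, c(1, 3, 2)]
    tmp <- kk
    kk$k_max <- -tmp$k_min
    kk$k_min <- -tmp$k_max
  }
  m <- triangle_mesh(verts, faces, normals = normals)
  attr(m, "k_max_true") <- kk$k_max
  attr(m, "k_min_true") <- kk$k_min
  m
}

#' Generate a condyle/fossa surface pair with a known clearance field
#'
#' A convex spherical-cap condyle (radius `condyle_r`, apex up) under a
#' concave socket offset vertically by `clearance`, so the analytic joint
#' gap is `clearance` at the apex and grows toward the rim. The socket
#' radius is `socket_r`; `incongruence > 0` morphs the socket toward an
#' ellipsoid (semi-axes `socket_r * (1 + incongruence)` laterally, and
#' `socket_r * (1 + incongruence / 2)` antero-posteriorly), increasing the
#' curvature mismatch monotonically.
#'
#' @param condyle_r,socket_r Radii in mm (`socket_r >= condyle_r`).
#' @param clearance Apex gap in mm (>= 0).
#' @param incongruence Nonnegative shape-mismatch parameter.
#' @param edge_length Mesh density (default 0.3 mm).
#' @param extent Patch half-width (default `0.4 * condyle_r`).
#' @return List with `condyle`, `fossa` ([triangle_mesh()]s) and
#'   `gap_true`, the analytic minimum distance from each condyle vertex to
#'   the socket surface (exact for `incongruence = 0`).
#' @export
gen_condyle_fossa_pair <- function(condyle_r = 10, socket_r = 10,
                                   clearance = 0.5, incongruence = 0,
                                   edge_length = 0.3, extent = NULL) {
  if (socket_r < condyle_r) stop("socket_r must be >= condyle_r")
  if (clearance < 0) stop("clearance must be nonnegative (surfaces intersect)")
  if (incongruence < 0) stop("incongruence must be nonnegative")
  extent <- extent %||% (0.4 * condyle_r)
  condyle <- gen_surface("sphere", list(radius = condyle_r, extent = extent),
                         edge_length = edge_length, convex = TRUE)
  a <- socket_r * (1 + incongruence)
  b <- socket_r * (1 + incongruence / 2)
  # socket patch extends further laterally so that every condyle vertex's
  # closest point on the socket sphere lies inside the meshed patch
  fossa_extent <- min(extent * 1.3 * socket_r / condyle_r, 0.75 * socket_r)
  fossa <- if (incongruence == 0) {
    gen_surface("sphere", list(radius = socket_r, extent = fossa_extent),
                edge_length = edge_length, convex = FALSE)
  } else {
    gen_surface("ellipsoid", list(a = a, b = b, c = socket_r,
                                  extent = fossa_extent),
                edge_length = edge_length, convex = FALSE)
  }
  # both apexes sit at the origin in gen_surface coordinates; lift the
  # socket so its apex is `clearance` above the condyle apex
  fossa$vertices[, 3] <- fossa$vertices[, 3] + clearance
  gap_true <- if (incongruence == 0) {
    # the lifted socket is the top cap of a sphere centered at
    # (0, 0, clearance - socket_r); condyle vertices lie inside it
    ctr <- c(0, 0, clearance - socket_r)
    d <- sweep(condyle$vertices, 2, ctr)
    socket_r - sqrt(rowSums(d^2))
  } else {
    rep(NA_real_, nrow(condyle$vertices))
  }
  list(condyle = condyle, fossa = fossa, gap_true = gap_true)
}

#' Generate the parameterized symmetric toy mandible
#'
#' A bilaterally symmetric musculoskeletal mandible for desk-scale
#' simulation and testing: two condylar elastic-foundation joint sites with
#' the articular-cartilage constants (h = 0.4 mm, E = 2.7 MPa, nu = 0.49),
#' six active Hill-type muscles per side in anatomical order (anterior/
#' middle/posterior temporalis, superficial/deep masseter, medial
#' pterygoid) with positive closing moment arms, seven cable ligaments per
#' side with the reference slack lengths (4/1.9/1.9/7.5/4/0/0 mm), and
#' bite landmarks at the first premolars and the lower incisor. The
#' condyle-top-to-menton length equals `length` exactly.
#'
#' @param length Mandible length in mm (default 117.8), in (90, 150).
#' @param muscle_strengths Optional named vector of maximum isometric
#'   forces (N) for `temporalis_anterior`, `temporalis_middle`,
#'   `temporalis_posterior`, `masseter_superficial`, `masseter_deep`,
#'   `medial_pterygoid`.
#' @param task_side Default task side of the model.
#' @param seed Unused placeholder for generator-interface uniformity (the
#'   toy mandible is fully deterministic).
#' @return A [tmj_model()].
#' @export
gen_toy_mandible <- function(length = 117.8, muscle_strengths = NULL,
                             task_side = "left", seed = NULL) {
  if (!(length > 90 && length < 150))
    stop("length must lie in (90, 150) mm")
  fmax <- c(temporalis_anterior = 160, temporalis_middle = 130,
            temporalis_posterior = 100, masseter_superficial = 270,
            masseter_deep = 120, medial_pterygoid = 200)
  if (!is.null(muscle_strengths)) fmax[names(muscle_strengths)] <- muscle_strengths
  condyle_top <- c(45, 0, 3)
  menton_z <- -40
  dy_menton <- sqrt(length^2 - condyle_top[1]^2 - (condyle_top[3] - menton_z)^2)
  menton <- c(0, dy_menton, menton_z)
  side_pts <- function(sgn) {
    list(
      temporalis_anterior = list(o = c(48, 25, 40), i = c(42, 35, 5)),
      temporalis_middle = list(o = c(50, 5, 45), i = c(42, 32, 5)),
      temporalis_posterior = list(o = c(50, -15, 35), i = c(42, 30, 5)),
      masseter_superficial = list(o = c(52, 47, 8), i = c(46, 25, -35)),
      masseter_deep = list(o = c(50, 30, 5), i = c(46, 28, -28)),
      medial_pterygoid = list(o = c(25, 35, 10), i = c(42, 25, -32))
    ) |> lapply(function(m) list(o = m$o * c(sgn, 1, 1), i = m$i * c(sgn, 1, 1)))
  }
  groups <- c(temporalis_anterior = "temporalis",
              temporalis_middle = "temporalis",
              temporalis_posterior = "temporalis",
              masseter_superficial = "masseter",
              masseter_deep = "masseter",
              medial_pterygoid = "medial_pterygoid")
  muscles <- list()
  for (side in c("left", "right")) {
    sgn <- if (side == "right") 1 else -1
    pts <- side_pts(sgn)
    for (nm in names(pts)) {
      muscles[[paste(side, nm, sep = "_")]] <- list(
        name = nm, side = side, group = unname(groups[nm]),
        origin = pts[[nm]]$o, insertion = pts[[nm]]$i,
        f_max = unname(fmax[nm]), optimal_length = NA, active = TRUE)
    }
  }
  lig_spec <- list(
    anterior = list(o = c(38, 8, 4), i = c(40, 5, -2), slack = 4),
    medial = list(o = c(38, 0, 4), i = c(40, -2, -3), slack = 1.9),
    lateral = list(o = c(52, 0, 4), i = c(50, -2, -3), slack = 1.9),
    posterior = list(o = c(44, -8, 4), i = c(44, -6, -3), slack = 7.5),
    lateral_tmj = list(o = c(52, 3, 8), i = c(50, -4, -10), slack = 4),
    sphenomandibular = list(o = c(30, 5, 15), i = c(38, 8, -20), slack = 0),
    stylomandibular = list(o = c(40, -18, 5), i = c(44, 10, -35), slack = 0)
  )
  ligaments <- list()
  for (side in c("left", "right")) {
    sgn <- if (side == "right") 1 else -1
    for (nm in names(lig_spec)) {
      l <- lig_spec[[nm]]
      ligaments[[paste(side, nm, sep = "_")]] <- list(
        name = nm, side = side, origin = l$o * c(sgn, 1, 1),
        insertion = l$i * c(sgn, 1, 1), stiffness = 250,
        slack_length = l$slack)
    }
  }
  joint_sites <- lapply(c(left = -1, right = 1), function(sgn) {
    list(side = if (sgn < 0) "left" else "right",
         condyle_center = c(sgn * 45, 0, -5),
         condyle_radius = 8,
         socket_center = c(sgn * 45, 0, -5 + 0.04),
         socket_radius = 8.05,
         ef = ef_params(), patch_half_angle = 80, n_rings = 12)
  })
  names(joint_sites) <- c("left", "right")
  bite_points <- list(premolar_left = c(-22, 70, -25),
                      premolar_right = c(22, 70, -25),
                      incisor = c(0, 92, -25))
  landmarks <- list(condyle_top_left = condyle_top * c(-1, 1, 1),
                    condyle_top_right = condyle_top,
                    menton = menton)
  tmj_model(muscles = muscles, ligaments = ligaments,
            joint_sites = joint_sites, bite_points = bite_points,
            landmarks = landmarks, mass_kg = 0.5,
            com = c(0, 35, -15), task_side = task_side)
}

#' Ramped bite-force target curve
#'
#' Smooth cosine ramp from 0 to the plateau over the first `ramp_frac` of
#' the task, then constant: the resampled unilateral-bite target used by
#' [simulate_task()].
#'
#' @param plateau_N Plateau force (N).
#' @param n Number of samples (default 250).
#' @param duration Task duration in s (default 0.25).
#' @param ramp_frac Fraction of the task spent ramping (default 0.4).
#' @return A [uniform_series()] at `n / duration` Hz.
#' @export
gen_force_curve <- function(plateau_N = 50, n = 250, duration = 0.25,
                            ramp_frac = 0.4) {
  t <- (seq_len(n) - 1) / n
  v <- ifelse(t < ramp_frac,
              plateau_N * 0.5 * (1 - cos(pi * t / ramp_frac)),
              plateau_N)
  uniform_series(v, n / duration, 0, units = "N")
}
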