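# Shared fixtures, built in code.

# simple sine-on-ramp series at 2 kHz
make_series <- function(values, fs = 2000) uniform_series(values, fs)

# two parallel square plane patches separated by `gap` (a above b)
make_plane_pair <- function(gap = 1, extent = 3, edge = 0.5) {
  a <- gen_surface("plane", list(extent = extent), edge_length = edge)
  a$vertices[, 3] <- a$vertices[, 3] + gap
  b <- gen_surface("plane", list(extent = extent * 2), edge_length = edge)
  list(a = a, b = b)
}

# single-muscle planar lever model: one vertical muscle per side at AP
# distance `m_arm` from the condyles, bite point at `b_arm`; the remaining
# five muscles per side are made negligibly weak so the model validates
make_lever_model <- function(m_arm = 35, b_arm = 70, f_max = 400) {
  model <- gen_toy_mandible()
  model$muscles <- lapply(model$muscles, function(m) {
    sgn <- if (m$side == "right") 1 else -1
    if (m$name == "masseter_superficial") {
      m$insertion <- c(sgn * 40, m_arm, -20)
      m$origin <- c(sgn * 40, m_arm, 40) # strictly vertical line
      m$f_max <- f_max
    } else {
      m$f_max <- 1e-6
    }
    m
  })
  model$bite_points <- list(premolar_left = c(-22, b_arm, -25),
                            premolar_right = c(22, b_arm, -25),
                            incisor = c(0, b_arm + 20, -25))
  model$gravity <- FALSE
  tmj_model(muscles = model$muscles, ligaments = model$ligaments,
            joint_sites = model$joint_sites, bite_points = model$bite_points,
            landmarks = model$landmarks, mass_kg = model$mass_kg,
            com = model$com, task_side = model$task_side,
            gravity = FALSE, damping = model$damping)
}

# mirror a model through the x = 0 plane and swap the task side
mirror_model <- function(model) {
  mx <- function(p) as.numeric(p) * c(-1, 1, 1)
  muscles <- lapply(model$muscles, function(m) {
    m$origin <- mx(m$origin); m$insertion <- mx(m$insertion)
    m$side <- if (m$side == "left") "right" else "left"
    m
  })
  names(muscles) <- vapply(muscles, function(m) paste(m$side, m$name, sep = "_"),
                           character(1))
  ligaments <- lapply(model$ligaments, function(l) {
    l$origin <- mx(l$origin); l$insertion <- mx(l$insertion)
    l$side <- if (l$side == "left") "right" else "left"
    l
  })
  sites <- lapply(model$joint_sites, function(s) {
    s$condyle_center <- mx(s$condyle_center)
    s$socket_center <- mx(s$socket_center)
    s$side <- if (s$side == "left") "right" else "left"
    s
  })
  names(sites) <- vapply(sites, `[[`, character(1), "side")
  sites <- sites[c("left", "right")]
  tmj_model(muscles = muscles, ligaments = ligaments, joint_sites = sites,
            bite_points = list(premolar_left = mx(model$bite_points$premolar_right),
                               premolar_right = mx(model$bite_points$premolar_left),
                               incisor = mx(model$bite_points$incisor)),
            landmarks = list(condyle_top_left = mx(model$landmarks$condyle_top_right),
                             condyle_top_right = mx(model$landmarks$condyle_top_left),
                             menton = mx(model$landmarks$menton)),
            mass_kg = model$mass_kg, com = mx(model$com),
            inertia_kgm2 = model$inertia_kgm2,
            task_side = if (model$task_side == "left") "right" else "left",
            gravity = model$gravity, damping = model$damping)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
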