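#' Planar bite constraint through three occlusal landmarks
#'
#' Fits the bite plane through the tips of the lower left and right first
#' premolars and the lower incisor, with the normal oriented superiorly
#' (toward the cranium, +z by the package's coordinate convention). The
#' constraint restricts the three mandible-fixed landmarks to this plane,
#' leaving two in-plane translations and one rotation about the normal
#' free.
#'
#' @param premolar_left,premolar_right,incisor 3-vectors in mm.
#' @return A list of class `bite_plane` with `point`, `normal` (unit),
#'   and `landmarks` (3 x 3 matrix, one row per constrained point).
#' @export
build_bite_plane <- function(premolar_left, premolar_right, incisor) {
  P <- rbind(as.numeric(premolar_left), as.numeric(premolar_right),
             as.numeric(incisor))
  if (ncol(P) != 3 || !all(is.finite(P))) stop("landmarks must be finite 3-vectors")
  n <- cross3(P[2, ] - P[1, ], P[3, ] - P[1, ])
  len <- sqrt(sum(n^2))
  if (len < 1e-9 * max(1, max(abs(P)))) stop("bite landmarks are collinear")
  n <- n / len
  # orient superiorly: prefer positive z, then y, then x
  key <- c(n[3], n[2], n[1])
  first <- which(abs(key) > 1e-12)[1]
  if (key[first] < 0) n <- -n
  structure(list(point = P[1, ], normal = n, landmarks = P),
            class = "bite_plane")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Musculoskeletal mandible model
#'
#' Rigid mandible against a fixed cranium, with Hill-type point-to-point
#' muscles, tension-only cable ligaments, per-side elastic-foundation joint
#' contact sites (sphere-in-socket approximation of disc-mediated load
#' transfer), occlusal bite landmarks, and anatomical landmarks for
#' morphometric bookkeeping. Coordinates are mm: +x lateral-right,
#' +y anterior, +z superior. Validation requires the six active muscles per
#' side (anterior/middle/posterior temporalis, superficial/deep masseter,
#' medial pterygoid) and non-collinear bite landmarks.
#'
#' @param muscles List of muscle entries: `name`, `side`, `group`
#'   (`temporalis`/`masseter`/`medial_pterygoid`), `origin` (cranium, mm),
#'   `insertion` (mandible, mm), `f_max` (N), `optimal_length` (mm, `NA`
#'   uses the reference length), `active` (logical).
#' @param ligaments List of entries: `name`, `side`, `origin`, `insertion`,
#'   `stiffness` (N per unit strain), `slack_length` (mm).
#' @param joint_sites List of two entries (`side`, `condyle_center`,
#'   `condyle_radius`, `socket_center`, `socket_radius`, `ef` an
#'   [ef_params()], `patch_half_angle` deg, `n_rings`).
#' @param bite_points List with `premolar_left`, `premolar_right`,
#'   `incisor` (mandible, mm).
#' @param landmarks List with `condyle_top_left`, `condyle_top_right`,
#'   `menton` (mandible, mm).
#' @param mass_kg Mandible (plus attached tissue) mass.
#' @param com Center of mass (mm); default centroid of the bite and condyle
#'   landmarks.
#' @param inertia_kgm2 3x3 inertia about the COM; default spherical with a
#'   40 mm gyration radius.
#' @param task_side Default bite task side.
#' @param gravity Include gravity (default `TRUE`).
#' @param damping List `translational` (N s/m) and `rotational` (N m s);
#'   quasi-static bias so the 0.25 s clench settles to near-equilibrium.
#' @return An object of class `tmj_model`.
#' @export
tmj_model <- function(muscles, ligaments, joint_sites, bite_points,
                      landmarks, mass_kg = 0.5, com = NULL,
                      inertia_kgm2 = NULL, task_side = "left",
                      gravity = TRUE,
                      damping = list(translational = 300, rotational = 1)) {
  task_side <- match.arg(task_side, c("left", "right"))
  need <- c(temporalis = 3L, masseter = 2L, medial_pterygoid = 1L)
  for (side in c("left", "right")) {
    act <- vapply(muscles, function(m) isTRUE(m$active) && m$side == side,
                  logical(1))
    grp <- vapply(muscles[act], function(m) m$group, character(1))
    cnt <- table(factor(grp, levels = names(need)))
    if (!all(cnt == need))
      stop(sprintf("side '%s' must have exactly 3 temporalis, 2 masseter and 1 medial pterygoid active muscles", side))
  }
  bp <- build_bite_plane(bite_points$premolar_left,
                         bite_points$premolar_right, bite_points$incisor)
  if (is.null(com)) {
    pts <- rbind(bp$landmarks,
                 as.numeric(landmarks$condyle_top_left),
                 as.numeric(landmarks$condyle_top_right))
    com <- colMeans(pts)
  }
  if (is.null(inertia_kgm2)) inertia_kgm2 <- diag(mass_kg * 0.04^2, 3)
  structure(list(muscles = muscles, ligaments = ligaments,
                 joint_sites = joint_sites, bite_points = bite_points,
                 landmarks = landmarks, mass_kg = mass_kg,
                 com = as.numeric(com), inertia_kgm2 = inertia_kgm2,
                 task_side = task_side, gravity = gravity,
                 damping = damping, bite_plane = bp),
            class = "tmj_model")
}

#' @export
print.tmj_model <- function(x, ...) {
  act <- sum(vapply(x$muscles, function(m) isTRUE(m$active), logical(1)))
  cat(sprintf("<tmj_model> %d muscles (%d active), %d ligaments, %d joint sites, task side %s, length %.1f mm\n",
              length(x$muscles), act, length(x$ligaments),
              length(x$joint_sites), x$task_side, mandible_length(x)))
  invisible(x)
}

#' Mandible length of a model
#'
#' Mean 3D distance from the left and right condyle tops to the menton.
#'
#' @param model A [tmj_model()].
#' @return Length in mm.
#' @export
mandible_length <- function(model) {
  lm <- model$landmarks
  m <- as.numeric(lm$menton)
  (sqrt(sum((as.numeric(lm$condyle_top_left) - m)^2)) +
      sqrt(sum((as.numeric(lm$condyle_top_right) - m)^2))) / 2
}
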