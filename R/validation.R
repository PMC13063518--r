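#' Rescale the mandible length along the anterior-posterior axis
#'
#' Moves every mandible-fixed attachment point and landmark along the anterior-posterior
#' (+y) axis in proportion to its AP distance from the condyle-top plane,
#' preserving medio-lateral and vertical coordinates, so that the resulting
#' condyle-top-to-menton length (mean 3D distance, see
#' [mandible_length()]) equals `target_length` exactly. Condyle tops and
#' joint sites (which lie in the condyle-top plane) are unchanged.
#'
#' @param model A [tmj_model()].
#' @param target_length Desired mandible length in mm (> 0).
#' @return The rescaled `tmj_model`.
#' @export
rescale_mandible <- function(model, target_length) {
  if (!inherits(model, "tmj_model")) stop("model must be a tmj_model")
  if (!is.finite(target_length) || target_length <= 0)
    stop("target_length must be positive")
  lm <- model$landmarks
  if (is.null(lm$condyle_top_left) || is.null(lm$condyle_top_right) ||
      is.null(lm$menton))
    stop("model must carry condyle-top and menton landmarks")
  y0 <- mean(c(lm$condyle_top_left[2], lm$condyle_top_right[2]))
  scale_pt <- function(p, s) { p[2] <- y0 + s * (p[2] - y0); p }
  length_at <- function(s) {
    m2 <- scale_pt(as.numeric(lm$menton), s)
    (sqrt(sum((as.numeric(lm$condyle_top_left) - m2)^2)) +
        sqrt(sum((as.numeric(lm$condyle_top_right) - m2)^2))) / 2
  }
  cur <- mandible_length(model)
  s0 <- target_length / cur
  f <- function(s) length_at(s) - target_length
  s <- if (abs(f(s0)) < 1e-12) s0 else
    stats::uniroot(f, interval = sort(c(0.25 * s0, 4 * s0)),
                   tol = 1e-12)$root
  # only mandible-fixed geometry is rescaled: the cranium (muscle and
  # ligament origins, socket centers) is untouched by a mandibular length
  # change, exactly as in surgical advancement/setback
  out <- model
  out$muscles <- lapply(model$muscles, function(m) {
    m$insertion <- scale_pt(as.numeric(m$insertion), s)
    m
  })
  out$ligaments <- lapply(model$ligaments, function(l) {
    l$insertion <- scale_pt(as.numeric(l$insertion), s)
    l
  })
  out$bite_points <- lapply(model$bite_points, function(p) scale_pt(as.numeric(p), s))
  out$landmarks <- lapply(model$landmarks, function(p) scale_pt(as.numeric(p), s))
  out$com <- scale_pt(as.numeric(model$com), s)
  out$bite_plane <- build_bite_plane(out$bite_points$premolar_left,
                                     out$bite_points$premolar_right,
                                     out$bite_points$incisor)
  out
}

#' Moment arm of the resultant muscle force
#'
#' Effective distance from the bilateral condyle-center axis to the line of
#' action of the resultant of all active muscle forces, defined
#' torque-consistently: the total muscle torque about the condylar axis
#' divided by the component of the resultant force perpendicular to that
#' axis. (Anchoring the resultant at an insertion centroid instead does not
#' preserve the summed torque and makes the arm track any anterior shift of
#' the insertions, which erases the length/moment-arm relationship this
#' quantity exists to expose.) Evaluated at a given state and activation
#' vector (by default the reference state).
#'
#' @param model A [tmj_model()] or [build_sim()] object.
#' @param activations Activation vector over the active muscles.
#' @param state Simulation state; default the reference state.
#' @return Moment arm in mm.
#' @export
resultant_moment_arm <- function(model, activations, state = NULL) {
  sim <- if (inherits(model, "tmj_sim")) model else build_sim(model)
  if (is.null(state)) state <- sim$state0
  na <- length(sim$active_idx)
  if (length(activations) != na || all(activations == 0))
    stop("need one activation per active muscle, at least one nonzero")
  p <- state$p; R <- state$R
  # condylar axis through the two joint-site condyle centers
  cl <- p + drop(R %*% sim$sites[[1]]$condyle_b)
  cr <- p + drop(R %*% sim$sites[[2]]$condyle_b)
  axis_d <- cr - cl
  axis_d <- axis_d / sqrt(sum(axis_d^2))
  Fsum <- c(0, 0, 0); tau <- 0
  ai <- 0
  for (m in sim$muscles[sim$active_idx]) {
    ai <- ai + 1
    x <- p + drop(R %*% m$insertion_b)
    vec <- m$origin_w - x
    l <- sqrt(sum(vec^2))
    fmag <- hill_static_force(activations[ai], l / MM, m$params)
    if (fmag > 0) {
      f <- fmag * vec / l
      Fsum <- Fsum + f
      tau <- tau + sum(cross3(x - cl, f) * axis_d)
    }
  }
  f_perp2 <- sum(Fsum^2) - sum(Fsum * axis_d)^2
  if (f_perp2 < 1e-24) stop("zero resultant muscle force")
  (abs(tau) / sqrt(f_perp2)) / MM
}

#' Ordinary least-squares line fit with R-squared
#'
#' @param x,y Numeric vectors of equal length (>= 3 points, `x` not all
#'   equal).
#' @return List with `slope`, `intercept`, `r_squared` (`NA` with a flag
#'   `degenerate = TRUE` when the response is constant).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 (x, y) points")
  if (max(x) - min(x) < 1e-12 * max(1, max(abs(x))))
    stop("x values are degenerate (all equal)")
  X <- cbind(1, x)
  cf <- stats::lm.fit(X, y)$coefficients
  ss_res <- sum((y - drop(X %*% cf))^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot < 1e-14 * max(1, mean(y)^2)) {
    return(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                r_squared = NA_real_, degenerate = TRUE))
  }
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       r_squared = 1 - ss_res / ss_tot, degenerate = FALSE)
}

#' Mandible-length sweep of normalized joint contact force
#'
#' The force-tracking sanity check: for each target length, rescale the
#' mandible, simulate the bite task, and record the average bilateral joint
#' contact force normalized to the bite force (mean of the left and right
#' terminal percentages / 100) against the ratio of mandible length to the
#' resultant-muscle moment arm (evaluated at the terminal activation
#' state). A least-squares line is fitted to the rows; the normalized joint
#' force is expected to vary approximately linearly with the ratio.
#'
#' @param model A [tmj_model()].
#' @param lengths Mandible lengths in mm (a warning is issued outside the
#'   physiologic 90-150 mm band).
#' @param force_curve Target curve for [simulate_task()].
#' @param ratios,weights,dt,n_substeps Passed to [simulate_task()].
#' @return A list of class `sweep_result` with `table` (data frame:
#'   `length_mm`, `moment_arm_mm`, `ratio`, `normalized_joint_force`,
#'   `failed`) and `fit` (from [linear_fit()], `NULL` when fewer than 3
#'   rows succeeded).
#' @export
run_sweep <- function(model, lengths = seq(105, 135, by = 5),
                      force_curve = gen_force_curve(50),
                      ratios = list(temporalis = 1, masseter = 1),
                      weights = tracking_weights(), dt = 1e-3,
                      n_substeps = 10) {
  if (any(lengths < 90 | lengths > 150))
    warning("sweep lengths outside the physiologic 90-150 mm band")
  if (any(diff(lengths) <= 0)) stop("lengths must be strictly increasing")
  rows <- lapply(lengths, function(L) {
    tryCatch({
      m <- rescale_mandible(model, L)
      res <- simulate_task(m, force_curve, ratios = ratios,
                           weights = weights, dt = dt,
                           n_substeps = n_substeps)
      pct <- summarize_joint_loading(res, digits = NA)
      n <- length(res$bite_force)
      arm <- resultant_moment_arm(m, res$activations[n, ],
                                  state = res$final_state)
      data.frame(length_mm = L, moment_arm_mm = arm, ratio = L / arm,
                 normalized_joint_force = (pct$left_pct + pct$right_pct) / 200,
                 failed = FALSE)
    }, error = function(e) {
      warning(sprintf("sweep length %g failed: %s", L, conditionMessage(e)))
      data.frame(length_mm = L, moment_arm_mm = NA_real_, ratio = NA_real_,
                 normalized_joint_force = NA_real_, failed = TRUE)
    })
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  fit <- if (sum(ok) >= 3) linear_fit(tab$ratio[ok],
                                      tab$normalized_joint_force[ok]) else NULL
  structure(list(table = tab, fit = fit), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d lengths (%d failed)", nrow(x$table),
              sum(x$table$failed)))
  if (!is.null(x$fit))
    cat(sprintf(": slope %.3f, intercept %.3f, R^2 %.4f",
                x$fit$slope, x$fit$intercept, x$fit$r_squared))
  cat("\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
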