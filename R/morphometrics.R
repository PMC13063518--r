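#' Round half away from zero
#'
#' Table output uses conventional half-up rounding at the printed precision
#' (base R `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Average repeated landmark selections
#'
#' Landmarks are selected several times by the observer; the centroid of the
#' repetitions is used as the landmark coordinate to minimize selection
#' error.
#'
#' @param selections Numeric matrix (one row per repetition, columns x/y/z in
#'   mm) or a list of 3-vectors.
#' @return The centroid, a 3-vector in mm.
#' @export
average_landmark <- function(selections) {
  m <- as_landmark_matrix(selections)
  if (nrow(m) < 1) stop("need at least one selection")
  colMeans(m)
}

as_landmark_matrix <- function(selections) {
  if (is.list(selections) && !is.data.frame(selections))
    selections <- do.call(rbind, lapply(selections, as.numeric))
  m <- as.matrix(selections)
  if (length(m) == 0 || nrow(m) == 0) stop("empty landmark selection set")
  if (ncol(m) != 3) stop("landmark selections must be 3D points")
  if (!all(is.finite(m))) stop("landmark selections must be finite")
  m
}

#' Mean radial error of repeated landmark selections
#'
#' Intra-observer variability statistic: the mean, over all selections in
#' all sets, of the Euclidean distance of each selection from the centroid
#' of its own set.
#'
#' @param sets A list of selection sets (each a matrix or list of 3-vectors
#'   with at least two repetitions).
#' @return Mean radial error in mm.
#' @export
mean_radial_error <- function(sets) {
  if (!is.list(sets) || length(sets) == 0) stop("sets must be a nonempty list")
  devs <- unlist(lapply(sets, function(s) {
    m <- as_landmark_matrix(s)
    if (nrow(m) < 2) stop("each set needs at least 2 selections")
    ctr <- colMeans(m)
    sqrt(rowSums(sweep(m, 2, ctr)^2))
  }))
  mean(devs)
}

#' Biting arm length
#'
#' Euclidean distance from a first-premolar tip to the condyle top on the
#' same or opposite side (ipsilateral/contralateral biting arm).
#'
#' @param premolar_tip,condyle_top 3-vectors in mm.
#' @return Distance in mm.
#' @export
biting_arm <- function(premolar_tip, condyle_top) {
  p <- as.numeric(premolar_tip); q <- as.numeric(condyle_top)
  if (length(p) != 3 || length(q) != 3 || !all(is.finite(c(p, q))))
    stop("points must be finite 3-vectors")
  sqrt(sum((p - q)^2))
}

#' Condylar area from measured axes
#'
#' The condylar area is approximated as the product of the manually measured
#' condylar major and minor axes.
#'
#' @param major_axis,minor_axis Axis lengths in mm (> 0).
#' @return Area in mm^2.
#' @export
condylar_area <- function(major_axis, minor_axis) {
  if (!is.finite(major_axis) || !is.finite(minor_axis) ||
      major_axis <= 0 || minor_axis <= 0)
    stop("axes must be positive")
  major_axis * minor_axis
}

#' Scaling stress
#'
#' The cross-case stress normalizer: unilateral bite force divided by
#' condylar area (N / mm^2 = MPa). Simulated von Mises stresses are reported
#' as ratios to this value so that subjects with different bite forces and
#' condyle sizes are comparable.
#'
#' @param bite_force Bite force in N (>= 0).
#' @param condylar_area Condylar area in mm^2 (> 0).
#' @return Scaling stress in MPa (full precision; round with
#'   [round_half_up()] for table output).
#' @export
scaling_stress <- function(bite_force, condylar_area) {
  if (any(!is.finite(condylar_area)) || any(condylar_area <= 0))
    stop("condylar area must be positive")
  if (any(!is.finite(bite_force)) || any(bite_force < 0))
    stop("bite force must be nonnegative")
  bite_force / condylar_area
}

#' Morphometric difference table
#'
#' Per-field differences of a case against a reference (the Class I
#' subject), computed at full precision.
#'
#' @param measure_case,measure_ref Named numeric vectors (or one-row data
#'   frames) with identical fields, e.g. LCA/RCA/LIBA/LCBA/RIBA/RCBA.
#' @param digits Rounding applied to the returned table (default 1 decimal,
#'   the printed precision); use `NA` for no rounding.
#' @return Named numeric vector of case minus reference.
#' @export
difference_table <- function(measure_case, measure_ref, digits = 1) {
  a <- unlist(measure_case); b <- unlist(measure_ref)
  if (!setequal(names(a), names(b)))
    stop("case and reference must have the same fields")
  d <- a - b[names(a)]
  if (!is.na(digits)) d <- round_half_up(d, digits)
  d
}
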