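#' Elastic-foundation contact parameters
#'
#' Thin compliant articular-cartilage layer modeled as a bed of independent
#' springs with logarithmic pressure-penetration law. The foundation
#' stiffness is `K = -(1 - nu) E / ((1 + nu) (1 - 2 nu))` (negative; the
#' logarithm of the remaining layer fraction is also negative, so pressure
#' is positive in compression).
#'
#' @param thickness Layer thickness h in mm (default 0.4).
#' @param elastic_modulus E in MPa (default 2.7).
#' @param poisson nu, in (0, 0.5) (default 0.49).
#' @return A list of class `ef_params` with `h`, `E`, `nu`, `K` (MPa).
#' @export
ef_params <- function(thickness = 0.4, elastic_modulus = 2.7,
                      poisson = 0.49) {
  if (!(poisson > 0 && poisson < 0.5)) stop("poisson must lie in (0, 0.5)")
  if (thickness <= 0) stop("thickness must be positive")
  if (elastic_modulus <= 0) stop("elastic modulus must be positive")
  K <- -(1 - poisson) * elastic_modulus /
    ((1 + poisson) * (1 - 2 * poisson))
  structure(list(h = thickness, E = elastic_modulus, nu = poisson, K = K),
            class = "ef_params")
}

#' Elastic-foundation contact pressure
#'
#' `p(d) = K ln(1 - d/h)`: zero at zero penetration, strictly increasing,
#' diverging as the penetration approaches the layer thickness. Negative
#' penetrations (open contact) return zero pressure; penetrations at or
#' beyond the layer thickness raise a saturation error.
#'
#' @param d Penetration in mm (vector allowed).
#' @param params An [ef_params()] object.
#' @return Contact pressure in MPa.
#' @export
ef_pressure <- function(d, params) {
  if (!inherits(params, "ef_params")) stop("params must be ef_params")
  if (any(d >= params$h))
    stop("penetration exceeds cartilage thickness (elastic foundation saturated)")
  p <- params$K * log(1 - pmax(d, 0) / params$h)
  p[d <= 0] <- 0
  p
}

check_def_gradient <- function(F, tol = 1e-6) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3, 3)) || !all(is.finite(F)))
    stop("F must be a finite 3x3 deformation gradient")
  if (abs(det(F) - 1) > tol)
    stop("deformation must be isochoric: |det F - 1| <= 1e-6 required")
  F
}

invariants_b <- function(F) {
  b <- F %*% t(F) # left Cauchy-Green
  I1 <- sum(diag(b))
  I2 <- 0.5 * (I1^2 - sum(b * b))
  c(I1 = I1, I2 = I2)
}

#' Mooney-Rivlin strain energy density (incompressible)
#'
#' `W = C1 (I1 - 3) + C2 (I2 - 3)` with I1, I2 the invariants of the left
#' Cauchy-Green tensor. Evaluated only on isochoric deformations
#' (`det F = 1` within 1e-6); no volumetric term is added. Defaults are the
#' TMJ-disc constants C1 = 0.9 MPa, C2 = 0.0009 MPa.
#'
#' @param F 3x3 deformation gradient with unit determinant.
#' @param C1,C2 Material constants in MPa.
#' @return Energy density in MPa.
#' @export
mooney_rivlin_energy <- function(F, C1 = 0.9, C2 = 0.0009) {
  if (C1 <= 0) stop("C1 must be positive")
  F <- check_def_gradient(F)
  iv <- invariants_b(F)
  C1 * (iv[["I1"]] - 3) + C2 * (iv[["I2"]] - 3)
}

#' Neo-Hookean strain energy density (incompressible)
#'
#' `W = C1 (I1 - 3)`; default is the TMJ-capsule constant C1 = 1.44 MPa.
#'
#' @param F 3x3 deformation gradient with unit determinant.
#' @param C1 Material constant in MPa.
#' @return Energy density in MPa.
#' @export
neo_hookean_energy <- function(F, C1 = 1.44) {
  if (C1 <= 0) stop("C1 must be positive")
  F <- check_def_gradient(F)
  C1 * (invariants_b(F)[["I1"]] - 3)
}

#' Closed-form incompressible uniaxial Cauchy stress (Mooney-Rivlin)
#'
#' Analytic companion to [mooney_rivlin_energy()] used to verify the energy
#' implementation by numerical differentiation:
#' `sigma = 2 (lambda^2 - 1/lambda) (C1 + C2 / lambda)`.
#'
#' @param stretch Uniaxial stretch lambda (> 0).
#' @param C1,C2 Material constants in MPa.
#' @return Cauchy stress in MPa.
#' @export
mr_uniaxial_stress <- function(stretch, C1 = 0.9, C2 = 0.0009) {
  if (any(stretch <= 0)) stop("stretch must be positive")
  2 * (stretch^2 - 1 / stretch) * (C1 + C2 / stretch)
}

#' Ligament (tension-only cable) parameters
#'
#' @param stiffness Elongation stiffness in N per unit strain (default 250).
#' @param initial_length Length at the reference configuration, mm.
#' @param slack_length Length added to the initial length before tension
#'   develops, mm.
#' @return A list of class `ligament_params`.
#' @export
ligament_params <- function(stiffness = 250, initial_length,
                            slack_length = 0) {
  if (stiffness < 0) stop("stiffness must be nonnegative")
  if (initial_length < 0 || slack_length < 0) stop("lengths must be nonnegative")
  if (stiffness > 0 && initial_length + slack_length <= 0)
    stop("rest length must be positive when stiffness is positive")
  structure(list(stiffness = stiffness, initial_length = initial_length,
                 slack_length = slack_length),
            class = "ligament_params")
}

#' Tension-only cable ligament force
#'
#' The rest length is `initial_length + slack_length`; the cable exerts
#' `stiffness * strain` newtons when stretched beyond it (strain referenced
#' to the slack-inclusive rest length) and nothing in compression.
#'
#' @param current_length Current cable length in mm (>= 0).
#' @param params A [ligament_params()] object.
#' @return Tension in N (>= 0).
#' @export
ligament_force <- function(current_length, params) {
  if (!inherits(params, "ligament_params")) stop("params must be ligament_params")
  if (any(current_length < 0)) stop("current_length must be nonnegative")
  L0 <- params$initial_length + params$slack_length
  if (params$stiffness == 0) return(rep(0, length(current_length)))
  params$stiffness * pmax(0, (current_length - L0) / L0)
}

#' Default active force-length curve
#'
#' Unimodal parabola `max(0, 1 - ((l/lopt - 1)/0.5)^2)`, equal to 1 at the
#' optimal length, vanishing at 50 % shortening/lengthening.
#' @param lnorm Normalized fiber length l/lopt.
#' @return Active scaling in \[0, 1\].
#' @export
hill_active_fl <- function(lnorm) pmax(0, 1 - ((lnorm - 1) / 0.5)^2)

#' Default passive force-length curve
#'
#' Zero up to the optimal length, quadratic beyond:
#' `k * (l/lopt - 1)^2` with k = 0.5.
#' @param lnorm Normalized fiber length l/lopt.
#' @return Passive scaling (>= 0).
#' @export
hill_passive_fl <- function(lnorm) 0.5 * pmax(0, lnorm - 1)^2

#' Hill-type point-to-point muscle parameters
#'
#' Static clenching form: the contraction-velocity factor is unity, so the
#' force is `F_max (a f_l(l/lopt) + f_p(l/lopt))`. The curve shapes default
#' to [hill_active_fl()] / [hill_passive_fl()] and are configurable because
#' subject-level Hill parameters live outside this package.
#'
#' @param max_isometric_force F_max in N (> 0).
#' @param optimal_length l_opt in mm (> 0).
#' @param active_fl,passive_fl Curve functions of normalized length.
#' @return A list of class `hill_params`.
#' @export
hill_params <- function(max_isometric_force, optimal_length,
                        active_fl = hill_active_fl,
                        passive_fl = hill_passive_fl) {
  if (max_isometric_force <= 0) stop("max_isometric_force must be positive")
  if (optimal_length <= 0) stop("optimal_length must be positive")
  structure(list(max_isometric_force = max_isometric_force,
                 optimal_length = optimal_length,
                 active_fl = active_fl, passive_fl = passive_fl),
            class = "hill_params")
}

#' Static Hill-type muscle force
#'
#' @param activation Activation in \[0, 1\].
#' @param current_length Current muscle-tendon length in mm.
#' @param params A [hill_params()] object.
#' @return Tension in N (>= 0).
#' @export
hill_static_force <- function(activation, current_length, params) {
  if (!inherits(params, "hill_params")) stop("params must be hill_params")
  if (any(activation < 0 | activation > 1))
    stop("activation must lie in [0, 1]")
  ln <- current_length / params$optimal_length
  pmax(0, params$max_isometric_force *
         (activation * params$active_fl(ln) + params$passive_fl(ln)))
}
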