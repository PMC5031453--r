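#' Hunt-Crossley contact parameters
#'
#' Compliant normal contact `R_y = E h^1.5 (1 + 1.5 b hdot)` (clamped at
#' zero) with a velocity-dependent Coulomb friction coefficient built from
#' static, dynamic and viscous terms.
#'
#' @param mu_s,mu_d,mu_v Static, dynamic and viscous friction coefficients.
#' @param v_t Transition speed (m/s) at which static friction peaks.
#' @param E Contact stiffness, N m^-1.5.
#' @param b Dissipation coefficient, s/m.
#' @return An object of class `contact_params`.
#' @export
contact_params <- function(mu_s = 0.9, mu_d = 0.9, mu_v = 0.6, v_t = 0.1,
                           E = 1e8, b = 0.5) {
  if (!(mu_s >= mu_d && mu_d >= 0)) stop("need mu_s >= mu_d >= 0")
  if (mu_v < 0 || v_t <= 0 || E <= 0 || b < 0)
    stop("invalid contact parameters")
  structure(list(mu_s = mu_s, mu_d = mu_d, mu_v = mu_v, v_t = v_t,
                 E = E, b = b),
            class = "contact_params")
}

#' Normal contact force
#'
#' @param h Penetration depth (m); non-positive values give zero force.
#' @param hdot Penetration rate (m/s, positive while penetrating deeper).
#' @param params A [contact_params()] object.
#' @return Normal force in N (vectorized over `h`, `hdot`).
#' @export
normal_force <- function(h, hdot, params = contact_params()) {
  f <- ifelse(h <= 0, 0, params$E * pmax(h, 0)^1.5 * (1 + 1.5 * params$b * hdot))
  pmax(f, 0)
}

#' Velocity-dependent friction coefficient
#'
#' Smooth Stribeck-type law: zero at rest, a peak near `mu_s` around the
#' transition speed `v_t`, decay towards `mu_d` plus a viscous term
#' `mu_v * v` at large slip speed.
#'
#' @param v_slip Slip speed magnitude (m/s, >= 0).
#' @param params A [contact_params()] object.
#' @return Dimensionless friction coefficient (vectorized).
#' @export
friction_coefficient <- function(v_slip, params = contact_params()) {
  u <- v_slip / params$v_t
  params$mu_v * v_slip + params$mu_d * tanh(4 * u) +
    (params$mu_s - params$mu_d) * (2 * u / (1 + u^2))
}

#' Tangential friction force
#'
#' Magnitude `mu(|v|) * R_y`, directed against slip.
#'
#' @param v_slip_signed Signed slip velocity (m/s).
#' @param R_y Normal force (N, >= 0).
#' @inheritParams friction_coefficient
#' @return Signed tangential force in N (vectorized).
#' @export
friction_force <- function(v_slip_signed, R_y, params = contact_params()) {
  -sign(v_slip_signed) * friction_coefficient(abs(v_slip_signed), params) * R_y
}

#' Centre of pressure
#'
#' Normal-force-weighted mean of the contact point x positions.
#'
#' @param forces A data.frame with columns `world_x` (m) and `R_y` (N).
#' @return CoP x-coordinate in m, or `NA` when the total normal force is
#'   zero (airborne; the failure monitor treats this as an event).
#' @export
cop_x <- function(forces) {
  tot <- sum(forces$R_y)
  if (tot <= 0) return(NA_real_)
  sum(forces$world_x * forces$R_y) / tot
}
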