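#' The nine muscle groups
#'
#' Gain sharing assigns one proportional/derivative gain pair per functional
#' muscle group; biarticular muscles form their own group overriding the
#' joint-based labels.
#'
#' @export
muscle_groups <- c("lumbar_extensor", "lumbar_flexor", "hip_extensor",
                   "hip_flexor", "knee_extensor", "knee_flexor",
                   "ankle_extensor", "ankle_flexor", "biarticular")

#' Muscle curve shape constants
#'
#' Shape constants for the Hill-type actuator curves: a Gaussian active
#' force-length curve, an exponential passive curve that reaches 1 at
#' `1 + pe_span` normalized length, a quadratic-toe/linear tendon curve that
#' reaches 1 at strain `eps0`, and a rational force-velocity curve with an
#' eccentric plateau.  `beta` is the fiber damping used by the
#' damped-equilibrium fiber rate law.
#'
#' @param gamma Active force-length width.
#' @param pe_k,pe_span Passive curve exponent and span.
#' @param eps0 Tendon strain at which the tendon force equals F0.
#' @param toe_frac Fraction of `eps0` covered by the quadratic toe region.
#' @param fv_kcc,fv_ke,fv_fmax Force-velocity curvature (concentric,
#'   eccentric) and eccentric plateau.
#' @param beta Normalized fiber damping.
#' @return An object of class `muscle_curves`.
#' @export
muscle_curves <- function(gamma = 0.45, pe_k = 5, pe_span = 0.7,
                          eps0 = 0.049, toe_frac = 0.5, fv_kcc = 4,
                          fv_ke = 12.5, fv_fmax = 1.4, beta = 0.1) {
  structure(list(gamma = gamma, pe_k = pe_k, pe_span = pe_span, eps0 = eps0,
                 toe_frac = toe_frac, fv_kcc = fv_kcc, fv_ke = fv_ke,
                 fv_fmax = fv_fmax, beta = beta),
            class = "muscle_curves")
}

#' Evaluate the actuator curves
#'
#' @param lhat Normalized fiber length `l_fiber / l_opt`.
#' @param vhat Normalized fiber velocity `lfdot / V_max`.
#' @param eps Tendon strain `(L_MT - l_fiber - l_ts) / l_ts`.
#' @param curves A [muscle_curves()] object.
#' @return `fl_active`, `fpe_passive`, `fv_forcevel`: dimensionless force
#'   multipliers; `ft_tendon`: tendon force as a fraction of F0.
#' @export
fl_active <- function(lhat, curves = muscle_curves())
  vapply(lhat, function(l) .muscle_curves_core(curves, l, 0, 0)$fl, 0)

#' @rdname fl_active
#' @export
fpe_passive <- function(lhat, curves = muscle_curves())
  vapply(lhat, function(l) .muscle_curves_core(curves, l, 0, 0)$fpe, 0)

#' @rdname fl_active
#' @export
ft_tendon <- function(eps, curves = muscle_curves())
  vapply(eps, function(e) .muscle_curves_core(curves, 1, 0, e)$ft, 0)

#' @rdname fl_active
#' @export
fv_forcevel <- function(vhat, curves = muscle_curves())
  vapply(vhat, function(v) .muscle_curves_core(curves, 1, v, 0)$fv, 0)

#' Muscle specification
#'
#' One Hill-type muscular-tendon actuator: contractile fiber in series with
#' a compliant tendon, routed with constant (posture-independent) moment
#' arms.  A positive moment arm means the actuator shortens when the joint
#' angle increases.
#'
#' @param name Muscle label.
#' @param group One of [muscle_groups].
#' @param F0 Maximum isometric force, N.
#' @param l_opt Optimal fiber length, m.
#' @param l_ts Tendon slack length, m.
#' @param v_max Maximum fiber shortening/lengthening speed, m/s.
#' @param moment_arms Named numeric vector (by joint name) of signed moment
#'   arms, m; magnitudes must stay below 0.2 m.
#' @param L0_MT Muscular-tendon length at the reference posture, m.
#' @param side `"left"`, `"right"` or `"midline"`.
#' @param t_act,t_dact Activation and deactivation time constants, s.
#' @param a_min Activation floor.
#' @return An object of class `muscle_spec`.
#' @export
muscle_spec <- function(name, group, F0, l_opt, l_ts, v_max, moment_arms,
                        L0_MT, side = "midline", t_act = 0.020,
                        t_dact = 0.040, a_min = 0) {
  if (!group %in% muscle_groups)
    stop("unknown muscle group '", group, "'")
  if (!side %in% c("left", "right", "midline")) stop("invalid side")
  if (F0 <= 0 || l_opt <= 0 || l_ts < 0 || v_max <= 0)
    stop("muscle constants must be positive (l_ts may be zero)")
  if (t_act <= 0 || t_dact <= 0) stop("time constants must be positive")
  if (a_min < 0 || a_min >= 1) stop("need 0 <= a_min < 1")
  if (is.null(names(moment_arms)) || !length(moment_arms))
    stop("moment_arms must be a named vector with at least one entry")
  if (all(moment_arms == 0)) stop("at least one moment arm must be nonzero")
  if (any(abs(moment_arms) >= 0.2)) stop("|moment arm| must be < 0.2 m")
  if (L0_MT <= 0) stop("L0_MT must be positive")
  structure(list(name = name, group = group, side = side, F0 = F0,
                 l_opt = l_opt, l_ts = l_ts, v_max = v_max,
                 t_act = t_act, t_dact = t_dact, a_min = a_min,
                 moment_arms = moment_arms, L0_MT = L0_MT),
            class = "muscle_spec")
}

muscle_names <- function(muscles) vapply(muscles, `[[`, "", "name")

# pack muscles for the C++ core; qref is the (radian) reference posture the
# path lengths L0_MT are quoted at
.muscles_pack <- function(muscles, plant, qref = NULL,
                          curves = muscle_curves()) {
  nm <- length(muscles)
  jn <- joint_names(plant)
  if (is.null(qref)) qref <- setNames(numeric(length(jn)), jn)
  qr <- setNames(numeric(length(jn)), jn)
  qr[names(qref)] <- qref
  if (nm == 0)
    return(list(nm = 0L, curves = unclass(curves)))
  grab <- function(f) vapply(muscles, `[[`, 0, f)
  r <- matrix(0, nm, length(jn), dimnames = list(muscle_names(muscles), jn))
  for (i in seq_len(nm)) {
    ma <- muscles[[i]]$moment_arms
    if (!all(names(ma) %in% jn))
      stop("muscle '", muscles[[i]]$name, "' references unknown joint(s): ",
           paste(setdiff(names(ma), jn), collapse = ", "))
    r[i, names(ma)] <- ma
  }
  list(nm = as.integer(nm), F0 = grab("F0"), lopt = grab("l_opt"),
       lts = grab("l_ts"), vmax = grab("v_max"), tact = grab("t_act"),
       tdact = grab("t_dact"), amin = grab("a_min"), L0 = grab("L0_MT"),
       r = r, qref = unname(qr), curves = unclass(curves))
}

#' Muscular-tendon length and velocity
#'
#' With constant moment arms the actuator length is affine in the joint
#' angles: `L_MT = L0_MT - sum_j r_j (q_j - q_ref_j)` and
#' `Ldot_MT = - sum_j r_j qdot_j`.
#'
#' @param muscle A [muscle_spec()].
#' @param q,qdot Named joint angles (rad) and velocities (rad/s).
#' @param q_ref Named reference posture (rad) at which `L0_MT` is quoted;
#'   defaults to zero.
#' @return A list with `L_MT` (m) and `Ldot_MT` (m/s).
#' @export
mt_length_velocity <- function(muscle, q, qdot = NULL, q_ref = NULL) {
  r <- muscle$moment_arms
  if (is.null(names(q)))
    stop("q must be named by joint")
  if (!all(names(r) %in% names(q)))
    stop("unknown joint(s) in moment arms: ",
         paste(setdiff(names(r), names(q)), collapse = ", "))
  if (is.null(qdot)) qdot <- setNames(numeric(length(q)), names(q))
  if (is.null(q_ref)) q_ref <- setNames(numeric(length(q)), names(q))
  qr <- setNames(numeric(length(q)), names(q))
  qr[names(q_ref)] <- q_ref
  list(L_MT = muscle$L0_MT - sum(r * (q[names(r)] - qr[names(r)])),
       Ldot_MT = -sum(r * qdot[names(r)]))
}

#' Activation dynamics delay coefficient
#'
#' Asymmetric first-order activation dynamics: the time "constant" depends
#' on the activation level and on whether excitation exceeds activation
#' (activation branch) or not (deactivation branch; equality deactivates).
#'
#' @param a Current activation in `[0, 1]`.
#' @param u_delayed Delayed excitation in `[0, 1]`.
#' @param t_act,t_dact Activation / deactivation time constants, s.
#' @return Delay coefficient in s.
#' @export
delay_coefficient <- function(a, u_delayed, t_act = 0.020, t_dact = 0.040) {
  ifelse(u_delayed > a, t_act * (0.5 + 1.5 * a), t_dact / (0.5 + 1.5 * a))
}

#' Activation rate
#'
#' `da/dt = (u(t - tau_trans) - a) / delta(a, u)`.
#'
#' @inheritParams delay_coefficient
#' @return Activation rate in 1/s.
#' @export
activation_rate <- function(a, u_delayed, t_act = 0.020, t_dact = 0.040) {
  (u_delayed - a) / delay_coefficient(a, u_delayed, t_act, t_dact)
}

#' Static fiber equilibrium
#'
#' Fiber length at which the tendon force balances the fiber force for a
#' fixed activation and muscular-tendon length (zero fiber velocity).
#'
#' @param muscle A [muscle_spec()].
#' @param a Activation.
#' @param L_MT Muscular-tendon length, m.
#' @param curves A [muscle_curves()] object.
#' @return Fiber length in m.
#' @export
fiber_equilibrium <- function(muscle, a, L_MT, curves = muscle_curves()) {
  if (L_MT < muscle$l_ts)
    stop("degenerate geometry: L_MT shorter than the tendon slack length")
  .fiber_equilibrium_core(curves, a, L_MT, muscle$l_opt, muscle$l_ts)
}

#' Advance the fiber state one step
#'
#' Damped-equilibrium fiber rate law: the normalized fiber velocity solves
#' `a fL(lhat) fV(v) + beta v = fT(eps) - fPE(lhat)`, so the fiber drifts
#' towards force balance with the tendon.  Integrated with RK4 holding the
#' muscular-tendon length and velocity over the step.
#'
#' @param state List with `a` (activation) and `l_fiber` (m).
#' @param muscle A [muscle_spec()].
#' @param L_MT,Ldot_MT Muscular-tendon length (m) and velocity (m/s).
#' @param dt Step, s.
#' @param curves A [muscle_curves()] object.
#' @return List with updated `l_fiber` (m) and `tendon_force` (N).
#' @export
fiber_dynamics_step <- function(state, muscle, L_MT, Ldot_MT, dt,
                                curves = muscle_curves()) {
  if (L_MT < muscle$l_ts)
    stop("degenerate geometry: L_MT shorter than the tendon slack length")
  a <- min(max(state$a, 0), 1)
  rate <- function(lf, Lm) {
    cv <- .muscle_curves_core(curves, lf / muscle$l_opt, 0,
                              (Lm - lf - muscle$l_ts) / muscle$l_ts)
    afl <- a * cv$fl
    rhs <- cv$ft - cv$fpe
    g <- function(v) afl * fv_forcevel(v, curves) + curves$beta * v - rhs
    # same clamped bracket as the simulation core
    v <- if (g(-1.5) >= 0) -1.5
    else if (g(3) <= 0) 3
    else uniroot(g, c(-1.5, 3), tol = 1e-12)$root
    v * muscle$v_max
  }
  lf <- state$l_fiber
  k1 <- rate(lf, L_MT)
  k2 <- rate(lf + dt / 2 * k1, L_MT + dt / 2 * Ldot_MT)
  k3 <- rate(lf + dt / 2 * k2, L_MT + dt / 2 * Ldot_MT)
  k4 <- rate(lf + dt * k3, L_MT + dt * Ldot_MT)
  lf <- lf + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  Lm <- L_MT + dt * Ldot_MT
  Fr <- muscle$F0 * ft_tendon((Lm - lf - muscle$l_ts) / muscle$l_ts, curves)
  list(l_fiber = lf, tendon_force = Fr)
}

#' Map tendon forces to joint torques
#'
#' `tau_j = sum_i r_ij F_i` with the sign convention of
#' [mt_length_velocity()] (a positive moment arm produces positive joint
#' torque).
#'
#' @param muscles List of [muscle_spec()] objects.
#' @param tendon_forces Numeric vector of forces (N, >= 0), one per muscle.
#' @param joints Character vector of joint names defining the output order.
#' @return Named numeric vector of torques, N m.
#' @export
muscle_joint_torques <- function(muscles, tendon_forces, joints) {
  stopifnot(length(muscles) == length(tendon_forces))
  tau <- setNames(numeric(length(joints)), joints)
  for (i in seq_along(muscles)) {
    r <- muscles[[i]]$moment_arms
    tau[names(r)] <- tau[names(r)] + r * tendon_forces[i]
  }
  tau
}
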