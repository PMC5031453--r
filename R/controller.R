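#' Neural delay configuration
#'
#' Pure transport delays of the control loop: `tau_fb` on the proprioceptive
#' feedback path and `tau_trans` on the descending command path.  Signals
#' are sampled at `control_step` with zero-order hold, so delays must be
#' integer multiples of the control step; the default 40 ms delays are exact
#' 40-sample shifts.
#'
#' @param tau_fb Feedback delay, s.
#' @param tau_trans Transmission delay, s.
#' @param control_step Controller sampling interval, s.
#' @return An object of class `delay_config`.
#' @export
delay_config <- function(tau_fb = 0.040, tau_trans = 0.040,
                         control_step = 0.001) {
  if (tau_fb < 0 || tau_trans < 0 || control_step <= 0)
    stop("delays must be >= 0 and control_step > 0")
  for (d in c(tau_fb, tau_trans)) {
    k <- d / control_step
    if (abs(k - round(k)) > 1e-9)
      stop("delays must be integer multiples of control_step")
  }
  structure(list(tau_fb = tau_fb, tau_trans = tau_trans,
                 control_step = control_step),
            class = "delay_config")
}

#' Nine-group PD gain set
#'
#' One dimensionless proportional/derivative pair per muscle group.
#'
#' @param kp,kd Named numeric vectors over the nine [muscle_groups]
#'   (missing groups default to 0); all gains must be >= 0.
#' @return An object of class `gain_set`: a data.frame with columns
#'   `group`, `kp`, `kd`.
#' @export
gain_set <- function(kp = NULL, kd = NULL) {
  fill <- function(v) {
    out <- setNames(numeric(9), muscle_groups)
    if (!is.null(v)) {
      if (is.null(names(v))) stop("gains must be named by group")
      if (!all(names(v) %in% muscle_groups))
        stop("unknown group(s): ",
             paste(setdiff(names(v), muscle_groups), collapse = ", "))
      out[names(v)] <- v
    }
    out
  }
  kp <- fill(kp); kd <- fill(kd)
  if (any(kp < 0) || any(kd < 0)) stop("gains must be >= 0")
  structure(data.frame(group = muscle_groups, kp = unname(kp),
                       kd = unname(kd), stringsAsFactors = FALSE),
            class = c("gain_set", "data.frame"))
}

#' Shared-gain parameterisation for the feed-forward search
#'
#' During the feed-forward activation search all extensor groups share one
#' `(P, D)` pair; flexors are scaled by 0.5 and the biarticular group by
#' 0.2, reflecting the dominance of the extensors during quiet standing.
#'
#' @param P,D Extensor proportional and derivative gains (>= 0).
#' @return A [gain_set()].
#' @export
scale_search_gains <- function(P, D) {
  if (P < 0 || D < 0) stop("P and D must be >= 0")
  ext <- grepl("_extensor$", muscle_groups)
  fl <- grepl("_flexor$", muscle_groups)
  kp <- ifelse(ext, P, ifelse(fl, 0.5 * P, 0.2 * P))
  kd <- ifelse(ext, D, ifelse(fl, 0.5 * D, 0.2 * D))
  gain_set(kp = setNames(kp, muscle_groups), kd = setNames(kd, muscle_groups))
}

#' Assign group gains to muscles
#'
#' Each muscle receives the `(kp, kd)` pair of its group.
#'
#' @param gains A [gain_set()].
#' @param muscles List of [muscle_spec()] objects.
#' @return A matrix with one row per muscle and columns `kp`, `kd`.
#' @export
assign_group_gains <- function(gains, muscles) {
  groups <- vapply(muscles, `[[`, "", "group")
  miss <- setdiff(groups, gains$group)
  if (length(miss))
    stop("no gains for group(s): ", paste(miss, collapse = ", "))
  i <- match(groups, gains$group)
  out <- cbind(kp = gains$kp[i], kd = gains$kd[i])
  rownames(out) <- muscle_names(muscles)
  out
}

#' Delayed PD feedback on muscular-tendon length and velocity
#'
#' `u_fb = kp (L_MT - L0) / L0 + kd (Ldot_MT - 0) / V_max`, with the length
#' error normalized by the objective-posture length and the velocity by the
#' maximum fiber speed, making both gains dimensionless and shareable within
#' a group.
#'
#' @param L_MT,Ldot_MT Delayed muscular-tendon length (m) and velocity (m/s).
#' @param L0 Reference length at the objective posture, m (> 0).
#' @param v_max Maximum fiber speed, m/s.
#' @param kp,kd Dimensionless gains.
#' @return Feedback control contribution (vectorized).
#' @export
feedback_control <- function(L_MT, Ldot_MT, L0, v_max, kp, kd) {
  if (any(L0 <= 0)) stop("reference length L0 must be positive")
  kp * (L_MT - L0) / L0 + kd * Ldot_MT / v_max
}

#' Total muscle excitation
#'
#' Sum of feed-forward and feedback contributions, clamped to `[0, 1]`
#' before entering the transmission delay and the activation dynamics.
#'
#' @param u_ff Feed-forward component.
#' @param u_fb Feedback component.
#' @return Clamped excitation (vectorized).
#' @export
total_control <- function(u_ff, u_fb) pmin(1, pmax(0, u_ff + u_fb))

#' Controller reference signals
#'
#' Muscular-tendon lengths at the objective posture (the feedback set
#' points), the zero reference lengthening velocity, and the per-muscle
#' maximum speeds used for normalization.
#'
#' @param muscles List of [muscle_spec()] objects.
#' @param posture Named joint angles (rad) of the objective posture.
#' @param q_ref Named reference posture at which the path `L0_MT` values are
#'   quoted (defaults to zero).
#' @return An object of class `controller_refs` with named vectors `L0_MT`,
#'   `Ldot0_MT` (all zero) and `V_max`.
#' @export
controller_refs <- function(muscles, posture, q_ref = NULL) {
  L0 <- vapply(muscles, function(m)
    mt_length_velocity(m, posture, q_ref = q_ref)$L_MT, 0)
  if (any(L0 <= 0))
    stop("non-positive reference length at the objective posture")
  nm <- muscle_names(muscles)
  structure(list(L0_MT = setNames(L0, nm),
                 Ldot0_MT = setNames(numeric(length(nm)), nm),
                 V_max = setNames(vapply(muscles, `[[`, 0, "v_max"), nm)),
            class = "controller_refs")
}

#' Neural controller
#'
#' Bundles the controller parameterization used by [simulate()]: constant
#' feed-forward activations, nine-group PD gains on delayed normalized
#' muscular-tendon length/velocity feedback, the loop delays, and the
#' objective-posture references.
#'
#' @param gains A [gain_set()].
#' @param u_ff Named numeric vector of feed-forward activations per muscle
#'   (missing muscles default to 0), values in `[0, 1]`.
#' @param delays A [delay_config()].
#' @param refs A [controller_refs()] object.
#' @return An object of class `neural_controller`.
#' @export
neural_controller <- function(gains = gain_set(), u_ff = NULL,
                              delays = delay_config(), refs) {
  if (!inherits(refs, "controller_refs")) stop("refs must be controller_refs")
  uff <- setNames(numeric(length(refs$L0_MT)), names(refs$L0_MT))
  if (!is.null(u_ff)) {
    if (is.null(names(u_ff))) stop("u_ff must be named by muscle")
    unknown <- setdiff(names(u_ff), names(uff))
    if (length(unknown))
      stop("u_ff references unknown muscle(s): ",
           paste(unknown, collapse = ", "))
    uff[names(u_ff)] <- u_ff
  }
  if (any(uff < 0 | uff > 1)) stop("u_ff values must lie in [0, 1]")
  structure(list(gains = gains, u_ff = uff, delays = delays, refs = refs),
            class = "neural_controller")
}

#' Sample-exact delay buffer
#'
#' Fixed-length FIFO at the control-step resolution.  Reading immediately
#' after a push returns the value pushed `delay` seconds (an exact number of
#' steps) earlier; the pre-history is filled with the initial value.
#'
#' @param initial Initial channel value(s) filling the pre-history.
#' @param delay Delay, s (integer multiple of `step`).
#' @param step Sampling interval, s.
#' @return An object of class `delay_buffer`.
#' @export
delay_buffer <- function(initial, delay, step) {
  k <- delay / step
  if (abs(k - round(k)) > 1e-9)
    stop("delay must be an integer multiple of the step")
  n <- as.integer(round(k)) + 1L
  e <- new.env(parent = emptyenv())
  e$data <- matrix(rep(as.numeric(initial), n), ncol = n)
  e$head <- 1L
  e$n <- n
  e$lag <- n - 1L
  class(e) <- "delay_buffer"
  e
}

#' @rdname delay_buffer
#' @param buffer A `delay_buffer`.
#' @param x Value(s) to push.
#' @export
buffer_push <- function(buffer, x) {
  buffer$head <- buffer$head %% buffer$n + 1L
  buffer$data[, buffer$head] <- x
  invisible(buffer)
}

#' @rdname delay_buffer
#' @export
buffer_read <- function(buffer) {
  i <- (buffer$head - 1L - buffer$lag) %% buffer$n + 1L
  buffer$data[, i]
}
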