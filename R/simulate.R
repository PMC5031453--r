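#' Simulation configuration
#'
#' @param duration Simulation end time, s (5 s for gain-optimization trials,
#'   60 s for validation runs).
#' @param dt Dynamics integration step, s (fixed-step RK4).
#' @param control_step Controller sampling interval, s (`dt` must divide it).
#' @param seed Integer seed recorded with the trial (the closed loop is
#'   deterministic; the seed tags result records).
#' @param com_fail_height CoM height below which the stance counts as
#'   collapsed, m.
#' @param record_stride Record every this many control steps.
#' @param monitor_failure Whether the failure monitor is active.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration, dt = 1e-4, control_step = 1e-3, seed = 1L,
                       com_fail_height = 0.4, record_stride = 10L,
                       monitor_failure = TRUE) {
  if (duration <= 0) stop("duration must be > 0")
  if (com_fail_height <= 0) stop("com_fail_height must be > 0")
  if (dt > control_step) stop("dt must not exceed control_step")
  k <- control_step / dt
  if (abs(k - round(k)) > 1e-9) stop("dt must divide control_step")
  structure(list(duration = duration, dt = dt, control_step = control_step,
                 seed = as.integer(seed), com_fail_height = com_fail_height,
                 record_stride = as.integer(record_stride),
                 monitor_failure = isTRUE(monitor_failure)),
            class = "sim_config")
}

#' Closed-loop forward simulation
#'
#' Integrates the coupled plant / muscle / contact / controller system with
#' fixed-step RK4, sampling the controller (and its delay buffers) every
#' control step, and monitoring the failure events: CoM height below the
#' threshold, or a heel or toe of either foot carrying zero normal force.
#' A numerical blow-up (non-finite state) is treated as a failure at that
#' time and flagged separately.
#'
#' @param plant A [plant_config()].
#' @param muscles List of [muscle_spec()] objects (may be empty/NULL for a
#'   passive plant).
#' @param controller A [neural_controller()], required when muscles are
#'   present.
#' @param sim A [sim_config()].
#' @param initial_state A [plant_state()].
#' @param initial_activations Named or plain numeric vector of initial
#'   activations; defaults to the controller's feed-forward activations.
#' @param q_ref Named reference posture (rad) at which muscle path lengths
#'   are quoted; defaults to zero.
#' @param curves A [muscle_curves()] object.
#' @return An object of class `stance_trial`; see Details.
#' @details The trial record holds the shared time grid `time`, joint angles
#'   `q_deg` (degrees, matrix), generalized velocities, CoM position
#'   (`com_x`, `com_y`), CoP (`cop_x`), activations and tendon forces (one
#'   column per muscle), per-point normal forces, the failure time `T_fail`
#'   and flags, and the initial coordinates `q0_deg`.
#' @export
simulate <- function(plant, muscles = NULL, controller = NULL,
                     sim = sim_config(duration = 5), initial_state,
                     initial_activations = NULL, q_ref = NULL,
                     curves = muscle_curves()) {
  if (is.null(muscles)) muscles <- list()
  nm <- length(muscles)
  pk <- .plant_pack(plant)
  jn <- joint_names(plant)
  qr <- setNames(numeric(length(jn)), jn)
  if (!is.null(q_ref)) qr[names(q_ref)] <- q_ref
  mk <- .muscles_pack(muscles, plant, qref = qr, curves = curves)
  st <- .state_gen(plant, initial_state)

  ctrl <- list(kp = numeric(0), kd = numeric(0), uff = numeric(0),
               L0 = numeric(0), vmax = numeric(0), tau_fb = 0, tau_trans = 0)
  a0 <- numeric(max(nm, 1))
  if (nm > 0) {
    if (is.null(controller))
      stop("a neural_controller is required when muscles are present")
    gm <- assign_group_gains(controller$gains, muscles)
    mn <- muscle_names(muscles)
    if (!all(mn %in% names(controller$refs$L0_MT)))
      stop("controller refs do not cover all muscles")
    ctrl <- list(kp = unname(gm[, "kp"]), kd = unname(gm[, "kd"]),
                 uff = unname(controller$u_ff[mn]),
                 L0 = unname(controller$refs$L0_MT[mn]),
                 vmax = unname(controller$refs$V_max[mn]),
                 tau_fb = controller$delays$tau_fb,
                 tau_trans = controller$delays$tau_trans)
    if (abs(controller$delays$control_step - sim$control_step) > 1e-12)
      stop("controller and simulation control steps differ")
    a0 <- rep(0, nm)
    if (is.null(initial_activations)) {
      a0 <- ctrl$uff
    } else if (!is.null(names(initial_activations))) {
      a0[match(names(initial_activations), mn)] <- initial_activations
    } else {
      if (length(initial_activations) != nm)
        stop("initial_activations length mismatch")
      a0 <- as.numeric(initial_activations)
    }
  }

  siml <- list(duration = sim$duration, dt = sim$dt,
               control_step = sim$control_step,
               record_stride = sim$record_stride,
               com_fail_height = sim$com_fail_height,
               monitor_failure = sim$monitor_failure)
  out <- .sim_core(pk, mk, ctrl, siml, list(gp = st$gp, gv = st$gv, a0 = a0))

  rec <- out$record
  ndof <- length(st$gp)
  base_free <- plant$base == "free"
  off <- if (base_free) 3L else 0L
  col <- 1L
  take <- function(n) {
    idx <- col:(col + n - 1L)
    col <<- col + n
    rec[, idx, drop = FALSE]
  }
  time <- drop(take(1))
  gp <- take(ndof)
  gv <- take(ndof)
  com <- take(2)
  cop <- drop(take(1))
  act <- if (nm) take(nm) else matrix(0, length(time), 0)
  frc <- if (nm) take(nm) else matrix(0, length(time), 0)
  ncp <- out$ncp
  ry <- if (ncp) take(ncp) else matrix(0, length(time), 0)

  qd <- rad2deg(gp[, off + seq_along(jn), drop = FALSE])
  colnames(qd) <- jn
  if (nm) colnames(act) <- colnames(frc) <- muscle_names(muscles)
  if (ncp)
    colnames(ry) <- vapply(plant$contact_points, function(cp)
      paste0(cp$name), "")
  structure(list(
    time = time, q_deg = qd,
    base = if (base_free) gp[, 1:3, drop = FALSE] else NULL,
    qdot = gv[, off + seq_along(jn), drop = FALSE],
    com_x = com[, 1], com_y = com[, 2], cop_x = cop,
    activations = act, tendon_forces = frc, contact_Ry = ry,
    T_fail = out$T_fail, failed = out$failed,
    numeric_blowup = out$numeric_blowup,
    q0_deg = qd[1, ], duration = sim$duration, seed = sim$seed,
    dt = sim$dt, control_step = sim$control_step,
    final_state = list(gp = out$final_gp, gv = out$final_gv,
                       a = out$final_a, lf = out$final_lf),
    joint_names = jn,
    muscle_names = if (nm) muscle_names(muscles) else character(0)),
    class = "stance_trial")
}

#' @export
print.stance_trial <- function(x, ...) {
  cat("<stance_trial>", format(x$duration), "s requested;",
      if (x$failed) paste0("FAILED at T_fail = ", format(x$T_fail), " s")
      else "stood the full trial", "\n")
  cat("  joints:", paste(x$joint_names, collapse = ", "), "\n")
  if (length(x$muscle_names))
    cat("  muscles:", length(x$muscle_names), "| CoM AP range:",
        format(diff(range(x$com_x))), "m\n")
  invisible(x)
}

#' Export a trial as CSV
#'
#' Writes the shared-time-grid trajectory table: time, joint angles in
#' degrees, CoM/CoP, activations, tendon forces and contact normal forces.
#'
#' @param trial A `stance_trial`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(time_s = trial$time, check.names = FALSE)
  for (j in colnames(trial$q_deg)) df[[paste0("q_", j, "_deg")]] <- trial$q_deg[, j]
  df$com_x_m <- trial$com_x
  df$com_y_m <- trial$com_y
  df$cop_x_m <- trial$cop_x
  for (m in colnames(trial$activations)) df[[paste0("a_", m)]] <- trial$activations[, m]
  for (m in colnames(trial$tendon_forces)) df[[paste0("f_", m, "_N")]] <- trial$tendon_forces[, m]
  for (p in colnames(trial$contact_Ry)) df[[paste0("Ry_", p, "_N")]] <- trial$contact_Ry[, p]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a trial result record as JSON
#'
#' @param trial A `stance_trial`.
#' @param path Output file path.
#' @param extra Optional named list merged into the record.
#' @param config Optional configuration object (plant/muscles/controller);
#'   when given, an md5 digest of its serialized form is recorded so result
#'   records can be matched to the configuration that produced them.
#' @return The path, invisibly.
#' @export
write_trial_json <- function(trial, path, extra = list(), config = NULL) {
  if (!is.null(config)) {
    tf <- tempfile()
    writeLines(deparse(config), tf)
    extra$config_digest <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  rec <- c(list(T_fail = trial$T_fail, failed = trial$failed,
                numeric_blowup = trial$numeric_blowup,
                duration = trial$duration, seed = trial$seed,
                dt = trial$dt, control_step = trial$control_step,
                q0_deg = as.list(trial$q0_deg)),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
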