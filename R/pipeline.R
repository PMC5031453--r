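trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Posture objective configuration
#'
#' @param free_coords Character vector of joint names searched over.
#' @param initial_guess_deg Named numeric vector (deg) for the free
#'   coordinates.
#' @param fixed_coords_deg Named numeric vector (deg) of coordinates held
#'   fixed (e.g. mildly flexed knees at 1 deg).
#' @param w_static Weight on the static-stability term (CoM and CoP squared
#'   distances from the base-of-support centre).
#' @param w_omega Weight on the squared static joint torques.
#' @return An object of class `posture_objective_config`.
#' @export
posture_objective_config <- function(free_coords, initial_guess_deg,
                                     fixed_coords_deg = numeric(0),
                                     w_static = 10000, w_omega = 0.1) {
  if (w_static < 0 || w_omega < 0) stop("weights must be >= 0")
  if (!all(free_coords %in% names(initial_guess_deg)))
    stop("initial_guess_deg must cover every free coordinate")
  if (length(intersect(free_coords, names(fixed_coords_deg))))
    stop("fixed coordinates cannot also be free")
  structure(list(free_coords = free_coords,
                 initial_guess_deg = initial_guess_deg,
                 fixed_coords_deg = fixed_coords_deg,
                 w_static = w_static, w_omega = w_omega),
            class = "posture_objective_config")
}

# static CoP of a supported posture; for a pinned base the weight acts
# through the CoM vertical, for a free base a short servo-held passive
# settle on the compliant contact determines it
.static_cop <- function(plant, q, settle_time = 0.2, dt = 1e-4) {
  if (plant$base == "pinned") return(com_position(plant, plant_state(q))[1])
  jn <- joint_names(plant)
  servo <- plant
  servo$joint_stiffness <- setNames(rep(3000, length(jn)), jn)
  servo$joint_damping <- setNames(rep(300, length(jn)), jn)
  servo$joint_neutral <- setNames(as.numeric(q[jn]), jn)
  tr <- simulate(servo, muscles = NULL,
                 sim = sim_config(duration = settle_time, dt = dt,
                                  monitor_failure = FALSE),
                 initial_state = plant_state(q[jn],
                                             base_position = plant$base_pose[1:2],
                                             base_orientation = plant$base_pose[3]))
  tail(tr$cop_x, 1)
}

#' Posture objective
#'
#' `J_pos = w_static [(CoM_x - BoS_x)^2 + (CoP_x - BoS_x)^2] +
#' w_omega sum_n Omega_n^2`: a statically stable posture keeps the CoM
#' projection and the initial CoP at the base-of-support centre, and the
#' torque term prefers postures that can be held with minimal effort.
#'
#' @param q_free Named numeric vector (rad) of the free coordinates.
#' @param plant A [plant_config()].
#' @param cfg A [posture_objective_config()].
#' @return Scalar objective; attributes `J_static`, `J_omega`, and the full
#'   posture (rad).
#' @export
posture_objective <- function(q_free, plant, cfg) {
  jn <- joint_names(plant)
  q <- setNames(numeric(length(jn)), jn)
  q[names(cfg$fixed_coords_deg)] <- deg2rad(cfg$fixed_coords_deg)
  q[cfg$free_coords] <- q_free[cfg$free_coords]
  st <- plant_state(q[jn], base_position = plant$base_pose[1:2],
                    base_orientation = plant$base_pose[3])
  bos <- bos_center(plant, st)
  comx <- com_position(plant, st)[1]
  copx <- tryCatch(.static_cop(plant, q), error = function(e) NA_real_)
  if (!is.finite(copx)) {
    out <- 1e8  # airborne candidate: large finite penalty
    attr(out, "airborne") <- TRUE
    return(out)
  }
  omega <- static_joint_torques(plant, st)
  Jstatic <- (comx - bos)^2 + (copx - bos)^2
  Jomega <- sum(omega^2)
  out <- cfg$w_static * Jstatic + cfg$w_omega * Jomega
  attr(out, "J_static") <- Jstatic
  attr(out, "J_omega") <- Jomega
  attr(out, "posture") <- q
  out
}

#' Optimize the objective posture
#'
#' CMA-ES over the free coordinates minimizing [posture_objective()].
#'
#' @inheritParams posture_objective
#' @param lambda,max_iter,seed CMA-ES settings.
#' @param sigma Initial step size, rad.
#' @return Named numeric vector of the full posture in degrees (reporting
#'   convention); attribute `J` carries the attained objective.
#' @export
optimize_posture <- function(plant, cfg, lambda = 8, sigma = 0.02,
                             max_iter = 60, seed = 1L) {
  x0 <- deg2rad(cfg$initial_guess_deg[cfg$free_coords])
  fn <- function(x) {
    as.numeric(posture_objective(setNames(x, cfg$free_coords), plant, cfg))
  }
  f0 <- fn(x0)
  res <- cmaes(fn, x0, sigma = sigma, lambda = lambda, max_iter = max_iter,
               seed = seed)
  best <- if (res$value <= f0) res$x else x0
  jn <- joint_names(plant)
  q <- setNames(numeric(length(jn)), jn)
  q[names(cfg$fixed_coords_deg)] <- deg2rad(cfg$fixed_coords_deg)
  q[cfg$free_coords] <- best
  out <- rad2deg(q)
  attr(out, "J") <- min(res$value, f0)
  out
}

#' Feed-forward search configuration
#'
#' @param P_grid,D_grid Grids of shared extensor proportional / derivative
#'   gains (defaults 0.0-2.0 in steps of 0.1, a 21 x 21 sweep).
#' @param trial_duration Trial length, s.
#' @param stand_criterion_height CoM height defining "still standing", m.
#' @param t1,t2 Averaging window for the activation extraction, s.
#' @return An object of class `uff_search_config`.
#' @export
uff_search_config <- function(P_grid = seq(0, 2, by = 0.1),
                              D_grid = seq(0, 2, by = 0.1),
                              trial_duration = 60,
                              stand_criterion_height = 0.4,
                              t1 = 3, t2 = 5) {
  if (!length(P_grid) || !length(D_grid)) stop("grids must be nonempty")
  if (!(t1 < t2 && t2 <= trial_duration)) stop("need t1 < t2 <= duration")
  structure(list(P_grid = P_grid, D_grid = D_grid,
                 trial_duration = trial_duration,
                 stand_criterion_height = stand_criterion_height,
                 t1 = t1, t2 = t2),
            class = "uff_search_config")
}

# bilateral symmetry class of each muscle: left/right pairs share the class
# label (the name with its side suffix removed)
.symmetry_classes <- function(muscles) {
  vapply(muscles, function(m) {
    if (m$side == "midline") m$name else sub("_(l|r)$", "", m$name)
  }, "")
}

#' Extract feed-forward activations from a standing trial
#'
#' Time-average (trapezoidal) of each muscle activation over the stable
#' window `[t1, t2]`, symmetrized by averaging left/right pairs.
#'
#' @param trial A `stance_trial` that stood through `t2`.
#' @param t1,t2 Averaging window, s.
#' @param muscles Optional list of [muscle_spec()] objects enabling the
#'   bilateral symmetrization; without it activations are returned as-is.
#' @return Named numeric vector of feed-forward activations.
#' @export
extract_uff <- function(trial, t1, t2, muscles = NULL) {
  if (t2 > max(trial$time) + 1e-9)
    stop("trial ends before t2; cannot extract feed-forward activations")
  sel <- trial$time >= t1 - 1e-12 & trial$time <= t2 + 1e-12
  tt <- trial$time[sel]
  span <- tt[length(tt)] - tt[1]
  cmean <- apply(trial$activations[sel, , drop = FALSE], 2,
                 function(a) trapz(tt, a) / span)
  if (!is.null(muscles)) {
    cls <- .symmetry_classes(muscles)
    for (cl in unique(cls)) {
      i <- which(cls == cl)
      cmean[i] <- mean(cmean[i])
    }
  }
  cmean
}

#' Euclidean norm of a feed-forward activation vector
#'
#' Quantifies the active stiffness level of the stance.
#'
#' @param c_ff Numeric vector of feed-forward activations (all muscles,
#'   both sides).
#' @return `sqrt(sum(c_ff^2))`.
#' @export
uff_norm <- function(c_ff) sqrt(sum(c_ff^2))

#' Grid search for feed-forward activation candidates
#'
#' For every `(P, D)` on the grid, builds the shared gain set
#' ([scale_search_gains()]), runs a zero-delay stance trial from the
#' objective posture with zero initial activations (activation dynamics
#' retained), and, if the model stands the full trial, extracts the
#' time-averaged activations as a feed-forward candidate.
#'
#' @param plant A [plant_config()].
#' @param muscles List of [muscle_spec()] objects.
#' @param posture Named objective posture (rad).
#' @param cfg A [uff_search_config()].
#' @param dt Dynamics step, s.
#' @param control_step Controller step, s.
#' @param record_stride Recording stride (control steps).
#' @param verbose Print progress.
#' @return A list with `candidates` (data.frame: `P`, `D`, `stood`,
#'   `uff_norm`, `sway` (integrated absolute joint excursion, rad s)),
#'   `uff` (list of candidate activation vectors, indexed like the standing
#'   rows), and `final_q` (list of end-of-trial postures, rad).
#' @export
run_uff_grid_search <- function(plant, muscles, posture,
                                cfg = uff_search_config(), dt = 1e-4,
                                control_step = 1e-3, record_stride = 10L,
                                verbose = FALSE) {
  refs <- controller_refs(muscles, posture)
  delays0 <- delay_config(0, 0, control_step)
  grid <- expand.grid(P = cfg$P_grid, D = cfg$D_grid)
  n <- nrow(grid)
  stood <- logical(n); norms <- rep(NA_real_, n); sway <- rep(NA_real_, n)
  uffs <- vector("list", n); finals <- vector("list", n)
  jn <- joint_names(plant)
  for (i in seq_len(n)) {
    gains <- scale_search_gains(grid$P[i], grid$D[i])
    ctrl <- neural_controller(gains, u_ff = NULL, delays = delays0,
                              refs = refs)
    tr <- tryCatch(
      simulate(plant, muscles, ctrl,
               sim = sim_config(duration = cfg$trial_duration, dt = dt,
                                control_step = control_step,
                                com_fail_height = cfg$stand_criterion_height,
                                record_stride = record_stride),
               initial_state = plant_state(posture[jn],
                                           base_position = plant$base_pose[1:2],
                                           base_orientation = plant$base_pose[3]),
               initial_activations = rep(0, length(muscles))),
      error = function(e) NULL)
    if (!is.null(tr) && !tr$failed) {
      stood[i] <- TRUE
      uffs[[i]] <- extract_uff(tr, cfg$t1, cfg$t2, muscles)
      norms[i] <- uff_norm(uffs[[i]])
      qrad <- deg2rad(tr$q_deg)
      sway[i] <- sum(vapply(seq_along(jn), function(j)
        trapz(tr$time, abs(qrad[, j] - qrad[1, j])), 0))
      finals[[i]] <- setNames(deg2rad(tr$q_deg[nrow(tr$q_deg), ]), jn)
    }
    if (verbose && i %% 25 == 0)
      message(sprintf("grid %d/%d: %d standing so far", i, n, sum(stood)))
  }
  list(candidates = data.frame(P = grid$P, D = grid$D, stood = stood,
                               uff_norm = norms, sway = sway),
       uff = uffs, final_q = finals)
}

#' Select feed-forward candidates by active stiffness level
#'
#' Picks, for each requested norm, the standing candidate whose
#' `||u_ff||` is nearest; ties resolved by the smaller integrated joint
#' excursion of the search trial.
#'
#' @param search Result of [run_uff_grid_search()].
#' @param norms Numeric vector of requested `||u_ff||` values.
#' @return Integer vector of row indices into `search$candidates`.
#' @export
select_uff <- function(search, norms) {
  cand <- search$candidates
  ok <- which(cand$stood)
  if (!length(ok)) stop("no standing candidates to select from")
  vapply(norms, function(nv) {
    d <- abs(cand$uff_norm[ok] - nv)
    near <- ok[d <= min(d) + 1e-12]
    near[which.min(cand$sway[near])]
  }, 0L)
}

#' Gain optimization configuration
#'
#' @param lambda CMA-ES population size.
#' @param sigma CMA-ES initial standard deviation (gain units).
#' @param max_iter Maximum CMA-ES iterations.
#' @param w_fail,w_stability Objective weights.
#' @param term_floor Terms whose square falls below this are zeroed.
#' @param T_simu Trial length for objective evaluations, s.
#' @param seed Integer seed.
#' @param floor_on_squares Apply the floor rule to the squared terms (the
#'   alternative reading applies it to the raw values).
#' @return An object of class `gain_opt_config`.
#' @export
gain_opt_config <- function(lambda = 20, sigma = 0.005, max_iter = 750,
                            w_fail = 500000, w_stability = 50,
                            term_floor = 1e-6, T_simu = 5, seed = 1L,
                            floor_on_squares = TRUE) {
  if (lambda < 2) stop("lambda must be >= 2")
  if (sigma <= 0) stop("sigma must be > 0")
  if (w_fail < 0 || w_stability < 0) stop("weights must be >= 0")
  structure(list(lambda = as.integer(lambda), sigma = sigma,
                 max_iter = as.integer(max_iter), w_fail = w_fail,
                 w_stability = w_stability, term_floor = term_floor,
                 T_simu = T_simu, seed = as.integer(seed),
                 floor_on_squares = isTRUE(floor_on_squares)),
            class = "gain_opt_config")
}

#' Gain optimization objective
#'
#' `J = w_fail J_fail + w_stability J_stability` with
#' `J_fail = (T_simu - T_fail) / T_fail` (zero when the trial never fails)
#' and `J_stability = sum_n int |q_n(t) - q_n(0)| dt` (trapezoidal, rad s).
#' Terms whose square falls below `term_floor` are zeroed.  A failure at
#' `T_fail = 0` receives a large finite surrogate (1e6).
#'
#' @param trial A `stance_trial` from a full-delay trial.
#' @param cfg A [gain_opt_config()].
#' @return A list with `J`, `J_fail`, `J_stability` (rad s) and
#'   `J_stability_deg` (deg s, reporting convenience).
#' @export
gain_objective <- function(trial, cfg = gain_opt_config()) {
  T_simu <- cfg$T_simu
  J_fail <- if (!trial$failed) 0
  else if (trial$T_fail <= 0) 1e6
  else (T_simu - trial$T_fail) / trial$T_fail
  qrad <- deg2rad(trial$q_deg)
  J_stab <- sum(vapply(seq_len(ncol(qrad)), function(j)
    trapz(trial$time, abs(qrad[, j] - qrad[1, j])), 0))
  floor_it <- function(x) {
    v <- if (cfg$floor_on_squares) x^2 else x
    if (v < cfg$term_floor) 0 else x
  }
  J_fail <- floor_it(J_fail)
  J_stab <- floor_it(J_stab)
  list(J = cfg$w_fail * J_fail + cfg$w_stability * J_stab,
       J_fail = J_fail, J_stability = J_stab,
       J_stability_deg = rad2deg(J_stab))
}

# gain_set <-> 18-vector (kp over the nine groups, then kd)
.gains_to_vec <- function(g) c(g$kp, g$kd)
.vec_to_gains <- function(x) {
  x <- pmax(x, 0)
  gain_set(kp = setNames(x[1:9], muscle_groups),
           kd = setNames(x[10:18], muscle_groups))
}

#' Optimize the nine-group PD gains under the full loop delay
#'
#' CMA-ES over the 18 gain variables, minimizing [gain_objective()] on
#' short trials simulated with the full feedback and transmission delays,
#' starting from the stable posture held by the selected feed-forward
#' activations (initial activations equal to `u_ff`).  Gains are kept
#' nonnegative by clipping.
#'
#' @param plant A [plant_config()].
#' @param muscles List of [muscle_spec()] objects.
#' @param u_ff Named feed-forward activation vector.
#' @param posture Named stable posture (rad) maintained by `u_ff`; also the
#'   feedback reference posture.
#' @param cfg A [gain_opt_config()].
#' @param delays A [delay_config()] (full 40 ms + 40 ms by default).
#' @param init_gains Optional [gain_set()] starting point (e.g. the
#'   `(P, D)`-derived set of the source candidate); without it the start is
#'   drawn uniformly from `[0, 0.3]` per gain.
#' @param sigma Optional CMA-ES step size overriding `cfg$sigma`.
#' @param dt Dynamics step, s.
#' @param record_stride Recording stride.
#' @param stop_fitness Optional early-stop objective value.
#' @return A list with `gains` (best [gain_set()]), `J`, the objective
#'   breakdown `objective`, and `trace` (best-so-far J per iteration,
#'   nonincreasing).
#' @export
optimize_gains <- function(plant, muscles, u_ff, posture,
                           cfg = gain_opt_config(),
                           delays = delay_config(), init_gains = NULL,
                           sigma = NULL, dt = 1e-4, record_stride = 10L,
                           stop_fitness = NULL) {
  refs <- controller_refs(muscles, posture)
  jn <- joint_names(plant)
  mn <- muscle_names(muscles)
  uffv <- setNames(numeric(length(mn)), mn)
  uffv[names(u_ff)] <- u_ff
  evaluate <- function(x) {
    gains <- .vec_to_gains(x)
    ctrl <- neural_controller(gains, u_ff = uffv, delays = delays,
                              refs = refs)
    tr <- tryCatch(
      simulate(plant, muscles, ctrl,
               sim = sim_config(duration = cfg$T_simu, dt = dt,
                                control_step = delays$control_step,
                                record_stride = record_stride),
               initial_state = plant_state(posture[jn],
                                           base_position = plant$base_pose[1:2],
                                           base_orientation = plant$base_pose[3]),
               initial_activations = uffv),
      error = function(e) NULL)
    if (is.null(tr)) return(cfg$w_fail * 1e6)
    gain_objective(tr, cfg)$J
  }
  if (is.null(init_gains)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(cfg$seed)
    x0 <- runif(18, 0, 0.3)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  } else {
    x0 <- .gains_to_vec(init_gains)
  }
  res <- cmaes(evaluate, x0, sigma = if (is.null(sigma)) cfg$sigma else sigma,
               lambda = cfg$lambda, max_iter = cfg$max_iter,
               seed = cfg$seed, lower = 0, stop_fitness = stop_fitness)
  best <- .vec_to_gains(res$x)
  list(gains = best, J = res$value, trace = res$trace,
       iterations = res$iterations, seed = cfg$seed)
}

#' End-to-end controller design on a fixture
#'
#' Runs the full two-stage variable design: objective-posture optimization,
#' the `(P, D)` grid search harvesting feed-forward candidates, selection by
#' requested active stiffness norm, gain optimization under the full loop
#' delay, and a closing validation run.
#'
#' @param fixture A fixture list (`plant`, `muscles`, `posture_cfg`), e.g.
#'   from [make_single_link_ankle()].
#' @param norms Requested `||u_ff||` values for candidate selection.
#' @param uff_cfg A [uff_search_config()].
#' @param gain_cfg A [gain_opt_config()].
#' @param delays A [delay_config()] for the gain stage.
#' @param dt Dynamics step for all trials, s.
#' @param sigma CMA-ES step size for the gain stage (gain units).
#' @param validate_duration Length of the closing validation run, s.
#' @param posture_seed Seed for the posture optimization.
#' @param posture_deg,search Optional precomputed stage results (the posture
#'   optimization and grid search are deterministic, so repeated runs with
#'   different gain-stage seeds can share them).
#' @param verbose Print stage progress.
#' @return A list of class `design_result`: objective posture (deg), the
#'   candidate census, selected candidate index, optimized gains with the
#'   objective trace, and the validation trial.
#' @export
run_design_pipeline <- function(fixture, norms = NULL,
                                uff_cfg = uff_search_config(),
                                gain_cfg = gain_opt_config(),
                                delays = delay_config(), dt = 1e-4,
                                sigma = NULL, validate_duration = 60,
                                posture_seed = 1L, posture_deg = NULL,
                                search = NULL, verbose = FALSE) {
  plant <- fixture$plant
  muscles <- fixture$muscles
  if (is.null(posture_deg))
    posture_deg <- optimize_posture(plant, fixture$posture_cfg,
                                    seed = posture_seed)
  posture <- deg2rad(posture_deg)
  if (verbose) message("objective posture (deg): ",
                       paste(sprintf("%s=%.2f", names(posture_deg),
                                     posture_deg), collapse = ", "))
  if (is.null(search))
    search <- run_uff_grid_search(plant, muscles, posture, uff_cfg, dt = dt,
                                  verbose = verbose)
  stood <- which(search$candidates$stood)
  if (!length(stood)) stop("grid search found no standing candidate")
  if (is.null(norms))
    norms <- stats::median(search$candidates$uff_norm[stood])
  sel <- select_uff(search, norms)[1]
  uff <- search$uff[[sel]]
  stable_posture <- search$final_q[[sel]]
  init_gains <- scale_search_gains(search$candidates$P[sel],
                                   search$candidates$D[sel])
  if (verbose) message(sprintf("selected (P=%.1f, D=%.1f), ||u_ff|| = %.4f",
                               search$candidates$P[sel],
                               search$candidates$D[sel],
                               search$candidates$uff_norm[sel]))
  opt <- optimize_gains(plant, muscles, uff, stable_posture, cfg = gain_cfg,
                        delays = delays, init_gains = init_gains,
                        sigma = sigma, dt = dt, stop_fitness = 1)
  refs <- controller_refs(muscles, stable_posture)
  ctrl <- neural_controller(opt$gains, u_ff = uff, delays = delays,
                            refs = refs)
  jn <- joint_names(plant)
  validation <- simulate(plant, muscles, ctrl,
                         sim = sim_config(duration = validate_duration,
                                          dt = dt,
                                          control_step = delays$control_step),
                         initial_state = plant_state(stable_posture[jn],
                                                     base_position = plant$base_pose[1:2],
                                                     base_orientation = plant$base_pose[3]),
                         initial_activations = setNames(
                           uff[muscle_names(muscles)],
                           muscle_names(muscles)))
  structure(list(posture_deg = posture_deg, search = search,
                 selected = sel, u_ff = uff, gains = opt$gains,
                 gain_trace = opt$trace, J = opt$J,
                 validation = validation,
                 stood_60s = !validation$failed),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result>\n  objective posture (deg):",
      paste(sprintf("%s=%.2f", names(x$posture_deg), x$posture_deg),
            collapse = ", "), "\n")
  cat(sprintf("  candidates standing: %d / %d\n",
              sum(x$search$candidates$stood), nrow(x$search$candidates)))
  cat(sprintf("  selected ||u_ff|| = %.4f; optimized J = %.4g\n",
              x$search$candidates$uff_norm[x$selected], x$J))
  cat(sprintf("  validation: %s\n",
              if (x$stood_60s) "stood the full run" else
                sprintf("failed at %.2f s", x$validation$T_fail)))
  invisible(x)
}
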