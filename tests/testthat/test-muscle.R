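mus <- muscle_spec("m", "ankle_extensor", F0 = 1000, l_opt = 0.1,
                   l_ts = 0.2, v_max = 1, moment_arms = c(j = 0.05),
                   L0_MT = 0.3)

test_that("muscular-tendon length/velocity map is affine in the angles", {
  out <- mt_length_velocity(mus, q = c(j = 0), qdot = c(j = 0))
  expect_equal(out$L_MT, 0.3, tolerance = 1e-15)
  expect_equal(out$Ldot_MT, 0)
  out <- mt_length_velocity(mus, q = c(j = 0.1))
  expect_equal(out$L_MT - 0.3, -0.005, tolerance = 1e-15)
  out <- mt_length_velocity(mus, q = c(j = 0.1), qdot = c(j = 2))
  expect_equal(out$Ldot_MT, -0.1, tolerance = 1e-15)
})

test_that("delay coefficient follows the asymmetric branches", {
  expect_equal(delay_coefficient(0, 1, 0.020, 0.040), 0.010)
  expect_equal(delay_coefficient(1, 0, 0.020, 0.040), 0.020)
  # equality uses the deactivation branch
  expect_equal(delay_coefficient(0.5, 0.5, 0.020, 0.040), 0.040 / 1.25)
})

test_that("activation rate matches hand substitution into the rate law", {
  expect_equal(activation_rate(0.3, 0.3), 0)
  expect_equal(activation_rate(0, 1, 0.020, 0.040), 100)
  expect_equal(activation_rate(0.5, 0.2, 0.020, 0.040), -0.3 / 0.032)
})

test_that("activation ODE: coarse RK4 matches a fine-step reference", {
  rk4 <- function(a0, u, dt, Tend) {
    a <- a0
    for (i in seq_len(round(Tend / dt))) {
      k1 <- activation_rate(a, u)
      k2 <- activation_rate(a + dt / 2 * k1, u)
      k3 <- activation_rate(a + dt / 2 * k2, u)
      k4 <- activation_rate(a + dt * k3, u)
      a <- min(1, max(0, a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)))
    }
    a
  }
  for (case in list(c(0, 1), c(1, 0), c(0.2, 0.7), c(0.9, 0.1))) {
    coarse <- rk4(case[1], case[2], 1e-3, 0.2)
    fine <- rk4(case[1], case[2], 1e-5, 0.2)
    expect_lt(abs(coarse - fine), 1e-4)
  }
})

test_that("activation rises faster than it decays (t_act < t_dact)", {
  step_time <- function(a0, u, target, up) {
    a <- a0; dt <- 1e-4; t <- 0
    while (if (up) a < target else a > target) {
      a <- a + dt * activation_rate(a, u)
      t <- t + dt
      if (t > 5) break
    }
    t
  }
  rise <- step_time(0, 1, 0.95, TRUE)
  decay <- step_time(1, 0, 0.05, FALSE)
  expect_lt(rise, decay)
  # monotone approach under constant excitation, staying in [0, 1]
  a <- 0.1; u <- 0.8; prev <- a
  for (i in 1:5000) {
    a <- a + 1e-4 * activation_rate(a, u)
    expect_true(a >= prev - 1e-15)
    prev <- a
  }
  expect_true(a <= u + 1e-6)
})

test_that("curve normalization: full activation at optimal length gives F0", {
  cv <- muscle_curves()
  expect_equal(fl_active(1, cv), 1)
  expect_equal(fv_forcevel(0, cv), 1)
  expect_equal(ft_tendon(cv$eps0, cv), 1)
  expect_equal(fpe_passive(1, cv), 0)
  expect_equal(fpe_passive(1 + cv$pe_span, cv), 1, tolerance = 1e-12)
})

test_that("tendon force is nonnegative and monotone in strain", {
  eps <- seq(-0.02, 0.12, by = 1e-3)
  ft <- ft_tendon(eps)
  expect_true(all(ft >= 0))
  expect_true(all(diff(ft) >= 0))
})

test_that("fiber settles to the static equilibrium at constant inputs", {
  for (a in c(0.05, 0.4, 0.9)) {
    L <- 0.305
    lf <- fiber_equilibrium(mus, a, L)
    # start away from equilibrium and settle with the rate law
    st <- list(a = a, l_fiber = 0.9 * lf)
    for (i in 1:4000) st <- c(st["a"],
                              fiber_dynamics_step(st, mus, L, 0, 1e-3))
    eps <- (L - st$l_fiber - mus$l_ts) / mus$l_ts
    fib <- a * fl_active(st$l_fiber / mus$l_opt) +
      fpe_passive(st$l_fiber / mus$l_opt)
    resid <- abs(ft_tendon(eps) - fib)
    expect_lt(resid, 1e-3)
    expect_equal(st$l_fiber, lf, tolerance = 1e-3)
  }
})

test_that("slack muscle at floor activation produces negligible force", {
  # short MT length: fiber below slack, tendon unstrained
  st <- list(a = 0, l_fiber = 0.07)
  out <- fiber_dynamics_step(st, mus, 0.27, 0, 1e-3)
  for (i in 1:500) out <- fiber_dynamics_step(list(a = 0, l_fiber = out$l_fiber),
                                              mus, 0.27, 0, 1e-3)
  expect_lt(out$tendon_force, 1e-6 * mus$F0)
})

test_that("joint torques are moment arm times force with sign symmetry", {
  ext <- muscle_spec("ext", "ankle_extensor", 1000, 0.1, 0.2, 1,
                     c(j = 0.05), 0.3)
  flx <- muscle_spec("flx", "ankle_flexor", 1000, 0.1, 0.2, 1,
                     c(j = -0.05), 0.3)
  expect_equal(unname(muscle_joint_torques(list(ext, flx), c(0, 0), "j")), 0)
  expect_equal(unname(muscle_joint_torques(list(ext), 100, "j")), 5)
  expect_equal(unname(muscle_joint_torques(list(ext, flx), c(200, 200), "j")),
               0, tolerance = 1e-12)
})

test_that("muscle validation enforces the physical ranges", {
  expect_error(muscle_spec("m", "not_a_group", 1, 0.1, 0.2, 1,
                           c(j = 0.05), 0.3), "group")
  expect_error(muscle_spec("m", "ankle_extensor", 1, 0.1, 0.2, 1,
                           c(j = 0.25), 0.3), "moment arm")
  expect_error(muscle_spec("m", "ankle_extensor", 1, 0.1, 0.2, 1,
                           c(j = 0), 0.3), "nonzero")
})
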