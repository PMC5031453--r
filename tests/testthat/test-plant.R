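test_that("force-free zero-gravity system has zero accelerations", {
  pl <- pendulum_plant(gravity = 0)
  fd <- forward_dynamics(pl, plant_state(q = 0.3))
  expect_equal(unname(fd$qddot), 0, tolerance = 1e-12)
})

test_that("pinned link matches the closed-form inverted pendulum", {
  pl <- pendulum_plant(mass = 1, d = 0.5, I = 0.05)
  th <- 0.1
  fd <- forward_dynamics(pl, plant_state(q = th))
  expect_equal(abs(unname(fd$qddot)),
               1 * 9.81 * 0.5 * sin(th) / (0.05 + 1 * 0.5^2),
               tolerance = 1e-12)
  expect_equal(abs(unname(fd$qddot)), 1.6323, tolerance = 1e-4)
})

test_that("forward dynamics agrees with the Lagrangian oracle on random chains", {
  set.seed(7)
  for (rep in 1:30) {
    nl <- sample(1:3, 1)
    free <- sample(c(TRUE, FALSE), 1)
    pl <- mk_random_chain(nl, free)
    rs <- random_chain_state(pl)
    tau <- runif(nl, -5, 5)
    fd <- forward_dynamics(pl, rs$state, joint_torques = tau)
    got <- if (free) c(fd$base_acceleration, fd$base_angular_acceleration,
                       fd$qddot) else fd$qddot
    taug <- if (free) c(0, 0, 0, tau) else tau
    want <- oracle_fd(pl, rs$gp, rs$gv, taug)
    expect_lt(max(abs(got - want)) / max(abs(want), 1e-9), 1e-6)
  }
})

test_that("external point forces enter through the point Jacobian", {
  set.seed(11)
  pl <- mk_random_chain(2, TRUE)
  rs <- random_chain_state(pl)
  # a pure vertical force equal to total weight applied at the CoM of a
  # segment changes that segment's dynamics exactly like reduced gravity
  f <- list(segment = "s2", point = pl$segments[[3]]$com_offset,
            force = c(0.4, -1.3))
  fd1 <- forward_dynamics(pl, rs$state, external_forces = list(f))
  got <- c(fd1$base_acceleration, fd1$base_angular_acceleration, fd1$qddot)
  # oracle: generalized force from numeric point Jacobian
  taug <- numeric(length(rs$gp))
  h <- 1e-100
  for (k in seq_along(rs$gp)) {
    e <- numeric(length(rs$gp)); e[k] <- 1
    fk <- oracle_fk(pl, rs$gp + (1i * h) * e)
    seg <- Filter(function(s) s$name == "s2", fk)[[1]]
    J <- Im(seg$com) / h
    taug[k] <- sum(J * f$force)
  }
  want <- oracle_fd(pl, rs$gp, rs$gv, taug)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
})

test_that("whole-body CoM is the mass-weighted segment mean", {
  segs <- list(segment_spec("a", 2, c(0, 1), 0.1),
               segment_spec("b", 2, c(0, 1), 0.1, parent_joint = "j"))
  jts <- list(joint_spec("j", "a", "b", c(0, 0), c(0, -1)))
  pl <- plant_config(segs, jts, base = "free")
  # with q = 0 the two CoMs sit at (0,1) and (0,2)
  st <- plant_state(q = 0)
  expect_equal(com_position(pl, st), c(0, 1.5), tolerance = 1e-12)
  # translation equivariance: shifting the base shifts the CoM exactly
  st2 <- plant_state(q = 0, base_position = c(0.37, -0.21))
  expect_equal(com_position(pl, st2), c(0.37, -0.21) + c(0, 1.5),
               tolerance = 1e-12)
})

test_that("base-of-support centre is the contact span midpoint", {
  fx <- make_single_link_ankle()
  st <- plant_state(q = 0)
  expect_equal(bos_center(fx$plant, st), ((-0.05) + 0.15) / 2,
               tolerance = 1e-12)
  pl <- pendulum_plant()
  expect_error(bos_center(pl, plant_state(q = 0)), "contact")
})

test_that("static joint torques match the closed form and the dV/dq oracle", {
  pl <- pendulum_plant(mass = 1, d = 0.5, I = 0.05)
  expect_equal(unname(static_joint_torques(pl, plant_state(q = 0))), 0,
               tolerance = 1e-12)
  th <- 0.1
  om <- static_joint_torques(pl, plant_state(q = th))
  expect_equal(abs(unname(om)), 1 * 9.81 * 0.5 * sin(th), tolerance = 1e-12)
  expect_equal(abs(unname(om)), 0.4897, tolerance = 1e-4)
  # three-link fixture: torques equal dV/dq (potential-energy oracle)
  fx <- make_three_link_sagittal()
  q <- c(ankle = -0.05, knee = 0.03, hip = -0.08)
  om3 <- static_joint_torques(fx$plant, plant_state(q))
  h <- 1e-100
  dV <- vapply(seq_along(q), function(k) {
    e <- numeric(length(q)); e[k] <- 1
    fk <- oracle_fk(fx$plant, q + (1i * h) * e)
    Im(sum(vapply(fk, function(s)
      if (s$dynamic) s$mass * 9.81 * s$com[2] else 0 + 0i, 0 + 0i))) / h
  }, 0)
  expect_equal(unname(om3), dV, tolerance = 1e-8)
})

test_that("mechanical energy: datum, mass linearity and conservation", {
  pl <- pendulum_plant(mass = 1, d = 0.5, I = 0.05)
  # at rest with the CoM at the datum height the energy is zero
  segs <- list(segment_spec("g", 1, c(0, 0), 1),
               segment_spec("link", 1, c(0.5, 0), 0.05, parent_joint = "j"))
  jts <- list(joint_spec("j", "g", "link", c(0, 0), c(0, 0)))
  pl0 <- plant_config(segs, jts, base = "pinned", contact_mode = "none")
  expect_equal(mechanical_energy(pl0, plant_state(q = 0)), 0,
               tolerance = 1e-12)
  # doubling the masses doubles the energy at a fixed state
  st <- plant_state(q = 0.4, qdot = 1.2)
  pl2 <- pendulum_plant(mass = 2, d = 0.5, I = 0.10)
  expect_equal(mechanical_energy(pl2, st), 2 * mechanical_energy(pl, st),
               tolerance = 1e-12)
  # conservation along a passive swing
  tr <- simulate(pl, sim = sim_config(duration = 5, dt = 1e-4,
                                      monitor_failure = FALSE),
                 initial_state = plant_state(q = 0.5))
  E <- vapply(seq_along(tr$time), function(i)
    mechanical_energy(pl, plant_state(q = deg2rad_t(tr$q_deg[i, 1]),
                                      qdot = tr$qdot[i, 1])), 0)
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-6)
})

test_that("plant validation rejects broken configurations", {
  expect_error(segment_spec("x", mass = -1, c(0, 0), 1), "mass")
  expect_error(segment_spec("x", mass = 1, c(0, 0), inertia = 0), "inertia")
  segs <- list(segment_spec("a", 1, c(0, 0), 1),
               segment_spec("b", 1, c(0, 0), 1, parent_joint = "j"))
  jts <- list(joint_spec("j", "a", "zzz", c(0, 0), c(0, 0)))
  expect_error(plant_config(segs, jts), "segment")
})
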