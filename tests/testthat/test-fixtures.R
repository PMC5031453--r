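test_that("single-link fixture: construction and linearized constants", {
  fx <- make_single_link_ankle()
  expect_equal(length(fx$muscles), 2)
  expect_equal(length(fx$plant$joints), 1)
  expect_s3_class(fx$plant, "plant_config")
  # passive toppling matches the linearized time constant sqrt(I/(m g d)):
  # from a small angle, q(t) ~ q0 cosh(t / tau)
  q0 <- 1e-4
  tr <- simulate(fx$plant, sim = sim_config(duration = 1, dt = 1e-4,
                                            monitor_failure = FALSE),
                 initial_state = plant_state(c(ankle = q0)))
  q1 <- deg2rad_t(tail(tr$q_deg[, 1], 1))
  tau_est <- 1 / acosh(q1 / q0)
  expect_equal(tau_est, fx$linearized$toppling_tau, tolerance = 1e-2)
})

test_that("three-link fixture: topology, groups and static balance", {
  fx <- make_three_link_sagittal()
  expect_equal(length(fx$plant$joints), 3)
  expect_equal(length(fx$muscles), 6)
  expect_setequal(unique(vapply(fx$muscles, `[[`, "", "group")),
                  c("ankle_extensor", "ankle_flexor", "knee_extensor",
                    "knee_flexor", "hip_extensor", "hip_flexor"))
  # every muscle path references existing joints
  jn <- vapply(fx$plant$joints, `[[`, "", "name")
  for (m in fx$muscles)
    expect_true(all(names(m$moment_arms) %in% jn))
  # with the CoM stacked over the joints, static torques are ~0 at upright
  om <- static_joint_torques(fx$plant, plant_state(c(ankle = 0, knee = 0,
                                                     hip = 0)))
  expect_true(all(abs(om) < 1e-9))
})

test_that("full model: 8 segments, 7 joints, 70 muscles, 9 groups, 35 classes", {
  fx <- make_full_sagittal_meta()
  expect_equal(length(fx$plant$segments), 8)
  expect_equal(length(fx$plant$joints), 7)
  expect_equal(length(fx$muscles), 70)
  groups <- vapply(fx$muscles, `[[`, "", "group")
  expect_setequal(unique(groups), muscle_groups)
  cls <- unique(sub("_(l|r)$", "", vapply(fx$muscles, `[[`, "", "name")))
  expect_equal(length(cls), 35)
  # free controller variables: 35 symmetry classes + 18 group gains = 53
  expect_equal(length(cls) + 2 * length(muscle_groups), 53)
  # four contact spheres per foot
  feet <- vapply(fx$plant$contact_points, function(cp) cp$foot, 0L)
  expect_equal(unname(table(feet)), c(4L, 4L), ignore_attr = TRUE)
  # bilateral symmetry of parameters within each class
  nm <- vapply(fx$muscles, `[[`, "", "name")
  for (cl in cls) {
    pair <- fx$muscles[nm %in% paste0(cl, c("_l", "_r"))]
    expect_equal(length(pair), 2)
    expect_equal(pair[[1]]$F0, pair[[2]]$F0)
    expect_equal(pair[[1]]$l_opt, pair[[2]]$l_opt)
    expect_equal(unname(pair[[1]]$moment_arms),
                 unname(pair[[2]]$moment_arms))
  }
})

test_that("fixture generation is deterministic per seed", {
  f1 <- make_full_sagittal_meta(seed = 4)
  f2 <- make_full_sagittal_meta(seed = 4)
  f3 <- make_full_sagittal_meta(seed = 5)
  expect_identical(f1$muscles, f2$muscles)
  expect_false(identical(f1$muscles, f3$muscles))
})

test_that("configs round-trip through the file format bit-identically", {
  for (fx in list(make_single_link_ankle(), make_full_sagittal_meta())) {
    p1 <- tempfile(fileext = ".yaml")
    p2 <- tempfile(fileext = ".yaml")
    write_plant_config(fx, p1)
    back <- read_plant_config(p1)
    write_plant_config(back, p2)
    expect_identical(readLines(p1), readLines(p2))
    # and the reconstructed objects carry identical numbers
    expect_identical(vapply(back$muscles, `[[`, 0, "l_opt"),
                     vapply(fx$muscles, `[[`, 0, "l_opt"))
    expect_equal(back$plant$segments, fx$plant$segments,
                 ignore_attr = TRUE)
  }
})
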