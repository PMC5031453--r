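test_that("feedback law normalizes by reference length and maximum speed", {
  expect_equal(feedback_control(0.3, 0, 0.3, 1, 0.5, 0.5), 0)
  expect_equal(feedback_control(0.303, 0, 0.3, 1, 0.05, 0), 5.0e-4)
  expect_equal(feedback_control(0.3, 0.02, 0.3, 1.0, 0, 0.1), 2.0e-3)
  expect_error(feedback_control(0.3, 0, 0, 1, 1, 1), "L0")
})

test_that("total control clamps the excitation to [0, 1]", {
  expect_equal(total_control(0.2, -0.05), 0.15)
  expect_equal(total_control(0.9, 0.3), 1)
  expect_equal(total_control(0.0, -0.2), 0)
})

test_that("group gains are shared within a group and cover all muscles", {
  g <- gain_set(kp = c(hip_flexor = 0.4), kd = c(hip_flexor = 0.1))
  m1 <- muscle_spec("pectineus", "hip_flexor", 100, 0.1, 0.1, 1,
                    c(hip = 0.04), 0.2)
  m2 <- muscle_spec("psoas", "hip_flexor", 200, 0.1, 0.1, 1,
                    c(hip = 0.05), 0.2)
  gm <- assign_group_gains(g, list(m1, m2))
  expect_equal(gm["pectineus", ], gm["psoas", ])
  # the 70-muscle model receives exactly 9 distinct pairs
  fx <- make_full_sagittal_meta()
  g9 <- gain_set(kp = setNames(seq(0.1, 0.9, by = 0.1), muscle_groups),
                 kd = setNames(seq(0.9, 0.1, by = -0.1), muscle_groups))
  gm <- assign_group_gains(g9, fx$muscles)
  expect_equal(nrow(unique(as.data.frame(gm))), 9)
  # a group present among the muscles but absent from the table errors
  gmiss <- g9[g9$group != "ankle_extensor", ]
  expect_error(assign_group_gains(gmiss, fx$muscles), "ankle_extensor")
})

test_that("search-gain scaling: extensors P, flexors 0.5, biarticular 0.2", {
  g <- scale_search_gains(1, 1)
  expect_equal(g$kp[g$group == "ankle_extensor"], 1)
  expect_equal(g$kp[g$group == "hip_flexor"], 0.5)
  expect_equal(g$kp[g$group == "biarticular"], 0.2)
  expect_equal(g$kd[g$group == "knee_flexor"], 0.5)
  g0 <- scale_search_gains(0, 0.3)
  expect_true(all(g0$kp == 0))
  g2 <- scale_search_gains(2.0, 0.1)
  expect_equal(g2$kp[g2$group == "lumbar_extensor"], 2.0)
  expect_equal(g2$kd[g2$group == "lumbar_extensor"], 0.1)
})

test_that("delay buffer returns samples exactly one delay later", {
  buf <- delay_buffer(0, delay = 0.040, step = 0.001)
  hit <- integer(0)
  for (k in 1:100) {
    buffer_push(buf, if (k == 10) 1 else 0)   # impulse at sample 10
    if (buffer_read(buf) != 0) hit <- c(hit, k)
  }
  expect_equal(hit, 50L)  # exactly 40 samples after the write
  # zero delay: read-after-write returns the current sample
  buf0 <- delay_buffer(0, delay = 0, step = 0.001)
  buffer_push(buf0, 7)
  expect_equal(buffer_read(buf0), 7)
  expect_error(delay_buffer(0, delay = 0.0405, step = 0.001), "multiple")
})

test_that("closed-loop latency is exactly tau_fb + tau_trans", {
  # near-infinite inertia: the joint ramps at constant speed, so the
  # activation response of the delayed loop is the undelayed response
  # shifted by exactly (tau_fb + tau_trans)
  segs <- list(segment_spec("g", 1, c(0, 0), 1),
               segment_spec("link", 1, c(0, 0.5), 1e16, parent_joint = "j"))
  jts <- list(joint_spec("j", "g", "link", c(0, 0), c(0, 0)))
  pl <- plant_config(segs, jts, base = "pinned", gravity = 0,
                     contact_mode = "none")
  m <- muscle_spec("m", "ankle_extensor", 100, 0.1, 0.2, 1,
                   c(j = 0.05), 0.3)
  refs <- controller_refs(list(m), c(j = 0))
  gains <- gain_set(kp = c(ankle_extensor = 1), kd = c(ankle_extensor = 0))
  run <- function(tau_fb, tau_trans) {
    ctrl <- neural_controller(gains, delays = delay_config(tau_fb, tau_trans),
                              refs = refs)
    simulate(pl, list(m), ctrl,
             sim = sim_config(duration = 0.5, dt = 1e-3,
                              record_stride = 1L, monitor_failure = FALSE),
             initial_state = plant_state(q = 0, qdot = -0.5),
             initial_activations = 0)$activations[, 1]
  }
  a0 <- run(0, 0)
  a_fb <- run(0.040, 0)
  a_both <- run(0.040, 0.040)
  n <- length(a0)
  expect_identical(a_fb[41:n], a0[1:(n - 40)])
  expect_identical(a_both[81:n], a0[1:(n - 80)])
  # the first delay's worth of samples runs on the pre-filled history
  expect_identical(a_both[1:80], rep(a0[1], 80))
})

test_that("pure feed-forward control is constant in time", {
  fx <- make_single_link_ankle()
  refs <- controller_refs(fx$muscles, c(ankle = 0))
  ctrl <- neural_controller(gain_set(),
                            u_ff = c(ankle_plantarflexor = 0.3,
                                     ankle_dorsiflexor = 0.3),
                            delays = delay_config(), refs = refs)
  tr <- simulate(fx$plant, fx$muscles, ctrl,
                 sim = sim_config(duration = 0.5, dt = 5e-4,
                                  monitor_failure = FALSE),
                 initial_state = plant_state(c(ankle = 0)))
  # activations start at u_ff and stay there
  expect_true(all(abs(tr$activations - 0.3) < 1e-9))
})

test_that("bilateral symmetry: mirrored states give mirrored feedback", {
  fx <- make_full_sagittal_meta()
  jn <- vapply(fx$plant$joints, `[[`, "", "name")
  posture <- setNames(numeric(7), jn)
  refs <- controller_refs(fx$muscles, posture)
  gains <- gain_set(kp = setNames(rep(0.3, 9), muscle_groups),
                    kd = setNames(rep(0.1, 9), muscle_groups))
  gm <- assign_group_gains(gains, fx$muscles)
  q <- c(lumbar = 0.05, hip_r = -0.04, knee_r = 0.02, ankle_r = -0.03,
         hip_l = 0.06, knee_l = -0.01, ankle_l = 0.04)
  mirror <- q[c("lumbar", "hip_l", "knee_l", "ankle_l",
                "hip_r", "knee_r", "ankle_r")]
  names(mirror) <- names(q)
  ufb <- function(qq) {
    vapply(seq_along(fx$muscles), function(i) {
      m <- fx$muscles[[i]]
      lv <- mt_length_velocity(m, qq)
      feedback_control(lv$L_MT, lv$Ldot_MT, refs$L0_MT[m$name],
                       refs$V_max[m$name], gm[i, "kp"], gm[i, "kd"])
    }, 0)
  }
  u1 <- ufb(q); u2 <- ufb(mirror)
  sides <- vapply(fx$muscles, `[[`, "", "side")
  nmn <- vapply(fx$muscles, `[[`, "", "name")
  partner <- match(ifelse(sides == "right", sub("_r$", "_l", nmn),
                          sub("_l$", "_r", nmn)), nmn)
  expect_equal(u1, u2[partner], tolerance = 1e-15)
})
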