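test_that("AP range is max minus min over the window", {
  t <- seq(0, 60, by = 0.01)
  expect_equal(ap_range(t, rep(0.02, length(t))), 0)
  A <- 0.005
  expect_equal(ap_range(t, A * sin(2 * pi * 0.5 * t)), 2 * A,
               tolerance = 1e-6)
  # linear ramp spanning exactly the window
  ramp <- approx(c(0, 30, 60), c(0, 0, 0.01), xout = t)$y
  expect_equal(ap_range(t, ramp, c(30, 60)), 0.01, tolerance = 1e-12)
  # shift invariance and amplitude linearity
  x <- 0.003 * sin(t) + 0.001 * cos(3 * t)
  expect_equal(ap_range(t, x + 5), ap_range(t, x), tolerance = 1e-9)
  expect_equal(ap_range(t, 3 * x), 3 * ap_range(t, x), tolerance = 1e-12)
  expect_error(ap_range(t, x, c(30, 80)), "window")
})

test_that("joint correlations: sign cases, affine invariance, independence", {
  t <- seq(0, 60, by = 0.02)
  base <- sin(0.7 * t) + 0.3 * sin(2.1 * t)
  tr <- structure(list(time = t,
                       q_deg = cbind(hip = base, knee = base,
                                     ankle = -base)),
                  class = "stance_trial")
  r <- joint_correlations(tr)
  expect_equal(unname(r["hip-knee"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["hip-ankle"]), -1, tolerance = 1e-12)
  # affine rescaling (sign-preserving) leaves r unchanged
  tr2 <- tr; tr2$q_deg[, "knee"] <- 2.5 * tr$q_deg[, "knee"] + 3
  expect_equal(joint_correlations(tr2)["hip-knee"], r["hip-knee"],
               tolerance = 1e-12)
  # symmetry in the pair arguments
  expect_equal(unname(joint_correlations(tr, list(c("knee", "hip")))),
               unname(r["hip-knee"]), tolerance = 1e-15)
  # independent noise decorrelates at the 2/sqrt(n) scale
  set.seed(99)
  n <- 3000
  tr3 <- structure(list(time = seq_len(n) * 0.02,
                        q_deg = cbind(hip = rnorm(n), knee = rnorm(n),
                                      ankle = rnorm(n))),
                   class = "stance_trial")
  r3 <- joint_correlations(tr3, window = c(0.02, n * 0.02))
  expect_true(all(abs(r3) < 0.06))
  # zero variance is undefined, reported as NA
  tr4 <- tr; tr4$q_deg[, "knee"] <- 1
  expect_warning(r4 <- joint_correlations(tr4, list(c("hip", "knee"))),
                 "variance")
  expect_true(is.na(r4))
})

test_that("activation deviations follow the range-table semantics", {
  tab <- activation_range_table(
    muscle = c("biceps_femoris", "soleus", "rectus_abdominus_2",
               "tibialis_anterior"),
    lo = c(0.02, 0.03, 0.00, 0.01),
    hi = c(0.10, 0.10, 0.10, 0.08))
  a <- c(biceps_femoris = 0.05, soleus = 0.01, rectus_abdominus_2 = 0.125,
         tibialis_anterior = 0.005, unlisted_muscle = 0.5)
  d <- activation_deviation(a, tab)
  expect_equal(unname(d["biceps_femoris"]), 0.000)
  expect_equal(unname(d["soleus"]), -0.020)
  expect_equal(unname(d["rectus_abdominus_2"]), 0.025)
  expect_equal(unname(d["tibialis_anterior"]), -0.005)
  expect_true(is.na(d["unlisted_muscle"]))
  # continuity at both edges, exactly zero on the range
  eps <- 1e-6
  edge <- activation_deviation(c(soleus = 0.03 - eps, soleus = 0.03,
                                 soleus = 0.10, soleus = 0.10 + eps), tab)
  expect_equal(unname(edge), c(-eps, 0, 0, eps), tolerance = 1e-6)
})

test_that("range table validation", {
  expect_error(activation_range_table("m", lo = 0.2, hi = 0.1), "lo <= hi")
  expect_error(activation_range_table("m", lo = 0, hi = 0.1, mode = 0.2),
               "mode")
})

test_that("phase portrait pairs displacement with its derivative", {
  t <- seq(0, 10, by = 0.01)
  tr <- structure(list(time = t, com_x = rep(0.04, length(t))),
                  class = "stance_trial")
  pp <- phase_portrait(tr)
  expect_true(all(abs(pp$com_vx) < 1e-12))
  expect_true(all(pp$com_x == 0.04))
  # sinusoid traces an ellipse with semi-axes (A, A w)
  A <- 0.01; w <- 2
  tr2 <- structure(list(time = t, com_x = A * sin(w * t)),
                   class = "stance_trial")
  pp2 <- phase_portrait(tr2)
  expect_equal(max(pp2$com_x), A, tolerance = 1e-4)
  expect_equal(max(pp2$com_vx), A * w, tolerance = 1e-3)
  # central differences recover a ramp slope to O(dt^2)
  tr3 <- structure(list(time = t, com_x = 0.003 * t),
                   class = "stance_trial")
  pp3 <- phase_portrait(tr3)
  expect_equal(pp3$com_vx[2:(length(t) - 1)],
               rep(0.003, length(t) - 2), tolerance = 1e-10)
})
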