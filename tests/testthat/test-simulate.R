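test_that("zero gravity, zero controls, at-rest start stays at rest", {
  fx <- make_single_link_ankle()
  pl <- fx$plant
  pl$gravity <- 0
  pl$contact_mode <- "none"  # weightless: no ground load to monitor
  refs <- controller_refs(fx$muscles, c(ankle = 0))
  ctrl <- neural_controller(gain_set(), delays = delay_config(), refs = refs)
  tr <- simulate(pl, fx$muscles, ctrl,
                 sim = sim_config(duration = 2, dt = 5e-4),
                 initial_state = plant_state(c(ankle = 0)),
                 initial_activations = c(0, 0))
  expect_false(tr$failed)
  expect_equal(tr$T_fail, 2)
  expect_true(all(abs(tr$q_deg) < 1e-9))
})

test_that("identical configuration and seed reproduce the trial bitwise", {
  fx <- make_single_link_ankle()
  refs <- controller_refs(fx$muscles, c(ankle = -0.02))
  ctrl <- neural_controller(scale_search_gains(1.4, 0.6),
                            delays = delay_config(), refs = refs)
  run <- function() simulate(fx$plant, fx$muscles, ctrl,
                             sim = sim_config(duration = 2, dt = 5e-4),
                             initial_state = plant_state(c(ankle = -0.02)),
                             initial_activations = c(0.01, 0))
  t1 <- run(); t2 <- run()
  expect_identical(t1$q_deg, t2$q_deg)
  expect_identical(t1$activations, t2$activations)
  expect_identical(t1$cop_x, t2$cop_x)
})

test_that("failure monitor triggers on CoM height and on foot unloading", {
  fx <- make_single_link_ankle()
  refs <- controller_refs(fx$muscles, c(ankle = 0))
  ctrl <- neural_controller(gain_set(), delays = delay_config(), refs = refs)
  # passive fall: the CoP leaves the heel-toe span well before the CoM
  # drops below the height threshold -> early failure event
  tr <- simulate(fx$plant, fx$muscles, ctrl,
                 sim = sim_config(duration = 10, dt = 5e-4),
                 initial_state = plant_state(c(ankle = -0.12)),
                 initial_activations = c(0, 0))
  expect_true(tr$failed)
  expect_lt(tr$T_fail, 10)
  # near the failure sample the CoP approaches the toe (recording is
  # strided, so the final boundary-crossing sample may fall between rows)
  expect_gt(max(tr$cop_x, na.rm = TRUE), 0.145)
  # with the monitor disabled the same trial runs to completion
  tr2 <- simulate(fx$plant, fx$muscles, ctrl,
                  sim = sim_config(duration = 1, dt = 5e-4,
                                   monitor_failure = FALSE),
                  initial_state = plant_state(c(ankle = -0.12)),
                  initial_activations = c(0, 0))
  expect_false(tr2$failed)
})

test_that("CoM-height failure triggers below the configured threshold", {
  # free-falling single segment with contact points but no support
  segs <- list(segment_spec("blob", 10, c(0, 0), 0.5))
  pl <- plant_config(segs, list(), base = "free", contact_mode = "none")
  tr <- simulate(pl, sim = sim_config(duration = 2, dt = 1e-3,
                                      com_fail_height = 0.4),
                 initial_state = plant_state(numeric(0),
                                             base_position = c(0, 0.45)))
  expect_true(tr$failed)
  # fall of ~5 cm under gravity: t ~= sqrt(2 h / g) ~= 0.101 s
  expect_equal(tr$T_fail, sqrt(2 * 0.05 / 9.81), tolerance = 0.05)
})

test_that("halving the step leaves the 60-s closed-loop CoM unchanged", {
  fx <- make_single_link_ankle()
  post <- c(ankle = -0.016)
  refs <- controller_refs(fx$muscles, post)
  ctrl <- neural_controller(scale_search_gains(1.4, 0.6),
                            delays = delay_config(), refs = refs)
  run <- function(dt) simulate(fx$plant, fx$muscles, ctrl,
                               sim = sim_config(duration = 60, dt = dt),
                               initial_state = plant_state(post),
                               initial_activations = c(0, 0))
  a <- run(2e-4); b <- run(1e-4)
  expect_false(a$failed)
  expect_lt(max(abs(a$com_x - b$com_x)), 1e-3)
})

test_that("trial export writes the trajectory table and result record", {
  fx <- make_single_link_ankle()
  refs <- controller_refs(fx$muscles, c(ankle = 0))
  ctrl <- neural_controller(scale_search_gains(1.2, 0.5),
                            delays = delay_config(), refs = refs)
  tr <- simulate(fx$plant, fx$muscles, ctrl,
                 sim = sim_config(duration = 0.5, dt = 5e-4),
                 initial_state = plant_state(c(ankle = -0.016)),
                 initial_activations = c(0, 0))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_trial_csv(tr, csv)
  df <- read.csv(csv)
  expect_true(all(c("time_s", "q_ankle_deg", "com_x_m", "com_y_m",
                    "cop_x_m", "a_ankle_plantarflexor",
                    "f_ankle_dorsiflexor_N", "Ry_heel_N") %in% names(df)))
  expect_equal(nrow(df), length(tr$time))
  expect_equal(df$com_x_m, tr$com_x, tolerance = 1e-12)
  write_trial_json(tr, js)
  rec <- jsonlite::read_json(js)
  expect_equal(rec$T_fail, tr$T_fail)
  expect_equal(rec$failed, tr$failed)
})
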