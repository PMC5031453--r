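#' Single-link ankle-strategy fixture
#'
#' A reduced standing model: the whole body above the ankle lumped into one
#' inverted-pendulum link pinned at the ankle on a grounded foot, actuated
#' by one lumped plantarflexor ("ankle extensor") and one lumped dorsiflexor
#' ("ankle flexor") with constant moment arms of 0.05 m magnitude.
#'
#' Sign conventions: the ankle coordinate is the counter-clockwise rotation
#' of the body from upright, so a forward (anterior, +x) lean is a negative
#' angle.  The plantarflexor has a positive moment arm (positive torque
#' rights a forward lean and the actuator stretches as the body leans
#' forward); the dorsiflexor mirrors it.
#'
#' The lumped actuator strengths are sized so that the length-normalized
#' feedback law spans the stability boundary within the 0-2 shared-gain
#' grid: the linearized feedback stiffness per muscle,
#' `kp F0 r^2 / L0_MT`, must exceed the gravitational toppling stiffness
#' `m g d` (about 690 N m/rad here) at feasible `kp`, which with a 0.05 m
#' moment arm and a 0.3 m reference length demands bilateral-equivalent
#' maximal forces of order 1e5 N.
#'
#' @param total_mass Lumped body mass above the ankle, kg.
#' @param com_height Height of the body CoM above the ankle, m.
#' @param seed Integer seed (fixture generation is deterministic; kept for
#'   the common fixture interface).
#' @return A list of class `stance_fixture` with `plant`, `muscles`,
#'   `posture_cfg`, and a `linearized` block with the closed-form
#'   inverted-pendulum constants (ankle inertia, `m g d`, toppling time
#'   constant).
#' @export
make_single_link_ankle <- function(total_mass = 70, com_height = 1.0,
                                   seed = 1L) {
  stopifnot(total_mass > 0, com_height > 0)
  I_com <- 12
  segs <- list(
    segment_spec("foot", mass = 2.4, com_offset = c(0.05, 0.03),
                 inertia = 0.015, length = 0.2),
    segment_spec("body", mass = total_mass, com_offset = c(0, com_height),
                 inertia = I_com, length = 1.7, parent_joint = "ankle"))
  jts <- list(joint_spec("ankle", "foot", "body",
                         anchor_parent = c(0, 0.08), anchor_child = c(0, 0)))
  cps <- list(list(name = "heel", segment = "foot",
                   local_position = c(-0.05, 0), role = "heel", foot = 1L),
              list(name = "toe", segment = "foot",
                   local_position = c(0.15, 0), role = "toe", foot = 1L))
  plant <- plant_config(segs, jts, base = "pinned", base_pose = c(0, 0, 0),
                        contact_points = cps)
  muscles <- list(
    muscle_spec("ankle_plantarflexor", "ankle_extensor", F0 = 1.0e5,
                l_opt = 0.06, l_ts = 0.24, v_max = 0.48,
                moment_arms = c(ankle = 0.05), L0_MT = 0.30),
    muscle_spec("ankle_dorsiflexor", "ankle_flexor", F0 = 8.0e4,
                l_opt = 0.07, l_ts = 0.23, v_max = 0.56,
                moment_arms = c(ankle = -0.05), L0_MT = 0.30))
  mgd <- total_mass * 9.81 * com_height
  I_ankle <- I_com + total_mass * com_height^2
  structure(list(
    name = "single_link_ankle", seed = as.integer(seed),
    plant = plant, muscles = muscles,
    posture_cfg = posture_objective_config(
      free_coords = "ankle", initial_guess_deg = c(ankle = 0)),
    linearized = list(I_ankle = I_ankle, mgd = mgd,
                      toppling_tau = sqrt(I_ankle / mgd))),
    class = "stance_fixture")
}

#' Three-link sagittal fixture
#'
#' Ankle-knee-hip standing model pinned at a grounded foot: lumped shank,
#' thigh and head-arms-trunk segments, with an extensor/flexor pair per
#' joint (six muscles exercising six of the nine gain groups).  Joint
#' coordinates are counter-clockwise rotations from upright; extensors
#' carry positive ankle / negative knee, hip moment arms chosen so that
#' each extensor rights a forward CoM excursion at its joint.
#'
#' @inheritParams make_single_link_ankle
#' @return A `stance_fixture` list with `plant`, `muscles`, `posture_cfg`.
#' @export
make_three_link_sagittal <- function(total_mass = 70, seed = 1L) {
  sc <- total_mass / 70
  segs <- list(
    segment_spec("foot", mass = 2.4 * sc, com_offset = c(0.05, 0.03),
                 inertia = 0.015, length = 0.2),
    segment_spec("shank", mass = 7.0 * sc, com_offset = c(0, 0.25),
                 inertia = 0.25, length = 0.43, parent_joint = "ankle"),
    segment_spec("thigh", mass = 14.0 * sc, com_offset = c(0, 0.18),
                 inertia = 0.35, length = 0.41, parent_joint = "knee"),
    segment_spec("hat", mass = 46.6 * sc, com_offset = c(0, 0.32),
                 inertia = 3.0, length = 0.8, parent_joint = "hip"))
  jts <- list(
    joint_spec("ankle", "foot", "shank", c(0, 0.08), c(0, 0)),
    joint_spec("knee", "shank", "thigh", c(0, 0.43), c(0, 0)),
    joint_spec("hip", "thigh", "hat", c(0, 0.41), c(0, 0)))
  cps <- list(list(name = "heel", segment = "foot",
                   local_position = c(-0.05, 0), role = "heel", foot = 1L),
              list(name = "toe", segment = "foot",
                   local_position = c(0.15, 0), role = "toe", foot = 1L))
  plant <- plant_config(segs, jts, base = "pinned",
                        contact_points = cps)
  mus <- function(name, group, F0, lopt, lts, r)
    muscle_spec(name, group, F0 = F0, l_opt = lopt, l_ts = lts,
                v_max = 10 * lopt, moment_arms = r, L0_MT = lopt + lts)
  muscles <- list(
    mus("ankle_plantarflexor", "ankle_extensor", 9e4, 0.06, 0.24,
        c(ankle = 0.05)),
    mus("ankle_dorsiflexor", "ankle_flexor", 7e4, 0.07, 0.23,
        c(ankle = -0.05)),
    mus("knee_vasti", "knee_extensor", 6e4, 0.09, 0.16, c(knee = -0.04)),
    mus("knee_flexor_short", "knee_flexor", 6e4, 0.10, 0.15,
        c(knee = 0.04)),
    mus("hip_glutei", "hip_extensor", 8e4, 0.11, 0.14, c(hip = 0.06)),
    mus("hip_iliopsoas", "hip_flexor", 6e4, 0.10, 0.13, c(hip = -0.06)))
  structure(list(
    name = "three_link_sagittal", seed = as.integer(seed),
    plant = plant, muscles = muscles,
    posture_cfg = posture_objective_config(
      free_coords = c("ankle", "hip"),
      initial_guess_deg = c(ankle = 0, hip = 0),
      fixed_coords_deg = c(knee = 1))),
    class = "stance_fixture")
}

# 35 bilateral symmetry classes of the full model: name, group, actuated
# joints (hip/knee/ankle are side-resolved on expansion), signed moment
# arms and maximal isometric forces.  Plausible documented stand-ins, not
# anatomical data.
.full_muscle_classes <- function() {
  cl <- function(name, group, joints, r, F0)
    list(name = name, group = group, joints = joints, r = r, F0 = F0)
  list(
    cl("erector_spinae", "lumbar_extensor", "lumbar", -0.06, 2500),
    cl("rectus_abdominus_1", "lumbar_flexor", "lumbar", 0.07, 600),
    cl("rectus_abdominus_2", "lumbar_flexor", "lumbar", 0.075, 600),
    cl("glut_max_1", "hip_extensor", "hip", -0.055, 570),
    cl("glut_max_2", "hip_extensor", "hip", -0.06, 550),
    cl("glut_max_3", "hip_extensor", "hip", -0.065, 550),
    cl("adductor_magnus_1", "hip_extensor", "hip", -0.05, 380),
    cl("adductor_magnus_2", "hip_extensor", "hip", -0.045, 340),
    cl("psoas", "hip_flexor", "hip", 0.05, 1000),
    cl("iliacus", "hip_flexor", "hip", 0.05, 850),
    cl("pectineus", "hip_flexor", "hip", 0.04, 180),
    cl("adductor_longus", "hip_flexor", "hip", 0.04, 420),
    cl("adductor_brevis", "hip_flexor", "hip", 0.035, 290),
    cl("tensor_fasciae_latae", "hip_flexor", "hip", 0.045, 230),
    cl("vastus_lateralis", "knee_extensor", "knee", -0.042, 1870),
    cl("vastus_medialis", "knee_extensor", "knee", -0.040, 1290),
    cl("vastus_intermedius", "knee_extensor", "knee", -0.041, 1230),
    cl("biceps_femoris_short_head", "knee_flexor", "knee", 0.035, 400),
    cl("soleus", "ankle_extensor", "ankle", 0.048, 3550),
    cl("tibialis_posterior", "ankle_extensor", "ankle", 0.040, 1270),
    cl("flexor_digitorum_longus", "ankle_extensor", "ankle", 0.035, 310),
    cl("flexor_hallucis_longus", "ankle_extensor", "ankle", 0.036, 320),
    cl("peroneus_longus", "ankle_extensor", "ankle", 0.030, 750),
    cl("tibialis_anterior", "ankle_flexor", "ankle", -0.040, 900),
    cl("extensor_digitorum_longus", "ankle_flexor", "ankle", -0.035, 510),
    cl("extensor_hallucis_longus", "ankle_flexor", "ankle", -0.036, 160),
    cl("peroneus_tertius", "ankle_flexor", "ankle", -0.030, 90),
    cl("medial_gastrocnemius", "biarticular", c("knee", "ankle"),
       c(0.020, 0.045), 1560),
    cl("lateral_gastrocnemius", "biarticular", c("knee", "ankle"),
       c(0.018, 0.043), 680),
    cl("biceps_femoris_long_head", "biarticular", c("hip", "knee"),
       c(-0.055, 0.030), 900),
    cl("semimembranosus", "biarticular", c("hip", "knee"),
       c(-0.055, 0.032), 1300),
    cl("semitendinosus", "biarticular", c("hip", "knee"),
       c(-0.050, 0.035), 410),
    cl("rectus_femoris", "biarticular", c("hip", "knee"),
       c(0.045, -0.042), 1170),
    cl("sartorius", "biarticular", c("hip", "knee"),
       c(0.040, 0.020), 160),
    cl("gracilis", "biarticular", c("hip", "knee"),
       c(0.035, 0.020), 160))
}

#' Full sagittal-plane standing model
#'
#' Eight segments (head-arms-trunk, pelvis, paired femur/shank/foot), seven
#' 1-DoF joints in the coordinate order lumbar, right hip, right knee,
#' right ankle, left hip, left knee, left ankle, and 70 muscular-tendon
#' actuators: 35 bilateral symmetry classes spanning all nine gain groups,
#' expanded to left/right pairs.  Four contact spheres per foot (heel, two
#' metatarsals, toe) with Hunt-Crossley contact under the free-floating
#' base.  All inertial and muscle parameters are plausible documented
#' stand-ins generated deterministically from the seed.
#'
#' @param total_mass Whole-body mass, kg.
#' @param stature Body height, m (scales nothing yet; recorded).
#' @param seed Integer seed for the parameter jitter.
#' @return A `stance_fixture` list with `plant`, `muscles`, `posture_cfg`.
#' @export
make_full_sagittal_meta <- function(total_mass = 75.4, stature = 1.75,
                                    seed = 1L) {
  stopifnot(total_mass > 0, stature > 0)
  sc <- total_mass / 75.4
  segs <- list(
    segment_spec("pelvis", mass = 11.0 * sc, com_offset = c(-0.03, 0.02),
                 inertia = 0.12, length = 0.2),
    segment_spec("hat", mass = 39.0 * sc, com_offset = c(0, 0.25),
                 inertia = 2.5, length = 0.6, parent_joint = "lumbar"),
    segment_spec("femur_r", mass = 8.0 * sc, com_offset = c(0, -0.17),
                 inertia = 0.15, length = 0.41, parent_joint = "hip_r"),
    segment_spec("shank_r", mass = 3.5 * sc, com_offset = c(0, -0.19),
                 inertia = 0.05, length = 0.43, parent_joint = "knee_r"),
    segment_spec("foot_r", mass = 1.2 * sc, com_offset = c(0.05, 0.03),
                 inertia = 0.01, length = 0.2, parent_joint = "ankle_r"),
    segment_spec("femur_l", mass = 8.0 * sc, com_offset = c(0, -0.17),
                 inertia = 0.15, length = 0.41, parent_joint = "hip_l"),
    segment_spec("shank_l", mass = 3.5 * sc, com_offset = c(0, -0.19),
                 inertia = 0.05, length = 0.43, parent_joint = "knee_l"),
    segment_spec("foot_l", mass = 1.2 * sc, com_offset = c(0.05, 0.03),
                 inertia = 0.01, length = 0.2, parent_joint = "ankle_l"))
  jts <- list(
    joint_spec("lumbar", "pelvis", "hat", c(-0.05, 0.10), c(0, 0),
               coordinate_index = 1L),
    joint_spec("hip_r", "pelvis", "femur_r", c(0, -0.02), c(0, 0),
               coordinate_index = 2L),
    joint_spec("knee_r", "femur_r", "shank_r", c(0, -0.41), c(0, 0),
               coordinate_index = 3L),
    joint_spec("ankle_r", "shank_r", "foot_r", c(0, -0.43), c(0, 0.08),
               coordinate_index = 4L),
    joint_spec("hip_l", "pelvis", "femur_l", c(0, -0.02), c(0, 0),
               coordinate_index = 5L),
    joint_spec("knee_l", "femur_l", "shank_l", c(0, -0.41), c(0, 0),
               coordinate_index = 6L),
    joint_spec("ankle_l", "shank_l", "foot_l", c(0, -0.43), c(0, 0.08),
               coordinate_index = 7L))
  cp <- function(nm, seg, x, role, foot)
    list(name = nm, segment = seg, local_position = c(x, 0), role = role,
         foot = foot)
  cps <- list(
    cp("heel_r", "foot_r", -0.05, "heel", 1L),
    cp("metatarsal_1_r", "foot_r", 0.06, "other", 1L),
    cp("metatarsal_2_r", "foot_r", 0.10, "other", 1L),
    cp("toe_r", "foot_r", 0.15, "toe", 1L),
    cp("heel_l", "foot_l", -0.05, "heel", 2L),
    cp("metatarsal_1_l", "foot_l", 0.06, "other", 2L),
    cp("metatarsal_2_l", "foot_l", 0.10, "other", 2L),
    cp("toe_l", "foot_l", 0.15, "toe", 2L))
  plant <- plant_config(segs, jts, base = "free",
                        base_pose = c(0, 0.94, 0), contact_points = cps)
  classes <- .full_muscle_classes()
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  lopt_tab <- round(runif(length(classes), 0.05, 0.12), 4)
  lts_tab <- round(runif(length(classes), 0.12, 0.28), 4)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  muscles <- list()
  for (i in seq_along(classes)) {
    cls <- classes[[i]]
    for (side in c("r", "l")) {
      jn <- vapply(cls$joints, function(j)
        if (j == "lumbar") "lumbar" else paste0(j, "_", side), "")
      muscles[[length(muscles) + 1]] <- muscle_spec(
        name = paste0(cls$name, "_", side), group = cls$group,
        F0 = cls$F0, l_opt = lopt_tab[i], l_ts = lts_tab[i],
        v_max = 10 * lopt_tab[i],
        moment_arms = setNames(cls$r, jn),
        L0_MT = lopt_tab[i] + lts_tab[i],
        side = if (side == "r") "right" else "left")
    }
  }
  structure(list(
    name = "full_sagittal_meta", seed = as.integer(seed),
    total_mass = total_mass, stature = stature,
    plant = plant, muscles = muscles,
    posture_cfg = posture_objective_config(
      free_coords = c("lumbar", "hip_r", "ankle_r", "hip_l", "ankle_l"),
      initial_guess_deg = c(lumbar = -10, hip_r = -5, ankle_r = 0,
                            hip_l = -5, ankle_l = 0),
      fixed_coords_deg = c(knee_r = 1, knee_l = 1))),
    class = "stance_fixture")
}

#' @export
print.stance_fixture <- function(x, ...) {
  cat("<stance_fixture>", x$name, "|", length(x$plant$segments),
      "segments,", length(x$plant$joints), "joints,", length(x$muscles),
      "muscles\n")
  invisible(x)
}

#' Fixture by name
#'
#' @param name One of `"single_link_ankle"`, `"three_link_sagittal"`,
#'   `"full_sagittal_meta"`.
#' @param seed Integer seed.
#' @return A `stance_fixture`.
#' @export
make_fixture <- function(name = c("single_link_ankle",
                                  "three_link_sagittal",
                                  "full_sagittal_meta"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
         single_link_ankle = make_single_link_ankle(seed = seed),
         three_link_sagittal = make_three_link_sagittal(seed = seed),
         full_sagittal_meta = make_full_sagittal_meta(seed = seed))
}
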