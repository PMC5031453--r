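#' Write a plant/muscle configuration file
#'
#' Serializes a plant (segments, joints, gravity, base, contact) and its
#' muscles to a hierarchical YAML config.  Lengths are metres, masses kg,
#' and angles degrees in the file (the degree/radian conversion happens
#' only at this boundary).
#'
#' @param fixture A list with `plant` (a [plant_config()]), `muscles`, and
#'   optionally `name`, or a `stance_fixture`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_plant_config <- function(fixture, path) {
  plant <- fixture$plant
  num <- function(v) as.numeric(v)
  segs <- lapply(plant$segments, function(s)
    list(name = s$name, mass = s$mass, com_offset = num(s$com_offset),
         inertia = s$inertia, length = s$length,
         parent_joint = if (is.null(s$parent_joint)) "" else s$parent_joint))
  jts <- lapply(plant$joints, function(j)
    list(name = j$name, parent_segment = j$parent_segment,
         child_segment = j$child_segment,
         anchor_parent = num(j$anchor_parent),
         anchor_child = num(j$anchor_child)))
  cps <- lapply(plant$contact_points, function(cp)
    list(name = cp$name, segment = cp$segment,
         local_position = num(cp$local_position), role = cp$role,
         foot = as.integer(if (is.null(cp$foot)) 1L else cp$foot)))
  mus <- lapply(fixture$muscles, function(m)
    list(name = m$name, group = m$group, side = m$side, F0 = m$F0,
         l_opt = m$l_opt, l_ts = m$l_ts, v_max = m$v_max,
         t_act = m$t_act, t_dact = m$t_dact, a_min = m$a_min,
         L0_MT = m$L0_MT,
         moment_arms = as.list(m$moment_arms)))
  cfg <- list(
    name = if (is.null(fixture$name)) "plant" else fixture$name,
    gravity = plant$gravity,
    base = plant$base,
    base_pose = num(plant$base_pose),
    joint_neutral_deg = as.list(rad2deg(plant$joint_neutral)),
    joint_stiffness = as.list(plant$joint_stiffness),
    joint_damping = as.list(plant$joint_damping),
    segments = segs, joints = jts,
    contact = unclass(plant$contact),
    contact_points = cps,
    muscles = mus)
  txt <- yaml::as.yaml(cfg, precision = 17L)
  writeLines(txt, path)
  invisible(path)
}

#' Read a plant/muscle configuration file
#'
#' @param path Path to a YAML config written by [write_plant_config()].
#' @return A list with `name`, `plant` and `muscles`.
#' @export
read_plant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  segs <- lapply(cfg$segments, function(s)
    segment_spec(s$name, s$mass, as.numeric(s$com_offset), s$inertia,
                 s$length,
                 parent_joint = if (identical(s$parent_joint, "")) NULL
                 else s$parent_joint))
  jts <- lapply(cfg$joints, function(j)
    joint_spec(j$name, j$parent_segment, j$child_segment,
               as.numeric(j$anchor_parent), as.numeric(j$anchor_child)))
  cps <- lapply(cfg$contact_points, function(cp)
    list(name = cp$name, segment = cp$segment,
         local_position = as.numeric(cp$local_position), role = cp$role,
         foot = as.integer(cp$foot)))
  cpar <- do.call(contact_params, cfg$contact)
  plant <- plant_config(
    segs, jts, gravity = cfg$gravity, base = cfg$base,
    base_pose = as.numeric(cfg$base_pose), contact_points = cps,
    contact = cpar,
    joint_stiffness = unlist(cfg$joint_stiffness),
    joint_damping = unlist(cfg$joint_damping),
    joint_neutral = deg2rad(unlist(cfg$joint_neutral_deg)))
  muscles <- lapply(cfg$muscles, function(m)
    muscle_spec(m$name, m$group, F0 = m$F0, l_opt = m$l_opt,
                l_ts = m$l_ts, v_max = m$v_max,
                moment_arms = unlist(m$moment_arms), L0_MT = m$L0_MT,
                side = m$side, t_act = m$t_act, t_dact = m$t_dact,
                a_min = m$a_min))
  list(name = cfg$name, plant = plant, muscles = muscles)
}
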