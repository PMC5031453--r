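#' Segment specification
#'
#' Describes one rigid body segment of the planar plant: its inertial
#' properties and the joint through which it hangs off its parent.
#'
#' @param name Segment label.
#' @param mass Segment mass in kg (> 0).
#' @param com_offset Length-2 numeric, segment CoM in the segment frame (m).
#' @param inertia Rotational inertia about the CoM in kg m^2 (> 0).
#' @param length Segment length in m (>= 0; descriptive only).
#' @param parent_joint Name of the joint connecting this segment to its
#'   parent, or `NULL` for the root segment.
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(name, mass, com_offset, inertia, length = 0,
                         parent_joint = NULL) {
  stopifnot(is.character(name), length(com_offset) == 2)
  if (mass <= 0) stop("segment mass must be > 0")
  if (inertia <= 0) stop("segment inertia must be > 0")
  if (length < 0) stop("segment length must be >= 0")
  structure(list(name = name, mass = mass, com_offset = as.numeric(com_offset),
                 inertia = inertia, length = length,
                 parent_joint = parent_joint),
            class = "segment_spec")
}

#' Joint specification
#'
#' A 1-DoF revolute joint between two segments. The joint world position is
#' `anchor_parent` expressed in the parent frame; the child frame is placed so
#' that `anchor_child` (in the child frame) coincides with it.  The joint
#' coordinate is the relative angle of the child with respect to the parent,
#' positive counter-clockwise; fixtures document the anatomical reading
#' (flexion/extension) per joint.
#'
#' @param name Joint label.
#' @param parent_segment,child_segment Segment names.
#' @param anchor_parent,anchor_child Length-2 anchors (m) in the respective
#'   segment frames.
#' @param coordinate_index Optional explicit coordinate index (1-based); by
#'   default joints are numbered in the order they appear in the config.
#' @return An object of class `joint_spec`.
#' @export
joint_spec <- function(name, parent_segment, child_segment, anchor_parent,
                       anchor_child, coordinate_index = NA_integer_) {
  stopifnot(length(anchor_parent) == 2, length(anchor_child) == 2)
  structure(list(name = name, parent_segment = parent_segment,
                 child_segment = child_segment,
                 anchor_parent = as.numeric(anchor_parent),
                 anchor_child = as.numeric(anchor_child),
                 coordinate_index = as.integer(coordinate_index)),
            class = "joint_spec")
}

#' Planar plant configuration
#'
#' Assembles segments and joints into a kinematic tree with an optional
#' 3-DoF floating base.  Generalized coordinates are
#' `(x, y, theta, q_1..q_n)` for a free base and `(q_1..q_n)` for a pinned
#' base (the root segment welded to the world at `base_pose`).
#'
#' @param segments List of [segment_spec()] objects.
#' @param joints List of [joint_spec()] objects.  Joint order defines the
#'   coordinate order unless `coordinate_index` is given.
#' @param gravity Gravitational acceleration magnitude, m/s^2, acting in -y.
#' @param base `"free"` (floating base) or `"pinned"` (root welded to world).
#' @param base_pose Length-3 `(x, y, theta)` world pose of the root frame,
#'   used as the fixed pose when pinned and as the default initial pose when
#'   free.
#' @param contact_points List of contact point specs, each a list with
#'   `name`, `segment`, `local_position` (length-2, m), `role` (one of
#'   `"heel"`, `"toe"`, `"other"`) and `foot` (integer foot id).
#' @param contact A [contact_params()] object.
#' @param contact_mode `"auto"` (Hunt-Crossley when the base is free, static
#'   support distribution when pinned), `"hc"`, `"support"`, or `"none"`.
#' @param joint_stiffness,joint_damping,joint_neutral Optional named numeric
#'   vectors of passive rotational stiffness (N m/rad), damping (N m s/rad)
#'   and neutral angle (rad) per joint; default zero.
#' @return An object of class `plant_config`.
#' @export
plant_config <- function(segments, joints, gravity = 9.81,
                         base = c("free", "pinned"), base_pose = c(0, 0, 0),
                         contact_points = list(),
                         contact = contact_params(),
                         contact_mode = c("auto", "hc", "support", "none"),
                         joint_stiffness = NULL, joint_damping = NULL,
                         joint_neutral = NULL) {
  base <- match.arg(base)
  contact_mode <- match.arg(contact_mode)
  seg_names <- vapply(segments, `[[`, "", "name")
  if (anyDuplicated(seg_names)) stop("duplicate segment names")
  joint_names <- vapply(joints, `[[`, "", "name")
  if (anyDuplicated(joint_names)) stop("duplicate joint names")
  ci <- vapply(joints, `[[`, 0L, "coordinate_index")
  if (all(is.na(ci))) ci <- seq_along(joints)
  if (anyDuplicated(ci) || any(is.na(ci)))
    stop("joint coordinate indices must be unique and complete")
  joints <- joints[order(ci)]
  joint_names <- joint_names[order(ci)]
  # identify root: the segment that is no joint's child
  children <- vapply(joints, `[[`, "", "child_segment")
  parents <- vapply(joints, `[[`, "", "parent_segment")
  if (!all(children %in% seg_names) || !all(parents %in% seg_names))
    stop("joint references a segment not in the config")
  root <- setdiff(seg_names, children)
  if (length(root) != 1)
    stop("kinematic graph must be a tree with a single root segment")
  if (anyDuplicated(children)) stop("kinematic graph must be a tree")
  if (length(joints) != length(segments) - 1)
    stop("a tree over n segments needs exactly n-1 joints")
  for (cp in contact_points) {
    if (!cp$segment %in% seg_names)
      stop("contact point on unknown segment: ", cp$segment)
    if (!cp$role %in% c("heel", "toe", "other"))
      stop("contact point role must be heel/toe/other")
  }
  pick <- function(v, def) {
    out <- rep(def, length(joints))
    names(out) <- joint_names
    if (!is.null(v)) out[names(v)] <- v
    out
  }
  structure(list(segments = segments, joints = joints,
                 root_segment = root, gravity = gravity, base = base,
                 base_pose = as.numeric(base_pose),
                 contact_points = contact_points, contact = contact,
                 contact_mode = contact_mode,
                 joint_stiffness = pick(joint_stiffness, 0),
                 joint_damping = pick(joint_damping, 0),
                 joint_neutral = pick(joint_neutral, 0)),
            class = "plant_config")
}

#' @export
print.plant_config <- function(x, ...) {
  cat("<plant_config>", length(x$segments), "segments,", length(x$joints),
      "joints,", x$base, "base,", length(x$contact_points),
      "contact points\n")
  invisible(x)
}

joint_names <- function(plant) vapply(plant$joints, `[[`, "", "name")
segment_names <- function(plant) vapply(plant$segments, `[[`, "", "name")
n_joints <- function(plant) length(plant$joints)

# topological order of segments (parents before children) and parent/joint
# index maps; internal
.plant_topology <- function(plant) {
  segs <- segment_names(plant)
  parent_of <- setNames(rep(NA_character_, length(segs)), segs)
  joint_of <- setNames(rep(NA_integer_, length(segs)), segs)
  for (j in seq_along(plant$joints)) {
    jt <- plant$joints[[j]]
    parent_of[jt$child_segment] <- jt$parent_segment
    joint_of[jt$child_segment] <- j
  }
  ord <- plant$root_segment
  while (length(ord) < length(segs)) {
    nxt <- segs[!segs %in% ord & parent_of[segs] %in% ord]
    if (!length(nxt)) stop("kinematic graph is not a connected tree")
    ord <- c(ord, nxt)
  }
  list(order = ord, parent_of = parent_of, joint_of = joint_of)
}

# pack a plant_config into the flat list consumed by the C++ core; internal
.plant_pack <- function(plant) {
  topo <- .plant_topology(plant)
  ord <- topo$order
  idx <- setNames(seq_along(ord) - 1L, ord)
  nseg <- length(ord)
  nj <- n_joints(plant)
  parent <- integer(nseg); jidx <- integer(nseg)
  anchor_p <- matrix(0, 2, nseg); anchor_c <- matrix(0, 2, nseg)
  mass <- numeric(nseg); inertia <- numeric(nseg); com <- matrix(0, 2, nseg)
  seg_by_name <- setNames(plant$segments, segment_names(plant))
  for (s in seq_along(ord)) {
    sg <- seg_by_name[[ord[s]]]
    mass[s] <- sg$mass; inertia[s] <- sg$inertia; com[, s] <- sg$com_offset
    pa <- topo$parent_of[ord[s]]
    if (is.na(pa)) {
      parent[s] <- -1L; jidx[s] <- -1L
    } else {
      parent[s] <- idx[[pa]]
      j <- topo$joint_of[[ord[s]]]
      jidx[s] <- j - 1L
      anchor_p[, s] <- plant$joints[[j]]$anchor_parent
      anchor_c[, s] <- plant$joints[[j]]$anchor_child
    }
  }
  mode_chr <- plant$contact_mode
  if (mode_chr == "auto")
    mode_chr <- if (plant$base == "free") "hc" else "support"
  if (!length(plant$contact_points)) mode_chr <- "none"
  mode <- match(mode_chr, c("none", "hc", "support")) - 1L
  ncp <- length(plant$contact_points)
  cp_seg <- integer(ncp); cp_role <- integer(ncp); cp_foot <- integer(ncp)
  cp_pos <- matrix(0, 2, max(ncp, 1))
  if (ncp) {
    for (i in seq_len(ncp)) {
      cp <- plant$contact_points[[i]]
      cp_seg[i] <- idx[[cp$segment]]
      cp_role[i] <- match(cp$role, c("heel", "toe", "other")) - 1L
      cp_foot[i] <- if (is.null(cp$foot)) 1L else as.integer(cp$foot)
      cp_pos[, i] <- cp$local_position
    }
  } else {
    cp_pos <- matrix(0, 2, 0)
  }
  list(nseg = nseg, nj = nj, base_free = plant$base == "free",
       gravity = plant$gravity, base_pose = plant$base_pose,
       parent = parent, jidx = jidx, anchor_p = anchor_p,
       anchor_c = anchor_c, mass = mass, inertia = inertia, com = com,
       jstiff = unname(plant$joint_stiffness),
       jdamp = unname(plant$joint_damping),
       jneutral = unname(plant$joint_neutral),
       contact_mode = mode, cp_seg = cp_seg, cp_role = cp_role,
       cp_foot = cp_foot, cp_pos = cp_pos,
       contact = unclass(plant$contact),
       seg_order = ord)
}

#' Plant state
#'
#' Generalized positions and velocities of the plant.  Angles are radians.
#'
#' @param q Named or plain numeric vector of joint angles (rad), one per
#'   joint in coordinate order.
#' @param qdot Joint angular velocities (rad/s), defaults to zero.
#' @param base_position,base_orientation Root frame world pose (free base).
#' @param base_velocity,base_angular_velocity Root frame world velocity.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(q, qdot = NULL, base_position = c(0, 0),
                        base_orientation = 0, base_velocity = c(0, 0),
                        base_angular_velocity = 0) {
  q <- as.numeric(q)
  if (is.null(qdot)) qdot <- numeric(length(q))
  if (length(qdot) != length(q)) stop("q and qdot must have equal length")
  vals <- c(q, qdot, base_position, base_orientation, base_velocity,
            base_angular_velocity)
  if (!all(is.finite(vals))) stop("plant state entries must be finite")
  structure(list(q = q, qdot = as.numeric(qdot),
                 base_position = as.numeric(base_position),
                 base_orientation = as.numeric(base_orientation),
                 base_velocity = as.numeric(base_velocity),
                 base_angular_velocity = as.numeric(base_angular_velocity)),
            class = "plant_state")
}

# generalized position/velocity vectors for the core; internal
.state_gen <- function(plant, state) {
  if (length(state$q) != n_joints(plant))
    stop("state has ", length(state$q), " joint angles; plant has ",
         n_joints(plant), " joints")
  if (plant$base == "free") {
    list(gp = c(state$base_position, state$base_orientation, state$q),
         gv = c(state$base_velocity, state$base_angular_velocity,
                state$qdot))
  } else {
    list(gp = state$q, gv = state$qdot)
  }
}

#' Forward dynamics of the plant
#'
#' Solves `M(q) vdot = f(q, v, tau, F_ext)` for the generalized accelerations
#' of the plant under joint torques and external point forces, including
#' gravity and the passive joint properties.  Muscles and ground contact are
#' not included here; they enter through [simulate()].
#'
#' @param plant A [plant_config()].
#' @param state A [plant_state()].
#' @param joint_torques Numeric vector of torques (N m), one per joint.
#' @param external_forces List of forces, each a list with `segment` (name),
#'   `point` (length-2, segment frame, m) and `force` (length-2, world
#'   frame, N).
#' @return A list with `qddot` (joint accelerations, rad/s^2) and, for a
#'   free base, `base_acceleration` (x, y) and `base_angular_acceleration`.
#' @export
forward_dynamics <- function(plant, state, joint_torques = NULL,
                             external_forces = list()) {
  nj <- n_joints(plant)
  if (is.null(joint_torques)) joint_torques <- numeric(nj)
  if (length(joint_torques) != nj)
    stop("need one torque per joint (", nj, ")")
  pk <- .plant_pack(plant)
  st <- .state_gen(plant, state)
  ef <- lapply(external_forces, function(e) {
    list(segment = match(e$segment, pk$seg_order) - 1L,
         point = as.numeric(e$point), force = as.numeric(e$force))
  })
  out <- .fd_core(pk, st$gp, st$gv, as.numeric(joint_torques), ef)
  gvdot <- as.numeric(out$gvdot)
  if (plant$base == "free") {
    list(base_acceleration = gvdot[1:2], base_angular_acceleration = gvdot[3],
         qddot = setNames(gvdot[-(1:3)], joint_names(plant)))
  } else {
    list(qddot = setNames(gvdot, joint_names(plant)))
  }
}

# kinematic snapshot; internal convenience
.plant_kin <- function(plant, state) {
  pk <- .plant_pack(plant)
  st <- .state_gen(plant, state)
  k <- .kin_core(pk, st$gp, st$gv)
  k$seg_order <- pk$seg_order
  k$pk <- pk
  k
}

#' Whole-body centre of mass
#'
#' Mass-weighted mean of segment CoM world positions.  For a pinned base the
#' welded root segment is excluded (it is part of the support, not of the
#' moving body).
#'
#' @inheritParams forward_dynamics
#' @return Length-2 numeric `(x, y)` in m.
#' @export
com_position <- function(plant, state) {
  k <- .plant_kin(plant, state)
  use <- .dynamic_segments(plant, k)
  m <- k$pk$mass[use]
  c(sum(m * k$com[1, use]), sum(m * k$com[2, use])) / sum(m)
}

#' @rdname com_position
#' @return `com_velocity`: length-2 numeric `(vx, vy)` in m/s.
#' @export
com_velocity <- function(plant, state) {
  k <- .plant_kin(plant, state)
  use <- .dynamic_segments(plant, k)
  m <- k$pk$mass[use]
  c(sum(m * k$comv[1, use]), sum(m * k$comv[2, use])) / sum(m)
}

.dynamic_segments <- function(plant, k) {
  if (plant$base == "free") seq_along(k$seg_order)
  else which(k$seg_order != plant$root_segment)
}

#' Base-of-support centre
#'
#' Midpoint of the anterior-posterior extent spanned by the contact sphere
#' centres (heel-most to toe-most, both feet).
#'
#' @inheritParams forward_dynamics
#' @return x-coordinate in m.
#' @export
bos_center <- function(plant, state) {
  if (!length(plant$contact_points))
    stop("plant has no contact points; base of support is undefined")
  k <- .plant_kin(plant, state)
  xs <- vapply(plant$contact_points, function(cp) {
    s <- match(cp$segment, k$seg_order)
    phi <- k$phi[s]
    k$o[1, s] + cos(phi) * cp$local_position[1] -
      sin(phi) * cp$local_position[2]
  }, 0)
  (min(xs) + max(xs)) / 2
}

#' Static joint torques to hold a posture
#'
#' Torque each joint must supply so that the zero-velocity posture has zero
#' joint accelerations under gravity, with the base supported.  For each
#' joint the torque is the gravity moment of the distal subtree about the
#' joint; when the base is free and the feet carry contact points, the
#' ground reaction (total weight, acting through the CoM vertical in static
#' balance) is distributed over the feet and included for subtrees that
#' contain contact points.
#'
#' @inheritParams forward_dynamics
#' @param posture A zero-velocity [plant_state()].
#' @return Named numeric vector of torques (N m), one per joint.
#' @export
static_joint_torques <- function(plant, posture) {
  if (any(posture$qdot != 0) || any(posture$base_velocity != 0) ||
      posture$base_angular_velocity != 0)
    stop("static_joint_torques requires a zero-velocity posture")
  if (plant$base == "free" && !length(plant$contact_points))
    stop("floating posture without support: add contact points or pin the base")
  k <- .plant_kin(plant, posture)
  g <- plant$gravity
  segs <- k$seg_order
  nj <- n_joints(plant)
  # child subtree membership per joint
  topo <- .plant_topology(plant)
  subtree <- lapply(seq_len(nj), function(j) {
    root_child <- plant$joints[[j]]$child_segment
    members <- root_child
    repeat {
      nxt <- segs[!segs %in% members & topo$parent_of[segs] %in% members]
      if (!length(nxt)) break
      members <- c(members, nxt)
    }
    members
  })
  # ground reaction distribution (free base only): total weight through the
  # CoM vertical, split between feet, then between heel and toe in each foot
  reactions <- list()
  if (plant$base == "free" && length(plant$contact_points)) {
    use <- .dynamic_segments(plant, k)
    W <- sum(k$pk$mass[use]) * g
    comx <- com_position(plant, posture)[1]
    feet <- unique(vapply(plant$contact_points, function(cp)
      if (is.null(cp$foot)) 1L else as.integer(cp$foot), 0L))
    for (f in feet) {
      cps <- Filter(function(cp) (is.null(cp$foot) && f == 1L) ||
                      identical(as.integer(cp$foot), f),
                    plant$contact_points)
      xs <- vapply(cps, function(cp) {
        s <- match(cp$segment, segs)
        phi <- k$phi[s]
        k$o[1, s] + cos(phi) * cp$local_position[1] -
          sin(phi) * cp$local_position[2]
      }, 0)
      roles <- vapply(cps, `[[`, "", "role")
      Wf <- W / length(feet)
      xh <- xs[roles == "heel"][1]; xt <- xs[roles == "toe"][1]
      if (is.na(xh) || is.na(xt)) next
      xc <- min(max(comx, min(xh, xt)), max(xh, xt))
      wt <- (xc - xh) / (xt - xh)
      reactions[[length(reactions) + 1]] <-
        list(segment = cps[[which(roles == "heel")[1]]]$segment,
             x = xh, R = Wf * (1 - wt))
      reactions[[length(reactions) + 1]] <-
        list(segment = cps[[which(roles == "toe")[1]]]$segment,
             x = xt, R = Wf * wt)
    }
  }
  seg_by_name <- setNames(seq_along(segs), segs)
  out <- numeric(nj)
  for (j in seq_len(nj)) {
    wx <- k$w[1, j]
    members <- subtree[[j]]
    s_idx <- seg_by_name[members]
    out[j] <- sum(k$pk$mass[s_idx] * g * (k$com[1, s_idx] - wx))
    for (r in reactions) {
      if (r$segment %in% members) out[j] <- out[j] - r$R * (r$x - wx)
    }
  }
  setNames(out, joint_names(plant))
}

#' Mechanical energy of the plant
#'
#' Kinetic plus gravitational potential energy (datum at world y = 0).  Used
#' primarily as an integrator diagnostic: passive conservative trajectories
#' must preserve it.
#'
#' @inheritParams forward_dynamics
#' @return Energy in J.
#' @export
mechanical_energy <- function(plant, state) {
  pk <- .plant_pack(plant)
  st <- .state_gen(plant, state)
  .energy_core(pk, st$gp, st$gv)
}
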