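# Independent numeric Lagrangian oracle. Own FK from the plant_config;
# kinetic energy via complex-step velocities (machine precision), so the
# mass matrix from the quadratic-form identity is exact; only dM/dq uses
# central differences.
oracle_fk <- function(plant, gen) {
  base_free <- plant$base == "free"
  segs <- plant$segments; names(segs) <- vapply(segs, `[[`, "", "name")
  jmap <- list(); for (j in seq_along(plant$joints)) jmap[[plant$joints[[j]]$child_segment]] <- j
  pose <- list()
  R <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  resolve <- function(name) {
    if (!is.null(pose[[name]])) return(pose[[name]])
    sg <- segs[[name]]
    if (is.null(sg$parent_joint)) {
      p <- if (base_free) list(o = gen[1:2], phi = gen[3]) else
        list(o = plant$base_pose[1:2] + 0 * gen[1], phi = plant$base_pose[3] + 0 * gen[1])
    } else {
      j <- jmap[[name]]
      jt <- plant$joints[[j]]
      pp <- resolve(jt$parent_segment)
      off <- if (base_free) 3 else 0
      w <- pp$o + R(pp$phi) %*% jt$anchor_parent
      phi <- pp$phi + gen[off + j]
      p <- list(o = drop(w - R(phi) %*% jt$anchor_child), phi = phi)
    }
    pose[[name]] <<- p
    p
  }
  out <- lapply(names(segs), function(n) {
    p <- resolve(n)
    sg <- segs[[n]]
    list(name = n, com = drop(p$o + R(p$phi) %*% sg$com_offset), phi = p$phi,
         mass = sg$mass, inertia = sg$inertia,
         dynamic = !(is.null(sg$parent_joint) && !base_free))
  })
  out
}
oracle_T <- function(plant, gp, gv) {
  h <- 1e-100
  f <- oracle_fk(plant, gp + (1i * h) * gv)
  T <- 0
  for (s in f) {
    if (!s$dynamic) next
    vcom <- Im(s$com) / h
    vphi <- Im(s$phi) / h
    T <- T + 0.5 * s$mass * sum(vcom^2) + 0.5 * s$inertia * vphi^2
  }
  T
}
oracle_V <- function(plant, gp) {
  f <- oracle_fk(plant, gp)
  sum(vapply(f, function(s)
    if (s$dynamic) s$mass * plant$gravity * Re(s$com[2]) else 0, 0))
}
oracle_M <- function(plant, gp) {
  n <- length(gp)
  M <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    ei <- numeric(n); ei[i] <- 1; ej <- numeric(n); ej[j] <- 1
    if (i == j) M[i, i] <- 2 * oracle_T(plant, gp, ei)
    else M[i, j] <- M[j, i] <- oracle_T(plant, gp, ei + ej) -
        oracle_T(plant, gp, ei) - oracle_T(plant, gp, ej)
  }
  M
}
oracle_fd <- function(plant, gp, gv, tau_gen, h = 1e-4) {
  n <- length(gp)
  M <- oracle_M(plant, gp)
  dVdq <- numeric(n); Mdot <- matrix(0, n, n); dTdq <- numeric(n)
  hc <- 1e-100
  for (k in 1:n) {
    e <- numeric(n); e[k] <- 1
    dVdq[k] <- Im(local({
      f <- oracle_fk(plant, gp + (1i * hc) * e)
      sum(vapply(f, function(s)
        if (s$dynamic) s$mass * plant$gravity * s$com[2] else 0+0i, 0+0i))
    })) / hc
    dMk <- (oracle_M(plant, gp + h * e) - oracle_M(plant, gp - h * e)) / (2 * h)
    Mdot <- Mdot + dMk * gv[k]
    dTdq[k] <- 0.5 * drop(gv %*% dMk %*% gv)
  }
  rhs <- tau_gen - dVdq - drop(Mdot %*% gv) + dTdq
  solve(M, rhs)
}

# random 1-3 link chain used by the dynamics cross-checks
mk_random_chain <- function(nl, free) {
  segs <- list(segment_spec("s0", runif(1, 0.5, 3), runif(2, -0.1, 0.1),
                            runif(1, 0.01, 0.3)))
  jts <- list()
  for (i in 1:nl) {
    segs[[i + 1]] <- segment_spec(paste0("s", i), runif(1, 0.5, 5),
                                  runif(2, -0.2, 0.3), runif(1, 0.02, 0.5),
                                  parent_joint = paste0("j", i))
    jts[[i]] <- joint_spec(paste0("j", i), paste0("s", i - 1), paste0("s", i),
                           runif(2, -0.3, 0.3), runif(2, -0.3, 0.3))
  }
  plant_config(segs, jts, base = if (free) "free" else "pinned",
               base_pose = c(runif(2, -0.2, 0.2), runif(1, -0.5, 0.5)))
}

random_chain_state <- function(plant) {
  free <- plant$base == "free"
  nj <- length(plant$joints)
  gp <- runif(nj + if (free) 3 else 0, -0.8, 0.8)
  gv <- runif(length(gp), -1, 1)
  if (free) {
    list(state = plant_state(q = gp[-(1:3)], qdot = gv[-(1:3)],
                             base_position = gp[1:2], base_orientation = gp[3],
                             base_velocity = gv[1:2],
                             base_angular_velocity = gv[3]),
         gp = gp, gv = gv)
  } else {
    list(state = plant_state(q = gp, qdot = gv), gp = gp, gv = gv)
  }
}

# simple pinned pendulum plant used across tests
pendulum_plant <- function(mass = 1, d = 0.5, I = 0.05, gravity = 9.81) {
  segs <- list(segment_spec("ground", 1, c(0, 0), 1),
               segment_spec("link", mass, c(0, d), I, parent_joint = "j"))
  jts <- list(joint_spec("j", "ground", "link", c(0, 0), c(0, 0)))
  plant_config(segs, jts, base = "pinned", gravity = gravity,
               contact_mode = "none")
}

deg2rad_t <- function(x) x * pi / 180
rad2deg_t <- function(x) x * 180 / pi
joint_names_t <- function(plant) vapply(plant$joints, `[[`, "", "name")
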