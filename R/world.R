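#' Wrap an angle to (-pi, pi]
#' @param a angle(s) in radians.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Differential-drive kinematic step
#'
#' Standard two-wheel kinematics over one time step: with left/right wheel
#' speeds `vl`, `vr`, the body advances at `v = (vl + vr)/2` and turns at
#' `omega = (vr - vl)/wheel_base`; for `omega != 0` the exact circular-arc
#' update is used.  Wheel speeds are clamped to `max_wheel_speed`.  At the
#' walls the position is clamped to the arena (heading preserved, so robots
#' slide along walls); the heading is wrapped to `(-pi, pi]`.
#'
#' @param pose numeric `c(x, y, heading)`.
#' @param wheel_speeds numeric `c(vl, vr)` in m/s.
#' @param dt time step in seconds.
#' @param cfg a [sim_config()].
#' @return Updated pose `c(x, y, heading)`.
#' @export
#' @examples
#' cfg <- sim_config()
#' step_kinematics(c(1, 1, 0), c(0.5, 0.5), 0.24, cfg)  # straight line in x
step_kinematics <- function(pose, wheel_speeds, dt, cfg) {
  stopifnot(dt > 0)
  vm <- cfg$max_wheel_speed
  vl <- min(vm, max(-vm, wheel_speeds[1]))
  vr <- min(vm, max(-vm, wheel_speeds[2]))
  v <- (vl + vr) / 2
  om <- (vr - vl) / cfg$wheel_base
  x <- pose[1]; y <- pose[2]; h <- pose[3]
  if (abs(om) < 1e-12) {
    x <- x + v * cos(h) * dt
    y <- y + v * sin(h) * dt
  } else {
    r <- v / om
    h2 <- h + om * dt
    x <- x + r * (sin(h2) - sin(h))
    y <- y - r * (cos(h2) - cos(h))
    h <- h2
  }
  lo <- cfg$robot_radius
  hi <- cfg$arena_side - cfg$robot_radius
  c(min(hi, max(lo, x)), min(hi, max(lo, y)), wrap_angle(h))
}

#' Effective vision range at a bearing
#'
#' Within `full_range_half_angle` of the optical axis a target category is
#' detectable up to its maximum range; from there the effective range
#' falls linearly to `min_detect_range` at the edge of the field of view;
#' beyond the field of view nothing is visible.
#'
#' @param bearing robot-relative bearing(s), radians.
#' @param max_range category maximum range (m).
#' @param cfg a [sim_config()].
#' @return Effective range(s); `-Inf` outside the field of view.
#' @export
effective_range <- function(bearing, max_range, cfg) {
  b <- abs(bearing)
  full <- cfg$full_range_half_angle
  fov <- cfg$fov_half_angle
  frac <- pmax(0, b - full) / (fov - full)
  r <- max_range + (cfg$min_detect_range - max_range) * frac
  r[b > fov] <- -Inf
  r
}

#' Nearest visible target per category
#'
#' Computes the percepts of an observer robot: the nearest visible energy
#' source, tail-lamp and face.  A partner robot shows its *face* to the
#' observer when its heading points within 90 degrees of the direction
#' towards the observer, and its *tail-lamp* otherwise (only while the lamp
#' is lit; the lamp is off during the post-mating refractory period).
#' Visibility combines distance against [effective_range()] for the
#' category with the bearing lying inside the field of view.
#'
#' @param observer pose `c(x, y, heading)` of the observing robot.
#' @param world list with `sources` (n x 2 matrix of positions), `robots`
#'   (m x 3 matrix of poses) and `lamp_on` (logical per robot).
#' @param cfg a [sim_config()].
#' @param self optional row index of the observer in `world$robots`
#'   (excluded from partner search).
#' @return List of three percepts (`energy_source`, `tail_lamp`, `face`),
#'   each `list(visible, distance, bearing, id)`.
#' @export
visible_targets <- function(observer, world, cfg, self = 0L) {
  ox <- observer[1]; oy <- observer[2]; oh <- observer[3]
  full <- cfg$full_range_half_angle
  fov <- cfg$fov_half_angle
  rmin <- cfg$min_detect_range
  # effective range at |bearing| b for a category with max range rmax
  eff <- function(b, rmax) {
    if (b > fov) return(-Inf)
    if (b <= full) return(rmax)
    rmax + (rmin - rmax) * (b - full) / (fov - full)
  }
  none <- list(visible = FALSE, distance = Inf, bearing = NA_real_,
               id = NA_integer_)
  out <- list(energy_source = none, tail_lamp = none, face = none)

  src <- world$sources
  if (!is.null(src) && nrow(src) > 0) {
    dx <- src[, 1] - ox; dy <- src[, 2] - oy
    d <- sqrt(dx * dx + dy * dy)
    b <- (atan2(dy, dx) - oh + pi) %% (2 * pi) - pi
    ab <- abs(b)
    rng <- cfg$detect_range_energy +
      (rmin - cfg$detect_range_energy) * pmax(0, ab - full) / (fov - full)
    vis <- ab <= fov & d <= rng
    if (any(vis)) {
      i <- which(vis)[which.min(d[vis])]
      out$energy_source <- list(visible = TRUE, distance = d[i],
                                bearing = b[i], id = i)
    }
  }

  rob <- world$robots
  if (!is.null(rob) && nrow(rob) > 0) {
    best_tail <- Inf; best_face <- Inf
    for (j in seq_len(nrow(rob))) {
      if (j == self) next
      dx <- rob[j, 1] - ox; dy <- rob[j, 2] - oy
      d <- sqrt(dx * dx + dy * dy)
      b <- (atan2(dy, dx) - oh + pi) %% (2 * pi) - pi
      # does the partner present its face or its rear to the observer?
      rel <- (rob[j, 3] - atan2(-dy, -dx) + pi) %% (2 * pi) - pi
      if (abs(rel) <= pi / 2) {
        if (d < best_face && d <= eff(abs(b), cfg$detect_range_face)) {
          best_face <- d
          out$face <- list(visible = TRUE, distance = d, bearing = b, id = j)
        }
      } else if (isTRUE(world$lamp_on[j])) {
        if (d < best_tail && d <= eff(abs(b), cfg$detect_range_tail)) {
          best_tail <- d
          out$tail_lamp <- list(visible = TRUE, distance = d, bearing = b,
                                id = j)
        }
      }
    }
  }
  out
}

#' Per-step energy metabolism
#'
#' Each time step the internal energy decreases by `E_decay_per_step`; each
#' captured energy source adds `E_gain_per_capture`, saturating at `E_max`.
#' An individual whose energy reaches zero dies.
#'
#' @param individual list with at least `energy` and `alive`.
#' @param captured number of energy sources captured this step.
#' @param cfg a [sim_config()].
#' @return The individual with updated `energy` and `alive`.
#' @export
update_energy <- function(individual, captured, cfg) {
  stopifnot(isTRUE(individual$alive))
  e <- min(cfg$E_max,
           individual$energy - cfg$E_decay_per_step +
             captured * cfg$E_gain_per_capture)
  individual$energy <- max(0, e)
  if (e <= 0) individual$alive <- FALSE
  individual
}

#' Respawn a captured energy source
#'
#' A captured source reappears at a position drawn uniformly over the
#' arena; draws too close to any robot (within a robot diameter plus the
#' capture radius, so a respawn cannot be captured in place) are rejected
#' and resampled.
#'
#' @param world world list (see [visible_targets()]).
#' @param source_id row index of the captured source.
#' @param cfg a [sim_config()].
#' @return The world with the source moved; source count unchanged.
#' @export
respawn_energy_source <- function(world, source_id, cfg) {
  clear <- cfg$robot_radius + cfg$capture_radius
  repeat {
    pos <- stats::runif(2, 0, cfg$arena_side)
    if (is.null(world$robots) || nrow(world$robots) == 0) break
    d2 <- (world$robots[, 1] - pos[1])^2 + (world$robots[, 2] - pos[2])^2
    if (all(d2 > clear^2)) break
  }
  world$sources[source_id, ] <- pos
  world
}

#' Mutual infrared mating window
#'
#' Two robots can exchange genotypes when they are within `mating_range`
#' of each other and each lies within `mating_half_angle` of the other's
#' heading (the IR ports point straight ahead).
#'
#' @param pose_a,pose_b robot poses `c(x, y, heading)`.
#' @param cfg a [sim_config()].
#' @return Logical.
#' @export
mating_condition <- function(pose_a, pose_b, cfg) {
  dx <- pose_b[1] - pose_a[1]; dy <- pose_b[2] - pose_a[2]
  if (dx * dx + dy * dy > cfg$mating_range^2) return(FALSE)
  b_ab <- wrap_angle(atan2(dy, dx) - pose_a[3])
  b_ba <- wrap_angle(atan2(-dy, -dx) - pose_b[3])
  abs(b_ab) <= cfg$mating_half_angle && abs(b_ba) <= cfg$mating_half_angle
}

#' Attempt a mating event between two individuals
#'
#' A mating initiated by `a` (via the predefined IR action) succeeds only
#' if the mutual range/angle window of [mating_condition()] holds both
#' *before and after* the two robots execute their actions, and neither
#' party is refractory.  On success each party independently reproduces
#' with probability equal to its normalized energy, creating two offspring
#' per reproducing party (offspring creation itself is the caller's job,
#' via [reproduce()]); both parties then enter the refractory state with
#' their tail-lamps off.
#'
#' @param a,b individual lists with `energy`, `alive` and `refractory`
#'   (steps remaining; 0 = not refractory).
#' @param pose_a_before,pose_b_before poses before action execution.
#' @param pose_a_after,pose_b_after poses after action execution.
#' @param cfg a [sim_config()].
#' @param ids optional integer ids of the two individuals.
#' @return A mating-event list (`energy_self`/`energy_partner` normalized,
#'   `reproduced_*` flags, `n_offspring_*` in {0, 2}) or `NULL` if the
#'   attempt fails.
#' @export
attempt_mating <- function(a, b, pose_a_before, pose_b_before,
                           pose_a_after, pose_b_after, cfg,
                           ids = c(NA_integer_, NA_integer_)) {
  if (!isTRUE(a$alive) || !isTRUE(b$alive)) return(NULL)
  if (a$refractory > 0 || b$refractory > 0) return(NULL)
  if (!mating_condition(pose_a_before, pose_b_before, cfg)) return(NULL)
  if (!mating_condition(pose_a_after, pose_b_after, cfg)) return(NULL)
  ea <- a$energy / cfg$E_max
  eb <- b$energy / cfg$E_max
  ra <- stats::runif(1) < ea
  rb <- stats::runif(1) < eb
  list(id_self = ids[1], id_partner = ids[2],
       energy_self = ea, energy_partner = eb,
       reproduced_self = ra, reproduced_partner = rb,
       n_offspring_self = if (ra) 2L else 0L,
       n_offspring_partner = if (rb) 2L else 0L)
}
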