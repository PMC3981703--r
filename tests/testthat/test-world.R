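cfg <- sim_config()

test_that("differential-drive kinematics match closed forms", {
  p0 <- c(1, 1, pi / 4)
  # zero wheel speeds leave the pose unchanged
  expect_equal(step_kinematics(p0, c(0, 0), 0.24, cfg), p0)
  # equal wheel speeds translate along the heading with no rotation
  p1 <- step_kinematics(p0, c(0.3, 0.3), 0.24, cfg)
  d <- 0.3 * 0.24
  expect_equal(p1, c(1 + d * cos(pi / 4), 1 + d * sin(pi / 4), pi / 4))
  # opposite equal speeds spin in place by (vr - vl)/wheel_base * dt
  p2 <- step_kinematics(p0, c(-0.2, 0.2), 0.24, cfg)
  expect_equal(p2[1:2], p0[1:2])
  expect_equal(p2[3], pi / 4 + (0.4 / cfg$wheel_base) * 0.24)
})

test_that("arc motion agrees with fine-step numeric integration", {
  oracle <- function(pose, vl, vr, dt, n = 40000) {
    v <- (vl + vr) / 2; om <- (vr - vl) / cfg$wheel_base
    h <- dt / n
    for (k in seq_len(n)) {
      pose <- c(pose[1] + v * cos(pose[3]) * h,
                pose[2] + v * sin(pose[3]) * h,
                pose[3] + om * h)
    }
    pose
  }
  for (sp in list(c(0.5, 0.3), c(0.1, 0.45), c(-0.2, 0.5))) {
    got <- step_kinematics(c(1.2, 1.1, 0.7), sp, 0.24, cfg)
    want <- oracle(c(1.2, 1.1, 0.7), sp[1], sp[2], 0.24)
    expect_equal(got[1:2], want[1:2], tolerance = 1e-6)
    expect_equal(got[3], wrap_angle(want[3]), tolerance = 1e-6)
  }
})

test_that("walls clamp position and preserve heading", {
  p <- step_kinematics(c(0.01, 1, pi), c(0.5, 0.5), 1, cfg)
  expect_equal(p[1], cfg$robot_radius)
  expect_equal(p[3], pi)
  p <- step_kinematics(c(2.49, 2.49, pi / 4), c(0.5, 0.5), 1, cfg)
  expect_equal(p[1:2], rep(cfg$arena_side - cfg$robot_radius, 2))
})

make_world <- function(sources = NULL, robots = NULL, lamp_on = TRUE) {
  list(sources = sources, robots = robots,
       lamp_on = rep(lamp_on, if (is.null(robots)) 0 else nrow(robots)))
}

test_that("vision ranges per category and angular falloff", {
  obs <- c(0, 1.25, 0)
  at <- function(d, bearing = 0) {
    cbind(d * cos(bearing), 1.25 + d * sin(bearing))
  }
  # energy source detectable to 2 m on the optical axis, not beyond
  w <- make_world(sources = at(1.9))
  expect_true(visible_targets(obs, w, cfg)$energy_source$visible)
  w <- make_world(sources = at(2.1))
  expect_false(visible_targets(obs, w, cfg)$energy_source$visible)
  # a face is only visible to 1 m: a robot facing us at 1.1 m is unseen
  w <- make_world(robots = rbind(c(1.1, 1.25, pi)))
  expect_false(visible_targets(obs, w, cfg)$face$visible)
  w <- make_world(robots = rbind(c(0.9, 1.25, pi)))
  expect_true(visible_targets(obs, w, cfg)$face$visible)
  # at the field-of-view edge only 0.2 m remains
  w <- make_world(sources = at(0.19, cfg$fov_half_angle - 1e-9))
  expect_true(visible_targets(obs, w, cfg)$energy_source$visible)
  w <- make_world(sources = at(0.21, cfg$fov_half_angle - 1e-9))
  expect_false(visible_targets(obs, w, cfg)$energy_source$visible)
  # midway between the full-range cone and the edge: (2.0 + 0.2)/2 = 1.1 m
  mid <- (cfg$full_range_half_angle + cfg$fov_half_angle) / 2
  expect_equal(effective_range(mid, cfg$detect_range_energy, cfg), 1.1)
  w <- make_world(sources = at(1.09, mid))
  expect_true(visible_targets(obs, w, cfg)$energy_source$visible)
  w <- make_world(sources = at(1.11, mid))
  expect_false(visible_targets(obs, w, cfg)$energy_source$visible)
})

test_that("vision is monotone: approaching targets never disappear", {
  set.seed(101)
  obs <- c(1.25, 1.25, 0.3)
  for (k in 1:200) {
    b <- runif(1, -cfg$fov_half_angle, cfg$fov_half_angle)
    d <- runif(1, 0.05, 2.2)
    ang <- obs[3] + b
    w1 <- make_world(sources = cbind(obs[1] + d * cos(ang),
                                     obs[2] + d * sin(ang)))
    w2 <- make_world(sources = cbind(obs[1] + 0.9 * d * cos(ang),
                                     obs[2] + 0.9 * d * sin(ang)))
    v1 <- visible_targets(obs, w1, cfg)$energy_source$visible
    v2 <- visible_targets(obs, w2, cfg)$energy_source$visible
    expect_true(!v1 || v2)
  }
})

test_that("face and tail-lamp visibility follow partner orientation", {
  obs <- c(1, 1, 0)
  # partner ahead, facing the observer: face visible, no tail-lamp
  w <- make_world(robots = rbind(c(1.6, 1, pi)))
  per <- visible_targets(obs, w, cfg)
  expect_true(per$face$visible)
  expect_false(per$tail_lamp$visible)
  # partner facing away: tail-lamp while lit, nothing when off
  w <- make_world(robots = rbind(c(1.6, 1, 0)))
  per <- visible_targets(obs, w, cfg)
  expect_false(per$face$visible)
  expect_true(per$tail_lamp$visible)
  w$lamp_on <- FALSE
  per <- visible_targets(obs, w, cfg)
  expect_false(per$tail_lamp$visible)
})

test_that("energy metabolism decays, saturates, and kills", {
  ind <- list(energy = 500, alive = TRUE)
  ind2 <- update_energy(ind, 0, cfg)
  expect_equal(ind2$energy, 500 - cfg$E_decay_per_step)
  expect_true(ind2$alive)
  # capture near the ceiling saturates at E_max
  ind <- list(energy = cfg$E_max - 10, alive = TRUE)
  expect_equal(update_energy(ind, 1, cfg)$energy, cfg$E_max)
  # depletion marks the individual dead
  ind <- list(energy = cfg$E_decay_per_step, alive = TRUE)
  expect_false(update_energy(ind, 0, cfg)$alive)
})

test_that("respawn conserves sources, is reproducible, and is uniform", {
  w <- make_world(sources = matrix(runif(8, 0, 2.5), ncol = 2),
                  robots = rbind(c(0.2, 0.2, 0)))
  set.seed(5)
  w1 <- respawn_energy_source(w, 2, cfg)
  expect_equal(nrow(w1$sources), 4)
  set.seed(5)
  w2 <- respawn_energy_source(w, 2, cfg)
  expect_identical(w1$sources, w2$sources)
  # chi-square uniformity over a 5x5 grid of the arena
  set.seed(99)
  pos <- matrix(NA_real_, 10000, 2)
  for (k in seq_len(nrow(pos))) {
    w <- respawn_energy_source(w, 1, cfg)
    pos[k, ] <- w$sources[1, ]
  }
  cell <- findInterval(pos[, 1], seq(0, 2.5, length.out = 6),
                       rightmost.closed = TRUE) +
    5 * (findInterval(pos[, 2], seq(0, 2.5, length.out = 6),
                      rightmost.closed = TRUE) - 1)
  counts <- tabulate(cell, 25)
  # the robot sits inside cell 1; drop it from the uniformity check
  expect_gt(stats::chisq.test(counts[-1])$p.value, 0.01)
})

test_that("mating needs the mutual window before and after the actions", {
  a <- list(energy = 800, alive = TRUE, refractory = 0)
  b <- list(energy = 600, alive = TRUE, refractory = 0)
  face_to_face <- list(c(1, 1, 0), c(1.8, 1, pi))       # 0.8 m apart
  too_far <- list(c(1, 1, 0), c(2.2, 1, pi))            # 1.2 m apart
  expect_true(mating_condition(face_to_face[[1]], face_to_face[[2]], cfg))
  expect_false(mating_condition(too_far[[1]], too_far[[2]], cfg))
  # partner facing away breaks the mutual angle condition
  expect_false(mating_condition(c(1, 1, 0), c(1.8, 1, 0), cfg))

  set.seed(1)
  ev <- attempt_mating(a, b, face_to_face[[1]], face_to_face[[2]],
                       face_to_face[[1]], face_to_face[[2]], cfg, ids = c(1, 2))
  expect_equal(ev$energy_self, 0.8)
  expect_equal(ev$energy_partner, 0.6)
  expect_true(ev$n_offspring_self %in% c(0L, 2L))
  expect_equal(ev$n_offspring_self, if (ev$reproduced_self) 2L else 0L)
  # in range before but separated after the actions: no event
  expect_null(attempt_mating(a, b, face_to_face[[1]], face_to_face[[2]],
                             too_far[[1]], too_far[[2]], cfg))
  # out of range before: no event
  expect_null(attempt_mating(a, b, too_far[[1]], too_far[[2]],
                             face_to_face[[1]], face_to_face[[2]], cfg))
  # refractory partner: no event
  b$refractory <- 10
  expect_null(attempt_mating(a, b, face_to_face[[1]], face_to_face[[2]],
                             face_to_face[[1]], face_to_face[[2]], cfg))
})
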