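cfg <- sim_config()

test_that("module selection is the sign of the weighted input sum", {
  x <- c(1, 0, -1, 0.5, -1)
  # zero weights give output 0: foraging (boundary belongs to foraging)
  expect_equal(select_module(rep(0, 5), x), "foraging")
  # bias-only positive output selects mating
  expect_equal(select_module(c(1, 0, 0, 0, 0), x), "mating")
  # hand-computed dot product: 0.2 + 0.3 + 0.2 - 0.1 = 0.6 > 0
  w <- c(0.2, 0.5, -0.3, 0.4, 0.1)
  expect_equal(sum(w * x), 0.6)
  expect_equal(select_module(w, x), "mating")
  # the refractory state forces foraging regardless of the output
  expect_equal(select_module(c(1, 0, 0, 0, 0), x, refractory = TRUE),
               "foraging")
})

test_that("input scaling hits the endpoints and decreases with distance", {
  none <- list(visible = FALSE, distance = Inf, bearing = NA, id = NA)
  seen <- function(d) list(visible = TRUE, distance = d, bearing = 0, id = 1)
  per0 <- list(energy_source = none, tail_lamp = none, face = none)
  expect_equal(unname(scale_inputs(cfg$E_max, per0, cfg)),
               c(1, 1, -1, -1, -1))
  expect_equal(unname(scale_inputs(0, per0, cfg)[2]), -1)
  expect_equal(unname(scale_inputs(500, per0, cfg)[1]), 1)  # constant bias
  # closeness channel: -1 at the category's maximum range, monotone in d
  per <- per0; per$energy_source <- seen(cfg$detect_range_energy)
  expect_equal(unname(scale_inputs(500, per, cfg)[3]), -1)
  dists <- seq(cfg$input_dist_floor, cfg$detect_range_energy, length.out = 60)
  vals <- vapply(dists, function(d) {
    per$energy_source <- seen(d)
    unname(scale_inputs(500, per, cfg)[3])
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 1)   # at the distance floor closeness saturates
  # invisible face stays -1
  expect_equal(unname(scale_inputs(500, per, cfg)[5]), -1)
})

test_that("behavior dispatch follows module and face visibility", {
  none <- list(visible = FALSE, distance = Inf, bearing = NA, id = NA)
  seen <- list(visible = TRUE, distance = 0.5, bearing = 0.1, id = 2)
  per <- list(energy_source = seen, tail_lamp = seen, face = seen)
  expect_equal(behavior_dispatch("foraging", per)$behavior, "foraging")
  expect_equal(behavior_dispatch("mating", per)$behavior, "mating")
  per$face <- none
  expect_equal(behavior_dispatch("mating", per)$behavior, "waiting")
  # nothing visible at all: waiting with the sentinel state
  per$tail_lamp <- none
  d <- behavior_dispatch("mating", per)
  expect_equal(d$behavior, "waiting")
  expect_equal(behavior_state(d$target, cfg$detect_range_tail, cfg), c(0.5, 1))
})

test_that("tile coding is deterministic with bounded feature count", {
  coder <- make_tile_coder(8, 8, seed = 3)
  s <- c(0.37, 0.62)
  f1 <- tile_features(coder, s)
  expect_length(f1, 8)
  expect_identical(f1, tile_features(coder, s))
  # a state in the same tile of every tiling activates identical features
  expect_identical(f1, tile_features(coder, s + 1e-9))
  expect_true(all(f1 >= 1 & f1 <= coder$n_features))
  # exhaustive grid never exceeds the table size, and out-of-range clamps
  grid <- expand.grid(seq(0, 1, length.out = 41), seq(0, 1, length.out = 41))
  feats <- unique(as.vector(apply(grid, 1,
                                  function(s) tile_features(coder, s))))
  expect_lte(length(feats), 8 * 8 * 8)
  expect_identical(tile_features(coder, c(2, -1)), tile_features(coder, c(1, 0)))
})

test_that("shaping rewards telescope and match the defining formula", {
  expect_equal(shaping_reward(1, 2, 0.9), 0.8)
  # constant potential with undiscounted returns contributes nothing
  expect_equal(shaping_reward(3, 3, 1), 0)
  # terminal transitions pin the successor potential at zero
  expect_equal(shaping_reward(2, 5, 0.9, terminal = TRUE), -2)
  # discounted sum over any trajectory telescopes to g^T phi_T - phi_0
  set.seed(8)
  gam <- 0.93
  phi <- rnorm(11)
  incr <- vapply(1:10, function(t) shaping_reward(phi[t], phi[t + 1], gam),
                 numeric(1))
  expect_equal(sum(gam^(0:9) * incr), gam^10 * phi[11] - phi[1])
})

test_that("meta genes decode into their documented ranges", {
  set.seed(2)
  for (k in 1:50) {
    m <- decode_meta(runif(4, -30, 30))
    expect_true(m$alpha > 0 && m$alpha <= 0.5)
    expect_true(m$gamma >= 0.8 && m$gamma < 1)
    expect_true(m$lambda >= 0 && m$lambda < 1)
    expect_true(m$temperature > 0 && m$temperature <= 1)
  }
})

test_that("Sarsa updates fix points and single steps exactly", {
  lrn <- sarsa_learner(10, 3, alpha = 0.5, gamma = 0.9)
  # all-zero table, terminal reward 1: Q becomes alpha * 1 = 0.5
  sarsa_update(lrn, "default", 4L, 2L, 1, terminal = TRUE)
  expect_equal(lrn$Q$default[4, 2], 0.5)
  # zero temporal-difference error leaves the table unchanged
  lrn2 <- sarsa_learner(10, 3, alpha = 0.5, gamma = 0.5)
  lrn2$Q$default[1, 1] <- 1
  lrn2$Q$default[2, 1] <- 2
  before <- lrn2$Q$default
  sarsa_update(lrn2, "default", 1L, 1L, 0, 2L, 1L)  # 0 + 0.5*2 - 1 = 0
  expect_equal(lrn2$Q$default, before)
  # learning rate is divided across active tiles
  lrn3 <- sarsa_learner(10, 2, alpha = 0.4, gamma = 0.9)
  sarsa_update(lrn3, "default", c(1L, 5L), 1L, 1, terminal = TRUE)
  expect_equal(lrn3$Q$default[1, 1], 0.2)
  expect_equal(lrn3$Q$default[5, 1], 0.2)
})

test_that("softmax exploration is uniform at equal values, greedy at low T", {
  lrn <- sarsa_learner(4, 5, temperature = 0.5)
  set.seed(31)
  draws <- replicate(10000, select_action(lrn, "default", 1L))
  freq <- tabulate(draws, 5) / 10000
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_true(all(abs(freq - 0.2) < 3 * se))
  # near-zero temperature picks the argmax
  lrn$Q$default[1, ] <- c(0, 0.3, 0.1, 0.05, 0.29)
  greedy <- replicate(200, select_action(lrn, "default", 1L,
                                         temperature = 1e-8))
  expect_true(all(greedy == 2L))
  # fixed seed reproduces the action sequence
  set.seed(7); a1 <- replicate(50, select_action(lrn, "default", 1L))
  set.seed(7); a2 <- replicate(50, select_action(lrn, "default", 1L))
  expect_identical(a1, a2)
})

test_that("Sarsa converges to the value-iteration solution on the chain", {
  gam <- 0.9
  q_star <- chain_q_star(gam)
  set.seed(12)
  q <- run_chain_sarsa(6000, alpha = 0.3, gamma = gam, temperature = 0.02)
  expect_lt(max(abs(q - q_star)), 1e-2)
})

test_that("bounded shaping leaves the learned greedy policy unchanged", {
  gam <- 0.9
  set.seed(21)
  q_plain <- run_chain_sarsa(4000, gamma = gam)
  for (rep in 1:3) {
    phi <- runif(4, -2, 2)
    q_shaped <- run_chain_sarsa(4000, gamma = gam, phi = phi)
    expect_identical(apply(q_shaped, 1, which.max),
                     apply(q_plain, 1, which.max))
  }
})

test_that("eligibility traces accelerate credit propagation backwards", {
  # one episode along a 4-step corridor: with traces the early states
  # already receive credit, with plain Sarsa only the final one does
  lrn <- sarsa_learner(4, 1, alpha = 0.5, gamma = 1, lambda = 0.9)
  for (s in 1:3) sarsa_update(lrn, "default", s, 1L, 0, s + 1L, 1L)
  sarsa_update(lrn, "default", 4L, 1L, 1, terminal = TRUE)
  expect_true(all(lrn$Q$default[, 1] > 0))
  lrn0 <- sarsa_learner(4, 1, alpha = 0.5, gamma = 1, lambda = 0)
  for (s in 1:3) sarsa_update(lrn0, "default", s, 1L, 0, s + 1L, 1L)
  sarsa_update(lrn0, "default", 4L, 1L, 1, terminal = TRUE)
  expect_equal(lrn0$Q$default[1:3, 1], rep(0, 3))
  expect_gt(lrn0$Q$default[4, 1], 0)
})
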