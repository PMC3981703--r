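# small configurations and shared fixtures for the test suite

# short-lifetime colony for structural tests (240-step lifetimes)
tiny_cfg <- function(...) {
  sim_config(subpop_size = 4L, steps_per_period = 80L, ...)
}

# geometry opened up so that matings actually happen in short runs:
# wide IR window and long refractory-free periods
social_cfg <- function(...) {
  sim_config(subpop_size = 4L, steps_per_period = 120L,
             mating_half_angle = pi, mating_range = 1.5,
             n_energy_sources = 8L, ...)
}

gene_matrix <- function(pop) {
  as.matrix(pop[, paste0("gene_", seq_len(51))])
}

# lazily cached tiny evolution run reused across test files
tiny_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(run_evolution(social_cfg(), 2, seed = 42))
    }
    cache
  }
})

# two-phenotype simplex lattice at the tested mixture resolution
simplex_grid_2 <- function(step = 0.125) {
  p1 <- seq(0, 1, by = step)
  cbind(p1, 1 - p1)
}

# independent bisection oracle for the waiting threshold: smallest E in
# [0, 1] with positive network output at face input -1
bisect_threshold <- function(w, x_b, x_t, tol = 1e-9) {
  out <- function(E) w[1] + w[2] * (2 * E - 1) + w[3] * x_b + w[4] * x_t - w[5]
  if (out(1) <= 0) return(1)
  if (out(0) > 0) return(0)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (out(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# exact value iteration for the 5-state deterministic chain used in the
# Sarsa convergence tests; moving right from state 4 reaches the terminal
# state with reward 1, every other transition has reward 0
chain_q_star <- function(gamma, n_states = 5) {
  ns <- n_states - 1  # non-terminal states
  Q <- matrix(0, ns, 2)  # actions: 1 = left, 2 = right
  repeat {
    Qn <- Q
    for (s in seq_len(ns)) {
      s_left <- max(1, s - 1)
      Qn[s, 1] <- gamma * max(Q[s_left, ])
      Qn[s, 2] <- if (s == ns) 1 else gamma * max(Q[s + 1, ])
    }
    if (max(abs(Qn - Q)) < 1e-12) break
    Q <- Qn
  }
  Q
}

# run tabular Sarsa on the chain with exploring starts and a near-greedy
# softmax policy; phi is an optional shaping potential over states.
# Episodes are capped: shaping can transiently trap a near-greedy policy
# in the state-1 self-loop, so long episodes restart from a fresh
# exploring start (the cap never triggers for the unshaped chain).
run_chain_sarsa <- function(episodes, alpha = 0.3, gamma = 0.9,
                            temperature = 0.02, phi = rep(0, 4),
                            max_steps = 60) {
  lrn <- sarsa_learner(n_features = 4, n_actions = 2, alpha = alpha,
                       gamma = gamma, temperature = temperature)
  for (ep in seq_len(episodes)) {
    s <- sample.int(4, 1)
    a <- sample.int(2, 1)          # exploring start
    for (k in seq_len(max_steps)) {
      if (a == 2 && s == 4) {      # terminal transition
        sarsa_update(lrn, "default", s, a, 1,
                     shaping = shaping_reward(phi[s], 0, gamma, terminal = TRUE),
                     terminal = TRUE)
        break
      }
      s2 <- if (a == 2) s + 1 else max(1, s - 1)
      a2 <- select_action(lrn, "default", s2)
      sarsa_update(lrn, "default", s, a, 0, s2, a2,
                   shaping = shaping_reward(phi[s], phi[s2], gamma))
      s <- s2; a <- a2
    }
  }
  lrn$Q$default
}
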