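#' Scale sensory inputs for the strategy network
#'
#' The five network inputs are the constant bias 1, the internal energy and
#' the closeness of the nearest energy source, tail-lamp and face, all in
#' `[-1, 1]`.  Energy maps affinely: `x_energy = 2 E / E_max - 1`.  Each
#' distance channel uses the inverse distance `1/d`, clamped to
#' `[1/R_cat, 1/d_floor]` (`R_cat` the category's maximum range, `d_floor`
#' the closest meaningful distance) and then mapped affinely to `[-1, 1]`,
#' so closeness increases as the target approaches.  An invisible target
#' is coded as -1.
#'
#' @param energy internal energy in `[0, E_max]`.
#' @param percepts percept list from [visible_targets()].
#' @param cfg a [sim_config()].
#' @return Named numeric vector `c(bias, energy, battery, tail, face)`.
#' @export
scale_inputs <- function(energy, percepts, cfg) {
  if (energy < 0 || energy > cfg$E_max) stop("energy outside [0, E_max]")
  hi <- 1 / cfg$input_dist_floor
  chan <- function(p, max_range) {
    if (!p$visible) return(-1)
    inv <- 1 / max(p$distance, cfg$input_dist_floor)
    lo <- 1 / max_range
    inv <- min(hi, max(lo, inv))
    2 * (inv - lo) / (hi - lo) - 1
  }
  c(bias = 1,
    energy = 2 * energy / cfg$E_max - 1,
    battery = chan(percepts$energy_source, cfg$detect_range_energy),
    tail = chan(percepts$tail_lamp, cfg$detect_range_tail),
    face = chan(percepts$face, cfg$detect_range_face))
}

#' Top-level module selection
#'
#' The linear strategy network computes the weighted sum of the five scaled
#' inputs; a strictly positive output selects the mating module, otherwise
#' the foraging module.  After a successful mating the mating module is
#' unavailable until the refractory state clears (`refractory = TRUE`
#' forces foraging).
#'
#' @param weights length-5 strategy weights.
#' @param input length-5 scaled input vector (see [scale_inputs()]).
#' @param refractory is the individual in its post-mating refractory state?
#' @return `"mating"` or `"foraging"`.
#' @export
#' @examples
#' select_module(c(0.2, 0.5, -0.3, 0.4, 0.1), c(1, 0, -1, 0.5, -1))
select_module <- function(weights, input, refractory = FALSE) {
  stopifnot(length(weights) == 5, length(input) == 5)
  if (refractory) return("foraging")
  if (sum(weights * input) > 0) "mating" else "foraging"
}

#' Behaviour dispatch within a module
#'
#' The foraging module always executes the foraging behaviour (target:
#' nearest energy source).  The mating module executes the mating
#' behaviour when a face is visible, and the waiting behaviour (target:
#' nearest tail-lamp) otherwise -- including when no tail-lamp is visible
#' either, in which case the waiting state carries the invisible sentinel.
#'
#' @param module `"foraging"` or `"mating"`.
#' @param percepts percept list from [visible_targets()].
#' @return List with `behavior` (`"foraging"`, `"waiting"`, `"mating"`)
#'   and `target` (the corresponding percept).
#' @export
behavior_dispatch <- function(module, percepts) {
  if (module == "foraging") {
    list(behavior = "foraging", target = percepts$energy_source)
  } else if (isTRUE(percepts$face$visible)) {
    list(behavior = "mating", target = percepts$face)
  } else {
    list(behavior = "waiting", target = percepts$tail_lamp)
  }
}

#' Normalized behaviour state
#'
#' Each behaviour learner sees the (relative angle, distance) pair of its
#' target, normalized to the unit square: angle from `-fov` .. `fov` to
#' `[0, 1]`, distance by the category's maximum range.  An invisible
#' target maps to the sentinel state (0.5, 1): straight ahead at maximal
#' distance.
#'
#' @param target a percept (`list(visible, distance, bearing, ...)`).
#' @param max_range the behaviour target category's maximum range.
#' @param cfg a [sim_config()].
#' @return Numeric `c(angle, distance)` in `[0, 1]^2`.
#' @export
behavior_state <- function(target, max_range, cfg) {
  if (!isTRUE(target$visible)) return(c(0.5, 1))
  a <- (target$bearing + cfg$fov_half_angle) / (2 * cfg$fov_half_angle)
  d <- target$distance / max_range
  c(min(1, max(0, a)), min(1, max(0, d)))
}

#' Tile coder over the unit square
#'
#' `n_tilings` overlapping `tiles_per_dim` x `tiles_per_dim` grids with
#' deterministic pseudo-random offsets derived from `seed`.  A state
#' activates exactly one tile per tiling.
#'
#' @param n_tilings number of tilings.
#' @param tiles_per_dim tiles per dimension of each tiling.
#' @param seed integer seed for the tiling offsets.
#' @return A `tile_coder` object.
#' @export
make_tile_coder <- function(n_tilings = 8L, tiles_per_dim = 8L, seed = 0L) {
  stopifnot(n_tilings >= 1, tiles_per_dim >= 1)
  off <- withr_seed(seed, function() {
    matrix(stats::runif(n_tilings * 2, 0, 1 / tiles_per_dim), ncol = 2)
  })
  structure(list(n_tilings = as.integer(n_tilings),
                 tiles_per_dim = as.integer(tiles_per_dim),
                 offsets = off,
                 n_features = as.integer(n_tilings * tiles_per_dim^2)),
            class = "tile_coder")
}

# run fn() under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Active tile features of a state
#'
#' @param coder a [make_tile_coder()] object.
#' @param state numeric `c(s1, s2)`; values outside `[0, 1]` are clamped.
#' @return Integer vector of `n_tilings` active feature indices (1-based,
#'   in `1..n_features`).
#' @export
tile_features <- function(coder, state) {
  s1 <- min(1, max(0, state[1]))
  s2 <- min(1, max(0, state[2]))
  m <- coder$tiles_per_dim
  i1 <- pmin(m - 1L, floor((s1 + coder$offsets[, 1]) * m))
  i2 <- pmin(m - 1L, floor((s2 + coder$offsets[, 2]) * m))
  as.integer((seq_len(coder$n_tilings) - 1L) * m * m + i1 * m + i2 + 1L)
}

# fixed Gaussian radial bases of the shaping potentials:
# 7 angle centres x 2 distance centres on the unit square, width 0.25
shaping_centers <- function() {
  ang <- seq(0, 1, length.out = 7)
  cbind(angle = rep(ang, 2), dist = rep(c(0.25, 0.75), each = 7))
}
.shaping_mu1 <- rep(seq(0, 1, length.out = 7), 2)
.shaping_mu2 <- rep(c(0.25, 0.75), each = 7)

#' Evaluate a shaping potential
#'
#' Each behaviour's shaping potential is a linear combination of 14 fixed
#' Gaussian bases on the normalized (angle, distance) square (7 angle
#' centres x 2 distance centres, width 0.25), with the 14 coefficients
#' taken from the genotype's shaping genes.  The potential feeds the
#' potential-based shaping reward of [shaping_reward()], so it can
#' accelerate learning without changing what is optimal.
#'
#' @param coef numeric vector of 14 basis coefficients.
#' @param state numeric `c(angle, distance)` in `[0, 1]^2`.
#' @return Scalar potential value.
#' @export
shaping_potential <- function(coef, state) {
  if (length(coef) != 14) stop("a shaping potential has 14 coefficients")
  d2 <- (state[1] - .shaping_mu1)^2 + (state[2] - .shaping_mu2)^2
  sum(coef * exp(d2 * -8))   # width 0.25: 1/(2 * 0.25^2) = 8
}

#' Potential-based shaping reward
#'
#' The auxiliary reward for a transition `s -> s'` is
#' \deqn{F = \gamma \Phi(s') - \Phi(s),}
#' with \eqn{\Phi(terminal) = 0}.  Summed over an episode the increments
#' telescope to \eqn{\gamma^T \Phi(s_T) - \Phi(s_0)}, which is why shaping
#' leaves optimal policies unchanged.
#'
#' @param phi_s potential at the current state.
#' @param phi_next potential at the next state.
#' @param gamma discount factor.
#' @param terminal is the transition terminal? (forces \eqn{\Phi(s') = 0}).
#' @return The shaping increment.
#' @export
#' @examples
#' shaping_reward(1, 2, 0.9)  # 0.8
shaping_reward <- function(phi_s, phi_next, gamma, terminal = FALSE) {
  stopifnot(is.finite(phi_s), is.finite(phi_next))
  if (terminal) phi_next <- 0
  gamma * phi_next - phi_s
}

#' Decode the four meta-parameter genes
#'
#' The raw meta genes pass through fixed squashing maps (logistic
#' \eqn{\sigma}) to the learner meta-parameters: learning rate
#' \eqn{0.5\,\sigma(g_1) \in (0, 0.5]}, discount
#' \eqn{0.8 + 0.2\,\sigma(g_2) \in [0.8, 1)}, trace decay
#' \eqn{\max(0, 2\sigma(g_3) - 1) \in [0, 1)} (plain Sarsa for half the
#' gene range), and softmax temperature \eqn{\sigma(g_4) \in (0, 1]}.
#'
#' @param meta_genes numeric vector of 4 raw genes.
#' @return Named list `alpha`, `gamma`, `lambda`, `temperature`.
#' @export
decode_meta <- function(meta_genes) {
  stopifnot(length(meta_genes) == 4, all(is.finite(meta_genes)))
  sig <- function(g) 1 / (1 + exp(-g))
  list(alpha = 0.5 * sig(meta_genes[1]),
       gamma = 0.8 + 0.2 * sig(meta_genes[2]),
       lambda = max(0, 2 * sig(meta_genes[3]) - 1),
       temperature = sig(meta_genes[4]))
}

#' Create a Sarsa learner with tile-coded features
#'
#' Action values are linear in binary tile features; with several active
#' features per state the learning rate is divided across them.  The
#' learner is an environment (reference semantics): [sarsa_update()] and
#' [select_action()] mutate it in place.  One learner can hold several
#' behaviours, each with its own action-value table and eligibility
#' traces; tables start at zero and are rebuilt from scratch at every
#' generation.
#'
#' @param n_features number of features per behaviour table.
#' @param n_actions number of actions (vector, one per behaviour, or
#'   scalar recycled).
#' @param alpha learning rate.
#' @param gamma discount factor.
#' @param lambda eligibility-trace decay (0 = plain Sarsa).
#' @param temperature softmax exploration temperature.
#' @param behaviors character names of the behaviours.
#' @return A `sarsa_learner` environment.
#' @export
sarsa_learner <- function(n_features, n_actions, alpha = 0.1, gamma = 0.9,
                          lambda = 0, temperature = 0.1,
                          behaviors = "default") {
  stopifnot(alpha > 0, gamma >= 0, gamma <= 1, lambda >= 0, lambda < 1,
            temperature > 0)
  n_actions <- rep_len(as.integer(n_actions), length(behaviors))
  lrn <- new.env(parent = emptyenv())
  lrn$alpha <- alpha; lrn$gamma <- gamma
  lrn$lambda <- lambda; lrn$temperature <- temperature
  lrn$behaviors <- behaviors
  lrn$n_features <- as.integer(n_features)
  lrn$Q <- lapply(n_actions, function(na) {
    matrix(0, nrow = n_features, ncol = na)
  })
  names(lrn$Q) <- behaviors
  lrn$z_cell <- stats::setNames(vector("list", length(behaviors)), behaviors)
  lrn$z_val <- stats::setNames(vector("list", length(behaviors)), behaviors)
  class(lrn) <- c("sarsa_learner", "environment")
  lrn
}

#' Action value of a feature set
#' @param learner a [sarsa_learner()].
#' @param behavior behaviour name.
#' @param feats active feature indices.
#' @return Numeric vector of action values.
#' @export
action_values <- function(learner, behavior, feats) {
  q <- learner$Q[[behavior]]
  if (length(feats) == 1L) q[feats, ] else colSums(q[feats, , drop = FALSE])
}

#' Softmax action selection
#'
#' Samples an action from the Boltzmann distribution over the action
#' values at the learner's temperature; as the temperature approaches
#' zero this becomes greedy.
#'
#' @inheritParams action_values
#' @param temperature optional override of the learner's temperature.
#' @return Integer action index.
#' @export
select_action <- function(learner, behavior, feats, temperature = NULL) {
  q <- action_values(learner, behavior, feats)
  tau <- if (is.null(temperature)) learner$temperature else temperature
  if (tau <= 0) stop("temperature must be > 0")
  w <- exp((q - max(q)) / tau)
  sample.int(length(q), 1L, prob = w)
}

#' Sarsa update over active tiles
#'
#' On-policy temporal-difference update
#' \deqn{Q(s,a) \leftarrow Q(s,a) + \alpha [r + F + \gamma Q(s',a') - Q(s,a)]}
#' applied across the active tiles (learning rate divided by the number of
#' active features), where `r` is the global reward and `F` an optional
#' shaping increment.  With `lambda > 0`, replacing eligibility traces
#' spread the temporal-difference error over recently visited tiles; a
#' terminal transition uses target `r + F` and clears the traces.
#'
#' @inheritParams action_values
#' @param action action taken at `s`.
#' @param reward global reward received.
#' @param feats_next,action_next successor feature set and action (ignored
#'   for terminal transitions).
#' @param shaping shaping-reward increment to add to the target.
#' @param terminal is this transition terminal?
#' @return The temporal-difference error, invisibly.  The learner is
#'   modified in place.
#' @export
sarsa_update <- function(learner, behavior, feats, action, reward,
                         feats_next = NULL, action_next = NULL,
                         shaping = 0, terminal = FALSE) {
  q_sa <- sum(learner$Q[[behavior]][feats, action])
  q_next <- if (terminal) 0 else {
    sum(learner$Q[[behavior]][feats_next, action_next])
  }
  delta <- reward + shaping + learner$gamma * q_next - q_sa
  k <- length(feats)
  nf <- learner$n_features
  cells <- feats + (action - 1L) * nf
  if (learner$lambda > 0) {
    zc <- learner$z_cell[[behavior]]
    zv <- learner$z_val[[behavior]]
    if (length(zc)) {
      zv <- zv * learner$gamma * learner$lambda
      keep <- zv > 1e-6 & !(zc %in% cells)
      zc <- zc[keep]; zv <- zv[keep]
    }
    zc <- c(zc, cells)
    zv <- c(zv, rep(1 / k, k))        # replacing traces
    learner$Q[[behavior]][zc] <- learner$Q[[behavior]][zc] +
      learner$alpha * delta * zv
    if (terminal) {
      learner$z_cell[[behavior]] <- integer(0)
      learner$z_val[[behavior]] <- numeric(0)
    } else {
      learner$z_cell[[behavior]] <- zc
      learner$z_val[[behavior]] <- zv
    }
  } else {
    learner$Q[[behavior]][cells] <- learner$Q[[behavior]][cells] +
      (learner$alpha / k) * delta
  }
  invisible(delta)
}
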