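#' Time-sharing schedule of a generation
#'
#' Each robot hosts a subpopulation of individuals that take control of it
#' in random order, for `periods_per_lifetime` periods of
#' `steps_per_period` steps each.  The schedule concatenates one
#' independent random permutation of the subpopulation per period slot, so
#' every individual appears exactly `periods_per_lifetime` times and each
#' robot serves `subpop_size * periods_per_lifetime` robot-periods.
#'
#' @param n_robots number of robots.
#' @param subpop_size individuals per robot.
#' @param periods periods per lifetime.
#' @return Integer matrix, `subpop_size * periods` rows x `n_robots`
#'   columns, of local individual indices (1..subpop_size).
#' @export
make_schedule <- function(n_robots, subpop_size, periods) {
  stopifnot(n_robots >= 1, subpop_size >= 1, periods >= 1)
  sched <- matrix(0L, nrow = subpop_size * periods, ncol = n_robots)
  for (r in seq_len(n_robots)) {
    sched[, r] <- unlist(lapply(seq_len(periods),
                                function(p) sample.int(subpop_size)))
  }
  sched
}

#' Resample a subpopulation from its offspring pool
#'
#' A new subpopulation of fixed size is drawn uniformly from the offspring
#' reproduced during the last generation: without replacement when the
#' pool is large enough, with replacement otherwise.  An empty pool
#' triggers random re-initialization (with a warning): the lineage died
#' out.
#'
#' @param pool matrix of offspring genotypes (possibly 0 rows).
#' @param subpop_size target subpopulation size.
#' @return `subpop_size` x 51 genotype matrix.
#' @export
next_generation <- function(pool, subpop_size) {
  if (is.null(pool) || nrow(pool) == 0) {
    warning("empty offspring pool: reinitializing subpopulation at random")
    return(random_genotype(subpop_size))
  }
  idx <- if (nrow(pool) >= subpop_size) {
    sample.int(nrow(pool), subpop_size)
  } else {
    sample.int(nrow(pool), subpop_size, replace = TRUE)
  }
  pool[idx, , drop = FALSE]
}

# wheel-speed action set: forward, two arcs, two spins (+ IR initiation for
# the mating behaviour, which keeps the wheels still)
action_table <- function(cfg) {
  v <- cfg$max_wheel_speed
  rbind(forward    = c(v, v),
        arc_left   = c(v / 3, v),
        arc_right  = c(v, v / 3),
        spin_left  = c(-v / 2, v / 2),
        spin_right = c(v / 2, -v / 2),
        ir_mate    = c(0, 0))
}

BEHAVIORS <- c("foraging", "waiting", "mating")

# event log accumulator (amortized append)
event_buffer <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$step <- integer(256); env$robot <- integer(256)
  env$ind <- integer(256); env$event <- character(256)
  env$energy <- numeric(256); env$partner <- integer(256)
  env
}

event_add <- function(buf, step, robot, ind, event, energy, partner = NA_integer_) {
  n <- buf$n + 1L
  if (n > length(buf$step)) {
    grow <- function(x) c(x, x)
    buf$step <- grow(buf$step); buf$robot <- grow(buf$robot)
    buf$ind <- grow(buf$ind); buf$event <- grow(buf$event)
    buf$energy <- grow(buf$energy); buf$partner <- grow(buf$partner)
  }
  buf$step[n] <- step; buf$robot[n] <- robot; buf$ind[n] <- ind
  buf$event[n] <- event; buf$energy[n] <- energy; buf$partner[n] <- partner
  buf$n <- n
  invisible(buf)
}

event_frame <- function(buf) {
  n <- buf$n
  data.frame(step = buf$step[seq_len(n)], robot_id = buf$robot[seq_len(n)],
             individual_id = buf$ind[seq_len(n)], event = buf$event[seq_len(n)],
             energy = buf$energy[seq_len(n)], partner_id = buf$partner[seq_len(n)])
}

#' Simulate one generation of the robot colony
#'
#' Runs the full arena simulation for one generation: the individuals of
#' each robot's subpopulation take control according to a fresh random
#' schedule, perceive the world, select modules with their strategy
#' network, learn their behaviours from scratch by Sarsa with tile coding
#' and genotype-defined shaping rewards, capture energy sources, and mate
#' by mutual infrared contact.  Reproduction feeds the per-robot offspring
#' pools; no selection happens here.
#'
#' When a controller dies the robot is handed to the next scheduled
#' individual immediately (each service lasts a full
#' `steps_per_period` unless cut short by death or the generation end, so
#' surviving individuals accumulate exactly
#' `steps_per_period * periods_per_lifetime` control steps).
#'
#' @param genotypes `(n_robots * subpop_size)` x 51 genotype matrix;
#'   individual `i` belongs to robot `ceiling(i / subpop_size)`.
#' @param cfg a [sim_config()].
#' @param phenotype optional character vector of per-individual phenotype
#'   labels; when given, per-partner-phenotype mating counts are recorded.
#' @return List with `stats` (per-individual data frame), `events`
#'   (event-log data frame), `pools` (per-robot offspring genotype
#'   matrices) and, with phenotypes, `mating_mix` (individual x phenotype
#'   count matrix).  Uses the current RNG state.
#' @export
simulate_generation <- function(genotypes, cfg, phenotype = NULL) {
  ns <- cfg$subpop_size; nr <- cfg$n_robots
  n <- ns * nr
  stopifnot(nrow(genotypes) == n, ncol(genotypes) == GENOME_LENGTH)
  robot_of <- rep(seq_len(nr), each = ns)
  lifetime <- cfg$steps_per_period * cfg$periods_per_lifetime
  n_world_steps <- ns * cfg$periods_per_lifetime * cfg$steps_per_period
  acts <- action_table(cfg)
  ranges <- c(foraging = cfg$detect_range_energy,
              waiting = cfg$detect_range_tail,
              mating = cfg$detect_range_face)
  coder <- make_tile_coder(cfg$n_tilings, cfg$tiles_per_dim, cfg$rng_seed)
  n_feat <- coder$n_features
  E_max_c <- cfg$E_max; E_decay_c <- cfg$E_decay_per_step
  E_gain_c <- cfg$E_gain_per_capture
  capture_r2 <- cfg$capture_radius^2
  refractory_c <- cfg$refractory_steps
  dt_c <- cfg$time_step

  # decode genotypes
  weights <- genotypes[, STRATEGY_GENES, drop = FALSE]
  shaping <- lapply(seq_len(n), function(i) {
    matrix(genotypes[i, SHAPING_GENES], nrow = 3, byrow = TRUE)
  })
  learners <- lapply(seq_len(n), function(i) {
    m <- decode_meta(genotypes[i, META_GENES])
    sarsa_learner(n_feat, c(5L, 5L, 6L), alpha = m$alpha, gamma = m$gamma,
                  lambda = m$lambda, temperature = m$temperature,
                  behaviors = BEHAVIORS)
  })

  # per-individual state
  energy <- rep(cfg$E_birth, n); alive <- rep(TRUE, n)
  refract <- rep(0L, n)
  captures <- integer(n); matings <- integer(n)
  sumE <- numeric(n); sumEp <- numeric(n)
  offspring_attr <- integer(n)
  steps_beh <- matrix(0L, n, 3)
  control_steps <- integer(n); death_step <- rep(NA_integer_, n)
  opp_steps <- integer(n); opp_forage <- integer(n)
  K <- 0L
  if (!is.null(phenotype)) {
    stopifnot(length(phenotype) == n)
    phen_lev <- sort(unique(phenotype))
    K <- length(phen_lev)
    phen_idx <- match(phenotype, phen_lev)
    mix_counts <- matrix(0L, n, K, dimnames = list(NULL, phen_lev))
  }

  # world state
  world <- list(
    sources = matrix(stats::runif(cfg$n_energy_sources * 2, 0, cfg$arena_side),
                     ncol = 2),
    robots = cbind(stats::runif(nr, cfg$robot_radius, cfg$arena_side - cfg$robot_radius),
                   stats::runif(nr, cfg$robot_radius, cfg$arena_side - cfg$robot_radius),
                   stats::runif(nr, -pi, pi)),
    lamp_on = rep(TRUE, nr)
  )

  # schedule and control
  sched <- make_schedule(nr, ns, cfg$periods_per_lifetime)
  qptr <- integer(nr); controller <- rep(NA_integer_, nr)
  slot_left <- integer(nr)
  # previous RL step per robot (for the controller's pending Sarsa update)
  prev_beh <- integer(nr); prev_feats <- vector("list", nr)
  prev_act <- integer(nr); prev_phi <- numeric(nr)
  pend_reward <- numeric(nr)

  pools <- lapply(seq_len(nr), function(r) {
    matrix(numeric(0), ncol = GENOME_LENGTH)
  })
  buf <- event_buffer()

  flush_learner <- function(r) {
    # terminal Sarsa update for the outgoing transition of robot r
    i <- controller[r]
    if (!is.na(i) && prev_beh[r] > 0L) {
      b <- BEHAVIORS[prev_beh[r]]
      sarsa_update(learners[[i]], b, prev_feats[[r]], prev_act[r],
                   pend_reward[r], shaping = -prev_phi[r], terminal = TRUE)
    }
    prev_beh[r] <<- 0L; pend_reward[r] <<- 0
  }

  advance_controller <- function(r) {
    flush_learner(r)
    controller[r] <<- NA_integer_
    while (qptr[r] < nrow(sched)) {
      qptr[r] <<- qptr[r] + 1L
      cand <- (r - 1L) * ns + sched[qptr[r], r]
      if (alive[cand] && control_steps[cand] < lifetime) {
        controller[r] <<- cand
        slot_left[r] <<- cfg$steps_per_period
        break
      }
    }
  }
  for (r in seq_len(nr)) advance_controller(r)

  for (t in seq_len(n_world_steps)) {
    ctrl <- controller
    lamp <- !is.na(ctrl)
    lamp[lamp] <- refract[ctrl[lamp]] == 0L & alive[ctrl[lamp]]
    world$lamp_on <- lamp
    active <- which(!is.na(ctrl))
    if (length(active) == 0) break

    initiated <- rep(FALSE, nr)
    chosen_b <- integer(nr)
    chosen_feats <- vector("list", nr)
    chosen_act <- integer(nr)
    chosen_phi <- numeric(nr)
    poses_before <- world$robots
    wheel <- matrix(0, nr, 2)

    for (r in active) {
      i <- ctrl[r]
      per <- visible_targets(poses_before[r, ], world, cfg, self = r)
      x <- scale_inputs(energy[i], per, cfg)
      refr <- refract[i] > 0L
      module <- select_module(weights[i, ], x, refractory = refr)
      # opportunism census: only an energy source in sight
      if (per$energy_source$visible && !per$tail_lamp$visible &&
          !per$face$visible) {
        opp_steps[i] <- opp_steps[i] + 1L
        if (module == "foraging") opp_forage[i] <- opp_forage[i] + 1L
      }
      disp <- behavior_dispatch(module, per)
      b <- match(disp$behavior, BEHAVIORS)
      st <- behavior_state(disp$target, ranges[[b]], cfg)
      feats <- tile_features(coder, st)
      phi <- shaping_potential(shaping[[i]][b, ], st)
      a <- select_action(learners[[i]], disp$behavior, feats)

      # Sarsa update of the pending transition
      if (prev_beh[r] > 0L) {
        if (prev_beh[r] == b) {
          F_sh <- learners[[i]]$gamma * phi - prev_phi[r]
          sarsa_update(learners[[i]], BEHAVIORS[b], prev_feats[[r]],
                       prev_act[r], pend_reward[r], feats, a, shaping = F_sh)
        } else {
          sarsa_update(learners[[i]], BEHAVIORS[prev_beh[r]], prev_feats[[r]],
                       prev_act[r], pend_reward[r],
                       shaping = -prev_phi[r], terminal = TRUE)
        }
      }
      chosen_b[r] <- b; chosen_feats[[r]] <- feats
      chosen_act[r] <- a; chosen_phi[r] <- phi
      steps_beh[i, b] <- steps_beh[i, b] + 1L
      control_steps[i] <- control_steps[i] + 1L
      if (b == 3L && a == 6L) initiated[r] <- TRUE
      wheel[r, ] <- acts[min(a, nrow(acts)), ]
    }

    # execute actions
    for (r in active) {
      world$robots[r, ] <- step_kinematics(poses_before[r, ], wheel[r, ],
                                           dt_c, cfg)
    }
    poses_after <- world$robots
    reward <- numeric(nr)

    # captures: nearest robot within capture radius wins each source
    captured_by <- integer(nrow(world$sources))
    for (s in seq_len(nrow(world$sources))) {
      d2 <- (poses_after[active, 1] - world$sources[s, 1])^2 +
        (poses_after[active, 2] - world$sources[s, 2])^2
      ok <- d2 <= capture_r2
      if (any(ok)) captured_by[s] <- active[which.min(ifelse(ok, d2, Inf))]
    }
    gained <- integer(n)
    for (s in which(captured_by > 0L)) {
      r <- captured_by[s]; i <- ctrl[r]
      gained[i] <- gained[i] + 1L
      captures[i] <- captures[i] + 1L
      reward[r] <- reward[r] + 1
      refract[i] <- 0L   # a capture ends the refractory period
      world <- respawn_energy_source(world, s, cfg)
      event_add(buf, t, r, i, "capture", energy[i])
    }

    # matings
    mated <- rep(FALSE, nr)
    for (r in which(initiated)) {
      if (mated[r]) next
      i <- ctrl[r]
      if (refract[i] > 0L) next
      cand <- setdiff(active, r)
      cand <- cand[!mated[cand] & refract[ctrl[cand]] == 0L]
      if (length(cand) == 0) {
        event_add(buf, t, r, i, "mating_fail", energy[i]); next
      }
      ok <- vapply(cand, function(r2) {
        mating_condition(poses_before[r, ], poses_before[r2, ], cfg) &&
          mating_condition(poses_after[r, ], poses_after[r2, ], cfg)
      }, logical(1))
      if (!any(ok)) {
        event_add(buf, t, r, i, "mating_fail", energy[i]); next
      }
      cand <- cand[ok]
      d2 <- (poses_after[cand, 1] - poses_after[r, 1])^2 +
        (poses_after[cand, 2] - poses_after[r, 2])^2
      r2 <- cand[which.min(d2)]
      j <- ctrl[r2]
      ev <- attempt_mating(
        list(energy = energy[i], alive = alive[i], refractory = refract[i]),
        list(energy = energy[j], alive = alive[j], refractory = refract[j]),
        poses_before[r, ], poses_before[r2, ],
        poses_after[r, ], poses_after[r2, ], cfg, ids = c(i, j))
      if (is.null(ev)) {
        event_add(buf, t, r, i, "mating_fail", energy[i]); next
      }
      mated[r] <- TRUE; mated[r2] <- TRUE
      matings[i] <- matings[i] + 1L; matings[j] <- matings[j] + 1L
      sumE[i] <- sumE[i] + ev$energy_self
      sumE[j] <- sumE[j] + ev$energy_partner
      sumEp[i] <- sumEp[i] + ev$energy_partner
      sumEp[j] <- sumEp[j] + ev$energy_self
      if (K > 0L) {
        mix_counts[i, phen_idx[j]] <- mix_counts[i, phen_idx[j]] + 1L
        mix_counts[j, phen_idx[i]] <- mix_counts[j, phen_idx[i]] + 1L
      }
      reward[r] <- reward[r] + 1; reward[r2] <- reward[r2] + 1
      refract[i] <- refractory_c; refract[j] <- refractory_c
      for (pp in list(c(i, j), c(j, i))) {
        pi_ <- pp[1]; pj_ <- pp[2]
        did <- if (pi_ == i) ev$reproduced_self else ev$reproduced_partner
        if (did) {
          rep_ <- reproduce(genotypes[pi_, ], genotypes[pj_, ],
                            cfg$crossover_rate, cfg$mutation_rate,
                            cfg$mutation_sd)
          rr <- robot_of[pi_]
          pools[[rr]] <- rbind(pools[[rr]], rep_$offspring)
          offspring_attr[pi_] <- offspring_attr[pi_] +
            sum(rep_$attribution == "parent")
          offspring_attr[pj_] <- offspring_attr[pj_] +
            sum(rep_$attribution == "partner")
        }
      }
      event_add(buf, t, r, i, "mating_success", energy[i], j)
      event_add(buf, t, r2, j, "mating_success", energy[j], i)
    }

    # metabolism, deaths, slot bookkeeping
    for (r in active) {
      i <- ctrl[r]
      energy[i] <- min(E_max_c,
                       energy[i] - E_decay_c + gained[i] * E_gain_c)
      pend_reward[r] <- pend_reward[r] + reward[r]
      prev_beh[r] <- chosen_b[r]; prev_feats[[r]] <- chosen_feats[[r]]
      prev_act[r] <- chosen_act[r]; prev_phi[r] <- chosen_phi[r]
      if (refract[i] > 0L) refract[i] <- refract[i] - 1L
      if (energy[i] <= 0) {
        energy[i] <- 0; alive[i] <- FALSE; death_step[i] <- t
        event_add(buf, t, r, i, "death", 0)
        advance_controller(r)
      } else {
        slot_left[r] <- slot_left[r] - 1L
        if (slot_left[r] == 0L) advance_controller(r)
      }
    }
  }
  for (r in seq_len(nr)) flush_learner(r)

  stats <- data.frame(
    robot_id = robot_of,
    individual_id = seq_len(n),
    fitness = offspring_attr,
    n_matings = matings,
    mean_energy_at_mating = ifelse(matings > 0, sumE / pmax(matings, 1), NA),
    mean_partner_energy = ifelse(matings > 0, sumEp / pmax(matings, 1), NA),
    captures = captures,
    steps_foraging = steps_beh[, 1],
    steps_waiting = steps_beh[, 2],
    steps_mating = steps_beh[, 3],
    control_steps = control_steps,
    final_energy = energy,
    death_step = death_step,
    opp_energy_steps = opp_steps,
    opp_energy_foraging = opp_forage
  )
  if (!is.null(phenotype)) stats$phenotype <- phenotype
  out <- list(stats = stats, events = event_frame(buf), pools = pools)
  if (K > 0L) out$mating_mix <- mix_counts
  out
}

#' Mating learning performance
#'
#' The efficiency statistic of the mating module: time steps spent in the
#' mating module (waiting + mating behaviour) divided by the number of
#' mating events achieved — the average mating interval.  Lower is better;
#' it correlates strongly with fitness in evolved populations.
#' Individuals with no matings get `NA`.
#'
#' @param pop population table with `steps_waiting`, `steps_mating`,
#'   `n_matings` columns.
#' @return Numeric vector, one value per row of `pop`.
#' @export
learning_performance <- function(pop) {
  need <- c("steps_waiting", "steps_mating", "n_matings")
  if (!all(need %in% names(pop))) {
    stop("pop must contain columns ", paste(need, collapse = ", "))
  }
  ifelse(pop$n_matings > 0,
         (pop$steps_waiting + pop$steps_mating) / pop$n_matings,
         NA_real_)
}

#' Run the embodied evolution experiment
#'
#' The full generational loop: random initial genotypes, then per
#' generation a fresh schedule, the arena simulation with within-lifetime
#' learning ([simulate_generation()]), and resampling of each robot's
#' subpopulation from its offspring pool ([next_generation()]).  There is
#' no explicit fitness function and no centralized selection: selection
#' pressure arises only from who manages to mate and reproduce.
#'
#' @param cfg a [sim_config()].
#' @param n_generations number of generations (0 = log the initial
#'   population only).
#' @param seed root seed; all randomness derives from it.
#' @param out_dir optional output directory; when given, writes
#'   `population.csv`, `events.csv`, the resolved config and a manifest.
#' @param progress print a line per generation?
#' @return List with `population` (per-generation per-individual table
#'   including the 51 gene columns), `events` (with `generation` column)
#'   and `final_genotypes`.
#' @export
run_evolution <- function(cfg, n_generations, seed = cfg$rng_seed,
                          out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "sim_config"), n_generations >= 0)
  streams <- rng_streams(seed)
  n <- cfg$subpop_size * cfg$n_robots

  set.seed(streams["evolution"])
  genotypes <- random_genotype(n)

  pop_list <- list(); ev_list <- list()
  gene_df <- function(g) {
    d <- as.data.frame(g)
    names(d) <- paste0("gene_", seq_len(GENOME_LENGTH))
    d
  }
  if (n_generations == 0) {
    pop <- cbind(generation = 0L,
                 data.frame(robot_id = rep(seq_len(cfg$n_robots),
                                           each = cfg$subpop_size),
                            individual_id = seq_len(n)),
                 gene_df(genotypes))
    pop_list[[1]] <- pop
  }
  for (gen in seq_len(n_generations)) {
    set.seed((streams["world"] + gen * 7919) %% 2147483647)
    sim <- simulate_generation(genotypes, cfg)
    pop <- cbind(generation = gen, sim$stats[, c("robot_id", "individual_id")],
                 gene_df(genotypes),
                 sim$stats[, setdiff(names(sim$stats),
                                     c("robot_id", "individual_id"))])
    pop_list[[gen]] <- pop
    if (nrow(sim$events) > 0) {
      ev_list[[gen]] <- cbind(generation = gen, sim$events)
    }
    set.seed((streams["evolution"] + gen * 104729) %% 2147483647)
    genotypes <- do.call(rbind, lapply(seq_len(cfg$n_robots), function(r) {
      next_generation(sim$pools[[r]], cfg$subpop_size)
    }))
    if (progress) {
      message(sprintf("generation %d: %d offspring, mean fitness %.2f",
                      gen, sum(vapply(sim$pools, nrow, integer(1))),
                      mean(sim$stats$fitness)))
    }
  }
  population <- do.call(rbind, pop_list)
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(generation = integer(0), step = integer(0),
               robot_id = integer(0), individual_id = integer(0),
               event = character(0), energy = numeric(0),
               partner_id = integer(0))
  rownames(population) <- NULL; rownames(events) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pop_path <- file.path(out_dir, "population.csv")
    ev_path <- file.path(out_dir, "events.csv")
    utils::write.csv(population, pop_path, row.names = FALSE)
    utils::write.csv(events, ev_path, row.names = FALSE)
    write_manifest(out_dir, cfg, seed, c(pop_path, ev_path))
  }
  list(population = population, events = events, final_genotypes = genotypes)
}
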