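test_that("genotype decode partitions the 51 genes disjointly", {
  set.seed(4)
  g <- random_genotype(1)[1, ]
  parts <- decode_genotype(g)
  expect_length(parts$strategy_weights, 5)
  expect_equal(dim(parts$shaping_genes), c(3, 14))
  expect_length(parts$meta_genes, 4)
  # round trip
  expect_equal(encode_genotype(parts), g)
  # perturbing a strategy gene touches nothing else
  g2 <- g; g2[3] <- g2[3] + 1
  parts2 <- decode_genotype(g2)
  expect_equal(parts2$shaping_genes, parts$shaping_genes)
  expect_equal(parts2$meta_genes, parts$meta_genes)
  expect_equal(which(parts2$strategy_weights != parts$strategy_weights), 3L)
  expect_error(decode_genotype(g[-1]), "51")
})

test_that("reproduction probability is linear in energy", {
  expect_equal(reproduction_probability(0, 1000), 0)
  expect_equal(reproduction_probability(1000, 1000), 1)
  expect_equal(reproduction_probability(400, 1000), 0.4)
  expect_error(reproduction_probability(1200, 1000))
})

test_that("reproduce copies, recombines and mutates as configured", {
  pa <- rep(0, 51); pb <- rep(1, 51)
  # no crossover, no mutation: exact parental copies
  set.seed(1)
  r <- reproduce(pa, pb, crossover_rate = 0, mutation_rate = 0)
  expect_equal(r$offspring[1, ], pa)
  expect_equal(r$offspring[2, ], pb)
  expect_equal(r$attribution, c("parent", "partner"))
  # forced crossover: one contiguous block from each parent
  set.seed(2)
  r <- reproduce(pa, pb, crossover_rate = 1, mutation_rate = 0)
  cut <- r$cut
  expect_true(cut >= 1 && cut <= 50)
  expect_equal(r$offspring[1, ], c(rep(0, cut), rep(1, 51 - cut)))
  expect_equal(r$offspring[2, ], c(rep(1, cut), rep(0, 51 - cut)))
  # attribution follows the majority side of the cut
  expect_equal(r$attribution[1], if (cut > 25.5) "parent" else "partner")
  # mutation perturbs roughly mutation_rate of the genes
  set.seed(3)
  r <- reproduce(pa, pb, crossover_rate = 0, mutation_rate = 1,
                 mutation_sd = 0.1)
  expect_true(all(r$offspring[1, ] != pa))
})

test_that("strategy-block mixing probability matches enumeration", {
  # printed headline case: 51 genes, 5 strategy genes, crossover 0.1
  expect_equal(strategy_mixing_probability(51, 5, 0.1), 0.008)
  expect_equal(strategy_mixing_probability(51, 5, 0), 0)
  expect_equal(strategy_mixing_probability(51, 1, 0.5), 0)
  # brute-force enumeration over all cut points for random shapes
  set.seed(9)
  for (k in 1:25) {
    L <- sample(3:120, 1)
    kk <- sample(seq_len(L), 1)
    pc <- runif(1)
    cuts <- seq_len(L - 1)
    expect_equal(strategy_mixing_probability(L, kk, pc),
                 pc * mean(cuts < kk))
  }
})

test_that("simulated reproduction mixes strategy blocks at the 0.8% rate", {
  set.seed(77)
  pa <- rep(0, 51); pb <- rep(1, 51)
  n <- 20000
  mixed <- 0L
  for (k in seq_len(n)) {
    r <- reproduce(pa, pb, crossover_rate = 0.1, mutation_rate = 0)
    blk <- r$offspring[1, 1:5]
    if (any(blk == 0) && any(blk == 1)) mixed <- mixed + 1L
  }
  p <- 0.008
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mixed / n - p), 3 * se)
})

test_that("schedules cover every individual exactly three times", {
  set.seed(5)
  s <- make_schedule(4, 20, 3)
  expect_equal(dim(s), c(60, 4))
  for (r in 1:4) {
    expect_equal(sort(tabulate(s[, r], 20)), rep(3L, 20))
  }
  set.seed(6)
  s2 <- make_schedule(4, 20, 3)
  expect_false(identical(s, s2))        # different order...
  expect_equal(apply(s2, 2, sort), apply(s, 2, sort))  # ...same multiset
})

test_that("subpopulation resampling draws only from the pool", {
  pool <- random_genotype(100)
  set.seed(10)
  nxt <- next_generation(pool, 20)
  expect_equal(dim(nxt), c(20, 51))
  expect_true(all(apply(nxt, 1, function(g) {
    any(apply(pool, 1, identical, y = g))
  })))
  # small pools are resampled with replacement
  small <- random_genotype(7)
  nxt2 <- next_generation(small, 20)
  expect_equal(nrow(nxt2), 20)
  expect_true(all(apply(nxt2, 1, function(g) {
    any(apply(small, 1, identical, y = g))
  })))
  # an extinct pool falls back to random re-initialization
  expect_warning(nxt3 <- next_generation(matrix(numeric(0), ncol = 51), 20),
                 "empty")
  expect_equal(dim(nxt3), c(20, 51))
  set.seed(10)
  expect_identical(next_generation(pool, 20), nxt)  # seeded determinism
})

test_that("a generation conserves offspring and accounts every step", {
  cfg <- social_cfg()
  set.seed(33)
  g <- random_genotype(cfg$subpop_size * cfg$n_robots)
  sim <- simulate_generation(g, cfg)
  st <- sim$stats
  lifetime <- cfg$steps_per_period * cfg$periods_per_lifetime
  # offspring ledger: attributed offspring equal pool contents, and both
  # equal two per reproduction success
  total_pool <- sum(vapply(sim$pools, nrow, integer(1)))
  expect_equal(sum(st$fitness), total_pool)
  expect_equal(total_pool %% 2, 0)
  # behaviour steps partition control steps
  expect_equal(st$steps_foraging + st$steps_waiting + st$steps_mating,
               st$control_steps)
  # survivors serve their full lifetime, the dead stop at death
  surv <- is.na(st$death_step)
  expect_true(all(st$control_steps[surv] == lifetime))
  expect_true(all(st$control_steps[!surv] < lifetime))
  expect_true(all(st$final_energy[!surv] == 0))
  # event log schema
  expect_true(all(sim$events$event %in%
                    c("capture", "mating_fail", "mating_success", "death")))
})

test_that("the energy ledger balances exactly when uncapped", {
  cfg <- social_cfg(E_max = 1e9, E_birth = 500)
  set.seed(14)
  g <- random_genotype(cfg$subpop_size * cfg$n_robots)
  sim <- simulate_generation(g, cfg)
  st <- sim$stats
  surv <- is.na(st$death_step)
  expect_true(any(surv))
  expect_equal(
    st$final_energy[surv],
    cfg$E_birth - st$control_steps[surv] * cfg$E_decay_per_step +
      st$captures[surv] * cfg$E_gain_per_capture
  )
})

test_that("learning performance is the mean mating interval", {
  pop <- data.frame(steps_waiting = c(100, 40, 10),
                    steps_mating = c(20, 20, 0),
                    n_matings = c(4, 0, 2))
  expect_equal(learning_performance(pop), c(30, NA, 5))
  expect_error(learning_performance(data.frame(a = 1)), "columns")
})

test_that("evolution runs are reproducible and structurally complete", {
  res <- tiny_run()
  cfg <- social_cfg()
  n <- cfg$subpop_size * cfg$n_robots
  expect_equal(nrow(res$population), 2 * n)
  expect_true(all(paste0("gene_", 1:51) %in% names(res$population)))
  expect_equal(sort(unique(res$population$generation)), 1:2)
  # same seed, same logs (byte-identical determinism)
  res2 <- suppressWarnings(run_evolution(social_cfg(), 2, seed = 42))
  expect_identical(res$population, res2$population)
  expect_identical(res$events, res2$events)
  # different seed diverges
  res3 <- suppressWarnings(run_evolution(social_cfg(), 2, seed = 43))
  expect_false(identical(res$population, res3$population))
  # zero generations: only the initial population is logged
  res0 <- run_evolution(tiny_cfg(), 0, seed = 1)
  expect_equal(unique(res0$population$generation), 0L)
  expect_equal(nrow(res0$events), 0)
})

test_that("run_evolution writes schema-valid CSV logs and a manifest", {
  out <- file.path(tempdir(), "polymate-testrun")
  on.exit(unlink(out, recursive = TRUE))
  res <- suppressWarnings(run_evolution(tiny_cfg(n_energy_sources = 8L), 1,
                                        seed = 3, out_dir = out))
  expect_true(file.exists(file.path(out, "population.csv")))
  expect_true(file.exists(file.path(out, "events.csv")))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  pop <- utils::read.csv(file.path(out, "population.csv"))
  expect_equal(nrow(pop), nrow(res$population))
  ev <- utils::read.csv(file.path(out, "events.csv"))
  expect_true(all(c("generation", "step", "robot_id", "individual_id",
                    "event", "energy", "partner_id") %in% names(ev)))
  cfg_back <- read_config(file.path(out, "config.txt"))
  expect_equal(cfg_back$n_energy_sources, 8L)
})
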