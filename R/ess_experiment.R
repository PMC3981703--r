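#' Fixed-proportion mixture experiment
#'
#' Measures frequency-dependent fitness directly: subpopulations are
#' assembled by sampling genotypes of each phenotype from its pool at
#' predefined proportions, a single generation of the arena simulation is
#' run (composition is *not* evolved), and the per-phenotype mating
#' counts, energies at mating and attributed offspring are averaged over
#' replicates.  Repeating this across a grid of proportions traces the
#' fitness curves whose crossing identifies the polymorphic
#' evolutionarily stable state.
#'
#' Proportions must be realizable at the population size
#' `n_robots * subpop_size`; non-realizable values are rounded to the
#' nearest multiple of `1 / population size` (with a message).  A
#' phenotype with positive proportion needs a non-empty genotype pool.
#'
#' @param pools named list of genotype matrices (one per phenotype).
#' @param mix named numeric vector of phenotype proportions (sums to 1;
#'   names must match `pools`).
#' @param replicates number of independent replicate generations.
#' @param cfg a [sim_config()].
#' @param seed root seed for the experiment.
#' @return Object of class `fitness_record`: list with `summary` (one row
#'   per phenotype: `n_bar`, `E_self`, `E_partner`, `F_bar` and standard
#'   errors), `mix` (realized proportions), `counts`, `mating_mix` (mean
#'   per-capita matings of each row phenotype with each column phenotype),
#'   `mating_totals` (summed event counts, row x partner phenotype) and
#'   `per_replicate`.
#' @export
fixed_proportion_experiment <- function(pools, mix, replicates, cfg,
                                        seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "sim_config"), replicates >= 1)
  if (is.null(names(mix)) || !all(names(mix) %in% names(pools))) {
    stop("mix must be named after the phenotype pools")
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("mix must be a probability vector")
  }
  N <- cfg$n_robots * cfg$subpop_size
  counts <- round(mix * N)
  # largest-remainder repair so the counts sum to N
  while (sum(counts) != N) {
    resid <- mix * N - counts
    if (sum(counts) < N) {
      j <- which.max(resid); counts[j] <- counts[j] + 1
    } else {
      j <- which.min(resid); counts[j] <- counts[j] - 1
    }
  }
  if (any(abs(counts - mix * N) > 1e-8)) {
    message("mix rounded to realizable proportions: ",
            paste(sprintf("%s=%g/%d", names(mix), counts, N), collapse = ", "))
  }
  for (ph in names(mix)[counts > 0]) {
    if (is.null(pools[[ph]]) || nrow(pools[[ph]]) == 0) {
      stop("phenotype '", ph, "' has positive proportion but an empty pool")
    }
  }
  phen <- names(mix)[counts > 0]
  K <- length(phen)

  streams <- rng_streams(seed)
  reps <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    set.seed((streams["analysis"] + rep_i * 15485863) %% 2147483647)
    labels <- rep(names(mix), counts)
    genotypes <- do.call(rbind, lapply(seq_along(mix), function(j) {
      k <- counts[j]
      if (k == 0) return(NULL)
      pool <- pools[[names(mix)[j]]]
      pool[sample.int(nrow(pool), k, replace = TRUE), , drop = FALSE]
    }))
    ord <- sample.int(N)        # random assignment to robots/slots
    genotypes <- genotypes[ord, , drop = FALSE]
    labels <- labels[ord]
    sim <- simulate_generation(genotypes, cfg, phenotype = labels)
    st <- sim$stats
    per_ph <- do.call(rbind, lapply(phen, function(ph) {
      s <- st[st$phenotype == ph, ]
      data.frame(phenotype = ph,
                 n_bar = mean(s$n_matings),
                 E_self = mean(s$mean_energy_at_mating, na.rm = TRUE),
                 E_partner = mean(s$mean_partner_energy, na.rm = TRUE),
                 F_bar = mean(s$fitness))
    }))
    mm <- sim$mating_mix
    tot <- t(vapply(phen, function(ph) {
      colSums(mm[st$phenotype == ph, , drop = FALSE])
    }, numeric(ncol(mm))))
    rownames(tot) <- phen
    reps[[rep_i]] <- list(summary = per_ph, totals = tot)
  }

  agg <- do.call(rbind, lapply(reps, `[[`, "summary"))
  summ <- do.call(rbind, lapply(phen, function(ph) {
    a <- agg[agg$phenotype == ph, ]
    data.frame(
      phenotype = ph,
      n_bar = mean(a$n_bar), E_self = mean(a$E_self, na.rm = TRUE),
      E_partner = mean(a$E_partner, na.rm = TRUE), F_bar = mean(a$F_bar),
      se_n = stats::sd(a$n_bar) / sqrt(nrow(a)),
      se_F = stats::sd(a$F_bar) / sqrt(nrow(a)))
  }))
  totals <- Reduce(`+`, lapply(reps, `[[`, "totals"))
  per_capita <- sweep(totals, 1, replicates * counts[phen], "/")

  structure(list(summary = summ, mix = counts / N, counts = counts,
                 mating_mix = per_capita, mating_totals = totals,
                 replicates = replicates,
                 per_replicate = agg), class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("<fitness_record> %d replicates, mix: %s\n", x$replicates,
              paste(sprintf("%s=%.3f", names(x$mix), x$mix), collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run mixture experiments over a grid of tracker proportions
#'
#' Convenience wrapper for the two-phenotype case: runs
#' [fixed_proportion_experiment()] at each tracker proportion and returns
#' the records in the long format expected by [fit_mating_model()].
#'
#' @param pools named list with `forager` and `tracker` genotype pools.
#' @param r_T_grid tracker proportions to test.
#' @param replicates replicates per proportion.
#' @param cfg a [sim_config()].
#' @param seed root seed.
#' @return Data frame with columns `r_T`, `phenotype`, `n_bar`, `E_self`,
#'   `E_partner`, `F_bar`.
#' @export
ess_grid <- function(pools, r_T_grid, replicates, cfg, seed = cfg$rng_seed) {
  stopifnot(all(c("forager", "tracker") %in% names(pools)))
  out <- list()
  for (k in seq_along(r_T_grid)) {
    r <- r_T_grid[k]
    rec <- fixed_proportion_experiment(
      pools, c(forager = 1 - r, tracker = r), replicates, cfg,
      seed = (seed + k * 512927) %% 2147483647)
    s <- rec$summary
    s$r_T <- r
    out[[k]] <- s[, c("r_T", "phenotype", "n_bar", "E_self", "E_partner",
                      "F_bar")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
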