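#' Simulation configuration
#'
#' Build the full configuration for the arena simulation, the embodied
#' genetic algorithm and the within-lifetime learners.  Values printed in the
#' source experiments (arena size, vision ranges, lifetime structure,
#' crossover rate, mutation standard deviation, subpopulation size) are the
#' defaults; quantities that the experiments used but did not print (energy
#' budget, refractory period, camera/IR angles, wheel geometry) are
#' calibrated defaults and fully configurable.
#'
#' All angles are in radians, lengths in metres, energies in abstract energy
#' units, durations in seconds.
#'
#' @param ... named overrides of any default field, e.g.
#'   `sim_config(n_energy_sources = 8)`.
#' @return An object of class `sim_config`: a validated named list.
#'
#' @details Key fields:
#' \describe{
#'   \item{arena_side}{side of the square arena (2.5 m).}
#'   \item{n_energy_sources}{number of energy sources, 4--16.}
#'   \item{time_step}{sensory-motor cycle (0.24 s).}
#'   \item{steps_per_period, periods_per_lifetime}{each individual controls a
#'     robot for 3 periods of 400 steps: a 1200-step lifetime.}
#'   \item{E_max, E_birth, E_decay_per_step, E_gain_per_capture}{energy
#'     budget, calibrated so a robot that never forages dies mid-lifetime
#'     (step 700 of 1200) and energies at mating sit near the top of the
#'     scale; all four are configurable.}
#'   \item{detect_range_energy, detect_range_tail, detect_range_face}{maximum
#'     vision ranges per target category (2.0 / 1.5 / 1.0 m) inside the
#'     full-range cone; outside it the effective range falls linearly to
#'     `min_detect_range` (0.2 m) at the edge of the field of view.}
#'   \item{mating_range, mating_half_angle}{mutual infrared window for
#'     genotype exchange (1 m).}
#'   \item{crossover_rate, mutation_rate, mutation_sd}{one-point crossover
#'     probability (0.1) and per-gene Gaussian mutation N(0, 0.1^2).}
#'   \item{subpop_size, n_robots}{20 time-shared individuals in each of 4
#'     robots.}
#'   \item{n_tilings, tiles_per_dim}{tile-coding resolution of the
#'     behaviour learners.}
#' }
#' @export
#' @examples
#' cfg <- sim_config(n_energy_sources = 8)
#' cfg$steps_per_period * cfg$periods_per_lifetime  # 1200-step lifetime
sim_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all overrides must be named")
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
}

default_config <- function() {
  list(
    arena_side            = 2.5,
    n_energy_sources      = 4L,
    time_step             = 0.24,
    steps_per_period      = 400L,
    periods_per_lifetime  = 3L,
    E_max                 = 1000,
    E_birth               = 700,
    E_decay_per_step      = 1,
    E_gain_per_capture    = 300,
    mating_range          = 1.0,
    mating_half_angle     = pi / 6,
    fov_half_angle        = pi / 4,
    full_range_half_angle = pi / 6,
    detect_range_energy   = 2.0,
    detect_range_tail     = 1.5,
    detect_range_face     = 1.0,
    min_detect_range      = 0.2,
    input_dist_floor      = 0.1,
    refractory_steps      = 30L,
    crossover_rate        = 0.1,
    mutation_rate         = 0.1,
    mutation_sd           = 0.1,
    subpop_size           = 20L,
    n_robots              = 4L,
    capture_radius        = 0.15,
    robot_radius          = 0.11,
    wheel_base            = 0.12,
    max_wheel_speed       = 0.5,
    n_tilings             = 8L,
    tiles_per_dim         = 8L,
    rng_seed              = 1L
  )
}

config_int_fields <- c(
  "n_energy_sources", "steps_per_period", "periods_per_lifetime",
  "refractory_steps", "subpop_size", "n_robots", "n_tilings",
  "tiles_per_dim", "rng_seed"
)

#' Validate a raw configuration
#'
#' Checks types, ranges and cross-field invariants of a configuration list
#' and returns it as a `sim_config` object.  Unknown fields are rejected,
#' missing fields are filled with the documented defaults.
#'
#' @param raw named list of configuration values (possibly partial).
#' @return A validated `sim_config`.
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) stop("config must be a named list")
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  cfg[names(raw)] <- raw

  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("config field '", field, "' must be a single finite number")
    }
    as.numeric(v)
  }
  for (f in names(cfg)) cfg[[f]] <- num1(f)
  for (f in config_int_fields) {
    if (cfg[[f]] != round(cfg[[f]])) stop("config field '", f, "' must be an integer")
    cfg[[f]] <- as.integer(cfg[[f]])
  }

  pos <- c(
    "arena_side", "time_step", "E_max", "E_decay_per_step",
    "E_gain_per_capture", "mating_range", "mating_half_angle",
    "fov_half_angle", "full_range_half_angle", "detect_range_energy",
    "detect_range_tail", "detect_range_face", "min_detect_range",
    "input_dist_floor", "mutation_sd", "capture_radius", "robot_radius",
    "wheel_base", "max_wheel_speed"
  )
  for (f in pos) {
    if (cfg[[f]] <= 0) stop("config field '", f, "' must be > 0")
  }
  for (f in c("crossover_rate", "mutation_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("config field '", f, "' must be a probability in [0, 1]")
    }
  }
  for (f in c("n_energy_sources", "steps_per_period", "periods_per_lifetime",
              "subpop_size", "n_robots", "n_tilings", "tiles_per_dim")) {
    if (cfg[[f]] < 1) stop("config field '", f, "' must be >= 1")
  }
  if (cfg$refractory_steps < 0) stop("refractory_steps must be >= 0")
  if (cfg$E_birth <= 0 || cfg$E_birth > cfg$E_max) {
    stop("E_birth must be in (0, E_max]")
  }
  if (cfg$full_range_half_angle > cfg$fov_half_angle) {
    stop("full_range_half_angle must not exceed fov_half_angle")
  }
  for (f in c("detect_range_energy", "detect_range_tail", "detect_range_face")) {
    if (cfg$min_detect_range >= cfg[[f]]) {
      stop("min_detect_range must be smaller than ", f)
    }
  }
  if (cfg$input_dist_floor >= cfg$detect_range_face) {
    stop("input_dist_floor must be smaller than every detection range")
  }
  if (cfg$n_robots < 2) stop("need at least 2 robots for mating")

  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read / write a configuration file
#'
#' The on-disk format is a flat `key = value` text file (one field per line,
#' `#` comments allowed, '.' decimal separator).  Missing keys take the
#' documented defaults; unknown keys are an error.
#'
#' @param path file path.
#' @return `read_config()` returns a validated `sim_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  raw <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for config key '", key, "'")
    raw[[key]] <- val
  }
  validate_config(raw)
}

#' @rdname read_config
#' @param cfg a `sim_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  lines <- vapply(
    names(cfg),
    function(f) sprintf("%s = %s", f, format(cfg[[f]], digits = 17)),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic child random-number streams
#'
#' All randomness in a run flows from one root seed.  Named child seeds for
#' the world, learning, evolution and analysis layers are derived from it by
#' a fixed integer hash so that each layer is independently reproducible.
#'
#' @param seed root seed (integer).
#' @return Named integer vector of child seeds, each in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' rng_streams(42)
rng_streams <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  seed <- as.numeric(seed) %% 2147483647
  names_ <- c("world", "learning", "evolution", "analysis")
  # Weyl-style mixing; all arithmetic exact in doubles (< 2^53)
  h <- (seed * 48271 + seq_along(names_) * 2246822519) %% 2147483647
  h <- (h * 69621) %% 2147483647
  stats::setNames(as.integer(h), names_)
}

#' Write a run manifest
#'
#' Records the resolved configuration, the root seed and an inventory of
#' output files (with row counts for CSVs) so a run can be reproduced
#' exactly.
#'
#' @param dir output directory (created if needed).
#' @param cfg resolved `sim_config` of the run.
#' @param seed root seed used.
#' @param files character vector of output file paths to inventory.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(dir, cfg, seed, files = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.txt")
  write_config(cfg, cfg_path)
  inv <- vapply(files, function(f) {
    n <- if (file.exists(f) && grepl("\\.csv$", f)) {
      length(readLines(f, warn = FALSE)) - 1L
    } else {
      NA_integer_
    }
    sprintf("%s rows=%s", basename(f), ifelse(is.na(n), "NA", n))
  }, character(1))
  manifest <- c(
    sprintf("package_version = %s", as.character(utils::packageVersion("polymate"))),
    sprintf("seed = %d", as.integer(seed)),
    sprintf("config = %s", basename(cfg_path)),
    inv
  )
  path <- file.path(dir, "manifest.txt")
  writeLines(manifest, path)
  invisible(path)
}
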