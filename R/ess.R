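#' Fitness decomposition at mating events
#'
#' The average fitness of a phenotype (its mean number of attributed
#' offspring) decomposes into mating frequency and reproductive success:
#' \deqn{\hat F = \bar n (\bar E_{self} + \bar E_{partner}),}
#' where \eqn{\bar n} is the mean number of mating events per lifetime and
#' \eqn{\bar E} are the mean normalized energies of the individual and its
#' partners at those events (each party reproduces two offspring with
#' probability equal to its normalized energy, and every offspring is
#' attributed to the parent contributing the majority of its genes).
#'
#' @param record data frame with columns `n_bar`, `E_self`, `E_partner` and
#'   optionally observed `F_bar` (one row per phenotype).
#' @return The input with columns `F_hat` (predicted fitness) and, when
#'   `F_bar` is present, `rel_error`.
#' @export
#' @examples
#' fitness_decomposition(data.frame(n_bar = 12, E_self = 0.8, E_partner = 0.8))
fitness_decomposition <- function(record) {
  need <- c("n_bar", "E_self", "E_partner")
  if (!all(need %in% names(record))) {
    stop("record must contain columns ", paste(need, collapse = ", "))
  }
  if (any(record$n_bar < 0)) stop("n_bar must be >= 0")
  if (any(record$E_self < 0 | record$E_self > 1) ||
      any(record$E_partner < 0 | record$E_partner > 1)) {
    stop("energies must be normalized to [0, 1]")
  }
  record$F_hat <- record$n_bar * (record$E_self + record$E_partner)
  if ("F_bar" %in% names(record)) {
    record$rel_error <- ifelse(record$F_bar == 0 & record$F_hat == 0, 0,
                               (record$F_hat - record$F_bar) /
                                 pmax(abs(record$F_bar), .Machine$double.eps))
  }
  record
}

#' Forager/tracker mating-mix model
#'
#' Two empirical regularities structure who mates with whom in a mixed
#' population with tracker proportion `r_T`: trackers mix with partners in
#' proportion to availability (their tracker-partner fraction is `r_T`),
#' while foragers mate with trackers *more* often than availability, with
#' excess parameter \eqn{\alpha \ge 0}:
#' \deqn{m_{FT}/m_F = r_T (1 + \alpha (1 - r_T)).}
#' Combining the tracker mixing law with the population bookkeeping
#' symmetry \eqn{N_F m_{FT} = N_T m_{TF}} yields the ratio of mating
#' frequencies
#' \deqn{\gamma(r_T) = m_F / m_T = 1 / (1 + \alpha (1 - r_T)),}
#' which is below 1 for \eqn{\alpha > 0} and rises to 1 as the population
#' fills with trackers.
#'
#' @param r_T tracker proportion(s) in `[0, 1]`.
#' @param alpha forager mixing-excess parameter, >= 0.
#' @return Data frame with columns `r_T`, `f_FT` (forager tracker-partner
#'   fraction, capped at 1) and `gamma`.
#' @export
#' @examples
#' mating_mix_model(c(0.125, 0.875), alpha = 0.15)
mating_mix_model <- function(r_T, alpha) {
  if (any(r_T < 0 | r_T > 1)) stop("r_T must lie in [0, 1]")
  if (length(alpha) != 1 || alpha < 0) stop("alpha must be a scalar >= 0")
  denom <- 1 + alpha * (1 - r_T)
  data.frame(r_T = r_T,
             f_FT = pmin(1, r_T * denom),
             gamma = 1 / denom)
}

#' Fit the mating-mix fitness model to mixture-experiment records
#'
#' From fixed-proportion experiment summaries at several tracker
#' proportions, fits: a least-squares line per phenotype for the mean
#' mating count \eqn{\bar n(r_T)}; constant (mean) approximations of the
#' per-phenotype energies at mating; and the mixing-excess parameter
#' \eqn{\hat\alpha} by least squares of the observed mating-frequency
#' ratios \eqn{\gamma = \bar n_F/\bar n_T} against
#' \eqn{1/(1 + \alpha(1 - r_T))}.  The fitted components are recomposed
#' into predicted fitness curves
#' \deqn{\hat F_F(r) = \bar n_F(r)\,(\bar E_F + (1 - f_{FT}(r))\bar E_F +
#'   f_{FT}(r)\bar E_T), \qquad
#'   \hat F_T(r) = \bar n_T(r)\,(\bar E_T + (1 - r)\bar E_F + r\bar E_T),}
#' whose intersection locates the evolutionarily stable forager/tracker
#' mixture.
#'
#' @param records data frame with one row per (mixture, phenotype):
#'   columns `r_T`, `phenotype` (`"forager"`/`"tracker"`), `n_bar`,
#'   `E_self`, and optionally `F_bar`.
#' @return Object of class `mating_mix_fit`: list with `alpha_hat`,
#'   `n_fit` (per-phenotype intercept/slope), `E_bar` (per-phenotype mean
#'   energy), `predict` (function of `r_T` returning predicted
#'   `F_forager`, `F_tracker`), and `crossing` (interior `r_T` where the
#'   predicted curves intersect, or NA).
#' @export
fit_mating_model <- function(records) {
  need <- c("r_T", "phenotype", "n_bar", "E_self")
  if (!all(need %in% names(records))) {
    stop("records must contain columns ", paste(need, collapse = ", "))
  }
  records$phenotype <- as.character(records$phenotype)
  if (!all(records$phenotype %in% c("forager", "tracker"))) {
    stop("phenotype must be 'forager' or 'tracker'")
  }
  if (length(unique(records$r_T)) < 3) {
    stop("need records at >= 3 distinct mixture points")
  }
  fits <- list(); E_bar <- c(forager = NA_real_, tracker = NA_real_)
  for (ph in c("forager", "tracker")) {
    sub <- records[records$phenotype == ph, ]
    if (nrow(sub) < 2 || length(unique(sub$r_T)) < 2) {
      stop("rank-deficient design: phenotype '", ph,
           "' observed at fewer than two distinct proportions")
    }
    fit <- stats::lm(n_bar ~ r_T, data = sub)
    fits[[ph]] <- stats::coef(fit)
    E_bar[ph] <- mean(sub$E_self)
  }
  # gamma observations where both phenotypes coexist
  both <- intersect(records$r_T[records$phenotype == "forager"],
                    records$r_T[records$phenotype == "tracker"])
  both <- both[both > 0 & both < 1]
  if (length(both) < 1) stop("no interior mixtures with both phenotypes")
  gam_obs <- vapply(both, function(r) {
    nf <- records$n_bar[records$phenotype == "forager" & records$r_T == r]
    nt <- records$n_bar[records$phenotype == "tracker" & records$r_T == r]
    mean(nf) / mean(nt)
  }, numeric(1))
  sse <- function(a) sum((gam_obs - 1 / (1 + a * (1 - both)))^2)
  alpha_hat <- stats::optimize(sse, c(0, 10))$minimum
  if (sse(0) <= sse(alpha_hat)) alpha_hat <- 0

  n_line <- function(ph, r) fits[[ph]][1] + fits[[ph]][2] * r
  predict_fun <- function(r_T) {
    f_FT <- pmin(1, r_T * (1 + alpha_hat * (1 - r_T)))
    data.frame(
      r_T = r_T,
      F_forager = n_line("forager", r_T) *
        (E_bar["forager"] + (1 - f_FT) * E_bar["forager"] + f_FT * E_bar["tracker"]),
      F_tracker = n_line("tracker", r_T) *
        (E_bar["tracker"] + (1 - r_T) * E_bar["forager"] + r_T * E_bar["tracker"]),
      row.names = NULL
    )
  }
  crossing <- find_crossing(function(r) {
    p <- predict_fun(r); p$F_forager - p$F_tracker
  })
  structure(list(alpha_hat = alpha_hat, n_fit = fits, E_bar = E_bar,
                 gamma_obs = data.frame(r_T = both, gamma = gam_obs),
                 predict = predict_fun, crossing = crossing),
            class = "mating_mix_fit")
}

#' @export
print.mating_mix_fit <- function(x, ...) {
  cat("<mating_mix_fit>\n")
  cat(sprintf("  alpha_hat : %.4f\n", x$alpha_hat))
  cat(sprintf("  E_bar     : forager %.3f, tracker %.3f\n",
              x$E_bar["forager"], x$E_bar["tracker"]))
  cat(sprintf("  crossing  : %s\n",
              if (is.na(x$crossing)) "none in (0, 1)"
              else sprintf("r_T = %.3f", x$crossing)))
  invisible(x)
}

# root of f on (0, 1) by sign change on a fine grid + uniroot refinement
find_crossing <- function(f, n_grid = 1024) {
  r <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  v <- vapply(r, f, numeric(1))
  s <- which(diff(sign(v)) != 0)
  if (length(s) == 0) return(NA_real_)
  stats::uniroot(f, c(r[s[1]], r[s[1] + 1]))$root
}

#' One step of the discrete replicator dynamics
#'
#' With a fixed population size, the proportion of phenotype *i* in the
#' next generation is its fitness-weighted share of the current mix:
#' \deqn{p_i' = p_i \bar F_i / \sum_j p_j \bar F_j.}
#'
#' @param p proportion vector on the probability simplex.
#' @param fitness nonnegative mean fitness per phenotype, same length.
#' @return Updated proportion vector (sums to 1).
#' @export
#' @examples
#' replicator_step(c(0.5, 0.5), c(2, 1))  # c(2/3, 1/3)
replicator_step <- function(p, fitness) {
  if (length(p) != length(fitness)) stop("p and fitness lengths differ")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("p must be a probability vector on the simplex")
  }
  if (any(fitness < 0)) stop("fitness must be nonnegative")
  mbar <- sum(p * fitness)
  if (mbar <= 0) stop("mean fitness is zero: replicator step undefined")
  p * fitness / mbar
}

#' Iterate the replicator dynamics
#'
#' @param p0 initial proportion vector.
#' @param fitness either a fixed fitness vector or a function of `p`
#'   returning one (frequency-dependent fitness).
#' @param steps number of generations.
#' @return Matrix of proportions, `steps + 1` rows (including `p0`).
#' @export
replicator_trajectory <- function(p0, fitness, steps) {
  stopifnot(steps >= 0)
  fit_fun <- if (is.function(fitness)) fitness else function(p) fitness
  out <- matrix(NA_real_, nrow = steps + 1, ncol = length(p0))
  out[1, ] <- p <- p0
  if (steps > 0) {
    for (t in seq_len(steps)) {
      p <- replicator_step(p, fit_fun(p))
      out[t + 1, ] <- p
    }
  }
  colnames(out) <- names(p0)
  out
}

#' Barycentric (de Finetti) coordinates
#'
#' Maps three-phenotype proportion vectors to the planar equilateral
#' triangle used in de Finetti diagrams: `x = p2 + p3/2`,
#' `y = sqrt(3)/2 * p3`.  The corners map to (0,0), (1,0) and
#' (0.5, sqrt(3)/2).
#'
#' @param p proportion vector of length 3, or a matrix with 3 columns.
#' @return Matrix with columns `x`, `y`.
#' @export
definetti_xy <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 3) stop("de Finetti coordinates need exactly 3 phenotypes")
  cbind(x = p[, 2] + p[, 3] / 2, y = sqrt(3) / 2 * p[, 3])
}

#' Replicator flow and attractors on a simplex grid
#'
#' Evaluates the one-generation replicator displacement
#' \eqn{\Delta p = p' - p} at every tested phenotype mixture, and flags
#' evolutionarily stable attractors: grid points where the displacement
#' magnitude is below `tol` *and* every neighbouring grid point's arrow
#' points towards them.  Points with a small arrow but without inward
#' neighbours (e.g. under uniform fitness) are `neutral`; the rest are
#' `flow`.  Grid cells of the expected lattice that are missing from the
#' input are reported in `missing`; no interpolation is attempted.
#'
#' @param mix matrix of tested proportions (rows on the simplex; 2 or 3
#'   columns).
#' @param fitness matrix of mean fitness per phenotype, same shape.
#' @param grid_step lattice resolution of the tested mixes (default 0.125).
#' @param tol attractor displacement tolerance (default 0.01).
#' @return List with `flow` (data frame: mix, `dp_*` displacement columns,
#'   `magnitude`, `status`, and for 3 phenotypes `x`, `y` de Finetti
#'   coordinates), `attractors` (subset with status `"attractor"`), and
#'   `missing` (matrix of absent lattice points).
#' @export
stability_map <- function(mix, fitness, grid_step = 0.125, tol = 0.01) {
  mix <- as.matrix(mix); fitness <- as.matrix(fitness)
  if (!all(dim(mix) == dim(fitness))) stop("mix and fitness shapes differ")
  K <- ncol(mix)
  n <- nrow(mix)
  dp <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    dp[i, ] <- replicator_step(mix[i, ], fitness[i, ]) - mix[i, ]
  }
  mag <- sqrt(rowSums(dp^2))

  # neighbours: lattice points one single-share transfer away
  is_neighbour <- function(i, j) {
    d <- abs(mix[i, ] - mix[j, ])
    sum(d) > 1e-9 && sum(d) <= 2 * grid_step + 1e-9
  }
  status <- rep("flow", n)
  for (i in seq_len(n)) {
    if (mag[i] >= tol) next
    nb <- which(vapply(seq_len(n), function(j) is_neighbour(i, j), logical(1)))
    inward <- length(nb) > 0 && all(vapply(nb, function(j) {
      v <- mix[i, ] - mix[j, ]
      sum(dp[j, ] * v) > 1e-12
    }, logical(1)))
    status[i] <- if (inward) "attractor" else "neutral"
  }

  lattice <- simplex_lattice(K, grid_step)
  present <- apply(lattice, 1, function(q) {
    any(apply(mix, 1, function(m) max(abs(m - q)) < 1e-9))
  })
  missing <- lattice[!present, , drop = FALSE]

  flow <- data.frame(mix)
  names(flow) <- paste0("p", seq_len(K))
  dpd <- data.frame(dp)
  names(dpd) <- paste0("dp", seq_len(K))
  flow <- cbind(flow, dpd, magnitude = mag, status = status)
  if (K == 3) {
    xy <- definetti_xy(mix)
    flow$x <- xy[, "x"]; flow$y <- xy[, "y"]
  }
  list(flow = flow, attractors = flow[flow$status == "attractor", ],
       missing = missing)
}

# all K-part compositions of 1 in multiples of grid_step
simplex_lattice <- function(K, grid_step) {
  m <- round(1 / grid_step)
  if (abs(m * grid_step - 1) > 1e-9) stop("grid_step must divide 1")
  parts <- expand.grid(rep(list(0:m), K - 1))
  keep <- rowSums(parts) <= m
  parts <- as.matrix(parts[keep, , drop = FALSE])
  lat <- cbind(parts, m - rowSums(parts)) * grid_step
  colnames(lat) <- paste0("p", seq_len(K))
  unname(lat)
}

#' de Finetti diagram of a three-phenotype stability map
#'
#' Draws the tested mixtures, the replicator arrows (scaled for
#' visibility) and the detected attractors in barycentric coordinates.
#' Requires ggplot2.
#'
#' @param map result of [stability_map()] for three phenotypes.
#' @param arrow_scale multiplier applied to the arrows (default 5).
#' @param labels vertex labels, bottom-left / bottom-right / top.
#' @return A ggplot object.
#' @export
plot_definetti <- function(map, arrow_scale = 5,
                           labels = c("F", "WT", "ST")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_definetti() needs the ggplot2 package")
  }
  flow <- map$flow
  if (is.null(flow$x)) stop("stability map is not three-phenotype")
  tip <- definetti_xy(diag(3))
  tri <- data.frame(x = tip[c(1, 2, 3, 1), "x"], y = tip[c(1, 2, 3, 1), "y"])
  head_xy <- definetti_xy(as.matrix(flow[, c("p1", "p2", "p3")]) +
                            arrow_scale * as.matrix(flow[, c("dp1", "dp2", "dp3")]))
  flow$xend <- head_xy[, "x"]; flow$yend <- head_xy[, "y"]
  fit_bg <- if (!is.null(flow$mean_fitness)) flow$mean_fitness else NULL
  gg <- ggplot2::ggplot(flow, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y),
                       inherit.aes = FALSE) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::geom_point(data = flow[flow$status == "attractor", ],
                        colour = "red", size = 3, shape = 15) +
    ggplot2::annotate("text", x = tip[, "x"] + c(-0.04, 0.04, 0),
                      y = tip[, "y"] + c(-0.03, -0.03, 0.04),
                      label = labels) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  gg
}
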