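#' Waiting-energy threshold of the mating-strategy network
#'
#' When a robot sees an energy source and a tail-lamp but no face, the
#' linear strategy network selects the mating module whenever
#' \deqn{w_0 + w_1 (2E - 1) + w_2 x_b + w_3 x_t - w_4 > 0,}
#' where `E` is the normalized internal energy, `x_b` and `x_t` are the
#' scaled closeness inputs of the nearest energy source and tail-lamp, and
#' the face channel is pinned at its invisible value -1 (hence the
#' \eqn{-w_4}).  The waiting threshold \eqn{\theta} is the minimal
#' normalized energy at which the mating module is selected, clipped to
#' `[0, 1]`:
#' \itemize{
#'   \item `w1 > 0`: \eqn{\theta = ((w_4 - w_0 - w_2 x_b - w_3 x_t)/w_1 + 1)/2},
#'     clipped.
#'   \item `w1 == 0`: the output is energy-independent; \eqn{\theta = 0}
#'     if the network favours mating, 1 otherwise.
#'   \item `w1 < 0`: mating is favoured at *low* energy; the complementary
#'     boundary \eqn{1 - E_0} is reported (0 if the output is positive for
#'     every energy, 1 if for none).  The evolved populations analysed here
#'     never produced this case; the convention only makes the statistic
#'     total.
#' }
#' A pure forager has \eqn{\theta = 1} everywhere: it never waits.
#'
#' @param weights numeric length-5 strategy weights \eqn{w_0 \ldots w_4}.
#' @param x_b scaled energy-source (battery) closeness input(s).
#' @param x_t scaled tail-lamp closeness input(s).
#' @return Threshold(s) in `[0, 1]`, vectorised over `x_b`/`x_t`.
#' @seealso [mean_threshold()] for the grid-averaged \eqn{\bar\theta}.
#' @export
#' @examples
#' waiting_threshold(c(0, 1, 0, 0, 0), 0, 0)  # mating iff 2E - 1 > 0: 0.5
waiting_threshold <- function(weights, x_b, x_t) {
  stopifnot(length(weights) == 5, all(is.finite(weights)))
  n <- max(length(x_b), length(x_t))
  x_b <- rep_len(x_b, n)
  x_t <- rep_len(x_t, n)
  w0 <- weights[1]; w1 <- weights[2]; w2 <- weights[3]
  w3 <- weights[4]; w4 <- weights[5]
  num <- w4 - w0 - w2 * x_b - w3 * x_t   # = w1*(2E - 1) at the boundary
  if (w1 > 0) {
    pmin(1, pmax(0, (num / w1 + 1) / 2))
  } else if (w1 == 0) {
    ifelse(num < 0, 0, 1)                # output > 0 independent of E
  } else {
    e0 <- (num / w1 + 1) / 2             # mating region is E < e0
    ifelse(e0 >= 1, 0, ifelse(e0 <= 0, 1, pmin(1, pmax(0, 1 - e0))))
  }
}

#' Grid of scaled visual inputs for threshold averaging
#'
#' 26 equidistant values between 0 and 1 (inclusive) for each of the two
#' sensory inputs, giving the 676-point grid over which waiting thresholds
#' are averaged.
#'
#' @param n_per_axis grid resolution per axis (default 26).
#' @return Data frame with columns `x_b`, `x_t` (676 rows at the default).
#' @export
threshold_grid <- function(n_per_axis = 26L) {
  stopifnot(n_per_axis >= 2)
  v <- seq(0, 1, length.out = n_per_axis)
  expand.grid(x_b = v, x_t = v, KEEP.OUT.ATTRS = FALSE)
}

#' Mean waiting threshold over the visual-input grid
#'
#' The phenotype statistic \eqn{\bar\theta}: the mean of
#' [waiting_threshold()] over the 26 x 26 grid of energy-source and
#' tail-lamp inputs.  \eqn{\bar\theta = 1} characterises foragers (never
#' wait); trackers have \eqn{\bar\theta < 1}, with strong trackers around
#' 0.2 and weak trackers around 0.5.
#'
#' @param weights length-5 strategy weight vector, or a matrix with one
#'   weight vector per row.
#' @param grid optionally a precomputed [threshold_grid()].
#' @return Scalar \eqn{\bar\theta}, or a vector (one per row of `weights`).
#' @export
mean_threshold <- function(weights, grid = threshold_grid()) {
  if (is.matrix(weights)) {
    return(apply(weights, 1, mean_threshold, grid = grid))
  }
  mean(waiting_threshold(weights, grid$x_b, grid$x_t))
}

#' Classify a population by its waiting-threshold distribution
#'
#' Population-level rule over the \eqn{\bar\theta} values of its
#' individuals: median > 0.98 is a *forager* population; otherwise a
#' standard deviation <= 0.19 is a *tracker* population and > 0.19 a
#' *polymorphic* population (the boundary value is assigned to tracker).
#'
#' @param theta_bar numeric vector of per-individual mean thresholds.
#' @return One of `"forager"`, `"tracker"`, `"polymorphic"`.
#' @export
#' @examples
#' classify_population(c(rep(1, 30), rep(0.4, 70)))  # polymorphic
classify_population <- function(theta_bar) {
  theta_bar <- as.numeric(theta_bar)
  if (length(theta_bar) < 2 || anyNA(theta_bar)) {
    stop("need at least two finite theta_bar values")
  }
  if (stats::median(theta_bar) > 0.98) return("forager")
  if (stats::sd(theta_bar) <= 0.19) return("tracker")
  "polymorphic"
}

#' Cluster individuals in mating-strategy weight space
#'
#' k-means clustering of individuals on the (bias, face-distance) weights
#' \eqn{(w_0, w_4)}, the plane in which forager and tracker genotypes
#' separate.  When per-individual mean thresholds are supplied, clusters
#' are mapped to phenotype labels by their median \eqn{\bar\theta}
#' (highest median = forager side, then decreasing threshold order:
#' forager, weak_tracker, strong_tracker for k = 3).
#'
#' @param points numeric matrix/data frame with one row per individual and
#'   two columns (w0, w4).
#' @param k number of clusters.
#' @param theta_bar optional per-individual mean thresholds used to name
#'   the clusters.
#' @param nstart random restarts passed to [stats::kmeans()].
#' @return List with `cluster` (integer labels), `phenotype` (character
#'   labels, if `theta_bar` given), `centers`, and `degenerate` (TRUE when
#'   fewer than `k` distinct points were available).
#' @export
cluster_strategy_weights <- function(points, k = 2, theta_bar = NULL,
                                     nstart = 10) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns (w0, w4)")
  if (k < 1) stop("k must be >= 1")
  if (nrow(points) < k) stop("need at least k points")
  n_distinct <- nrow(unique(points))
  if (k == 1 || n_distinct < k) {
    cl <- list(cluster = rep(1L, nrow(points)),
               centers = matrix(colMeans(points), nrow = 1))
    degenerate <- (k > 1)
  } else {
    cl <- stats::kmeans(points, centers = k, nstart = nstart, iter.max = 100)
    degenerate <- FALSE
  }
  out <- list(cluster = cl$cluster, centers = cl$centers,
              degenerate = degenerate)
  if (!is.null(theta_bar)) {
    stopifnot(length(theta_bar) == nrow(points))
    kk <- max(cl$cluster)
    med <- vapply(seq_len(kk), function(j) {
      stats::median(theta_bar[cl$cluster == j])
    }, numeric(1))
    name_pool <- switch(as.character(min(kk, 3)),
      "1" = "forager",
      "2" = c("forager", "tracker"),
      "3" = c("forager", "weak_tracker", "strong_tracker")
    )
    if (kk > 3) name_pool <- c(name_pool, paste0("cluster", 4:kk))
    ord <- order(med, decreasing = TRUE)   # high theta_bar first
    labels <- character(kk)
    labels[ord] <- name_pool[seq_len(kk)]
    out$phenotype <- labels[cl$cluster]
    out$cluster_phenotype <- labels
    out$cluster_median_theta <- med
  }
  out
}

#' Split trackers into weak and strong sub-phenotypes
#'
#' k-means with k = 2 on the one-dimensional \eqn{\bar\theta} values of
#' tracker individuals.  The cluster with the lower threshold centre is
#' the *strong* trackers (they wait almost regardless of energy), the
#' higher one the *weak* trackers.
#'
#' @param theta_bar mean thresholds of tracker individuals.
#' @return Character vector of labels `"strong_tracker"` / `"weak_tracker"`.
#' @export
split_trackers <- function(theta_bar) {
  theta_bar <- as.numeric(theta_bar)
  if (length(theta_bar) < 2) stop("need at least two trackers to split")
  if (length(unique(theta_bar)) < 2) {
    return(rep("strong_tracker", length(theta_bar)))
  }
  cl <- stats::kmeans(matrix(theta_bar, ncol = 1), centers = 2, nstart = 10)
  strong <- which.min(cl$centers)
  ifelse(cl$cluster == strong, "strong_tracker", "weak_tracker")
}

#' Lifetime time budget over the three basic behaviors
#'
#' Fractions of an individual's lived steps spent executing foraging,
#' waiting and mating.  Accepts either per-behaviour step counts or a
#' population table with `steps_foraging`, `steps_waiting`, `steps_mating`
#' columns.
#'
#' @param logs data frame with the three step-count columns (one row per
#'   individual), or a numeric length-3 vector of counts.
#' @return Data frame with columns `foraging`, `waiting`, `mating`, rows
#'   summing to 1 (all-zero rows are rejected).
#' @export
time_budget <- function(logs) {
  if (is.numeric(logs) && length(logs) == 3) {
    logs <- data.frame(steps_foraging = logs[1], steps_waiting = logs[2],
                       steps_mating = logs[3])
  }
  need <- c("steps_foraging", "steps_waiting", "steps_mating")
  if (!all(need %in% names(logs))) {
    stop("logs must contain columns ", paste(need, collapse = ", "))
  }
  m <- as.matrix(logs[, need])
  if (any(m < 0)) stop("negative step counts")
  tot <- rowSums(m)
  if (any(tot == 0)) stop("individual with no logged steps")
  out <- m / tot
  colnames(out) <- c("foraging", "waiting", "mating")
  as.data.frame(out)
}

#' Phenotype a population table
#'
#' Convenience pipeline over a population table (as produced by
#' [run_evolution()] or [generate_fixture_population()]): computes
#' \eqn{\bar\theta} per individual, clusters the (w0, w4) weights, names
#' the clusters, and classifies the population.
#'
#' @param pop data frame with gene columns `gene_1` ... `gene_51`.
#' @param k number of genotype clusters (default 2).
#' @return List with `individuals` (the input plus `theta_bar`, `cluster`,
#'   `phenotype` columns) and `population_label`.
#' @export
phenotype_population <- function(pop, k = 2) {
  gene_cols <- paste0("gene_", 1:5)
  if (!all(gene_cols %in% names(pop))) {
    stop("population table must contain columns gene_1 ... gene_51")
  }
  w <- as.matrix(pop[, gene_cols])
  tb <- mean_threshold(w)
  cl <- cluster_strategy_weights(w[, c(1, 5)], k = k, theta_bar = tb)
  pop$theta_bar <- tb
  pop$cluster <- cl$cluster
  pop$phenotype <- if (!is.null(cl$phenotype)) cl$phenotype else NA_character_
  list(individuals = pop, population_label = classify_population(tb),
       clusters = cl)
}
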