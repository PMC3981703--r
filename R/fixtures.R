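#' Strategy-weight templates of the known phenotypes
#'
#' Hand-built weight vectors \eqn{(w_0 \ldots w_4)} whose mean waiting
#' thresholds sit in the bands that characterise the phenotypes: foragers
#' at \eqn{\bar\theta = 1} (the network never favours mating without a
#' visible face), trackers around 0.40, strong trackers around 0.22 and
#' weak trackers around 0.48.
#'
#' @return Named list of length-5 weight vectors.
#' @export
phenotype_templates <- function() {
  list(
    forager        = c(-0.5, 0.3, 0.3, 0.1, 0.9),
    tracker        = c(0.60, 1, 0.15, -0.05, 0.45),
    weak_tracker   = c(0.54, 1, 0.10, -0.10, 0.50),
    strong_tracker = c(0.80, 1, 0.20, -0.08, 0.30)
  )
}

#' Generate a synthetic phenotype population
#'
#' Builds a population table around the [phenotype_templates()]: strategy
#' weights are the template plus Gaussian noise, shaping and meta genes
#' are drawn uniformly on \[-1, 1\].  Useful for testing the phenotyping
#' and ESS layers without running evolution.
#'
#' @param template one of `"forager"`, `"tracker"`, `"weak_tracker"`,
#'   `"strong_tracker"`, or a named vector of mixture proportions over
#'   them (e.g. `c(forager = 0.25, tracker = 0.75)`).
#' @param n number of individuals (>= 1).
#' @param noise_sd standard deviation of the strategy-weight noise.
#' @return Data frame with columns `individual_id`, `true_phenotype`,
#'   `gene_1` ... `gene_51`.
#' @export
#' @examples
#' pop <- generate_fixture_population("forager", 10, noise_sd = 0)
#' mean_threshold(as.matrix(pop[, paste0("gene_", 1:5)]))  # all 1
generate_fixture_population <- function(template, n, noise_sd = 0.05) {
  if (n < 1) stop("n must be >= 1")
  tmpl <- phenotype_templates()
  if (is.character(template)) {
    template <- stats::setNames(1, match.arg(template, names(tmpl)))
  }
  if (is.null(names(template)) || !all(names(template) %in% names(tmpl))) {
    stop("template must name known phenotypes: ",
         paste(names(tmpl), collapse = ", "))
  }
  if (any(template < 0) || abs(sum(template) - 1) > 1e-8) {
    stop("mixture proportions must sum to 1")
  }
  counts <- stats::rmultinom(1, n, template)[, 1]
  # deterministic counts when proportions are exact multiples
  exact <- template * n
  if (all(abs(exact - round(exact)) < 1e-9)) counts <- round(exact)
  labels <- rep(names(template), counts)
  genes <- matrix(stats::runif(n * GENOME_LENGTH, -1, 1), nrow = n)
  for (i in seq_len(n)) {
    w <- tmpl[[labels[i]]]
    genes[i, STRATEGY_GENES] <- w + stats::rnorm(5, 0, noise_sd)
  }
  out <- data.frame(individual_id = seq_len(n), true_phenotype = labels)
  gd <- as.data.frame(genes)
  names(gd) <- paste0("gene_", seq_len(GENOME_LENGTH))
  cbind(out, gd)
}
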