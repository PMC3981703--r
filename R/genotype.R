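#' @name genotype
#' @title The 51-gene genotype
#'
#' @description
#' Each individual carries 51 real-valued genes, partitioned as:
#' genes 1--5, the weights \eqn{w_0 \ldots w_4} of the linear
#' mating-strategy network (bias, internal energy, energy-source closeness,
#' tail-lamp closeness, face closeness); genes 6--47, the 42 coefficients of
#' the potential-based shaping rewards of the three behaviour learners (14
#' per behaviour); genes 48--51, the squashed meta-parameters of the Sarsa
#' learners (learning rate, discount, trace decay, softmax temperature).
#' The strategy block sits at the *start* of the genome, which together with
#' the low crossover rate makes mixed-strategy offspring rare (see
#' [strategy_mixing_probability()]).
NULL

GENOME_LENGTH <- 51L
STRATEGY_GENES <- 1:5
SHAPING_GENES <- 6:47
META_GENES <- 48:51

#' Decode a genotype into its functional parts
#'
#' @param genes numeric vector of length 51.
#' @return A list with components `strategy_weights` (length 5),
#'   `shaping_genes` (3 x 14 matrix, one row per behaviour in the order
#'   foraging, waiting, mating) and `meta_genes` (length 4, raw genes; see
#'   [decode_meta()] for the squashed meta-parameters).
#' @export
#' @examples
#' g <- random_genotype(1)[1, ]
#' str(decode_genotype(g))
decode_genotype <- function(genes) {
  genes <- as.numeric(genes)
  if (length(genes) != GENOME_LENGTH || anyNA(genes)) {
    stop("a genotype must be 51 finite real genes")
  }
  list(
    strategy_weights = genes[STRATEGY_GENES],
    shaping_genes = matrix(genes[SHAPING_GENES], nrow = 3, byrow = TRUE,
                           dimnames = list(c("foraging", "waiting", "mating"),
                                           NULL)),
    meta_genes = genes[META_GENES]
  )
}

#' Encode genotype parts back into a gene vector
#'
#' Inverse of [decode_genotype()].
#'
#' @param parts list as returned by [decode_genotype()].
#' @return Numeric vector of length 51.
#' @export
encode_genotype <- function(parts) {
  genes <- c(parts$strategy_weights,
             as.numeric(t(parts$shaping_genes)),
             parts$meta_genes)
  if (length(genes) != GENOME_LENGTH) stop("parts do not form 51 genes")
  genes
}

#' Random initial genotypes
#'
#' Initial populations draw every gene i.i.d. uniform on \[-1, 1\].
#'
#' @param n number of genotypes.
#' @return `n` x 51 numeric matrix, one genotype per row.
#' @export
random_genotype <- function(n) {
  stopifnot(n >= 1)
  matrix(stats::runif(n * GENOME_LENGTH, -1, 1), nrow = n)
}

#' Energy-dependent reproduction probability
#'
#' At a successful mating each party independently reproduces with
#' probability proportional to its internal energy: `E / E_max`.
#'
#' @param E current energy level(s), in `[0, E_max]`.
#' @param E_max maximum energy level.
#' @return Probability in `[0, 1]` (vectorised over `E`).
#' @export
reproduction_probability <- function(E, E_max) {
  stopifnot(E_max > 0)
  if (any(E < 0 | E > E_max)) stop("E must lie in [0, E_max]")
  E / E_max
}

#' Create two offspring from a mating pair
#'
#' With probability `crossover_rate` a one-point crossover recombines the
#' two genomes at a cut point uniform over the 50 internal gene boundaries;
#' otherwise the offspring start as copies of parent and partner.  Every
#' gene is then independently mutated with probability `mutation_rate` by
#' adding Gaussian noise `N(0, mutation_sd^2)`.  Both offspring enter the
#' *parent's* subpopulation pool.  Each offspring is attributed to whichever
#' parent contributed the majority of its genes (used for the fitness
#' ledger).
#'
#' @param parent,partner numeric gene vectors of length 51.
#' @param crossover_rate probability of one-point crossover.
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sd mutation standard deviation.
#' @return List with `offspring` (2 x 51 matrix), `crossed` (flag),
#'   `cut` (cut point after gene `cut`, or NA), and `attribution`
#'   (length-2 vector with values "parent"/"partner").
#' @export
reproduce <- function(parent, partner, crossover_rate = 0.1,
                      mutation_rate = 0.1, mutation_sd = 0.1) {
  L <- GENOME_LENGTH
  crossed <- stats::runif(1) < crossover_rate
  if (crossed) {
    cut <- sample.int(L - 1L, 1L)  # cut after gene `cut`
    o1 <- c(parent[1:cut], partner[(cut + 1L):L])
    o2 <- c(partner[1:cut], parent[(cut + 1L):L])
    # majority of genes decides attribution; L is odd so no ties
    attribution <- if (cut > L / 2) c("parent", "partner") else c("partner", "parent")
  } else {
    cut <- NA_integer_
    o1 <- parent
    o2 <- partner
    attribution <- c("parent", "partner")
  }
  off <- rbind(o1, o2, deparse.level = 0)
  if (mutation_rate > 0) {
    hit <- matrix(stats::runif(2 * L) < mutation_rate, nrow = 2)
    nhit <- sum(hit)
    if (nhit > 0) off[hit] <- off[hit] + stats::rnorm(nhit, 0, mutation_sd)
  }
  list(offspring = off, crossed = crossed, cut = cut, attribution = attribution)
}

#' Probability that an offspring mixes strategy genes of both parents
#'
#' Under one-point crossover applied with probability `pc`, with the cut
#' point uniform over the `L - 1` internal gene boundaries, an offspring's
#' leading block of `k` strategy genes contains genes from both parents
#' exactly when crossover fires and the cut falls strictly inside the block:
#' \deqn{P = p_c (k - 1) / (L - 1).}
#' At the defaults (L = 51, k = 5, pc = 0.1) this is 0.008, i.e. the 0.8%
#' chance that keeps mating-strategy lineages genetically coherent.
#'
#' @param L genome length.
#' @param k length of the leading strategy block.
#' @param pc crossover probability.
#' @return Probability of a mixed strategy block.
#' @export
#' @examples
#' strategy_mixing_probability(51, 5, 0.1)  # 0.008
strategy_mixing_probability <- function(L, k, pc) {
  stopifnot(L >= 2, k >= 1, k <= L, pc >= 0, pc <= 1)
  pc * (k - 1) / (L - 1)
}

#' Monte-Carlo estimate of the strategy-mixing probability
#'
#' Simulates `n` reproduction events (crossover Bernoulli plus uniform cut
#' point) and counts offspring whose leading `k`-gene block mixes both
#' parents.  Serves as an independent stochastic check of
#' [strategy_mixing_probability()].
#'
#' @inheritParams strategy_mixing_probability
#' @param n number of simulated reproduction events.
#' @return List with `estimate`, `se` (binomial standard error) and `n`.
#' @export
simulate_strategy_mixing <- function(n, L = 51, k = 5, pc = 0.1) {
  stopifnot(n >= 1)
  crossed <- stats::runif(n) < pc
  cut <- sample.int(L - 1L, n, replace = TRUE)
  mixed <- crossed & cut >= 1L & cut <= (k - 1L)
  p <- mean(mixed)
  list(estimate = p, se = sqrt(p * (1 - p) / n), n = as.integer(n))
}
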