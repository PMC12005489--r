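#' Empirical trait distribution of a population
#'
#' The discrete probability map over calcium oscillation frequencies (or
#' any discrete trait): support values are the sorted distinct observed
#' values, probabilities their relative frequencies.
#'
#' @param values numeric vector of per-agent trait values (nonempty).
#' @return An object of class `trait_distribution` with `support`,
#'   `probabilities` (summing to 1) and `n_agents`.
#' @export
trait_distribution <- function(values) {
  if (length(values) == 0) stop("cannot build a distribution from no agents")
  tab <- table(values)
  structure(
    list(support = as.numeric(names(tab)),
         probabilities = as.numeric(tab) / length(values),
         n_agents = length(values)),
    class = "trait_distribution")
}

#' @export
print.trait_distribution <- function(x, ...) {
  cat(sprintf("<trait_distribution> %d agents, %d distinct values\n",
              x$n_agents, length(x$support)))
  print(stats::setNames(round(x$probabilities, 4), x$support))
  invisible(x)
}

#' Probability of one trait value under a distribution
#' @param d a [trait_distribution()].
#' @param value trait value(s).
#' @return Probability (0 for values outside the support).
#' @export
trait_probability <- function(d, value) {
  p <- d$probabilities[match(value, d$support)]
  p[is.na(p)] <- 0
  p
}

#' Cumulative distribution over the sorted support
#' @param d a [trait_distribution()].
#' @return Data frame with `value` and `cumulative` (nondecreasing, last
#'   entry 1).
#' @export
cumulative_distribution <- function(d) {
  data.frame(value = d$support, cumulative = cumsum(d$probabilities))
}

#' Posterior probability of egg contact given a trait value
#'
#' Bayes' theorem applied to the simulation bookkeeping: for trait value i
#' with initial relative proportion q_i and likelihood P(q_i | contact)
#' (the trait distribution among contacting agents), the posterior fitness
#' is `P(contact | q_i) = P(contact) * P(q_i | contact) / q_i`, with the
#' flat prior P(contact) = 1/N by default (every agent assumed an equal
#' chance of contact before the outcome is observed). Trait values absent
#' among contactors get posterior 0. The total-probability identity
#' `sum_i posterior_i * q_i = prior` holds exactly.
#'
#' @param initial a [trait_distribution()] of the initial population.
#' @param contactors trait values of the agents that contacted the egg
#'   (must all occur in the initial support).
#' @param prior prior contact probability; default `1 / initial$n_agents`.
#' @return Data frame with `value`, `q` (initial), `likelihood`, and
#'   `posterior`.
#' @export
posterior_contact <- function(initial, contactors, prior = NULL) {
  if (is.null(prior)) prior <- 1 / initial$n_agents
  stopifnot(prior > 0, prior <= 1)
  if (length(contactors) == 0) stop("no contacting agents")
  if (!all(contactors %in% initial$support))
    stop("contactor trait absent from the initial population (bookkeeping bug)")
  lik <- trait_distribution(contactors)
  likelihood <- trait_probability(lik, initial$support)
  posterior <- prior * likelihood / initial$probabilities
  data.frame(value = initial$support, q = initial$probabilities,
             likelihood = likelihood, posterior = posterior)
}

#' Relative information gain (Kullback-Leibler divergence)
#'
#' `D(q' || q) = sum_i q'_i * log2(q'_i / q_i)` in bits, the magnitude of
#' selection between the post-selection distribution q' and the initial
#' distribution q. Zero terms follow the 0 * log 0 = 0 convention; the
#' result is nonnegative, zero exactly when the distributions coincide,
#' and not symmetric in its arguments. Requires support(q') within
#' support(q), which holds whenever q' describes a subset of the agents
#' behind q.
#'
#' @param q_prime,q [trait_distribution()] objects (or numeric vectors of
#'   probabilities over a shared support in the same order).
#' @return Information gain in bits.
#' @export
relative_information_gain <- function(q_prime, q) {
  if (inherits(q_prime, "trait_distribution") &&
      inherits(q, "trait_distribution")) {
    support <- q$support
    if (!all(q_prime$support %in% support))
      stop("q' has mass outside the support of q (bookkeeping bug)")
    p <- trait_probability(q_prime, support)
    base <- q$probabilities
  } else {
    p <- as.numeric(q_prime); base <- as.numeric(q)
    stopifnot(length(p) == length(base))
    if (any(p > 0 & base == 0))
      stop("q' has mass outside the support of q (bookkeeping bug)")
  }
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / base[nz]))
}

#' Selection summary of one simulation run
#'
#' Bundles the initial trait distribution, the contactor distribution, the
#' Bayesian posterior table and the relative information gain for a run.
#'
#' @param initial_values per-agent trait values of the full population.
#' @param contactor_values trait values of the contacting agents
#'   ("contactor": any agent with positive accrued egg-contact time).
#' @param prior prior contact probability; default 1/N.
#' @return An object of class `selection_summary`.
#' @export
selection_summary <- function(initial_values, contactor_values,
                              prior = NULL) {
  q <- trait_distribution(initial_values)
  qp <- trait_distribution(contactor_values)
  structure(
    list(initial = q,
         contactors = qp,
         posterior = posterior_contact(q, contactor_values, prior),
         information_gain_bits = relative_information_gain(qp, q),
         n_contactors = length(contactor_values)),
    class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf(
    "<selection_summary> %d/%d agents contacted; information gain %.3f bits\n",
    x$n_contactors, x$initial$n_agents, x$information_gain_bits))
  print(x$posterior)
  invisible(x)
}
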