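#' Sample calcium oscillation frequencies
#'
#' Each agent carries an intracellular calcium oscillator with an integer
#' frequency Omega_i (Hz) drawn from a Poisson distribution with mean
#' `lambda`. Zero draws are kept: an agent with Omega_i = 0 never crosses
#' the gating threshold and so never changes motility state, a real
#' mechanism that distinguishes low-lambda populations.
#'
#' @param lambda mean oscillation frequency (Hz, > 0).
#' @param n number of agents.
#' @return Integer vector of `n` frequencies.
#' @export
sample_frequencies <- function(lambda, n) {
  if (lambda <= 0) stop("lambda must be positive")
  stopifnot(n >= 0)
  stats::rpois(n, lambda)
}

#' Intracellular calcium level of an oscillator
#'
#' The oscillator is `Ca(t) = (1 - cos(2 * pi * Omega * t)) / 2`, a squared
#' sine normalised to \[0, 1\], with phase zero at t = 0. Omega is a cyclic
#' frequency in Hz.
#'
#' @param omega_hz oscillation frequency in Hz (scalar or vector).
#' @param t time in seconds (scalar or vector).
#' @return Calcium level(s) in \[0, 1\].
#' @export
calcium_level <- function(omega_hz, t) {
  (1 - cos(2 * pi * omega_hz * t)) / 2
}

#' Calcium-gated Markov model of motility-state switching
#'
#' Motility-state changes are stochastic and time-homogeneous: whenever an
#' agent's calcium level exceeds `ca_threshold` (a fraction of the maximum,
#' default 0.97) at a sampled step, its next state is drawn from the row of
#' the transition matrix for its current state; below the threshold the
#' state is held with probability 1. The default matrix is the calibrated
#' five-state table in which "weak" is nearly absorbing (self-transition
#' 0.99, the only exit a 0.01 flow to "slow"), so populations drain towards
#' weak motility over long runs. `strict_absorbing = TRUE` zeroes that exit
#' and renormalises, making weak truly absorbing.
#'
#' @param transition_matrix optional 5 x 5 row-stochastic matrix (rows and
#'   columns in [motility_states()] order); default the built-in table.
#' @param ca_threshold gating threshold as a fraction of the calcium
#'   maximum.
#' @param strict_absorbing make the weak state strictly absorbing.
#' @return An object of class `markov_motility_model`.
#' @export
markov_motility_model <- function(transition_matrix = NULL,
                                  ca_threshold = 0.97,
                                  strict_absorbing = FALSE) {
  if (is.null(transition_matrix)) transition_matrix <- default_transition_matrix()
  P <- as.matrix(transition_matrix)
  stopifnot(nrow(P) == 5, ncol(P) == 5, all(P >= 0))
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  if (strict_absorbing) {
    P[5, ] <- c(0, 0, 0, 0, 1)
  }
  dimnames(P) <- list(motility_states(), motility_states())
  stopifnot(ca_threshold >= 0, ca_threshold <= 1)
  structure(list(transition_matrix = P, ca_threshold = ca_threshold),
            class = "markov_motility_model")
}

#' Built-in motility-state transition matrix
#' @return The default 5 x 5 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  P <- matrix(c(
    0.95, 0.02, 0.01, 0.01, 0.01,
    0.02, 0.94, 0.02, 0.01, 0.01,
    0.01, 0.02, 0.94, 0.02, 0.01,
    0.00, 0.01, 0.02, 0.95, 0.02,
    0.00, 0.00, 0.00, 0.01, 0.99), nrow = 5, byrow = TRUE)
  dimnames(P) <- list(motility_states(), motility_states())
  P
}

#' Load a transition matrix from a CSV or JSON table
#'
#' CSV tables must be 5 x 5 numeric with optional header/rownames matching
#' [motility_states()]; JSON tables are a nested array in state order.
#'
#' @param path file path (`.csv` or `.json`).
#' @inheritParams markov_motility_model
#' @return A [markov_motility_model()].
#' @export
load_transition_matrix <- function(path, ca_threshold = 0.97) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    P <- do.call(rbind, jsonlite::read_json(path, simplifyVector = TRUE))
    if (is.list(P)) P <- matrix(unlist(P), nrow = 5, byrow = TRUE)
  } else {
    tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    P <- as.matrix(tab)
  }
  markov_motility_model(matrix(as.numeric(P), 5, 5,
                               dimnames = list(motility_states(),
                                               motility_states())),
                        ca_threshold = ca_threshold)
}

#' @export
print.markov_motility_model <- function(x, ...) {
  cat(sprintf("<markov_motility_model> gate: Ca > %g of maximum\n",
              x$ca_threshold))
  print(round(x$transition_matrix, 3))
  invisible(x)
}

#' Apply one gated transition opportunity
#'
#' If `ca_level` exceeds the model's gating threshold the next state is
#' drawn from the current state's transition-matrix row (self-transitions
#' allowed); otherwise the state is returned unchanged.
#'
#' @param state current state name (one of [motility_states()]).
#' @param ca_level calcium level in \[0, 1\].
#' @param model a [markov_motility_model()].
#' @return The next state name.
#' @export
maybe_transition <- function(state, ca_level, model) {
  states <- motility_states()
  i <- match(state, states)
  if (is.na(i)) stop(sprintf("unknown motility state '%s'", state))
  stopifnot(ca_level >= 0, ca_level <= 1)
  if (ca_level <= model$ca_threshold) return(state)
  u <- stats::runif(1)
  states[transition_index(model$transition_matrix[i, ], u)]
}

# first index whose cumulative row probability exceeds u
# (identical lookup is used by the C++ engine)
transition_index <- function(row, u) {
  cs <- cumsum(row)
  for (j in seq_along(cs)) if (u <= cs[j]) return(j)
  length(cs)
}

#' Stationary distribution of a motility transition matrix
#'
#' The left eigenvector for eigenvalue 1 of the (eligible-step) chain,
#' normalised to sum to 1. For reducible matrices the recurrent classes
#' are reported instead of a unique stationary vector.
#'
#' @param model a [markov_motility_model()] or a row-stochastic matrix.
#' @return Named probability vector over the five states, or (reducible
#'   case) a list with `absorbing_classes`.
#' @export
stationary_distribution <- function(model) {
  P <- if (inherits(model, "markov_motility_model"))
    model$transition_matrix else as.matrix(model)
  n <- nrow(P)
  # irreducibility: every state reachable from every other
  reach <- (P > 0) | diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  if (!all(reach)) {
    # recurrent states: mutually reachable with everything they reach
    recurrent <- vapply(seq_len(n), function(i)
      all(reach[which(reach[i, ]), i]), logical(1))
    return(list(absorbing_classes = which(recurrent)))
  }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, rownames(P) %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Motility-state occupancy over time for an oscillating population
#'
#' Simulates the gated Markov dynamics alone (no spatial motion): all
#' agents start progressive; at each step of length tau an agent whose
#' calcium level exceeds the gate draws a transition. Returns the fraction
#' of agents in each state at every step.
#'
#' @param frequencies integer vector of per-agent oscillation frequencies
#'   (Hz), e.g. from [sample_frequencies()].
#' @param model a [markov_motility_model()].
#' @param n_steps number of model steps of length `tau`.
#' @param tau step length in seconds.
#' @return Matrix `(n_steps + 1) x 5` of state fractions; row 1 is t = 0
#'   (all progressive).
#' @export
occupancy_timecourse <- function(frequencies, model, n_steps,
                                 tau = model_time_step()) {
  n <- length(frequencies)
  stopifnot(n >= 1)
  P <- model$transition_matrix
  cum <- t(apply(P, 1, cumsum))
  state <- rep(1L, n)
  occ <- matrix(0, n_steps + 1, 5,
                dimnames = list(NULL, motility_states()))
  occ[1, ] <- tabulate(state, 5) / n
  for (k in seq_len(n_steps)) {
    ca <- calcium_level(frequencies, k * tau)
    idx <- which(ca > model$ca_threshold)
    if (length(idx)) {
      u <- stats::runif(length(idx))
      state[idx] <- max.col(u <= cum[state[idx], , drop = FALSE],
                            ties.method = "first")
    }
    occ[k + 1, ] <- tabulate(state, 5) / n
  }
  occ
}
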