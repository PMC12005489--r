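#' Simulation configuration
#'
#' Bundles everything needed for one run: environment, population size and
#' composition, stop rule, placement policy and master seed.
#'
#' Composition modes: `"fixed"` assigns each agent a permanent motility
#' class from `class_mix`; `"markov"` starts every agent progressive,
#' assigns Poisson(`lambda`) calcium oscillation frequencies, and lets the
#' gated Markov model switch states over time.
#'
#' Stop rules: `"first_contact"` ends at the first egg contact;
#' `"cumulative_contact"` ends once the summed egg-contact time over all
#' agents reaches `contact_threshold_s` (default 5 s — the assumption
#' being that after that much total contact, fertilisation has happened if
#' it is going to); `"fixed_duration"` runs for `duration_s` of model time.
#' All runs are additionally capped at `max_steps` steps, reported as a
#' `"timeout"` end reason rather than an error.
#'
#' @param env a [grid_environment()].
#' @param n_agents number of agents (agents may overlap freely).
#' @param mode `"fixed"` or `"markov"`.
#' @param class_mix named numeric vector of class counts or proportions
#'   over [motility_states()] (fixed mode). `"mixed"` is shorthand for
#'   equal proportions.
#' @param lambda mean calcium oscillation frequency in Hz (markov mode).
#' @param model a [markov_motility_model()] (markov mode).
#' @param stop_rule one of `"first_contact"`, `"cumulative_contact"`,
#'   `"fixed_duration"`.
#' @param contact_threshold_s cumulative contact-time threshold (seconds).
#' @param duration_s run length for `"fixed_duration"` (seconds).
#' @param placement `"start_region"` (uniform over the start cells) or
#'   `"uniform"` (uniform over all corridor cells).
#' @param max_steps hard step cap.
#' @param record_trajectories,record_occupancy store per-step positions /
#'   state fractions in the result.
#' @param param_table optional 5 x 4 numeric matrix overriding the
#'   built-in movement parameters (rows in [motility_states()] order,
#'   columns v, sigma_r, omega, sigma_theta), mainly for controlled
#'   kinematics tests.
#' @param seed master seed (integer) or `NULL` to use the current RNG
#'   state.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(env, n_agents,
                              mode = c("fixed", "markov"),
                              class_mix = "mixed", lambda = 10,
                              model = markov_motility_model(),
                              stop_rule = c("fixed_duration",
                                            "first_contact",
                                            "cumulative_contact"),
                              contact_threshold_s = 5,
                              duration_s = 2,
                              placement = c("start_region", "uniform"),
                              max_steps = 1e6,
                              record_trajectories = FALSE,
                              record_occupancy = FALSE,
                              param_table = NULL,
                              seed = NULL) {
  mode <- match.arg(mode)
  stop_rule <- match.arg(stop_rule)
  placement <- match.arg(placement)
  stopifnot(n_agents >= 1, contact_threshold_s > 0)
  if (identical(class_mix, "mixed"))
    class_mix <- stats::setNames(rep(1, 5), motility_states())
  structure(
    list(env = env, n_agents = as.integer(n_agents), mode = mode,
         class_mix = class_mix, lambda = lambda, model = model,
         stop_rule = stop_rule, contact_threshold_s = contact_threshold_s,
         duration_s = duration_s, placement = placement,
         max_steps = max_steps,
         record_trajectories = record_trajectories,
         record_occupancy = record_occupancy,
         param_table = param_table, seed = seed),
    class = "simulation_config")
}

#' Initialise an agent population
#'
#' Places `n_agents` on corridor cells according to the placement policy
#' (agents may share cells — paths cross freely), draws headings uniformly
#' on \[0, 2*pi), and assigns motility classes: markov mode starts every
#' agent progressive with a Poisson(lambda) oscillation frequency; fixed
#' mode deals classes out according to `class_mix`.
#'
#' Consumes the current RNG stream; call inside a seeded context for
#' reproducibility (done by [run_simulation()]).
#'
#' @param config a [simulation_config()].
#' @return A list with vectors `x`, `y` (um), `heading` (rad), `state`
#'   (integer, [motility_states()] order), `omega_hz` (length 0 in fixed
#'   mode).
#' @export
initialize_population <- function(config) {
  env <- config$env
  n <- config$n_agents
  cells <- if (config$placement == "start_region") {
    config$env$start_cells
  } else {
    which(!env$barrier, arr.ind = TRUE)
  }
  idx <- pmin(floor(stats::runif(n) * nrow(cells)) + 1L, nrow(cells))
  cs <- env$cell_size_um
  x <- (cells[idx, 1] - 1 + stats::runif(n)) * cs
  y <- (cells[idx, 2] - 1 + stats::runif(n)) * cs
  heading <- stats::runif(n, 0, 2 * pi)
  if (config$mode == "markov") {
    state <- rep(1L, n)
    omega <- as.numeric(sample_frequencies(config$lambda, n))
  } else {
    mix <- config$class_mix[motility_states()]
    mix[is.na(mix)] <- 0
    counts <- round(mix / sum(mix) * n)
    while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
    while (sum(counts) < n) counts[which.min(counts)] <- counts[which.min(counts)] + 1
    state <- rep(seq_len(5), times = counts)
    omega <- numeric(0)
  }
  list(x = x, y = y, heading = heading, state = state, omega_hz = omega)
}

#' Resolve a proposed move against barriers and arena walls
#'
#' If the proposed position falls in a barrier cell or outside the arena,
#' the agent keeps its current position this step and its heading is
#' redrawn uniformly from the half-circle centred on the inward normal of
#' the blocked cell face (both faces for a corner hit), then perturbed by
#' the agent's class-specific angular noise. Otherwise the move stands.
#'
#' @param position current position (um), guaranteed on a corridor cell.
#' @param proposed proposed position (um).
#' @param heading heading after the motion update (rad).
#' @param class a [motility_class()].
#' @param env a [grid_environment()].
#' @return List with resolved `position`, `heading`, and logical
#'   `blocked`.
#' @export
handle_barrier <- function(position, proposed, heading, class, env) {
  cs <- env$cell_size_um
  pc <- floor(proposed / cs)       # 0-based
  nx <- nrow(env$barrier); ny <- ncol(env$barrier)
  inside <- pc[1] >= 0 && pc[1] < nx && pc[2] >= 0 && pc[2] < ny
  blocked <- !inside || env$barrier[pc[1] + 1, pc[2] + 1]
  if (!blocked)
    return(list(position = proposed, heading = heading, blocked = FALSE))
  cc <- floor(position / cs)
  if (!inside || env$barrier[cc[1] + 1, cc[2] + 1] == FALSE) {
    # fine either way; current cell must be corridor
  }
  if (env$barrier[cc[1] + 1, cc[2] + 1])
    stop("agent already inside a barrier cell (engine invariant violated)")
  normal <- atan2(cc[2] - pc[2], cc[1] - pc[1])
  u <- stats::runif(1)
  eta <- stats::rnorm(1)
  heading <- normal + pi * (u - 0.5) + class$sigma_theta * pi / 180 * eta
  list(position = position, heading = heading, blocked = TRUE)
}

#' Run one simulation
#'
#' Advances the world in steps of tau = 1/25.4 s until the configured stop
#' rule fires (or the step cap is hit). Within each step every agent is
#' updated: (1) calcium gating and possible Markov state transition
#' (markov mode), (2) the motion step for its current class, (3) barrier
#' and wall handling, (4) search-coverage marking, (5) egg-contact accrual
#' (+tau whenever the agent's cell is the egg cell). Agents do not
#' interact, so update order has no effect; draws are made in fixed
#' agent-index order from a single seeded RNG, making runs bit-for-bit
#' reproducible for a given seed.
#'
#' @param config a [simulation_config()].
#' @param engine `"cpp"` (compiled stepper, default) or `"r"` (pure-R
#'   reference stepper with the identical RNG draw order; slow, intended
#'   for validation).
#' @return An object of class `simulation_result`: `end_reason`
#'   (`"first_contact"`, `"cumulative_contact"`, `"duration"`,
#'   `"timeout"`), `n_steps`, `elapsed_s`, `time_to_first_contact_s`
#'   (`NA` if none), per-agent `contact_time_s`, `omega_hz` and final
#'   `state`, search coverage (`search_fraction`, `area_searched_um2`,
#'   and the same at first contact), the final visited mask, and
#'   optionally `trajectories` and `occupancy`.
#' @export
run_simulation <- function(config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initialize_population(config)
  env <- config$env
  stop_code <- match(config$stop_rule,
                     c("first_contact", "cumulative_contact",
                       "fixed_duration"))
  duration_steps <- as.integer(ceiling(config$duration_s / model_time_step()))
  markov <- config$mode == "markov"
  raw <- if (engine == "cpp") {
    run_engine_cpp(env$barrier, env$cell_size_um, env$egg_cell,
                   pop$x, pop$y, pop$heading, pop$state,
                   if (markov) pop$omega_hz else numeric(0),
                   config$model$transition_matrix,
                   config$model$ca_threshold,
                   config$param_table %||% class_param_matrix(),
                   model_time_step(),
                   stop_code, config$contact_threshold_s,
                   duration_steps, config$max_steps,
                   config$record_trajectories, config$record_occupancy)
  } else {
    run_engine_r(env, pop, markov, config, stop_code, duration_steps)
  }
  tau <- model_time_step()
  corridor_n <- sum(!env$barrier)
  fc <- raw$first_contact_step
  structure(list(
    end_reason = c("first_contact", "cumulative_contact", "duration",
                   "timeout")[raw$end_reason],
    n_steps = raw$n_steps,
    elapsed_s = raw$n_steps * tau,
    time_to_first_contact_s = if (fc >= 0) fc * tau else NA_real_,
    contact_time_s = raw$contact_time_s,
    omega_hz = pop$omega_hz,
    state = raw$state,
    x = raw$x, y = raw$y, heading = raw$heading,
    visited = raw$visited,
    search_fraction = raw$n_visited / corridor_n,
    area_searched_um2 = raw$n_visited * env$cell_size_um^2,
    search_fraction_at_first_contact =
      if (fc >= 0) raw$visited_at_first_contact / corridor_n else NA_real_,
    area_at_first_contact_um2 =
      if (fc >= 0) raw$visited_at_first_contact * env$cell_size_um^2
      else NA_real_,
    trajectories = if (config$record_trajectories)
      structure(list(x = raw$traj_x, y = raw$traj_y, dt = tau),
                class = "trajectory_set"),
    occupancy = raw$occupancy,
    config = config), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d agents, %g steps (%.2f s model time), ended: %s\n",
    length(x$contact_time_s), x$n_steps, x$elapsed_s, x$end_reason))
  cat(sprintf(
    "  first contact: %s | total contact: %.2f s | searched %.1f%% (%g um^2)\n",
    if (is.na(x$time_to_first_contact_s)) "none"
    else sprintf("%.2f s", x$time_to_first_contact_s),
    sum(x$contact_time_s), 100 * x$search_fraction, x$area_searched_um2))
  invisible(x)
}

# Pure-R reference stepper. Mirrors run_engine_cpp draw for draw.
run_engine_r <- function(env, pop, markov, config, stop_code,
                         duration_steps, k0 = 0L) {
  tau <- model_time_step()
  cs <- env$cell_size_um
  nx <- nrow(env$barrier); ny <- ncol(env$barrier)
  egg <- env$egg_cell - 1L
  P <- config$model$transition_matrix
  thr <- config$model$ca_threshold
  pars <- config$param_table %||% class_param_matrix()
  om_rad <- pars[, 3] * (pi / 180)
  sth_rad <- pars[, 4] * (pi / 180)
  sqrt_tau <- sqrt(tau)
  n <- length(pop$x)
  x <- pop$x; y <- pop$y; th <- pop$heading; st <- pop$state
  om <- pop$omega_hz
  visited <- matrix(FALSE, nx, ny)
  n_visited <- 0
  contact <- numeric(n)
  first_contact_step <- -1
  visited_at_first <- -1
  for (i in seq_len(n)) {
    cc <- floor(c(x[i], y[i]) / cs)
    if (env$barrier[cc[1] + 1, cc[2] + 1])
      stop("agent initialised outside the corridor")
    if (!visited[cc[1] + 1, cc[2] + 1]) {
      visited[cc[1] + 1, cc[2] + 1] <- TRUE
      n_visited <- n_visited + 1
    }
    if (all(cc == egg) && first_contact_step < 0) {
      first_contact_step <- 0
      visited_at_first <- n_visited
    }
  }
  traj_x <- if (config$record_trajectories) list(x) else NULL
  traj_y <- if (config$record_trajectories) list(y) else NULL
  occ <- if (config$record_occupancy) list(tabulate(st, 5) / n) else NULL
  k <- k0
  end_reason <- 0L
  if (stop_code == 1 && first_contact_step == 0) end_reason <- 1L
  while (end_reason == 0L) {
    if (k - k0 >= config$max_steps) { end_reason <- 4L; break }
    s <- if (k %% 2 == 0) 1 else -1
    t_now <- (k + 1) * tau
    for (i in seq_len(n)) {
      if (markov && om[i] > 0) {
        ca <- 0.5 * (1 - cos(2 * pi * om[i] * t_now))
        if (ca > thr) {
          u <- stats::runif(1)
          st[i] <- transition_index(P[st[i], ], u)
        }
      }
      cls <- st[i]
      eta_th <- stats::rnorm(1)
      th[i] <- th[i] + (s * om_rad[cls] + sth_rad[cls] * eta_th)
      eta_r <- stats::rnorm(1)
      step_len <- pars[cls, 1] * tau + pars[cls, 2] * sqrt_tau * eta_r
      px <- x[i] + step_len * cos(th[i])
      py <- y[i] + step_len * sin(th[i])
      pc <- floor(c(px, py) / cs)
      blocked <- pc[1] < 0 || pc[1] >= nx || pc[2] < 0 || pc[2] >= ny ||
        env$barrier[pc[1] + 1, pc[2] + 1]
      if (blocked) {
        cc <- floor(c(x[i], y[i]) / cs)
        normal <- atan2(cc[2] - pc[2], cc[1] - pc[1])
        u2 <- stats::runif(1)
        eta_p <- stats::rnorm(1)
        th[i] <- normal + pi * (u2 - 0.5) + sth_rad[cls] * eta_p
      } else {
        x[i] <- px; y[i] <- py
        if (!visited[pc[1] + 1, pc[2] + 1]) {
          visited[pc[1] + 1, pc[2] + 1] <- TRUE
          n_visited <- n_visited + 1
        }
      }
      cc <- floor(c(x[i], y[i]) / cs)
      if (all(cc == egg)) {
        contact[i] <- contact[i] + tau
        if (first_contact_step < 0) {
          first_contact_step <- k + 1
          visited_at_first <- n_visited
        }
      }
    }
    k <- k + 1
    if (config$record_trajectories) {
      traj_x[[k - k0 + 1]] <- x; traj_y[[k - k0 + 1]] <- y
    }
    if (config$record_occupancy) occ[[k - k0 + 1]] <- tabulate(st, 5) / n
    if (stop_code == 1 && first_contact_step >= 0) end_reason <- 1L
    else if (stop_code == 2 &&
             sum(contact) >= config$contact_threshold_s - 1e-12)
      end_reason <- 2L
    else if (stop_code == 3 && k - k0 >= duration_steps) end_reason <- 3L
  }
  list(end_reason = end_reason, n_steps = k - k0,
       first_contact_step = first_contact_step,
       visited_at_first_contact = visited_at_first,
       contact_time_s = contact, x = x, y = y, heading = th, state = st,
       visited = visited, n_visited = n_visited,
       traj_x = if (!is.null(traj_x)) do.call(cbind, traj_x),
       traj_y = if (!is.null(traj_y)) do.call(cbind, traj_y),
       occupancy = if (!is.null(occ)) do.call(rbind, occ))
}

#' Advance a world list by one step (reference semantics)
#'
#' Single-step driver over the pure-R reference engine, mainly useful for
#' inspecting the step contract in tests. `world` is a list with `env`,
#' `pop` (as from [initialize_population()]), `config`, `step_index`, and
#' accumulators created on first use.
#'
#' @param world a world list; create with [make_world()].
#' @return The advanced world.
#' @export
step_world <- function(world) {
  cfg <- world$config
  cfg$max_steps <- 1
  cfg$record_trajectories <- FALSE
  cfg$record_occupancy <- FALSE
  cfg$stop_rule <- "fixed_duration"
  raw <- run_engine_r(world$env, world$pop,
                      cfg$mode == "markov", cfg, 3L, 1L,
                      k0 = world$step_index)
  world$pop$x <- raw$x; world$pop$y <- raw$y
  world$pop$heading <- raw$heading; world$pop$state <- raw$state
  world$contact_time_s <- world$contact_time_s + raw$contact_time_s
  world$env$visited <- world$env$visited | raw$visited
  world$step_index <- world$step_index + 1L
  world
}

#' @rdname step_world
#' @param config a [simulation_config()].
#' @export
make_world <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initialize_population(config)
  list(env = config$env, pop = pop, config = config,
       contact_time_s = numeric(config$n_agents), step_index = 0L)
}
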