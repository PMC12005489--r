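#' Replicate seeds derived from a master seed
#'
#' Deterministic per-replicate seeds: `master * 10007 + index`, folded into
#' the 32-bit integer range. Logged in every sweep table so any single
#' replicate can be re-run in isolation.
#'
#' @param master master seed (integer).
#' @param n number of seeds.
#' @return Integer vector of length `n`.
#' @export
replicate_seeds <- function(master, n) {
  as.integer((as.double(master) * 10007 + seq_len(n)) %% 2147483647)
}

#' Ensemble search sweep over motility compositions
#'
#' Fixed-composition populations (default 250 agents, the five pure
#' classes plus the equal "mixed" ensemble) searching an arena for a fixed
#' duration (default 2 s, a typical CASA acquisition window), with
#' per-step RMSD and search-progress curves.
#'
#' @param compositions named list of class-mix specifications (values
#'   accepted by [simulation_config()]'s `class_mix`).
#' @param env arena; default the open bundled arena.
#' @param n_agents agents per simulation.
#' @param duration_s run length (s).
#' @param replicates replicate runs per composition.
#' @param seed master seed.
#' @return A list with `curves` (data frame: composition, replicate, step,
#'   t_s, rmsd_um, search_fraction) and `summary` (final-step medians).
#' @export
sweep_motility_composition <- function(
    compositions = c(as.list(stats::setNames(motility_states(),
                                             motility_states())),
                     list(mixed = "mixed")),
    env = maze_fixture("A"), n_agents = 250, duration_s = 2,
    replicates = 1, seed = 1) {
  rows <- list()
  for (ci in seq_along(compositions)) {
    comp <- compositions[[ci]]
    mix <- if (identical(comp, "mixed")) "mixed"
    else if (is.character(comp)) stats::setNames(1, comp)
    else comp
    seeds <- replicate_seeds(seed + ci * 1000L, replicates)
    for (r in seq_len(replicates)) {
      cfg <- simulation_config(env, n_agents, mode = "fixed",
                               class_mix = mix,
                               stop_rule = "fixed_duration",
                               duration_s = duration_s,
                               placement = "uniform",
                               record_trajectories = TRUE,
                               seed = seeds[r])
      res <- run_simulation(cfg)
      tr <- res$trajectories
      r_curve <- rmsd(tr)
      vis_curve <- cumulative_search_fraction(res, env)
      rows[[length(rows) + 1]] <- data.frame(
        composition = names(compositions)[ci], replicate = r,
        step = seq_along(r_curve) - 1L,
        t_s = (seq_along(r_curve) - 1) * tr$dt,
        rmsd_um = r_curve, search_fraction = vis_curve)
    }
  }
  curves <- do.call(rbind, rows)
  final <- curves[curves$step == max(curves$step), ]
  summary <- do.call(rbind, lapply(split(final, final$composition),
    function(d) data.frame(composition = d$composition[1],
                           rmsd_um = stats::median(d$rmsd_um),
                           search_fraction = stats::median(d$search_fraction))))
  rownames(summary) <- NULL
  list(curves = curves, summary = summary)
}

# per-step cumulative distinct-cell fraction from recorded trajectories
cumulative_search_fraction <- function(res, env) {
  tr <- res$trajectories
  cs <- env$cell_size_um
  nx <- nrow(env$barrier)
  corridor_n <- sum(!env$barrier)
  m <- ncol(tr$x)
  seen <- logical(nx * ncol(env$barrier))
  out <- numeric(m)
  count <- 0
  for (j in seq_len(m)) {
    idx <- (floor(tr$y[, j] / cs)) * nx + floor(tr$x[, j] / cs) + 1
    new <- unique(idx[!seen[idx]])
    count <- count + length(new)
    seen[new] <- TRUE
    out[j] <- count / corridor_n
  }
  out
}

#' First-contact sweep over sperm number
#'
#' Progressive-only populations of increasing size searching until the
#' first egg contact; replicates per population size. Captures the time to
#' first contact and the area searched at that moment.
#'
#' @param env arena (default open bundled arena).
#' @param n_values vector of population sizes.
#' @param replicates replicates per size.
#' @param seed master seed.
#' @param maze_label label recorded in the output.
#' @param placement placement policy. The default places all agents in
#'   the arena's designated start region, which reproduces the published
#'   density laws (more agents search more space before first contact);
#'   `"uniform"` scatters them over the whole corridor instead.
#' @param max_steps per-run step cap.
#' @return Data frame: maze, n_agents, replicate, seed,
#'   time_to_first_contact_s, area_at_first_contact_um2, end_reason.
#' @export
sweep_sperm_number <- function(env = maze_fixture("A"),
                               n_values = c(1, 10, 100, 1000),
                               replicates = 100, seed = 1,
                               maze_label = "A",
                               placement = "start_region",
                               max_steps = 1e6) {
  rows <- list()
  for (ni in seq_along(n_values)) {
    seeds <- replicate_seeds(seed + ni * 100000L, replicates)
    for (r in seq_len(replicates)) {
      cfg <- simulation_config(env, n_values[ni], mode = "fixed",
                               class_mix = c(progressive = 1),
                               stop_rule = "first_contact",
                               placement = placement,
                               max_steps = max_steps, seed = seeds[r])
      res <- run_simulation(cfg)
      rows[[length(rows) + 1]] <- data.frame(
        maze = maze_label, n_agents = n_values[ni], replicate = r,
        seed = seeds[r],
        time_to_first_contact_s = res$time_to_first_contact_s,
        area_at_first_contact_um2 = res$area_at_first_contact_um2,
        end_reason = res$end_reason)
    }
  }
  do.call(rbind, rows)
}

#' Two-factor heterogeneity sweep (maze complexity x lambda)
#'
#' The full two-factor design: populations of `n_agents` markov-mode
#' agents with Poisson(lambda) calcium oscillation frequencies searching
#' each maze until the cumulative egg-contact time reaches
#' `contact_threshold_s` (default 5 s). For each run the table records the
#' search time (elapsed model time at the stop rule) and the selection
#' statistics of the contacting subpopulation (relative information gain,
#' contactor counts).
#'
#' @param mazes named list of [grid_environment()]s; default the three
#'   bundled arenas.
#' @param lambdas Poisson means (Hz).
#' @param replicates replicates per factor cell.
#' @param n_agents agents per simulation.
#' @param contact_threshold_s cumulative contact threshold (s).
#' @param seed master seed.
#' @param max_steps per-run step cap.
#' @return Data frame: maze, tcw, lambda, replicate, seed, search_time_s,
#'   info_gain_bits, n_contactors, n_distinct_contact_freqs, end_reason.
#' @export
sweep_heterogeneity <- function(mazes = NULL, lambdas = c(1, 10, 20),
                                replicates = 100, n_agents = 100,
                                contact_threshold_s = 5, seed = 1,
                                max_steps = 1e6) {
  if (is.null(mazes))
    mazes <- list(A = maze_fixture("A"), B = maze_fixture("B"),
                  C = maze_fixture("C"))
  tcw <- vapply(mazes, function(e)
    total_weighted_complexity(maze_to_graph(e)), numeric(1))
  rows <- list()
  cell <- 0L
  for (mi in seq_along(mazes)) {
    for (li in seq_along(lambdas)) {
      cell <- cell + 1L
      seeds <- replicate_seeds(seed + cell * 1000000L, replicates)
      for (r in seq_len(replicates)) {
        cfg <- simulation_config(mazes[[mi]], n_agents, mode = "markov",
                                 lambda = lambdas[li],
                                 stop_rule = "cumulative_contact",
                                 contact_threshold_s = contact_threshold_s,
                                 placement = "start_region",
                                 max_steps = max_steps, seed = seeds[r])
        res <- run_simulation(cfg)
        contactors <- res$omega_hz[res$contact_time_s > 0]
        ig <- if (length(contactors) > 0)
          selection_summary(res$omega_hz, contactors)$information_gain_bits
        else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          maze = names(mazes)[mi], tcw = tcw[mi], lambda = lambdas[li],
          replicate = r, seed = seeds[r],
          search_time_s = res$elapsed_s,
          info_gain_bits = ig,
          n_contactors = length(contactors),
          n_distinct_contact_freqs = length(unique(contactors)),
          end_reason = res$end_reason)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-way fixed-effects ANOVA with percent-of-total variation
#'
#' Standard balanced two-factor decomposition via [stats::aov()], plus the
#' percent of total variation attributed to each effect,
#' `100 * SS_effect / SS_total` (SS_total includes the residual), the
#' convention under which main-effect, interaction, and residual shares
#' sum to 100.
#'
#' @param data a data frame.
#' @param response,factor_a,factor_b column names.
#' @return An `anova_table` data frame: term, df, sum_sq, mean_sq, f,
#'   p_value, percent_of_total.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  a <- factor(data[[factor_a]])
  b <- factor(data[[factor_b]])
  y <- data[[response]]
  tab <- table(a, b)
  if (length(unique(as.vector(tab))) != 1)
    stop("unbalanced design: equal replicates per factor cell are required")
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("both factors need at least two levels")
  fit <- stats::aov(y ~ a * b)
  sm <- summary(fit)[[1]]
  ss <- sm[["Sum Sq"]]
  total <- sum(ss)
  out <- data.frame(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b),
             "residual"),
    df = sm[["Df"]],
    sum_sq = ss,
    mean_sq = sm[["Mean Sq"]],
    f = sm[["F value"]],
    p_value = sm[["Pr(>F)"]],
    percent_of_total = 100 * ss / total)
  class(out) <- c("anova_table", "data.frame")
  attr(out, "fit") <- fit
  attr(out, "factors") <- c(factor_a, factor_b)
  out
}

#' Tukey honestly-significant-difference comparisons
#'
#' Studentised-range adjusted pairwise comparisons of the levels of one
#' factor from a fitted [two_way_anova()] table (or raw data).
#'
#' @param x an `anova_table` from [two_way_anova()], or a data frame (in
#'   which case `response` and `factor` name columns and a one-way fit is
#'   used).
#' @param factor which factor's levels to compare.
#' @param response response column (data-frame method).
#' @return Data frame: comparison, diff, lwr, upr, p_adj.
#' @export
tukey_hsd <- function(x, factor, response = NULL) {
  if (inherits(x, "anova_table")) {
    fit <- attr(x, "fit")
    which_term <- c("a", "b")[match(factor, attr(x, "factors"))]
    if (is.na(which_term)) stop("unknown factor: ", factor)
    tk <- stats::TukeyHSD(fit, which = which_term)[[which_term]]
  } else {
    f <- factor(x[[factor]])
    y <- x[[response]]
    tk <- stats::TukeyHSD(stats::aov(y ~ f))[["f"]]
  }
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL)
}
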