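#' Model time step
#'
#' One model-time advancement equals one flagellar beat cross at the mean
#' beat-cross frequency of 25.4 Hz, so the step is tau = 1/25.4 s (about
#' 40 ms). All per-step quantities in the movement functions are scaled by
#' this constant.
#'
#' @return The time step in seconds.
#' @export
model_time_step <- function() 1 / 25.4

#' Motility class parameter sets
#'
#' A motility class bundles the four movement-function parameters of one
#' named swimming pattern: nominal radial speed `v` (um/s), radial noise
#' amplitude `sigma_r` (um/s^(1/2)), nominal angular speed `omega`
#' (degrees per tau), and angular noise amplitude `sigma_theta`
#' (degrees per tau^(1/2)), plus the oscillation period `tau` (s).
#'
#' `builtin_classes()` returns the five calibrated mouse-sperm classes
#' (progressive, intermediate, hyperactive, slow, weak); `motility_class()`
#' looks one up by name or builds a custom one.
#'
#' @param name class name.
#' @param v,sigma_r,omega,sigma_theta,tau custom parameter values; when all
#'   are `NULL` the name must be one of the five built-in classes.
#' @return A `motility_class` object (a named list).
#' @export
motility_class <- function(name, v = NULL, sigma_r = NULL, omega = NULL,
                           sigma_theta = NULL, tau = NULL) {
  if (is.null(v) && is.null(sigma_r) && is.null(omega) &&
      is.null(sigma_theta)) {
    tab <- builtin_classes()
    if (!name %in% names(tab))
      stop(sprintf("unknown motility class '%s' (built-ins: %s)", name,
                   paste(names(tab), collapse = ", ")))
    return(tab[[name]])
  }
  stopifnot(v >= 0, sigma_r >= 0, sigma_theta >= 0)
  if (is.null(tau)) tau <- model_time_step()
  stopifnot(tau > 0)
  structure(list(name = name, v = v, sigma_r = sigma_r, omega = omega,
                 sigma_theta = sigma_theta, tau = tau),
            class = "motility_class")
}

#' @rdname motility_class
#' @export
builtin_classes <- function() {
  tau <- model_time_step()
  mk <- function(name, v, sr, om, st)
    structure(list(name = name, v = v, sigma_r = sr, omega = om,
                   sigma_theta = st, tau = tau), class = "motility_class")
  list(
    progressive  = mk("progressive",  279.4, 0.58,  45, 17.3),
    intermediate = mk("intermediate", 419.1, 0.29, 120, 11.5),
    hyperactive  = mk("hyperactive",  419.1, 0.29, 180, 51.0),
    slow         = mk("slow",         152.4, 1.15, 135, 26.0),
    weak         = mk("weak",         101.6, 0.29, 180, 52.0)
  )
}

#' @export
print.motility_class <- function(x, ...) {
  cat(sprintf(
    "<motility_class> %s: v = %g um/s, sigma_r = %g um/s^0.5, omega = %g deg/tau, sigma_theta = %g deg/tau^0.5\n",
    x$name, x$v, x$sigma_r, x$omega, x$sigma_theta))
  invisible(x)
}

#' Motility class names in engine order
#' @return Character vector of the five state names.
#' @export
motility_states <- function() {
  c("progressive", "intermediate", "hyperactive", "slow", "weak")
}

# parameter matrix (v, sigma_r, omega_deg, sigma_theta_deg) in state order
class_param_matrix <- function() {
  tab <- builtin_classes()
  t(vapply(motility_states(), function(nm) {
    cl <- tab[[nm]]
    c(v = cl$v, sigma_r = cl$sigma_r, omega = cl$omega,
      sigma_theta = cl$sigma_theta)
  }, numeric(4)))
}

#' Advance one agent by one model step
#'
#' The self-propelled random walk: the heading first turns by
#' `s_k * omega + sigma_theta * eta_theta` (converted to radians), where
#' `s_k = (-1)^step_index` is the discretised flagellar drive that flips
#' sign once per advancement (one beat cross per step, producing the
#' alternating-arc trajectory), then the agent translates along the new
#' heading by `v * tau + sigma_r * sqrt(tau) * eta_r`. `eta_theta` and
#' `eta_r` are independent standard Gaussian draws; the radial draw is
#' shared by the x and y displacement components.
#'
#' Draw order (heading noise first, then radial noise) is part of the
#' engine's reproducibility contract.
#'
#' @param position numeric `c(x, y)` in micrometres.
#' @param heading heading angle in radians.
#' @param class a [motility_class()].
#' @param step_index integer step counter, starting at 0.
#' @return List with `position` and `heading` after the step.
#' @export
motion_step <- function(position, heading, class, step_index) {
  s <- if (step_index %% 2 == 0) 1 else -1
  eta_theta <- stats::rnorm(1)
  heading <- heading + s * class$omega * pi / 180 +
    class$sigma_theta * pi / 180 * eta_theta
  eta_r <- stats::rnorm(1)
  step_len <- class$v * class$tau + class$sigma_r * sqrt(class$tau) * eta_r
  list(position = position + step_len * c(cos(heading), sin(heading)),
       heading = heading)
}

#' Simulate free-space trajectories for one motility class
#'
#' Vectorised simulation of `n` independent agents in unbounded space
#' (no arena, no barriers), used for displacement scaling and CASA-style
#' analyses of the pure movement functions.
#'
#' @param class a [motility_class()].
#' @param n number of agents.
#' @param n_steps number of model steps.
#' @param headings optional initial headings (radians; default uniform).
#' @return A list of class `trajectory_set` with matrices `x`, `y`
#'   (`n x (n_steps+1)`, micrometres), `dt` seconds between samples.
#' @export
simulate_trajectories <- function(class, n, n_steps, headings = NULL) {
  tau <- class$tau
  if (is.null(headings)) headings <- stats::runif(n, 0, 2 * pi)
  x <- matrix(0, n, n_steps + 1)
  y <- matrix(0, n, n_steps + 1)
  th <- headings
  om <- class$omega * pi / 180
  st <- class$sigma_theta * pi / 180
  for (k in seq_len(n_steps)) {
    s <- if ((k - 1) %% 2 == 0) 1 else -1
    th <- th + s * om + st * stats::rnorm(n)
    step_len <- class$v * tau + class$sigma_r * sqrt(tau) * stats::rnorm(n)
    x[, k + 1] <- x[, k] + step_len * cos(th)
    y[, k + 1] <- y[, k] + step_len * sin(th)
  }
  structure(list(x = x, y = y, dt = tau), class = "trajectory_set")
}

#' Root-mean-square displacement of a trajectory set
#'
#' `sqrt(mean_i [(x_i(t) - x_i(0))^2 + (y_i(t) - y_i(0))^2])` at each
#' sampled time. Ballistic-like motion gives RMSD proportional to t;
#' diffusion-like motion gives RMSD proportional to sqrt(t).
#'
#' @param traj a `trajectory_set` (see [simulate_trajectories()]) or a list
#'   with matrices `x`, `y` (agents in rows, samples in columns).
#' @param step optional sample index (1 = start); default all samples.
#' @return RMSD in micrometres (vector over samples, or scalar if `step`
#'   given).
#' @export
rmsd <- function(traj, step = NULL) {
  if (nrow(traj$x) == 0) stop("empty trajectory set")
  dx2 <- (traj$x - traj$x[, 1])^2 + (traj$y - traj$y[, 1])^2
  out <- sqrt(colMeans(dx2))
  if (is.null(step)) out else out[step]
}

#' Fitted log-log displacement scaling exponent
#'
#' Slope of log RMSD against log time over steps `fit_range`, the standard
#' diagnostic separating ballistic (slope 1) from diffusive (slope 0.5)
#' motion.
#'
#' @param traj a `trajectory_set`.
#' @param fit_range integer vector of step numbers (>= 1) used in the fit.
#' @return The fitted slope.
#' @export
rmsd_scaling_exponent <- function(traj, fit_range = NULL) {
  r <- rmsd(traj)[-1]                    # drop t = 0
  t <- seq_along(r) * traj$dt
  if (is.null(fit_range)) fit_range <- seq_along(r)
  stats::coef(stats::lm(log(r[fit_range]) ~ log(t[fit_range])))[[2]]
}

#' CASA-style velocity metrics of one trajectory
#'
#' Computer-aided sperm analysis summaries of a single tracked path:
#' VCL (curvilinear velocity; total point-to-point path length over
#' duration), VSL (straight-line velocity; net start-to-end displacement
#' over duration), VAP (average-path velocity; length of the 5-point
#' moving-average path over duration, window truncated symmetrically at
#' the ends), and the
#' ratios LIN = VSL/VCL and STR = VSL/VAP (0 when the denominator is 0).
#'
#' @param x,y numeric vectors of sampled positions (micrometres).
#' @param dt sampling interval in seconds.
#' @return Named list with `VCL`, `VSL`, `VAP` (um/s), `LIN`, `STR`.
#' @export
casa_metrics <- function(x, y, dt = model_time_step()) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  duration <- (n - 1) * dt
  if (duration <= 0) stop("zero-duration trajectory")
  path_len <- sum(sqrt(diff(x)^2 + diff(y)^2))
  vcl <- path_len / duration
  vsl <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2) / duration
  xs <- moving_average(x, 5)
  ys <- moving_average(y, 5)
  vap <- sum(sqrt(diff(xs)^2 + diff(ys)^2)) / duration
  list(VCL = vcl, VSL = vsl, VAP = vap,
       LIN = if (vcl > 0) vsl / vcl else 0,
       STR = if (vap > 0) vsl / vap else 0)
}

# centred moving average; the window truncates symmetrically near the
# edges (width 1, 3, 5, ...) so the smoothed path keeps its endpoints
moving_average <- function(v, w) {
  h <- w %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    hw <- min(h, i - 1, n - i)
    mean(v[(i - hw):(i + hw)])
  }, numeric(1))
}

#' Export a trajectory set as a tidy data frame
#'
#' One row per agent per sample: `agent_id`, `step`, `t_s`, `x_um`, `y_um`.
#'
#' @param traj a `trajectory_set`.
#' @return A data frame.
#' @export
trajectories_to_df <- function(traj) {
  n <- nrow(traj$x); m <- ncol(traj$x)
  data.frame(
    agent_id = rep(seq_len(n), times = m),
    step = rep(seq_len(m) - 1L, each = n),
    t_s = rep((seq_len(m) - 1) * traj$dt, each = n),
    x_um = as.vector(traj$x),
    y_um = as.vector(traj$y))
}
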