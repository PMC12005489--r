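test_that("population initialisation honours placement and composition", {
  env <- maze_fixture("B")
  cfg <- simulation_config(env, 250, mode = "fixed", class_mix = "mixed",
                           stop_rule = "fixed_duration", seed = 1)
  set.seed(1)
  pop <- initialize_population(cfg)
  expect_equal(tabulate(pop$state, 5), rep(50L, 5))   # 50 agents per class
  # start-region placement: all agents inside the single start cell
  sc <- env$start_cells[1, ]
  cs <- env$cell_size_um
  expect_true(all(floor(pop$x / cs) + 1 == sc[1]))
  expect_true(all(floor(pop$y / cs) + 1 == sc[2]))
  expect_true(all(pop$heading >= 0 & pop$heading < 2 * pi))

  cfgm <- simulation_config(env, 40, mode = "markov", lambda = 10,
                            stop_rule = "fixed_duration", seed = 2)
  set.seed(2)
  popm <- initialize_population(cfgm)
  expect_true(all(popm$state == 1L))                  # all progressive
  expect_length(popm$omega_hz, 40)
})

test_that("egg contact accrues exactly one time step per step on the egg cell", {
  env <- load_maze(write_maze_lines("S.E"))
  cfg <- simulation_config(env, 5, mode = "fixed",
                           class_mix = c(weak = 1),
                           stop_rule = "fixed_duration",
                           duration_s = 127 / 25.4,
                           placement = "uniform",
                           record_trajectories = TRUE, seed = 3)
  res <- run_simulation(cfg)
  expect_equal(res$n_steps, 127)          # 5 s of model time
  expect_equal(res$elapsed_s, 5, tolerance = 1e-12)
  # recount contact from the recorded endpoints (steps 1..127)
  egg_col <- floor(res$trajectories$x[, -1] / 40) + 1
  per_agent <- rowSums(egg_col == 3) / 25.4
  expect_equal(res$contact_time_s, per_agent)
})

test_that("an agent initialised on the egg cell contacts at time zero", {
  env <- load_maze(write_maze_lines("SE"))
  cfg <- simulation_config(env, 1, mode = "fixed",
                           class_mix = c(progressive = 1),
                           stop_rule = "first_contact", seed = 5)
  # start cell adjacent to egg; force placement on the egg by using a
  # maze whose start IS within the egg cell region: use uniform placement
  # over a 1-corridor-cell world where start == egg is impossible, so
  # instead check the time-zero rule via uniform placement hitting E
  found <- FALSE
  for (s in 1:50) {
    cfg <- simulation_config(env, 4, mode = "fixed",
                             class_mix = c(progressive = 1),
                             stop_rule = "first_contact",
                             placement = "uniform", seed = s)
    res <- run_simulation(cfg)
    if (res$time_to_first_contact_s == 0) { found <- TRUE; break }
  }
  expect_true(found)
  expect_equal(res$n_steps, 0)
  expect_equal(res$end_reason, "first_contact")
})

test_that("a noise-free ballistic agent reaches the egg in closed-form time", {
  # corridor of 12 cells, 480 um; agent starts at x = 20, egg cell spans
  # [440, 480); heading 0 at exactly 10 um per step => first in egg cell
  # after ceil((440 - 20) / 10) = 42 steps
  env <- load_maze(write_maze_lines(paste0("S", strrep(".", 10), "E")))
  pt <- class_param_matrix_for_test(v = 254)
  cfg <- simulation_config(env, 1, mode = "fixed",
                           class_mix = c(progressive = 1),
                           stop_rule = "first_contact",
                           param_table = pt, seed = 1)
  w <- make_world(cfg)
  w$pop$x <- 20; w$pop$y <- 20; w$pop$heading <- 0
  steps <- 0
  repeat {
    w <- step_world(w)
    steps <- steps + 1
    if (sum(w$contact_time_s) > 0 || steps > 200) break
  }
  expect_equal(steps, 42)
  expect_equal(sum(w$contact_time_s), 1 / 25.4)
})

test_that("fixed-duration runs execute ceil(duration / tau) steps", {
  env <- maze_fixture("A")
  cfg <- simulation_config(env, 10, mode = "fixed",
                           stop_rule = "fixed_duration", duration_s = 2,
                           placement = "uniform", seed = 4)
  res <- run_simulation(cfg)
  expect_equal(res$n_steps, 51)            # 2 s at 25.4 steps/s
  expect_equal(res$end_reason, "duration")
})

test_that("identical master seeds give bit-identical results", {
  cfg <- simulation_config(maze_fixture("C"), 30, mode = "markov",
                           lambda = 10, stop_rule = "cumulative_contact",
                           contact_threshold_s = 1, seed = 77)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  for (f in c("x", "y", "heading", "state", "contact_time_s", "n_steps",
              "visited", "search_fraction"))
    expect_identical(a[[f]], b[[f]])
})

test_that("the compiled and pure-R engines replay the same stream identically", {
  for (mode in c("fixed", "markov")) {
    cfg <- simulation_config(maze_fixture("B"), 6, mode = mode,
                             lambda = 10, class_mix = "mixed",
                             stop_rule = "fixed_duration", duration_s = 3,
                             record_occupancy = TRUE, seed = 13)
    a <- run_simulation(cfg, engine = "cpp")
    b <- run_simulation(cfg, engine = "r")
    expect_identical(a$x, b$x)
    expect_identical(a$heading, b$heading)
    expect_identical(a$state, b$state)
    expect_identical(a$visited, b$visited)
    expect_identical(a$contact_time_s, b$contact_time_s)
    expect_identical(a$occupancy, b$occupancy)
  }
})

test_that("no agent ever occupies a barrier cell", {
  cfg <- simulation_config(maze_fixture("C"), 50, mode = "fixed",
                           class_mix = "mixed",
                           stop_rule = "fixed_duration", duration_s = 4,
                           record_trajectories = TRUE, seed = 6)
  res <- run_simulation(cfg)
  env <- maze_fixture("C")
  cs <- env$cell_size_um
  cx <- floor(res$trajectories$x / cs) + 1
  cy <- floor(res$trajectories$y / cs) + 1
  expect_true(all(cx >= 1 & cx <= 17 & cy >= 1 & cy <= 17))
  expect_false(any(env$barrier[cbind(as.vector(cx), as.vector(cy))]))
})

test_that("blocked moves keep position and reorient off the wall", {
  env <- maze_fixture("A")
  cl <- motility_class("progressive")
  # open move stands
  set.seed(1)
  out <- handle_barrier(c(100, 100), c(110, 104), 0.4, cl, env)
  expect_false(out$blocked)
  expect_equal(out$position, c(110, 104))
  # heading into the right-hand arena wall: stay put, turn back leftwards
  set.seed(1)
  out <- handle_barrier(c(679, 300), c(681, 300), 0, cl, env)
  expect_true(out$blocked)
  expect_equal(out$position, c(679, 300))
  expect_lt(cos(out$heading), 0)          # inward normal points -x
  # corner hit: resolved heading points into the arena diagonal half-plane
  set.seed(2)
  hits <- replicate(200, {
    o <- handle_barrier(c(679, 679), c(681, 681), pi / 4, cl, env)
    cos(o$heading - atan2(-1, -1))
  })
  expect_true(mean(hits > 0) > 0.9)
  # an agent already inside a barrier is an invariant violation
  envB <- maze_fixture("B")
  expect_error(handle_barrier(c(5, 620), c(6, 621), 0, cl, envB),
               "invariant")
})

test_that("a world with zero steps has only the initial cells visited", {
  env <- maze_fixture("A")
  cfg <- simulation_config(env, 20, mode = "fixed",
                           stop_rule = "fixed_duration",
                           placement = "uniform", seed = 9)
  w <- make_world(cfg)
  cs <- env$cell_size_um
  cells <- unique(cbind(floor(w$pop$x / cs) + 1, floor(w$pop$y / cs) + 1))
  expect_lte(nrow(cells), 20)
  res_cells <- sum(run_simulation(
    simulation_config(env, 20, mode = "fixed",
                      stop_rule = "fixed_duration", duration_s = 1e-9,
                      placement = "uniform", seed = 9))$visited)
  # one step of ~11-16 um can add at most one new cell per agent
  expect_lte(res_cells, 40)
})

test_that("unsatisfiable stop rules end as timeouts, not errors", {
  # no egg contact possible in time: 1 slow agent far from egg, tiny cap
  cfg <- simulation_config(maze_fixture("C"), 1, mode = "fixed",
                           class_mix = c(slow = 1),
                           stop_rule = "first_contact",
                           max_steps = 10, seed = 2)
  res <- run_simulation(cfg)
  expect_equal(res$end_reason, "timeout")
  expect_equal(res$n_steps, 10)
  expect_true(is.na(res$time_to_first_contact_s))
})
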