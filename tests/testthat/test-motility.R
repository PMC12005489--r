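test_that("built-in motility classes carry the calibrated parameter table", {
  cl <- motility_class("progressive")
  expect_equal(c(cl$v, cl$sigma_r, cl$omega, cl$sigma_theta),
               c(279.4, 0.58, 45, 17.3))
  wk <- motility_class("weak")
  expect_equal(c(wk$v, wk$sigma_r, wk$omega, wk$sigma_theta),
               c(101.6, 0.29, 180, 52.0))
  expect_equal(motility_class("intermediate")$v, 419.1)
  expect_equal(motility_class("hyperactive")$sigma_theta, 51.0)
  expect_equal(motility_class("slow")$omega, 135)
  expect_error(motility_class("fast"), "unknown motility class")
  expect_equal(model_time_step(), 1 / 25.4)
  for (cl in builtin_classes()) expect_equal(cl$tau, 1 / 25.4)
})

test_that("the noise-free motion step is exact kinematics", {
  cl <- motility_class("test", v = 254, sigma_r = 0, omega = 0,
                       sigma_theta = 0)
  set.seed(1)
  out <- motion_step(c(0, 0), 0, cl, step_index = 0)
  expect_equal(out$position, c(10, 0))   # 254 um/s over 1/25.4 s

  still <- motility_class("still", v = 0, sigma_r = 0, omega = 90,
                          sigma_theta = 40)
  out <- motion_step(c(3, 4), 1.2, still, step_index = 5)
  expect_equal(out$position, c(3, 4))    # zero speed: position frozen

  # alternating arcs: heading swings +45 then -45, net direction kept
  arc <- motility_class("arc", v = 100, sigma_r = 0, omega = 45,
                        sigma_theta = 0)
  s1 <- motion_step(c(0, 0), 0, arc, step_index = 0)
  expect_equal(s1$heading, 45 * pi / 180)
  s2 <- motion_step(s1$position, s1$heading, arc, step_index = 1)
  expect_equal(s2$heading, 0)
})

test_that("noise-free rectilinear walkers have RMSD = v t to machine precision", {
  cl <- motility_class("ballistic", v = 200, sigma_r = 0, omega = 0,
                       sigma_theta = 0)
  tr <- simulate_trajectories(cl, n = 4, n_steps = 50)
  t <- (0:50) * tr$dt
  expect_equal(rmsd(tr), 200 * t, tolerance = 1e-12)
  expect_equal(rmsd(tr, step = 51), 200 * 50 / 25.4)
})

test_that("rmsd matches a naive per-agent recomputation", {
  set.seed(11)
  tr <- simulate_trajectories(motility_class("slow"), n = 20, n_steps = 30)
  naive <- sqrt(mean(vapply(seq_len(20), function(i)
    (tr$x[i, 16] - tr$x[i, 1])^2 + (tr$y[i, 16] - tr$y[i, 1])^2,
    numeric(1))))
  expect_equal(rmsd(tr, step = 16), naive)
  expect_error(rmsd(list(x = matrix(0, 0, 2), y = matrix(0, 0, 2))),
               "empty")
})

test_that("heading process with zero angular noise is 2-step periodic", {
  arc <- motility_class("arc", v = 100, sigma_r = 0, omega = 70,
                        sigma_theta = 0)
  h <- 0.3
  headings <- numeric(6)
  pos <- c(0, 0)
  for (k in 0:5) {
    st <- motion_step(pos, h, arc, step_index = k)
    pos <- st$position; h <- st$heading
    headings[k + 1] <- h
  }
  expect_equal(headings[c(1, 3, 5)], rep(headings[1], 3))
  expect_equal(headings[c(2, 4, 6)], rep(headings[2], 3))
})

test_that("log-log RMSD slope separates ballistic from diffusive motion", {
  set.seed(5)
  ballistic <- motility_class("b", v = 200, sigma_r = 0.5, omega = 45,
                              sigma_theta = 0.5)
  diffusive <- motility_class("d", v = 0, sigma_r = 5, omega = 0,
                              sigma_theta = 1000)
  sb <- rmsd_scaling_exponent(simulate_trajectories(ballistic, 1000, 100),
                              fit_range = 10:100)
  sd_ <- rmsd_scaling_exponent(simulate_trajectories(diffusive, 1000, 100),
                               fit_range = 10:100)
  expect_equal(sb, 1, tolerance = 0.1)
  expect_equal(sd_, 0.5, tolerance = 0.2)
})

test_that("CASA metrics follow their definitions on canonical paths", {
  # straight line at constant speed: all three velocities equal, ratios 1
  x <- seq(0, 100, by = 10); y <- rep(0, 11)
  m <- casa_metrics(x, y, dt = 0.1)
  expect_equal(m$VCL, 100)
  expect_equal(m$VSL, 100)
  expect_equal(m$VAP, 100)
  expect_equal(m$LIN, 1)
  expect_equal(m$STR, 1)

  # closed square loop: returns to start, so VSL = LIN = 0
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  m <- casa_metrics(sq[, 1], sq[, 2], dt = 0.25)
  expect_equal(m$VSL, 0)
  expect_equal(m$LIN, 0)
  expect_gt(m$VCL, 0)

  expect_error(casa_metrics(c(0, 1), c(0, 0), dt = 0), "zero-duration")
})

test_that("VCL >= VAP >= VSL ordering holds on simulated trajectories", {
  set.seed(21)
  for (nm in motility_states()) {
    tr <- simulate_trajectories(motility_class(nm), n = 5, n_steps = 51)
    for (i in 1:5) {
      m <- casa_metrics(tr$x[i, ], tr$y[i, ], dt = tr$dt)
      expect_gte(m$VCL, m$VAP - 1e-9)
      expect_gte(m$VAP, m$VSL - 1e-9)
      expect_gte(m$VSL, 0)
    }
  }
})

test_that("simulated progressive VCL approximates its nominal speed", {
  set.seed(31)
  tr <- simulate_trajectories(motility_class("progressive"), n = 1000,
                              n_steps = 51)
  vcl <- vapply(seq_len(1000), function(i)
    casa_metrics(tr$x[i, ], tr$y[i, ], dt = tr$dt)$VCL, numeric(1))
  expect_equal(mean(vcl), 279.4, tolerance = 0.1)
})

test_that("trajectory export is tidy", {
  tr <- simulate_trajectories(motility_class("weak"), n = 3, n_steps = 4)
  df <- trajectories_to_df(tr)
  expect_equal(nrow(df), 3 * 5)
  expect_equal(names(df), c("agent_id", "step", "t_s", "x_um", "y_um"))
  expect_equal(df$x_um[df$step == 0], rep(0, 3))
})
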