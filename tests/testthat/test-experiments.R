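test_that("two-way ANOVA reproduces a brute-force mean decomposition", {
  set.seed(20)
  a <- rep(c("x", "y", "z"), each = 20)
  b <- rep(rep(c("u", "v"), each = 10), times = 3)
  y <- rnorm(60, mean = as.integer(factor(a)) + 2 * (b == "v"))
  d <- data.frame(a = a, b = b, y = y)
  out <- two_way_anova(d, "y", "a", "b")

  # brute force: nested cell/marginal means
  grand <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  ss_a <- sum(20 * (ma - grand)^2)
  ss_b <- sum(30 * (mb - grand)^2)
  ss_cells <- sum(10 * (mab - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - mab[interaction(a, b)])^2)
  expect_equal(out$sum_sq, c(ss_a, ss_b, ss_ab, ss_res), tolerance = 1e-10)
  expect_equal(sum(out$percent_of_total), 100)
  expect_equal(out$df, c(2, 1, 2, 54))
})

test_that("the 3x3x100 design has 891 residual degrees of freedom", {
  set.seed(22)
  d <- expand.grid(maze = c("A", "B", "C"), lambda = c(1, 10, 20),
                   rep = 1:100)
  d$y <- rnorm(nrow(d))
  out <- two_way_anova(d, "y", "maze", "lambda")
  expect_equal(out$df[out$term == "residual"], 891)
  expect_equal(out$df[out$term == "maze:lambda"], 4)
})

test_that("purely additive cell means give zero interaction", {
  d <- expand.grid(a = c("l1", "l2", "l3"), b = c("m1", "m2"), rep = 1:4)
  d$y <- as.integer(factor(d$a)) * 2 + as.integer(factor(d$b)) * 5
  out <- two_way_anova(d, "y", "a", "b")
  expect_equal(out$sum_sq[out$term == "a:b"], 0, tolerance = 1e-20)
  expect_equal(out$sum_sq[out$term == "residual"], 0, tolerance = 1e-20)
})

test_that("percent of total variation is invariant to affine rescaling", {
  set.seed(23)
  d <- expand.grid(a = c("p", "q"), b = c("r", "s"), rep = 1:15)
  d$y <- rnorm(60) + (d$a == "p") * 1.5
  p1 <- two_way_anova(d, "y", "a", "b")$percent_of_total
  d$y2 <- 3.7 * d$y - 11
  p2 <- two_way_anova(d, "y2", "a", "b")$percent_of_total
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("unbalanced or degenerate designs are rejected", {
  d <- data.frame(a = c("x", "x", "y"), b = c("u", "v", "u"), y = 1:3)
  expect_error(two_way_anova(d, "y", "a", "b"), "unbalanced")
  d2 <- data.frame(a = rep("x", 4), b = rep(c("u", "v"), 2), y = rnorm(4))
  expect_error(two_way_anova(d2, "y", "a", "b"), "two levels")
})

test_that("Tukey HSD flags shifted groups and not identical ones", {
  set.seed(24)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 30),
                  y = c(rnorm(30), rnorm(30), rnorm(30) + 3))
  tk <- tukey_hsd(d, "g", response = "y")
  expect_gt(tk$p_adj[tk$comparison == "b-a"], 0.5)
  expect_lt(tk$p_adj[tk$comparison == "c-a"], 0.05)
  expect_lt(tk$p_adj[tk$comparison == "c-b"], 0.05)
})

test_that("Tukey adjusted p-values match a permutation reference", {
  # two groups: Tukey over {a,b} reduces to an F/t test; compare the
  # smallest adjusted p with a permutation p-value of the mean difference
  set.seed(25)
  y <- c(rnorm(12), rnorm(12) + 1.2)
  g <- rep(c("a", "b"), each = 12)
  tk <- tukey_hsd(data.frame(g = g, y = y), "g", response = "y")
  obs <- abs(diff(tapply(y, g, mean)))
  perm <- replicate(4000, {
    gp <- sample(g)
    abs(diff(tapply(y, gp, mean)))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(tk$p_adj - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.01)
})

test_that("Tukey on a fitted two-way table compares levels of one factor", {
  set.seed(26)
  d <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:20)
  d$y <- rnorm(80) + (d$a == "y") * 2
  out <- two_way_anova(d, "y", "a", "b")
  tk <- tukey_hsd(out, "a")
  expect_equal(nrow(tk), 1)
  expect_lt(tk$p_adj, 0.01)
  expect_error(tukey_hsd(out, "zzz"), "unknown factor")
})

test_that("composition sweeps report per-step search and displacement curves", {
  out <- sweep_motility_composition(
    compositions = list(progressive = "progressive", weak = "weak",
                        mixed = "mixed"),
    n_agents = 60, duration_s = 1, replicates = 2, seed = 5)
  expect_equal(sort(unique(out$curves$composition)),
               c("mixed", "progressive", "weak"))
  expect_equal(max(out$curves$step), 26)   # 1 s at 25.4 Hz, ceiling
  # faster class displaces further on average
  sm <- out$summary
  expect_gt(sm$rmsd_um[sm$composition == "progressive"],
            sm$rmsd_um[sm$composition == "weak"])
  # mixed ensemble sits between the pure extremes
  expect_true(sm$rmsd_um[sm$composition == "mixed"] <=
                max(sm$rmsd_um) + 1e-9 &&
              sm$rmsd_um[sm$composition == "mixed"] >=
                min(sm$rmsd_um) - 1e-9)
  # search fraction curves are nondecreasing in time
  one <- subset(out$curves, composition == "mixed" & replicate == 1)
  expect_true(all(diff(one$search_fraction) >= 0))
})

test_that("sperm-number sweeps return a tidy replicate table", {
  tab <- sweep_sperm_number(n_values = c(5, 50), replicates = 4, seed = 9)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$end_reason == "first_contact"))
  expect_true(all(tab$time_to_first_contact_s >= 0))
  expect_true(all(tab$area_at_first_contact_um2 >= 1600))
  # deterministic replay from logged seeds
  tab2 <- sweep_sperm_number(n_values = c(5, 50), replicates = 4, seed = 9)
  expect_identical(tab, tab2)
})

test_that("heterogeneity sweeps populate selection statistics per replicate", {
  tab <- sweep_heterogeneity(
    mazes = list(A = maze_fixture("A")), lambdas = c(1, 20),
    replicates = 3, n_agents = 50, contact_threshold_s = 2, seed = 11)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$end_reason == "cumulative_contact"))
  expect_true(all(tab$info_gain_bits >= 0))
  expect_true(all(tab$n_contactors >= 1))
  expect_equal(tab$tcw, rep(1, 6))
})
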