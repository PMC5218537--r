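test_that("exact test matches enumeration on worked examples", {
  # control {1,2,3,4}, treated {3,4}: qualifying ordered pairs (3,4),(4,3),(4,4)
  t1 <- convolution_mean_test(c(1, 2, 3, 4), c(3, 4))
  expect_equal(t1$p_value, 3 / 16, tolerance = 1e-12)
  expect_equal(t1$direction, "above")
  expect_equal(t1$n_treated, 2L)

  t2 <- convolution_mean_test(c(1, 2, 3, 4), c(1, 1))
  expect_equal(t2$p_value, 1 / 16, tolerance = 1e-12)
  expect_equal(t2$direction, "below")

  # zero deviation covers the whole sample space
  t3 <- convolution_mean_test(rep(900, 20), c(900, 900, 900))
  expect_equal(t3$p_value, 1)
  expect_equal(t3$direction, "none")
})

test_that("stats-only interface matches the sample interface", {
  t_samp <- convolution_mean_test(c(1, 2, 3, 4), c(3, 4))
  t_stat <- convolution_mean_test_from_stats(c(1, 2, 3, 4), 3.5, 2)
  expect_equal(t_stat$p_value, t_samp$p_value, tolerance = 1e-12)
  expect_equal(t_stat$direction, t_samp$direction)

  expect_equal(convolution_mean_test_from_stats(c(1, 2, 3, 4), 2.5, 7)$p_value, 1)
  # unreachable sum above a point-mass control
  expect_equal(convolution_mean_test_from_stats(rep(900, 10), 901, 15)$p_value, 0)
  expect_error(convolution_mean_test_from_stats(1:4, 2, 0), "invalid group size")
})

test_that("exact test equals full enumeration for random small problems", {
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    control <- sample(1:30, k)
    n <- sample(1:4, 1)
    treated <- sample(control, n, replace = TRUE)
    got <- convolution_mean_test(control, treated)$p_value
    want <- enum_mean_test_p(control, mean(treated), n)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pooling concatenates raw lifespans", {
  ctrl <- c(1, 2, 3, 4)
  pooled <- pooled_mean_test(ctrl, list(c(3, 4), c(1, 1)))
  expect_equal(pooled$n_treated, 4L)
  expect_equal(pooled$treated_mean, 2.25)
  expect_equal(pooled$direction, "below")
  # enumeration over all 256 ordered 4-tuples: 106 have sum <= 9
  expect_equal(pooled$p_value, 106 / 256, tolerance = 1e-12)
  expect_equal(pooled$p_value, enum_mean_test_p(ctrl, 2.25, 4), tolerance = 1e-12)

  # single group reduces to the plain test; identical groups pool to n = 45
  g <- c(900, 950, 1000) * 1
  expect_equal(pooled_mean_test(ctrl, list(c(3, 4)))$p_value,
               convolution_mean_test(ctrl, c(3, 4))$p_value)
  trip <- pooled_mean_test(c(800, 900, 1000), rep(list(rep(g, 5)), 3))
  expect_equal(trip$n_treated, 45L)
  expect_equal(trip$treated_mean, mean(g))
})

test_that("p-value is monotone as the treated mean moves away from control", {
  ctrl <- make_control_cohort(n = 120, seed = 3)
  up <- sapply(seq(mean(ctrl) + 10, mean(ctrl) + 200, by = 10), function(m) {
    convolution_mean_test_from_stats(ctrl, m, 15)$p_value
  })
  expect_true(all(diff(up) <= 1e-12))
  down <- sapply(seq(mean(ctrl) - 10, mean(ctrl) - 200, by = -10), function(m) {
    convolution_mean_test_from_stats(ctrl, m, 15)$p_value
  })
  expect_true(all(diff(down) <= 1e-12))
})

test_that("Monte-Carlo resampling reproduces the exact p-value", {
  ctrl <- make_control_cohort(n = 200, seed = 8)
  for (m in c(820, 950)) {
    p_ex <- convolution_mean_test_from_stats(ctrl, m, 15)$p_value
    p_mc <- monte_carlo_mean_test(ctrl, m, 15, reps = 50000, seed = 21)
    se <- sqrt(p_ex * (1 - p_ex) / 50000)
    expect_lt(abs(p_ex - p_mc), 3 * se)
  }
  expect_equal(monte_carlo_mean_test(ctrl, mean(round(ctrl)), 15,
                                     reps = 100, seed = 1), 1)
  expect_identical(monte_carlo_mean_test(ctrl, 950, 15, reps = 1000, seed = 4),
                   monte_carlo_mean_test(ctrl, 950, 15, reps = 1000, seed = 4))
  expect_error(monte_carlo_mean_test(ctrl, 950, 15, reps = 1000), "seed")
})

test_that("exact p agrees with the normal approximation at n = 60", {
  ctrl <- make_control_cohort(n = 335, seed = 14)
  d <- ddist_from_samples(ctrl)
  mo <- ddist_moments(d)
  for (m in c(820, 850, 930, 950)) {
    p_ex <- convolution_mean_test_from_stats(ctrl, m, 60)$p_value
    z <- (m - mo[["mean"]]) / sqrt(mo[["variance"]] / 60)
    p_norm <- if (m > mo[["mean"]]) stats::pnorm(z, lower.tail = FALSE) else stats::pnorm(z)
    if (p_ex >= 0.001 && p_ex <= 0.5) {
      expect_lt(abs(p_ex - p_norm), 0.01)
    }
  }
})

test_that("directional p is calibrated at twice the level, doubled p at the level", {
  ctrl <- make_control_cohort(n = 335, seed = 99)
  d <- ddist_from_samples(ctrl)
  S <- ddist_nfold(d, 15)
  mu <- ddist_moments(d)[["mean"]]
  set.seed(5)
  n_rep <- 800
  p_dir <- p_two <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    trt <- sample(ctrl, 15, replace = TRUE)
    m <- mean(trt)
    if (m == mu) {
      p_dir[r] <- p_two[r] <- 1
    } else {
      p_dir[r] <- ddist_tail_prob(S, sum(trt), if (m > mu) "upper" else "lower")
      p_two[r] <- min(1, 2 * p_dir[r])
    }
  }
  # direction chosen from the data: size ~ 2 * alpha (99.9% binomial bands)
  expect_gt(mean(p_dir <= 0.05), 0.10 - 3.29 * sqrt(0.1 * 0.9 / n_rep))
  expect_lt(mean(p_dir <= 0.05), 0.10 + 3.29 * sqrt(0.1 * 0.9 / n_rep))
  # doubled (two-sided) variant: size ~ alpha
  expect_lt(abs(mean(p_two <= 0.05) - 0.05), 3.29 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("input contracts are enforced", {
  expect_error(convolution_mean_test(numeric(0), 1:3), "no observations")
  expect_error(convolution_mean_test(1:3, numeric(0)), "no observations")
  expect_error(convolution_mean_test(1:3, c(2, -4)), "invalid lifespan")
  two <- convolution_mean_test(c(1, 2, 3, 4), c(3, 4), two_sided = TRUE)
  expect_equal(two$p_value, 2 * 3 / 16, tolerance = 1e-12)
})
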