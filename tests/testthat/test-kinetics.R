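test_that("noiseless logarithmic data is recovered exactly", {
  t <- c(1:10, 15, 20, 25, 30)
  y <- -0.048 * log(t) + 0.2877
  f <- fit_log_decay(t, y, time_offset = 0)
  expect_equal(f$c, -0.048, tolerance = 1e-12)
  expect_equal(f$y0, 0.2877, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # offset-1 convention recovers data generated with that convention
  t2 <- c(0:10, 15, 20, 25, 30)
  y2 <- -8.94 * log(t2 + 1) + 36.8
  f2 <- fit_log_decay(t2, y2, time_offset = 1)
  expect_equal(f2$c, -8.94, tolerance = 1e-10)
  expect_equal(f2$y0, 36.8, tolerance = 1e-9)
})

test_that("degenerate inputs are handled: constants, short series, t = 0 at offset 0", {
  f <- fit_log_decay(c(1, 5, 9, 20), rep(3.2, 4))
  expect_equal(f$c, 0)
  expect_equal(f$r2, 0)
  expect_error(fit_log_decay(c(1, 2), c(3, 4)), "at least 3")
  expect_warning(f0 <- fit_log_decay(c(0, 1, 5, 9), c(5, 4, 3, 2), time_offset = 0),
                 "dropping")
  expect_equal(f0$n, 3)
})

test_that("Cox-Snell pseudo-R2 under Gaussian likelihood equals classical R2", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    t <- sort(runif(n, 0.5, 40))
    y <- rnorm(1, 0, 2) * log(t) + rnorm(1, 5, 3) + rnorm(n, 0, runif(1, 0.01, 2))
    f <- fit_log_decay(t, y, time_offset = 0)
    # independent classical R2 from a direct lm
    m <- lm(y ~ log(t))
    r2_classical <- summary(m)$r.squared
    expect_equal(f$r2, r2_classical, tolerance = 1e-12)
    expect_equal(f$r2_classical, r2_classical, tolerance = 1e-12)
    expect_true(f$r2 >= 0 && f$r2 <= 1)
  }
})

test_that("the fitted slope is unbiased on noisy synthetic trajectories", {
  # tumor decay printed equation, sd 0.01, 100 replicates
  t <- c(1:10, 15, 20, 25, 30)
  mu <- -0.048 * log(t) + 0.2877
  set.seed(101)
  c_hat <- replicate(100, fit_log_decay(t, mu + rnorm(14, 0, 0.01),
                                        time_offset = 0)$c)
  expect_lt(abs(mean(c_hat) + 0.048), 0.005)
  # OLS theory oracle for the slope standard error
  x <- log(t)
  se_theory <- 0.01 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(sd(c_hat) - se_theory) / se_theory, 0.35)

  # central-field standard coefficient, brain-scale noise
  t15 <- c(0:10, 15, 20, 25, 30)
  mu15 <- -0.862 * log(t15 + 1) + 8
  set.seed(102)
  c_hat2 <- replicate(100, fit_log_decay(t15, mu15 + rnorm(15, 0, 0.5))$c)
  se2 <- 0.5 / sqrt(sum((log(t15 + 1) - mean(log(t15 + 1)))^2))
  expect_lt(abs(mean(c_hat2) + 0.862), 3 * se2 / sqrt(100))
})

test_that("two-point half-life follows the exponential convention and its invariances", {
  expect_equal(half_life_two_point(0, 1, 30, 0.5), 30)
  expect_equal(half_life_two_point(0, 4.231, 30, 1), 14.42, tolerance = 0.005)
  expect_equal(half_life_two_point(0, 8.0, 30, 4.4),
               30 * log(2) / log(8 / 4.4))
  expect_equal(round(half_life_two_point(0, 8.0, 30, 4.4), 1), 34.8)
  # scale-invariant in y, translation-invariant in t
  expect_equal(half_life_two_point(0, 8, 30, 4.4),
               half_life_two_point(0, 80, 30, 44))
  expect_equal(half_life_two_point(5, 8, 35, 4.4),
               half_life_two_point(0, 8, 30, 4.4))
  expect_error(half_life_two_point(0, 1, 30, 1.5), "decay")
  expect_error(half_life_two_point(30, 1, 0, 0.5), "exceed")
})

test_that("percent change matches direct arithmetic on the printed trajectories", {
  s <- data.frame(time_min = c(0, 10, 30), mean = c(4.6, 2.8, NA))
  expect_equal(percent_change(s, 0, 10), 100 * (2.8 - 4.6) / 4.6)
  expect_equal(round(percent_change(s, 0, 10), 1), -39.1)
  b <- data.frame(time_min = c(0, 30), mean = c(8.0, 4.4))
  expect_equal(percent_change(b, 0, 30), -45)
  expect_equal(percent_change(b, 0, 0), 0)
  expect_error(percent_change(b, 0, 10), "not present")
  expect_error(percent_change(data.frame(time_min = 0:1, mean = c(0, 1)), 0, 1),
               "zero")
})

test_that("group comparison reproduces the closed-form Student t", {
  res <- compare_groups(c(1, 2, 3), c(11, 12, 13))
  expect_equal(round(res$statistic, 2), -12.25)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(5)
  for (rep in 1:25) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), 0.5)
    got <- compare_groups(a, b)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(got$statistic, t_oracle, tolerance = 1e-12)
    expect_true(got$p_value > 0 && got$p_value <= 1)
  }
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("per-ROI fit tables mirror the single-series fitter", {
  t <- c(0:10, 15, 20, 25, 30)
  ts <- rbind(
    data.frame(roi = "central", time_min = t, mean = 8 - 0.862 * log(t + 1)),
    data.frame(roi = "edge", time_min = t, mean = 5 - 0.469 * log(t + 1)))
  tab <- fit_log_decay_table(ts)
  expect_equal(tab$c[tab$roi == "central"], -0.862, tolerance = 1e-10)
  expect_equal(tab$c[tab$roi == "edge"], -0.469, tolerance = 1e-10)
  expect_equal(tab$n, c(15, 15))
})
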