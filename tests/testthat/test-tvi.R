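test_that("basis construction follows the knot policy and partitions unity", {
  # median of strictly-positive follow-up times sets the knot (14 days here)
  times <- c(0, 0, 0, 10, 14, 200)
  b14 <- build_tvi_basis(times, degree = 1L)
  expect_equal(b14$knot_days, 14)
  expect_equal(b14$dimension, 3L)
  # even follow-up count: knot at the midpoint of the middle pair
  b15 <- build_tvi_basis(c(0, 12, 14, 16, 20), degree = 1L)
  expect_equal(b15$knot_days, 15)

  # degree 0: indicator pair summing to 1
  b0 <- build_tvi_basis(times, degree = 0L)
  X0 <- tvi_design(b0, seq(0, 200, by = 7))
  expect_true(all(rowSums(X0) == 1))
  expect_true(all(X0 %in% c(0, 1)))
  expect_equal(b0$dimension, 2L)

  # degree 1: partition of unity, non-negative entries at random times
  set.seed(21)
  X1 <- tvi_design(b14, runif(50, 0, 200))
  expect_equal(rowSums(X1), rep(1, 50), tolerance = 1e-12)
  expect_true(all(X1 >= 0))

  expect_error(build_tvi_basis(c(5, 5, 5)), "distinct")
  expect_error(build_tvi_basis(times, knot_policy = "fixed", knot = 500),
               "inside")
})

test_that("fit_curve solves least squares, including rank-deficient designs", {
  times <- c(0, 0, 10, 14, 30, 180, 200, 240)
  b <- build_tvi_basis(times, degree = 1L)
  # constant y -> perfect fit
  f <- fit_curve(rep(3.5, 8), times, b)
  expect_equal(f$fitted_values, rep(3.5, 8), tolerance = 1e-12)
  expect_equal(f$rss, 0, tolerance = 1e-20)

  # full-rank design matches the normal-equations oracle
  set.seed(22)
  y <- rnorm(8, 8)
  f2 <- fit_curve(y, times, b)
  X <- tvi_design(b, times)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f2$rss, sum((y - X %*% beta)^2), tolerance = 1e-10)
  expect_equal(f2$rank, 3L)

  # two distinct times under the degree-1 basis: rank deficient, but the
  # RSS equals the per-time mean fit
  t2 <- c(0, 0, 0, 180, 180, 180)
  y2 <- c(1, 2, 3, 7, 9, 11)
  b2 <- build_tvi_basis(t2, degree = 1L, knot_policy = "fixed", knot = 90)
  f3 <- fit_curve(y2, t2, b2)
  expect_lt(f3$rank, 3L)
  rss_means <- sum((y2[1:3] - 2)^2) + sum((y2[4:6] - 9)^2)
  expect_equal(f3$rss, rss_means, tolerance = 1e-10)
  expect_error(fit_curve(numeric(0), numeric(0), b2), "empty")
})

test_that("the RSS-ratio statistic matches the segment-mean oracle", {
  # worked fixture: pooled segment SS {1,3,1,3}->4 and {5,7,1,3}->20,
  # per-group segments each 2, so T = (24 - 8)/8 = 2
  y <- c(1, 3, 5, 7, 1, 3, 1, 3)
  t <- c(1, 2, 20, 30, 1, 2, 20, 30)
  g <- c(rep("ISR", 4), rep("NO_ISR", 4))
  b <- build_tvi_basis(t, degree = 0L, knot_policy = "fixed", knot = 10)
  tt <- tvi_statistic(y, t, g, b)
  orc <- oracle_segment_T(y, t, g, 10)
  expect_equal(tt$rss_null, orc$rss_null, tolerance = 1e-12)
  expect_equal(tt$rss_alt, orc$rss_alt, tolerance = 1e-12)
  expect_equal(tt$statistic, orc$statistic, tolerance = 1e-12)
  expect_equal(tt$statistic, 2)

  # identical data in both groups -> T = 0
  y0 <- c(1, 3, 5, 7, 1, 3, 5, 7)
  expect_equal(tvi_statistic(y0, t, g, b)$statistic, 0)

  # shift and scale invariance
  expect_equal(tvi_statistic(5 * y + 2, t, g, b)$statistic, tt$statistic,
               tolerance = 1e-10)
  expect_equal(tvi_statistic(-0.3 * y, t, g, b)$statistic, tt$statistic,
               tolerance = 1e-10)
})

test_that("nesting and oracle agreement hold over random degree-0 cases", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(6:16, 1L)
    t <- sample(c(0, 0, 7, 14, 21, 180, 210, 365), n, replace = TRUE)
    while (length(unique(t)) < 2L) t <- sample(c(0, 14, 180), n, replace = TRUE)
    knot <- 50
    t[1:2] <- c(0, 180)  # ensure both segments populated
    y <- rnorm(n)
    g <- sample(c("ISR", "NO_ISR"), n, replace = TRUE)
    g[1:2] <- c("ISR", "NO_ISR")
    b <- build_tvi_basis(t, degree = 0L, knot_policy = "fixed", knot = knot)
    tt <- tvi_statistic(y, t, g, b)
    orc <- oracle_segment_T(y, t, g, knot)
    expect_lte(tt$rss_alt, tt$rss_null + 1e-10)
    if (is.finite(orc$statistic)) {
      expect_equal(tt$statistic, orc$statistic, tolerance = 1e-10)
    } else {
      expect_true(tt$degenerate || tt$statistic == orc$statistic)
    }
  }
})

test_that("a perfect alternative fit is flagged degenerate with T = Inf", {
  # one observation per (group, segment): per-group fit is exact
  y <- c(1, 5, 2, 9)
  t <- c(1, 100, 1, 100)
  g <- c("ISR", "ISR", "NO_ISR", "NO_ISR")
  b <- build_tvi_basis(t, degree = 0L, knot_policy = "fixed", knot = 50)
  tt <- tvi_statistic(y, t, g, b)
  expect_true(tt$degenerate)
  expect_equal(tt$statistic, Inf)
})

test_that("bootstrap p-values are deterministic, valid and calibrated", {
  y <- c(1, 3, 5, 7, 1, 3, 1, 3)
  t <- c(1, 2, 20, 30, 1, 2, 20, 30)
  g <- c(rep("ISR", 4), rep("NO_ISR", 4))
  subj <- c(1, 1, 2, 2, 3, 3, 4, 4)
  b <- build_tvi_basis(t, degree = 0L, knot_policy = "fixed", knot = 10)
  p1 <- bootstrap_pvalue(y, t, g, b, n_bootstrap = 299L, seed = 5L,
                         subjects = subj)
  p2 <- bootstrap_pvalue(y, t, g, b, n_bootstrap = 299L, seed = 5L,
                         subjects = subj)
  expect_identical(p1$p_value, p2$p_value)
  expect_gt(p1$p_value, 0)
  expect_lte(p1$p_value, 1)
  expect_error(bootstrap_pvalue(y, t, g, b, n_bootstrap = 0L, subjects = subj),
               "n_bootstrap")
  expect_error(bootstrap_pvalue(y, t, g, b), "subject")

  # T_obs = 0 (identical groups) -> p = 1 under the add-one convention
  y0 <- c(1, 3, 5, 7, 1, 3, 5, 7)
  p0 <- bootstrap_pvalue(y0, t, g, b, n_bootstrap = 199L, seed = 1L,
                         scheme = "iid_residual")
  expect_equal(p0$p_value, 1)
})

test_that("null p-values are approximately uniform", {
  # 150 null genes on a small longitudinal design, iid noise
  m <- simulate_manifest(cohort_design("custom", n_subjects = 30L,
                                       isr_fraction = 0.4), seed = 24L)
  ex <- simulate_expression(m, signal_spec(n_probes = 150L,
                                           frac_main_effect = 0,
                                           frac_interaction = 0,
                                           sigma_subject = 0),
                            seed = 25L)
  res <- run_timecourse_scan(ex$matrix, m, n_bootstrap = 299L, seed = 26L,
                             scheme = "iid_residual")
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("power increases with the planted divergence", {
  m <- simulate_manifest(cohort_design("custom", n_subjects = 40L,
                                       isr_fraction = 0.4), seed = 27L)
  rate <- vapply(c(0, 1.5), function(delta) {
    spec <- signal_spec(n_probes = 60L, frac_main_effect = 0,
                        frac_interaction = if (delta > 0) 1 else 0,
                        delta_interaction = delta, sigma_noise = 0.5,
                        sigma_subject = 0.2)
    ex <- simulate_expression(m, spec, seed = 28L)
    res <- run_timecourse_scan(ex$matrix, m, n_bootstrap = 199L, seed = 29L)
    mean(res$p_value < 0.05)
  }, numeric(1L))
  expect_gt(rate[2L], rate[1L])
  expect_gt(rate[2L], 0.5)
})
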