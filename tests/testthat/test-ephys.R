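test_that("failure rates are simple proportions", {
  expect_equal(failure_rate(rep(c(TRUE, FALSE), 25)), 0.5)
  expect_equal(failure_rate(rep(FALSE, 30)), 0)
  expect_error(failure_rate(logical(0)), "no trials")
  set.seed(61)
  tr <- runif(200) < 0.3
  expect_equal(failure_rate(tr), sum(tr) / 200)
})

test_that("silent-synapse formula matches hand values and is monotone", {
  expect_equal(silent_fraction(0.6, 0.36), 50)      # ln(.6)/ln(.36) = 1/2
  for (f in c(0.2, 0.5, 0.8)) expect_equal(silent_fraction(f, f), 0)
  # strictly increasing in F-60 at fixed F+45, approaching 100%
  v <- sapply(seq(0.31, 0.99, by = 0.02), silent_fraction, f_plus45 = 0.3)
  expect_true(all(diff(v) > 0))
  expect_gt(silent_fraction(0.9999, 0.3), 99)
  # boundary rates: clamped with a trial count, NA without
  expect_warning(ps <- silent_fraction(0, 0.5, n_minus60 = 50), "clamped")
  expect_equal(ps, 100 * (1 - log(1 / 100) / log(0.5)))
  expect_warning(ps2 <- silent_fraction(0, 0.5), "NA")
  expect_true(is.na(ps2))
})

test_that("estimator recovers the planted silent fraction from trials", {
  rec <- sim_minimal_stim(0.35, 0.5, n_trials = 1e5, seed = 62)
  est <- estimate_silent(rec)
  expect_lt(abs(est$percent_silent - 35), 2)
  # bootstrap interval covers the point estimate and is ordered
  est_b <- estimate_silent(sim_minimal_stim(0.3, 0.5, 500, seed = 63),
                           n_boot = 200, seed = 1)
  expect_lt(est_b$ci[1], est_b$ci[2])
  expect_true(est_b$percent_silent >= est_b$ci[1] - 1e-9 &&
                est_b$percent_silent <= est_b$ci[2] + 1e-9)
})

test_that("decay fitting is exact on noiseless traces and robust to offsets", {
  expect_equal(decay_tau(sim_epsc_trace(100, noise_sd = 0))$tau, 100,
               tolerance = 1e-6)
  expect_equal(decay_tau(sim_epsc_trace(50, noise_sd = 0, baseline = 30))$tau,
               50, tolerance = 1e-5)
  # invariance to amplitude scaling and time-origin shift
  tr <- sim_epsc_trace(80, amplitude = 60, noise_sd = 0.5, seed = 64)
  t1 <- decay_tau(tr)$tau
  tr_scaled <- tr; tr_scaled$current <- tr$current * 3.7
  expect_equal(decay_tau(tr_scaled)$tau, t1, tolerance = 1e-9)
  tr_shift <- tr; tr_shift$time <- tr$time + 250
  expect_equal(decay_tau(tr_shift)$tau, t1, tolerance = 1e-9)
})

test_that("noisy decay recovery is unbiased within tolerance", {
  taus <- sapply(1:60, function(i)
    decay_tau(sim_epsc_trace(80, amplitude = 100, noise_sd = 1, seed = i))$tau)
  expect_lt(abs(mean(taus) - 80), 3)
})

test_that("two-way ANOVA matches the textbook sums of squares", {
  y <- c(12, 14, 13, 18, 17, 19, 22, 21, 23, 30, 28, 29)
  tr <- rep(c("ctl", "drug"), each = 6)
  ct <- rep(rep(c("D1", "D2"), each = 3), 2)
  gc <- group_comparison(y, tr, ct)
  want <- anova_oracle(y, factor(tr), factor(ct))
  expect_equal(gc$anova["tr", "F value"], want$F1, tolerance = 1e-10)
  expect_equal(gc$anova["ct", "F value"], want$F2, tolerance = 1e-10)
  expect_equal(gc$anova["tr:ct", "F value"], want$F12, tolerance = 1e-10)
  # planned contrasts present for both cell types
  expect_equal(nrow(gc$contrasts), 2)
  expect_true(all(gc$contrasts$p >= 0 & gc$contrasts$p <= 1))
  # Shapiro screening has one row per non-empty cell
  expect_equal(nrow(gc$shapiro), 4)
})

test_that("treatment effects of two residual SDs are detected reliably", {
  set.seed(65)
  rej <- replicate(200, {
    n <- 20
    tr <- rep(c("ctl", "drug"), each = 2 * n)
    ct <- rep(rep(c("D1", "D2"), each = n), 2)
    y <- rnorm(4 * n, mean = ifelse(tr == "drug", 2, 0))
    gc <- group_comparison(y, tr, ct)
    gc$anova["tr", "Pr(>F)"] < 0.05
  })
  expect_gte(mean(rej), 0.9)
})

test_that("degenerate comparisons are handled explicitly", {
  expect_error(group_comparison(1:3, c("a", "a", "b"), c("x", "x", "x")),
               ">= 2 cells")
  gc <- group_comparison(rep(5, 8), rep(c("a", "b"), each = 4),
                         rep(c("x", "y"), 4))
  expect_true(all(gc$anova[c("tr", "ct", "tr:ct"), "Pr(>F)"] > 0.99))
})
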