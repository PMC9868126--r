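test_that("identical groups give zero log-fold and p = 1", {
  y <- rep(c(5L, 7L, 9L, 4L, 8L, 6L), 2)
  f <- fit_region_nb(y, rep(c("c", "t"), each = 6), "c")
  expect_equal(f$contrasts$log_fold, 0)
  expect_equal(f$contrasts$z, 0)
  expect_equal(f$contrasts$p_raw, 1)
})

test_that("all-zero regions are untestable, not errors", {
  f <- fit_region_nb(rep(0L, 12), rep(c("c", "t"), each = 6), "c")
  expect_true(f$untestable)
  expect_true(is.na(f$contrasts$p_raw))
})

test_that("closed-form NB fit agrees with glm.nb where both apply", {
  # group-mean MLEs are the sample means for any dispersion; glm.nb is the
  # independent route to the same coefficients
  set.seed(41)
  for (i in 1:10) {
    y <- rnbinom(18, mu = 120, size = 3)
    g <- factor(rep(c("c", "t1", "t2"), each = 6))
    f <- fit_region_nb(y, g, "c")
    gfit <- suppressWarnings(MASS::glm.nb(y ~ relevel(g, "c")))
    expect_equal(unname(f$contrasts$log_fold), unname(coef(gfit)[2:3]),
                 tolerance = 1e-6)
  }
})

test_that("null raw p-values are uniform at small n", {
  set.seed(11)
  g <- factor(rep(c("c", "t"), each = 6))
  p <- replicate(2000, {
    y <- rnbinom(12, mu = 150, size = 1 / 0.4)
    fit_region_nb(y, g, "c")$contrasts$p_raw
  })
  D <- suppressWarnings(ks.test(p, "punif"))$statistic
  # 0.05 allows for the residual small-sample approximation of the Wald t
  expect_lt(unname(D), 0.05)
  expect_lt(abs(mean(p) - 0.5), 0.03)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("planted log-folds are recovered without material bias", {
  set.seed(12)
  g <- factor(rep(c("c", "t"), each = 6))
  lf <- replicate(500, {
    y <- c(rnbinom(6, mu = 100, size = 1 / 0.3),
           rnbinom(6, mu = 300, size = 1 / 0.3))
    fit_region_nb(y, g, "c")$contrasts$log_fold
  })
  expect_lt(abs(median(lf) - log(3)), 0.15 * log(3))
})

test_that("Dunnett adjustment matches closed forms and dominates the raw p", {
  # k = 1: no multiplicity, identical to the two-sided p
  expect_equal(dunnett_p(2.3, n = 6, n0 = 6), 2 * pnorm(-2.3), tolerance = 1e-7)
  expect_equal(dunnett_p(2.3, n = 6, n0 = 6, df = 10, k = 1),
               2 * pt(-2.3, 10), tolerance = 1e-6)
  # k = 2 independent limit: Sidak
  expect_equal(dunnett_p(1.96, rho = 0, k = 2),
               1 - (1 - 2 * pnorm(-1.96))^2, tolerance = 1e-8)
  # monotonicity over random designs
  set.seed(13)
  for (i in 1:50) {
    z <- runif(3, 0, 4)
    n <- sample(4:9, 3, replace = TRUE)
    df <- sample(c(10, 20, Inf), 1)
    p <- dunnett_p(z, n = n, n0 = 7, df = df)
    praw <- if (is.finite(df)) 2 * pt(-z, df) else 2 * pnorm(-z)
    expect_true(all(p >= praw - 1e-12))
    expect_true(all(p <= 1))
  }
})

test_that("BH q-values match the brute-force step-up", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), cutoff = 0.1)
  expect_equal(r$q, rep(0.04, 4))
  expect_true(all(r$significant))
  r1 <- bh_fdr(rep(1, 5))
  expect_equal(r1$q, rep(1, 5))
  expect_false(any(r1$significant))
  expect_length(bh_fdr(numeric(0))$q, 0)

  set.seed(14)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p)$q, bh_oracle(p))
  }
  # NAs excluded from m and returned NA
  p <- c(0.01, NA, 0.04)
  r2 <- bh_fdr(p)
  expect_true(is.na(r2$q[2]))
  expect_equal(r2$q[c(1, 3)], bh_oracle(p[c(1, 3)]))
})

test_that("fold index is the ratio of means and volume-invariant", {
  expect_equal(fold_index(c(40, 40), c(10, 10)), 4)
  expect_equal(fold_index(1:5, 1:5), 1)
  expect_warning(fi <- fold_index(c(1, 2), c(0, 0)), "zero")
  expect_true(is.na(fi))
  # counts vs densities: identical to machine precision
  set.seed(15)
  tc <- rpois(6, 50); cc <- rpois(6, 20); vol <- 0.37
  expect_equal(fold_index(tc, cc), fold_index(tc / vol, cc / vol))
})

test_that("fold-index ratios recover staged planted effects", {
  g3 <- data.frame(label = c("c", "t1", "t7"), n = c(300L, 300L, 300L),
                   control = c(NA, "c", "c"), stringsAsFactors = FALSE)
  spec <- cohort_spec(n_regions = 3, groups = g3, module_loading = 0,
                      dispersion = 0.2, seed = 44,
                      baseline_density = rep(200, 3), volumes = rep(1, 3),
                      fold_effects = list(t1 = c(R001 = 2), t7 = c(R001 = 4)))
  sim <- sim_cohort(spec)
  y <- sim$counts$counts[, "R001"]; grp <- sim$counts$group
  f1 <- fold_index(y[grp == "t1"], y[grp == "c"])
  f7 <- fold_index(y[grp == "t7"], y[grp == "c"])
  expect_lt(abs(f7 / f1 - 2), 0.2)
})

test_that("significant region lists are nested and ordered", {
  sim <- sim_cohort(cohort_spec(
    n_regions = 30, seed = 16, module_loading = 0,
    baseline_density = rep(150, 30), volumes = rep(1, 30),
    fold_effects = list(cocaine7d = setNames(rep(4, 6), sprintf("R%03d", 1:6)))))
  d <- fos_diff(sim$counts, sim$regions)
  s_strict <- significant_regions(d, 0.01)
  s_loose <- significant_regions(d, 0.1)
  expect_true(all(s_strict %in% s_loose))
  expect_length(significant_regions(d, 1e-12), 0)
  # planted strong effects surface
  expect_gt(length(intersect(s_loose, sprintf("R%03d", 1:6))), 3)
  # ordering within one contrast: q ascending
  s1 <- significant_regions(d, 0.1, family = "saline", group = "cocaine7d")
  tab <- d$table[d$table$family == "saline" & d$table$group == "cocaine7d", ]
  q1 <- tab$q_bh[match(s1, tab$region)]
  expect_true(all(diff(q1) >= -1e-12))
  expect_s3_class(summary(d), "summary.fos_diff")
})

test_that("fos_diff respects exclusions and family structure", {
  sim <- sim_cohort(cohort_spec(n_regions = 10, seed = 17))
  rs <- region_set(as.data.frame(sim$regions)[
    c("id", "acronym", "name", "parent", "anatomical_group", "volume")],
    exclude = "R003")
  d <- fos_diff(sim$counts, rs)
  expect_false("R003" %in% d$table$region)
  expect_setequal(unique(d$table$family), c("water", "saline"))
  expect_setequal(unique(d$table$group[d$table$family == "water"]),
                  c("sugar1d", "sugar7d"))
})
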