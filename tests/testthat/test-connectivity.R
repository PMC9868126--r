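test_that("correlation matrices reproduce Pearson r exactly", {
  m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("a", 1:5), paste0("R", 1:6)))
  m[, 2] <- 2 * m[, 1]                    # perfect linear
  m[, 3] <- -m[, 1] + 7                   # perfect inverse
  r <- correlation_matrix(m)
  expect_equal(r["R1", "R2"], 1)
  expect_equal(r["R1", "R3"], -1)
  # brute-force covariance / sd oracle on every pair
  for (i in 1:6) for (j in 1:6) {
    num <- mean((m[, i] - mean(m[, i])) * (m[, j] - mean(m[, j])))
    den <- sqrt(mean((m[, i] - mean(m[, i]))^2) * mean((m[, j] - mean(m[, j]))^2))
    expect_equal(unname(r[i, j]), num / den, tolerance = 1e-12)
  }
  expect_identical(r, structure(t(unclass(r)), group = attr(r, "group"),
                                n_animals = attr(r, "n_animals"),
                                class = class(r)))  # symmetry
  expect_true(all(diag(unclass(r)) == 1))
})

test_that("correlation is invariant to per-region affine rescaling", {
  set.seed(51)
  m <- matrix(rpois(40, 30), 5, 8, dimnames = list(NULL, paste0("R", 1:8)))
  r1 <- unclass(correlation_matrix(m))
  m2 <- sweep(sweep(m, 2, runif(8, 0.5, 4), `*`), 2, runif(8, -3, 3), `+`)
  r2 <- unclass(correlation_matrix(m2))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("zero-variance regions yield NA rows and too-few animals error", {
  m <- matrix(rnorm(20), 4, 5, dimnames = list(NULL, paste0("R", 1:5)))
  m[, 4] <- 3
  r <- correlation_matrix(m)
  expect_true(all(is.na(r["R4", ])))
  expect_true(all(is.na(r[, "R4"])))
  expect_false(anyNA(r[c(1:3, 5), c(1:3, 5)]))
  expect_error(correlation_matrix(m[1:2, ]), ">= 3 animals")
})

test_that("heatmap ordering keeps anatomical blocks and is input-order invariant", {
  set.seed(52)
  sim <- sim_cohort(cohort_spec(n_regions = 24, n_modules = 2, seed = 52))
  dens <- to_density(sim$counts, sim$regions)
  cm <- correlation_matrix(dens, "water")
  ord <- anatomical_heatmap_order(cm, sim$regions)
  expect_setequal(ord, colnames(cm))
  # block boundaries: anatomical groups stay contiguous
  ag <- setNames(sim$regions$anatomical_group, sim$regions$acronym)[ord]
  expect_equal(length(rle(ag)$values), length(unique(ag)))
  # permuting the matrix columns leaves the ordering unchanged
  perm <- sample(ncol(cm))
  cmp <- structure(unclass(cm)[perm, perm], group = attr(cm, "group"),
                   n_animals = attr(cm, "n_animals"), class = class(cm))
  expect_identical(anatomical_heatmap_order(cmp, sim$regions), ord)
  # missing anatomical labels are an error
  rs_bad <- sim$regions; rs_bad$anatomical_group[1] <- NA
  expect_error(anatomical_heatmap_order(cm, rs_bad), "anatomical")
})

test_that("planted module members end up adjacent in the ordering", {
  big <- data.frame(label = "g", n = 60L, control = NA_character_)
  spec <- cohort_spec(n_regions = 12, groups = big, n_modules = 2, seed = 53)
  sim <- sim_cohort(spec)
  # single anatomical block so ordering is purely correlation-driven
  rs <- sim$regions; rs$anatomical_group <- "all"
  cm <- correlation_matrix(to_density(sim$counts, rs), "g")
  ord <- anatomical_heatmap_order(cm, rs)
  mod <- spec$modules[match(ord, spec$acronyms)]
  expect_equal(length(rle(mod)$values), 2)   # two contiguous module runs
})

test_that("clustering merges the closest profiles first and normalises heights", {
  # two regions: one merge at normalised height 1
  r2 <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  d2 <- cluster_structures(r2)
  expect_equal(length(d2$merge_heights), 1)
  expect_equal(d2$heights_norm, 1)

  # profiles with d(A,B) = 1, d(A,C) = d(B,C) = 10: A,B merge first
  pro <- rbind(A = c(0, 0, 0), B = c(1, 0, 0), C = c(0.5, sqrt(99.75), 0))
  colnames(pro) <- rownames(pro)
  d3 <- cluster_structures(pro)
  first <- d3$hclust$merge[1, ]
  expect_setequal(rownames(pro)[-first], c("A", "B"))
  expect_equal(max(d3$heights_norm), 1)
  expect_true(all(diff(d3$merge_heights) >= 0))
})

test_that("modularity curves count modules below each cut", {
  fake <- structure(list(leaves = paste0("L", 1:4),
                         heights_norm = c(0.2, 0.5, 0.9)),
                    class = "fos_dendrogram")
  mc <- modularity_curve(fake, n_steps = 101)
  expect_equal(mc$modules[mc$cut_fraction == 0], 4)
  expect_equal(mc$modules[mc$cut_fraction == 1], 1)
  expect_equal(mc$modules[which.min(abs(mc$cut_fraction - 0.6))], 2)
  expect_true(all(diff(mc$modules) <= 0))

  # property: non-increasing with fixed endpoints on simulated data
  sim <- sim_cohort(cohort_spec(n_regions = 25, seed = 54))
  dend <- cluster_structures(correlation_matrix(to_density(sim$counts, sim$regions), "water"))
  mc2 <- modularity_curve(dend)
  expect_true(all(diff(mc2$modules) <= 0))
  expect_equal(mc2$modules[1], length(dend$leaves))
  expect_equal(mc2$modules[nrow(mc2)], 1)
})

test_that("log-rank comparison matches the textbook computation", {
  mk <- function(h) structure(list(leaves = seq_along(h) + 1,
                                   heights_norm = h), class = "fos_dendrogram")
  # identical merge multisets: statistic exactly 0, p = 1
  h <- c(0.1, 0.4, 0.7, 1)
  same <- compare_modularity_logrank(mk(h), mk(h))
  expect_identical(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # 6-event fixture vs hand-computed O - E and variance
  ha <- c(0.1, 0.3, 0.8); hb <- c(0.2, 0.6, 1)
  got <- compare_modularity_logrank(mk(ha), mk(hb))
  want <- logrank_oracle(ha, hb)
  expect_equal(got$statistic, want$chisq, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)

  # symmetry under swapping groups
  rev <- compare_modularity_logrank(mk(hb), mk(ha))
  expect_equal(rev$statistic, got$statistic, tolerance = 1e-12)
  expect_error(compare_modularity_logrank(mk(c(0.5)), mk(hb)), ">= 2 merges")
})

test_that("graph construction enumerates nodes, edges and degrees exactly", {
  # 3 significant nodes, pairwise r = (AB .8, AC .76, BC .7) at cut .75
  r <- diag(3); dimnames(r) <- list(c("A", "B", "C"), c("A", "B", "C"))
  r["A", "B"] <- r["B", "A"] <- 0.8
  r["A", "C"] <- r["C", "A"] <- 0.76
  r["B", "C"] <- r["C", "B"] <- 0.7
  g <- build_graph(c("A", "B", "C"), r, r_cut = 0.75)
  expect_equal(nrow(g$edges), 2)
  expect_equal(unname(g$degree[c("A", "B", "C")]), c(2, 1, 1))
  expect_equal(g$hubs[1], "A")

  expect_equal(nrow(build_graph(c("A", "B", "C"), r, r_cut = 0.99)$edges), 0)
  # strictly positive rule: strong negative correlation is not an edge
  rn <- r; rn["A", "B"] <- rn["B", "A"] <- -0.9
  expect_equal(nrow(build_graph(c("A", "B"), rn, r_cut = 0.75)$edges), 0)
  expect_warning(g0 <- build_graph(character(0), r), "empty")
  expect_length(g0$nodes, 0)
})

test_that("graph nodes equal the significant-region list", {
  sim <- sim_cohort(cohort_spec(
    n_regions = 25, seed = 55, baseline_density = rep(200, 25),
    volumes = rep(1, 25),
    fold_effects = list(cocaine7d = setNames(rep(5, 8), sprintf("R%03d", 1:8)))))
  d <- fos_diff(sim$counts, sim$regions)
  cm <- correlation_matrix(to_density(sim$counts, sim$regions), "cocaine7d")
  g <- suppressWarnings(build_graph(d, cm, p_cut = 0.1))
  expect_setequal(g$nodes, significant_regions(d, 0.1))
})

test_that("our adjusted Rand index agrees with the mclust reference", {
  set.seed(56)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})
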