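#' Negative-binomial fit of one region within one treatment family
#'
#' Fits counts ~ group with a log link and a log-volume offset (so
#' coefficients are density log-folds), then forms one Wald contrast per
#' treatment group against the family control. For this one-way layout the
#' group-mean MLEs are the sample means for any dispersion, so the fit is
#' exact: the dispersion is profiled out by 1-D likelihood maximisation with
#' the Cox-Reid adjustment (which removes the downward small-sample bias of
#' plain ML dispersion), and Wald statistics are referred to a t distribution
#' with the residual degrees of freedom. A dispersion estimate at the Poisson
#' boundary is flagged `"poisson"`; a region with zero counts in every animal
#' is flagged untestable (NA p) rather than an error.
#'
#' @param y integer counts, one per animal in the family.
#' @param group factor of group labels (must contain `control`).
#' @param control label of the family control group.
#' @param volume region volume (scalar, or one value per animal; only a
#'   constant offset keeps the closed-form fit exact).
#' @return list of class `region_fit`: `group_means` (mean count per group),
#'   `dispersion` (CR-adjusted alpha-hat), `df` (residual df used for the t
#'   reference), `contrasts` (data frame with `group`, `log_fold`, `se`, `z`,
#'   `p_raw`, `p_dunnett`), `family_dist` ("negbin" or "poisson" boundary),
#'   `untestable`.
#' @export
fit_region_nb <- function(y, group, control, volume = 1) {
  group <- factor(group)
  if (!control %in% levels(group)) stop("control group absent from data")
  if (nlevels(group) < 2) stop("need at least two groups")
  if (any(table(group) < 2)) stop("need >= 2 animals per group")
  group <- stats::relevel(group, ref = control)
  treatments <- levels(group)[-1]
  k <- nlevels(group)
  df_resid <- length(y) - k
  res <- list(group_means = c(tapply(y, group, mean))[levels(group)],
              dispersion = NA_real_, df = df_resid,
              contrasts = data.frame(group = treatments,
                                     log_fold = NA_real_, se = NA_real_,
                                     z = NA_real_, p_raw = NA_real_,
                                     p_dunnett = NA_real_,
                                     stringsAsFactors = FALSE),
              family_dist = NA_character_, untestable = FALSE)
  class(res) <- "region_fit"

  if (all(y == 0)) {
    res$untestable <- TRUE
    return(res)
  }

  n_g <- stats::setNames(as.numeric(table(group)), levels(group))
  mu_hat <- res$group_means                      # exact MLE for any alpha
  mu_i <- mu_hat[as.character(group)]
  # Cox-Reid adjusted profile likelihood in theta = 1/alpha;
  # adjustment is -0.5 log det(X'WX) = -0.5 sum_g log(n_g mu_g theta/(theta+mu_g))
  mu_cr <- pmax(mu_hat, 0.5 / n_g)               # keep adjustment finite
  apl <- function(log_theta) {
    th <- exp(log_theta)
    sum(stats::dnbinom(y, size = th, mu = pmax(mu_i, 1e-10), log = TRUE)) -
      0.5 * sum(log(n_g * mu_cr * th / (th + mu_cr)))
  }
  opt <- stats::optimize(apl, interval = log(c(1e-2, 1e6)), maximum = TRUE,
                         tol = 1e-6)
  theta <- exp(opt$maximum)
  alpha <- 1 / theta
  res$dispersion <- alpha
  res$family_dist <- if (alpha < 1.5e-6) "poisson" else "negbin"

  # Wald contrasts: var(log mu_g) = (1/mu_g + alpha)/n_g by Fisher information,
  # with a half-count floor on zero group means
  mu_w <- pmax(mu_hat, 0.5 / n_g)
  v <- (1 / mu_w + alpha) / n_g
  est <- log(mu_w[treatments]) - log(mu_w[[control]])
  se <- sqrt(v[treatments] + v[[control]])
  z <- ifelse(se > 0, est / se, 0)
  res$contrasts$log_fold <- unname(est)
  res$contrasts$se <- unname(se)
  res$contrasts$z <- unname(z)
  res$contrasts$p_raw <- unname(2 * stats::pt(-abs(z), df = df_resid))
  res
}

#' Dunnett many-to-one adjusted p-value
#'
#' Probability that the maximum of k correlated standard normals exceeds
#' `|z|` in absolute value, with the Dunnett correlation
#' `rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`. Because that matrix has
#' the one-factor product form `rho_ij = b_i b_j`, the probability reduces to
#' a single Gaussian integral which is evaluated exactly by quadrature.
#'
#' With finite `df` the statistics share an estimated scale and the reference
#' is multivariate t: the normal quadrature is mixed over the chi distribution
#' of the scale, so `k = 1` reduces exactly to the two-sided t p-value.
#'
#' @param z observed Wald statistic(s); vectorized.
#' @param n vector of treatment-group sizes (length k).
#' @param n0 control-group size.
#' @param rho optional scalar common correlation overriding the sample-size
#'   formula (`rho = 0` gives the independent-limit Sidak value).
#' @param k number of contrasts; defaults to `length(n)`.
#' @param df residual degrees of freedom for the t reference; `Inf` (default)
#'   gives the normal-theory Dunnett probability.
#' @return adjusted two-sided p-value(s), always `>=` the unadjusted p.
#' @examples
#' dunnett_p(1.96, rho = 0, k = 2)   # Sidak: 1 - (1 - 0.05)^2
#' @export
dunnett_p <- function(z, n = NULL, n0 = NULL, rho = NULL,
                      k = if (!is.null(n)) length(n) else 1L, df = Inf) {
  if (is.null(rho)) {
    if (is.null(n) || is.null(n0)) stop("give either rho or group sizes n, n0")
    b <- sqrt(n / (n + n0))
  } else {
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
    b <- rep(sqrt(rho), k)
  }
  if (length(b) < 1) stop("at least one contrast is required")
  if (is.finite(df)) {
    f <- dunnett_evaluator(b, df)
    adj <- vapply(z, function(zi) if (is.na(zi)) NA_real_ else f(abs(zi)),
                  numeric(1))
  } else {
    adj <- vapply(z, function(zi) {
      if (is.na(zi)) return(NA_real_)
      min(1, max(0, 1 - dunnett_inside_normal(abs(zi), b)))
    }, numeric(1))
  }
  # quadrature error must never let the adjusted p drop below the raw p
  praw <- if (is.finite(df)) 2 * stats::pt(-abs(z), df) else 2 * stats::pnorm(-abs(z))
  pmax(adj, praw)
}

.dunnett_cache <- new.env(parent = emptyenv())

# cached adjusted-p evaluator for a fixed design (b, df): the inner normal
# probability and the chi-mixture are tabulated once and splined
dunnett_evaluator <- function(b, df) {
  key <- paste(paste(sprintf("%.8f", b), collapse = ","), df)
  if (!is.null(.dunnett_cache[[key]])) return(.dunnett_cache[[key]])
  u <- seq(0, 24, by = 0.05)
  Pn <- vapply(u, function(ui) dunnett_inside_normal(ui, b), numeric(1))
  Pn <- cummax(pmin(Pn, 1))
  PnFun <- stats::splinefun(u, Pn, method = "hyman")
  cg <- seq(0, 15, by = 0.05)
  pt_mix <- vapply(cg, function(cc) {
    if (cc == 0) return(1)
    inside <- stats::integrate(function(s)
      PnFun(pmin(cc * s, 24)) * 2 * df * s * stats::dchisq(df * s^2, df),
      0, Inf, rel.tol = 1e-9)$value
    min(1, max(1e-300, 1 - inside))
  }, numeric(1))
  lspl <- stats::splinefun(cg, log(pt_mix), method = "hyman")
  k <- length(b)
  f <- function(absz) {
    if (absz > 15) return(min(1, k * 2 * stats::pt(-absz, df)))
    min(1, exp(lspl(absz)))
  }
  .dunnett_cache[[key]] <- f
  f
}

# P(max_i |Z_i| <= c) for Z ~ N(0, R), R = one-factor b b' + diag(1 - b^2):
# exact 1-D Gaussian quadrature over the shared factor
dunnett_inside_normal <- function(cc, b) {
  s <- sqrt(1 - b^2)
  stats::integrate(function(x) {
    px <- stats::dnorm(x)
    for (i in seq_along(b))
      px <- px * (stats::pnorm((cc - b[i] * x) / s[i]) -
                  stats::pnorm((-cc - b[i] * x) / s[i]))
    px
  }, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
}


#' Fill Dunnett-adjusted p-values into a region fit
#'
#' @param fit a `region_fit` from [fit_region_nb()]
#' @param n_per_group named vector of animals per group (including the control)
#' @param control control group label
#' @return the fit with `contrasts$p_dunnett` filled.
#' @export
dunnett_adjust <- function(fit, n_per_group, control) {
  stopifnot(inherits(fit, "region_fit"))
  k <- nrow(fit$contrasts)
  if (k == 0) stop("fit has no contrasts")
  n <- n_per_group[fit$contrasts$group]
  fit$contrasts$p_dunnett <- dunnett_p(fit$contrasts$z, n = n,
                                       n0 = n_per_group[[control]],
                                       df = fit$df)
  fit
}

#' Benjamini-Hochberg step-up q-values with significance flags
#'
#' NAs are excluded from the effective number of tests and returned NA.
#'
#' @param p vector of p-values (NAs allowed).
#' @param cutoff FDR level for the flags (0.1 for the activation lists, 0.01
#'   for network nodes).
#' @return list with `q` (q-values) and `significant` (`q <= cutoff`).
#' @export
bh_fdr <- function(p, cutoff = 0.1) {
  if (length(p) == 0) return(list(q = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(q = q, significant = !is.na(q) & q <= cutoff)
}

#' Fold index: ratio of group mean activation to control mean
#'
#' Computed on densities or counts interchangeably (region volume cancels).
#'
#' @param treatment vector of per-animal values (counts or densities) in the
#'   treatment group.
#' @param control vector of per-animal values in the control group.
#' @return `mean(treatment) / mean(control)`, or NA with a warning when the
#'   control mean is zero.
#' @export
fold_index <- function(treatment, control) {
  mc <- mean(control)
  if (mc == 0) {
    warning("control mean is zero; fold index undefined")
    return(NA_real_)
  }
  mean(treatment) / mc
}

#' Differential regional activation: NB GLM, Dunnett, then BH
#'
#' The package's core estimator. For every region and every treatment family
#' (a control group plus the treatment groups compared against it), counts are
#' modelled as negative-binomial with a group factor and a log-volume offset;
#' each treatment-vs-control Wald p-value is Dunnett-adjusted for the
#' many-to-one comparisons within the family, and Benjamini-Hochberg
#' adjustment is then applied across regions (by default separately per
#' contrast, switchable to pooling a family's contrasts jointly).
#'
#' @param x a [count_table]
#' @param regions a [region_set] supplying volumes; excluded regions are
#'   dropped before fitting.
#' @param families named list, one element per family:
#'   `list(control = "water", treatments = c("sugar1d", "sugar7d"))`. When
#'   NULL, a water family and/or saline family are inferred from group labels
#'   containing "water"/"sugar" and "saline"/"cocaine"; otherwise the first
#'   group is taken as control for all others.
#' @param bh_cutoff FDR level for the `sig_bh` flag (default 0.1).
#' @param bh_pool `"per_contrast"` (default) applies BH across regions within
#'   each treatment contrast; `"family"` pools all contrasts of a family.
#' @return object of class `fos_diff` with a `table` data frame: `region`,
#'   `family`, `group`, `fold_index`, `log_fold`, `se`, `z`, `p_raw`,
#'   `p_dunnett`, `q_bh`, `sig_bh` (q <= 0.1), `sig_network` (q <= 0.01),
#'   `dispersion`, `fit_family`.
#' @seealso [significant_regions()], [build_graph()]
#' @export
fos_diff <- function(x, regions = NULL, families = NULL, bh_cutoff = 0.1,
                     bh_pool = c("per_contrast", "family")) {
  stopifnot(inherits(x, "count_table"))
  bh_pool <- match.arg(bh_pool)
  if (!is.null(regions)) x <- drop_excluded(x, regions)
  grp <- x$group
  if (is.null(families)) families <- infer_families(levels(grp))
  vol <- if (is.null(regions)) stats::setNames(rep(1, ncol(x$counts)), colnames(x$counts))
         else stats::setNames(regions$volume, regions$acronym)[colnames(x$counts)]

  rows <- list()
  for (fam in names(families)) {
    ctrl <- families[[fam]]$control
    trts <- families[[fam]]$treatments
    use <- grp %in% c(ctrl, trts)
    gg <- droplevels(grp[use])
    npg <- table(gg)
    for (r in colnames(x$counts)) {
      y <- x$counts[use, r]
      fit <- fit_region_nb(y, gg, ctrl, volume = vol[[r]])
      fit <- if (fit$untestable) fit else dunnett_adjust(fit, npg, ctrl)
      fi <- vapply(trts, function(tg) {
        suppressWarnings(fold_index(y[gg == tg], y[gg == ctrl]))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, family = fam, group = fit$contrasts$group,
        fold_index = unname(fi[fit$contrasts$group]),
        log_fold = fit$contrasts$log_fold, se = fit$contrasts$se,
        z = fit$contrasts$z, p_raw = fit$contrasts$p_raw,
        p_dunnett = fit$contrasts$p_dunnett,
        dispersion = fit$dispersion, fit_family = fit$family_dist,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  tab$q_bh <- NA_real_
  pool_key <- if (bh_pool == "per_contrast") paste(tab$family, tab$group)
              else tab$family
  for (key in unique(pool_key)) {
    idx <- pool_key == key
    tab$q_bh[idx] <- bh_fdr(tab$p_dunnett[idx], bh_cutoff)$q
  }
  tab$sig_bh <- !is.na(tab$q_bh) & tab$q_bh <= bh_cutoff
  tab$sig_network <- !is.na(tab$q_bh) & tab$q_bh <= 0.01

  structure(list(table = tab, families = families, bh_cutoff = bh_cutoff,
                 bh_pool = bh_pool, n_regions = ncol(x$counts),
                 n_animals = nrow(x$counts), call = match.call()),
            class = "fos_diff")
}

infer_families <- function(labels) {
  fams <- list()
  if ("water" %in% labels) {
    t <- setdiff(grep("sugar|sucrose", labels, value = TRUE), "water")
    if (length(t)) fams$water <- list(control = "water", treatments = t)
  }
  if ("saline" %in% labels) {
    t <- setdiff(grep("cocaine", labels, value = TRUE), "saline")
    if (length(t)) fams$saline <- list(control = "saline", treatments = t)
  }
  if (!length(fams))
    fams <- list(all = list(control = labels[1], treatments = labels[-1]))
  fams
}

#' @export
print.fos_diff <- function(x, ...) {
  cat("Differential c-Fos activation (NB GLM -> Dunnett -> BH)\n")
  cat(sprintf("  %d regions, %d animals, %d treatment %s (BH pool: %s)\n",
              x$n_regions, x$n_animals, length(x$families),
              if (length(x$families) == 1) "family" else "families",
              x$bh_pool))
  for (fam in names(x$families)) {
    tf <- x$table[x$table$family == fam, ]
    for (g in unique(tf$group)) {
      tg <- tf[tf$group == g, ]
      cat(sprintf("  %s vs %s: %d / %d regions at q <= %.2g (%d at q <= 0.01)\n",
                  g, x$families[[fam]]$control, sum(tg$sig_bh), nrow(tg),
                  x$bh_cutoff, sum(tg$sig_network)))
    }
  }
  invisible(x)
}

#' @export
summary.fos_diff <- function(object, alpha = object$bh_cutoff, ...) {
  tab <- object$table
  out <- do.call(rbind, lapply(split(tab, paste(tab$family, tab$group)), function(d) {
    data.frame(family = d$family[1], group = d$group[1],
               n_regions = nrow(d), n_sig = sum(!is.na(d$q_bh) & d$q_bh <= alpha),
               median_fold = stats::median(d$fold_index, na.rm = TRUE),
               max_fold = suppressWarnings(max(d$fold_index, na.rm = TRUE)))
  }))
  rownames(out) <- NULL
  structure(list(by_group = out, alpha = alpha), class = "summary.fos_diff")
}

#' @export
print.summary.fos_diff <- function(x, ...) {
  cat("Significant regions at q <=", x$alpha, "\n")
  print(x$by_group, row.names = FALSE)
  invisible(x)
}

#' @export
coef.fos_diff <- function(object, ...) {
  tab <- object$table
  stats::xtabs(log_fold ~ region + group, data = tab, sparse = FALSE)
}

#' @export
plot.fos_diff <- function(x, alpha = x$bh_cutoff, ...) {
  tab <- x$table[!is.na(x$table$q_bh) & !is.na(x$table$fold_index), ]
  graphics::plot(log2(tab$fold_index), -log10(pmax(tab$q_bh, 1e-300)),
                 xlab = "log2 fold index", ylab = "-log10 q",
                 col = ifelse(tab$q_bh <= alpha, "firebrick", "grey40"),
                 pch = 16, cex = 0.6, ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(x)
}

#' Regions significant at an FDR level
#'
#' @param x a [fos_diff] object
#' @param alpha FDR cutoff on the BH q-values (0.1 for activation lists,
#'   0.01 for network nodes).
#' @param family,group optional filters to one family and/or one contrast.
#' @return character vector of region acronyms with `q <= alpha`, ordered by
#'   q then by descending fold index.
#' @export
significant_regions <- function(x, alpha = 0.1, family = NULL, group = NULL) {
  stopifnot(inherits(x, "fos_diff"))
  tab <- x$table
  if (!is.null(family)) tab <- tab[tab$family == family, ]
  if (!is.null(group)) tab <- tab[tab$group == group, ]
  tab <- tab[!is.na(tab$q_bh) & tab$q_bh <= alpha, ]
  tab <- tab[order(tab$q_bh, -tab$fold_index), ]
  unique(tab$region)
}
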