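#' Failure rate of a minimal-stimulation trial sequence
#'
#' @param trials logical vector, TRUE = failure (no evoked response).
#' @return fraction of failures.
#' @export
failure_rate <- function(trials) {
  if (length(trials) == 0) stop("no trials")
  mean(as.logical(trials))
}

#' Percentage of silent synapses from failure rates
#'
#' `percent silent = 100 * (1 - ln(F-60) / ln(F+45))`, where F-60 and F+45 are
#' the failure rates at -60 mV (AMPAR-mediated) and +45 mV (NMDAR-mediated).
#' A higher ratio of failures at -60 mV relative to +45 mV corresponds to a
#' higher percentage of silent synapses. Boundary rates (exactly 0 or 1) make
#' the logs degenerate; when trial counts are supplied they are clamped to
#' `1/(2n)` resp. `1 - 1/(2n)` with a warning (continuity correction), and
#' without trial counts they yield NA. Sampling noise can make the estimate
#' negative; values are reported untruncated so group means stay unbiased.
#'
#' @param f_minus60,f_plus45 failure rates in `[0, 1]`.
#' @param n_minus60,n_plus45 trial counts used for boundary clamping.
#' @return percentage of silent synapses (may be negative), NA when undefined.
#' @examples
#' silent_fraction(0.6, 0.36)  # 50: ln(0.6)/ln(0.36) = 0.5
#' @export
silent_fraction <- function(f_minus60, f_plus45, n_minus60 = NULL, n_plus45 = NULL) {
  clamp <- function(f, n, lab) {
    if (is.na(f)) return(NA_real_)
    if (f < 0 || f > 1) stop(lab, " must lie in [0, 1]")
    if (f == 0 || f == 1) {
      if (is.null(n)) {
        warning(lab, " is at the boundary and no trial count given; returning NA")
        return(NA_real_)
      }
      warning(lab, " clamped to avoid log of 0 (boundary rate with n = ", n, ")")
      f <- max(1 / (2 * n), min(1 - 1 / (2 * n), f))
    }
    f
  }
  f60 <- clamp(f_minus60, n_minus60, "F-60mV")
  f45 <- clamp(f_plus45, n_plus45, "F+45mV")
  if (is.na(f60) || is.na(f45)) return(NA_real_)
  100 * (1 - log(f60) / log(f45))
}

#' Silent-synapse estimate for one recorded cell
#'
#' Computes both failure rates from the trial sequences, applies the
#' silent-synapse formula, and optionally bootstraps trials for a percentile
#' confidence interval.
#'
#' @param rec a `minimal_stim` recording (see [sim_minimal_stim()]), or any
#'   list with logical `trials_minus60` and `trials_plus45` (TRUE = failure).
#' @param n_boot bootstrap replicates (0 = no interval).
#' @param conf confidence level.
#' @param seed seed for the bootstrap resampling.
#' @return object of class `silent_estimate`: `f_minus60`, `f_plus45`,
#'   `percent_silent`, `ci` (or NULL), `n_trials`.
#' @export
estimate_silent <- function(rec, n_boot = 0, conf = 0.95, seed = 1L) {
  t60 <- as.logical(rec$trials_minus60)
  t45 <- as.logical(rec$trials_plus45)
  if (length(t60) < 10 || length(t45) < 10)
    warning("fewer than 10 trials per potential; estimate will be unstable")
  f60 <- failure_rate(t60)
  f45 <- failure_rate(t45)
  ps <- suppressWarnings(silent_fraction(f60, f45, length(t60), length(t45)))
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    bs <- replicate(n_boot, {
      b60 <- failure_rate(sample(t60, replace = TRUE))
      b45 <- failure_rate(sample(t45, replace = TRUE))
      suppressWarnings(silent_fraction(b60, b45, length(t60), length(t45)))
    })
    ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  }
  structure(list(f_minus60 = f60, f_plus45 = f45, percent_silent = ps,
                 ci = ci, n_trials = c(minus60 = length(t60), plus45 = length(t45)),
                 cell_id = rec$cell_id, cell_type = rec$cell_type,
                 group = rec$group),
            class = "silent_estimate")
}

#' @export
print.silent_estimate <- function(x, ...) {
  cat(sprintf("Silent synapses: %.1f%% (F-60 = %.3f, F+45 = %.3f)\n",
              x$percent_silent, x$f_minus60, x$f_plus45))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap CI: [%.1f, %.1f]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Decay time constant of an EPSC trace
#'
#' Fits `I(t) = A * exp(-(t - t_peak)/tau) + C` by least squares from the
#' current peak to the end of the trace. The linear parameters (A, C) are
#' profiled out for each candidate tau (variable projection), leaving a 1-D
#' minimisation that is robust even on noiseless traces. Optionally a
#' bi-exponential is fitted and the amplitude-weighted tau reported.
#'
#' @param trace an `epsc_trace` (list with `time` in ms and `current` in pA).
#' @param biexponential also fit `A1 exp(-t/tau1) + A2 exp(-t/tau2) + C` and
#'   report the amplitude-weighted time constant.
#' @return object of class `decay_fit`: `tau` (ms), `amplitude`, `baseline`,
#'   `rmse`, `method`, and for the bi-exponential fit `tau_components`.
#'   NA tau with a diagnostic when no usable decay is found.
#' @export
decay_tau <- function(trace, biexponential = FALSE) {
  t <- trace$time
  y <- trace$current
  if (length(t) < 5) stop("trace too short")
  pk <- which.max(abs(y - stats::median(y)))
  sgn <- sign(y[pk] - stats::median(y))
  if (sgn == 0) sgn <- 1
  tt <- t[pk:length(t)] - t[pk]
  yy <- (y[pk:length(t)]) * sgn
  if (length(tt) < 4 || stats::var(yy) == 0)
    return(structure(list(tau = NA_real_, rmse = NA_real_,
                          method = "mono", note = "no decay after peak"),
                     class = "decay_fit"))

  rss_of <- function(log_tau) {
    X <- cbind(exp(-tt / exp(log_tau)), 1)
    fit <- stats::lm.fit(X, yy)
    sum(fit$residuals^2)
  }
  span <- max(tt)
  opt <- stats::optimize(rss_of, interval = log(c(span / 5000, span * 5)),
                         tol = 1e-10)
  tau <- exp(opt$minimum)
  X <- cbind(exp(-tt / tau), 1)
  beta <- stats::lm.fit(X, yy)$coefficients
  res <- yy - X %*% beta
  out <- list(tau = tau, amplitude = unname(beta[1]) * sgn,
              baseline = unname(beta[2]) * sgn,
              rmse = sqrt(mean(res^2)), method = "mono")

  if (biexponential) {
    rss_bi <- function(p) {
      X2 <- cbind(exp(-tt / exp(p[1])), exp(-tt / exp(p[2])), 1)
      f <- stats::lm.fit(X2, yy)
      sum(f$residuals^2)
    }
    op <- stats::optim(c(log(tau / 5), log(tau * 2)), rss_bi,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000))
    taus <- exp(op$par)
    X2 <- cbind(exp(-tt / taus[1]), exp(-tt / taus[2]), 1)
    b2 <- stats::lm.fit(X2, yy)$coefficients
    w <- abs(b2[1:2])
    out$tau_components <- sort(taus)
    out$tau_weighted <- sum(w * taus) / sum(w)
    out$method <- "biexponential"
  }
  structure(out, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (is.na(x$tau)) cat("Decay fit failed:", x$note, "\n")
  else cat(sprintf("Decay tau = %.2f ms (RMSE %.3g pA, %s fit)\n",
                   x$tau, x$rmse, x$method))
  invisible(x)
}

#' Shapiro-Wilk screening plus two-way ANOVA with planned contrasts
#'
#' The analysis applied to per-cell measurements (percent silent synapses,
#' decay time): normality of each treatment x cell-type group is screened
#' with Shapiro-Wilk, a two-way ANOVA (treatment, cell type, interaction) is
#' fitted, and planned pairwise treatment contrasts within each cell type are
#' tested with the pooled ANOVA residual variance.
#'
#' @param values numeric vector of per-cell measurements.
#' @param treatment factor (e.g. water/sugar7d/saline/cocaine7d).
#' @param cell_type factor (e.g. D1/D2).
#' @param contrasts list of length-2 character vectors of treatment labels to
#'   compare within each cell type; default: every treatment pair present.
#' @return object of class `group_comparison`: `shapiro` (per-group W and p),
#'   `anova` (two-way table), `contrasts` (pairwise t on pooled residual MS).
#' @export
group_comparison <- function(values, treatment, cell_type,
                             contrasts = NULL) {
  treatment <- factor(treatment)
  cell_type <- factor(cell_type)
  tab <- table(treatment, cell_type)
  if (any(tab[tab > 0] < 2))
    stop("every non-empty treatment x cell-type combination needs >= 2 cells")
  df <- data.frame(v = values, tr = treatment, ct = cell_type)

  sw <- do.call(rbind, lapply(split(df, list(df$tr, df$ct), drop = TRUE),
    function(d) {
      p <- if (nrow(d) >= 3 && stats::var(d$v) > 0)
        tryCatch(stats::shapiro.test(d$v)$p.value, error = function(e) NA_real_)
      else NA_real_
      data.frame(treatment = d$tr[1], cell_type = d$ct[1], n = nrow(d),
                 shapiro_p = p)
    }))
  rownames(sw) <- NULL

  fit <- stats::aov(v ~ tr * ct, data = df)
  an <- summary(fit)[[1]]
  rownames(an) <- trimws(rownames(an))
  # all-constant data (total SS at floating-point noise): F = 0, p = 1
  constant <- sum(an$`Sum Sq`) <= 1e-16 * length(values) * (1 + mean(values)^2)
  if (constant) {
    eff <- seq_len(nrow(an) - 1)
    an$`F value`[eff] <- 0
    an$`Pr(>F)`[eff] <- 1
  }
  mse <- if (constant) 0 else an["Residuals", "Mean Sq"]
  dfr <- an["Residuals", "Df"]

  if (is.null(contrasts))
    contrasts <- utils::combn(levels(treatment), 2, simplify = FALSE)
  cc <- do.call(rbind, lapply(levels(cell_type), function(ct) {
    do.call(rbind, lapply(contrasts, function(pr) {
      a <- df$v[df$tr == pr[1] & df$ct == ct]
      b <- df$v[df$tr == pr[2] & df$ct == ct]
      if (!length(a) || !length(b)) return(NULL)
      tstat <- if (mse == 0) {
        if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
      } else (mean(a) - mean(b)) / sqrt(mse * (1 / length(a) + 1 / length(b)))
      data.frame(cell_type = ct, a = pr[1], b = pr[2],
                 mean_a = mean(a), mean_b = mean(b), t = tstat, df = dfr,
                 p = 2 * stats::pt(-abs(tstat), dfr))
    }))
  }))
  rownames(cc) <- NULL
  structure(list(shapiro = sw, anova = an, contrasts = cc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Two-way ANOVA\n"); print(x$anova)
  cat("\nPlanned contrasts (pooled residual MS)\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
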