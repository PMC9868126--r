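#' Specify a synthetic c-Fos cohort
#'
#' Builds the full parameter record for [sim_cohort()]. The defaults mirror a
#' six-group reward-exposure design: a water control with its one-day and
#' seven-day sucrose groups, and a saline control with its one-day and
#' seven-day cocaine groups, at the realistic group sizes n = 7, 5, 7, 7, 6, 6
#' and ~380 atlas regions. Counts are negative-binomial around
#' baseline_density * volume with group-specific fold effects; cross-animal
#' correlation is planted through a shared per-module log-normal latent factor.
#'
#' @param n_regions number of regions.
#' @param groups data frame with columns `label`, `n`, `control` (`NA` for
#'   control groups themselves). Default: the six-group design above.
#' @param baseline_density per-region baseline densities (cells/mm^3);
#'   default drawn log-uniformly in 10-1000 from `seed`.
#' @param volumes per-region volumes (mm^3); default log-uniform in 0.01-5.
#' @param fold_effects groups x regions matrix of multiplicative effects, or a
#'   named list `list(group = c(acronym = fold, ...))`; unspecified entries are 1.
#' @param n_modules number of planted correlation modules (contiguous equal
#'   blocks), or an explicit integer membership vector of length `n_regions`.
#' @param module_loading loading of the shared per-module latent factor on the
#'   log-mean scale, in `[0, 1)`; 0 plants no correlation. Default 0.8, which
#'   puts within-module inter-animal correlation in the 0.7-0.8 range.
#' @param dispersion negative-binomial dispersion alpha (Var = mu + alpha*mu^2);
#'   0 gives Poisson noise. Default 0.3.
#' @param seed integer seed; every generator in the package is deterministic
#'   given its seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 380,
                        groups = NULL,
                        baseline_density = NULL,
                        volumes = NULL,
                        fold_effects = NULL,
                        n_modules = 6,
                        module_loading = 0.8,
                        dispersion = 0.3,
                        seed = 1L) {
  if (is.null(groups))
    groups <- data.frame(
      label = c("water", "sugar1d", "sugar7d", "saline", "cocaine1d", "cocaine7d"),
      n = c(7L, 5L, 7L, 7L, 6L, 6L),
      control = c(NA, "water", "water", NA, "saline", "saline"),
      stringsAsFactors = FALSE)
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (nrow(groups) < 1 || any(groups$n < 1)) stop("every group needs >= 1 animal")
  if (anyDuplicated(groups$label)) stop("duplicate group labels")
  bad <- !is.na(groups$control) & !groups$control %in% groups$label
  if (any(bad)) stop("control group not in design: ", groups$control[bad][1])
  if (module_loading < 0 || module_loading >= 1)
    stop("module_loading must lie in [0, 1)")
  if (dispersion < 0) stop("dispersion must be >= 0")
  acr <- sprintf("R%03d", seq_len(n_regions))

  set.seed(seed)
  if (is.null(baseline_density)) baseline_density <- 10^stats::runif(n_regions, 1, 3)
  if (is.null(volumes)) volumes <- 10^stats::runif(n_regions, log10(0.01), log10(5))
  if (length(baseline_density) != n_regions || any(baseline_density <= 0))
    stop("baseline_density must be positive, one per region")
  if (length(volumes) != n_regions || any(volumes <= 0))
    stop("volumes must be positive, one per region")

  if (length(n_modules) == n_regions) {
    modules <- as.integer(n_modules)
  } else {
    modules <- as.integer(cut(seq_len(n_regions), n_modules, labels = FALSE))
  }

  fe <- matrix(1, nrow(groups), n_regions,
               dimnames = list(groups$label, acr))
  if (!is.null(fold_effects)) {
    if (is.matrix(fold_effects)) {
      fe[rownames(fold_effects), colnames(fold_effects)] <- fold_effects
    } else {
      for (g in names(fold_effects)) fe[g, names(fold_effects[[g]])] <- fold_effects[[g]]
    }
  }
  if (any(fe <= 0)) stop("fold effects must be positive")

  structure(list(n_regions = n_regions, acronyms = acr, groups = groups,
                 baseline_density = baseline_density, volumes = volumes,
                 fold_effects = fe, modules = modules,
                 module_loading = module_loading, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' For animal a in group g, region r in module m: the log-mean is
#' `log(baseline_density[r] * volume[r] * fold[g, r]) + loading * u[m, a]`
#' with `u ~ N(0, 1)` shared by all regions of one module within one animal,
#' and the count is negative-binomial with that mean and dispersion alpha.
#'
#' @param spec a [cohort_spec]
#' @return list with `counts` (a [count_table]), `regions` (a [region_set];
#'   flat forest, anatomical groups assigned as ten contiguous divisions), and
#'   `truth` (fold-effect matrix and module membership).
#' @export
sim_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 1L)
  g <- spec$groups
  animal_group <- rep(g$label, g$n)
  animals <- paste0(animal_group, "_", unlist(lapply(g$n, seq_len)))
  n_anim <- length(animals)
  K <- max(spec$modules)

  counts <- matrix(0L, n_anim, spec$n_regions,
                   dimnames = list(animals, spec$acronyms))
  base_mu <- spec$baseline_density * spec$volumes
  for (a in seq_len(n_anim)) {
    u <- stats::rnorm(K)
    eta <- log(base_mu * spec$fold_effects[animal_group[a], ]) +
      spec$module_loading * u[spec$modules]
    mu <- exp(eta)
    counts[a, ] <- if (spec$dispersion > 0)
      stats::rnbinom(spec$n_regions, mu = mu, size = 1 / spec$dispersion)
    else stats::rpois(spec$n_regions, mu)
  }

  anat <- paste0("Div", sprintf("%02d", cut(seq_len(spec$n_regions),
                                            min(10, spec$n_regions),
                                            labels = FALSE)))
  regions <- region_set(data.frame(
    id = seq_len(spec$n_regions), acronym = spec$acronyms,
    name = paste("Region", spec$acronyms), parent = NA_character_,
    anatomical_group = anat, volume = spec$volumes,
    stringsAsFactors = FALSE))

  list(counts = count_table(counts, stats::setNames(animal_group, animals)),
       regions = regions,
       truth = list(fold_effects = spec$fold_effects, modules = spec$modules))
}

#' Generate a minimal-stimulation recording with a planted silent fraction
#'
#' Trials at +45 mV fail with probability `f45`; trials at -60 mV fail with
#' probability `f45^(1 - s)`, the inverse of the silent-synapse estimator
#' `1 - ln(F-60)/ln(F+45)`, so the planted `s` is recoverable from the
#' empirical failure rates.
#'
#' @param s planted silent fraction, in `[0, 1)`.
#' @param f45 failure rate at +45 mV, in `(0, 1)`.
#' @param n_trials trials per holding potential.
#' @param seed integer seed.
#' @param cell_id,cell_type,group metadata carried on the recording.
#' @return object of class `minimal_stim`: logical trial vectors
#'   `trials_minus60`, `trials_plus45` (TRUE = failure) plus metadata.
#' @export
sim_minimal_stim <- function(s, f45, n_trials = 50L, seed = 1L,
                             cell_id = "cell1", cell_type = "D1",
                             group = "control") {
  if (s < 0 || s >= 1) stop("silent fraction s must lie in [0, 1)")
  if (f45 <= 0 || f45 >= 1) stop("f45 must lie in (0, 1)")
  if (n_trials < 1) stop("n_trials must be >= 1")
  f60 <- f45^(1 - s)
  set.seed(seed)
  structure(list(cell_id = cell_id, cell_type = cell_type, group = group,
                 trials_minus60 = stats::runif(n_trials) < f60,
                 trials_plus45 = stats::runif(n_trials) < f45,
                 truth = list(s = s, f45 = f45, f60 = f60)),
            class = "minimal_stim")
}

#' Generate a noisy single-exponential EPSC decay trace
#'
#' @param tau decay time constant (ms).
#' @param amplitude peak current (pA).
#' @param noise_sd Gaussian noise SD (pA).
#' @param dt sampling step (ms); 0.1 ms matches 10 kHz acquisition.
#' @param duration trace length (ms).
#' @param seed integer seed.
#' @param baseline constant offset (pA).
#' @return object of class `epsc_trace`: list with `time` (ms) and
#'   `current` (pA).
#' @export
sim_epsc_trace <- function(tau, amplitude = 100, noise_sd = 0, dt = 0.1,
                           duration = 500, seed = 1L, baseline = 0) {
  if (tau <= 0 || dt <= 0 || duration <= 0)
    stop("tau, dt and duration must be positive")
  t <- seq(0, duration, by = dt)
  set.seed(seed)
  structure(list(time = t,
                 current = amplitude * exp(-t / tau) + baseline +
                   stats::rnorm(length(t), 0, noise_sd)),
            class = "epsc_trace")
}

#' Generate a random-walk centroid track
#'
#' @param n_steps number of frames.
#' @param step_scale SD of per-frame displacement in each axis (input units).
#' @param seed integer seed.
#' @param fps frames per second for the timestamps.
#' @return object of class `centroid_track`: data frame `t`, `x`, `y`.
#' @export
sim_track <- function(n_steps, step_scale = 1, seed = 1L, fps = 30) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (step_scale < 0) stop("step_scale must be >= 0")
  set.seed(seed)
  x <- cumsum(c(0, stats::rnorm(n_steps - 1, 0, step_scale)))
  y <- cumsum(c(0, stats::rnorm(n_steps - 1, 0, step_scale)))
  structure(data.frame(t = (seq_len(n_steps) - 1) / fps, x = x, y = y),
            class = c("centroid_track", "data.frame"))
}

#' Build a two-bottle lick-time record
#'
#' @param t_left,t_right seconds spent drinking from each bottle.
#' @param session_length session duration in seconds (2 h default).
#' @return object of class `lick_record`.
#' @export
lick_record <- function(t_left, t_right, session_length = 7200) {
  if (t_left < 0 || t_right < 0) stop("drinking times must be >= 0")
  if (t_left + t_right > session_length)
    stop("total drinking time exceeds session length")
  structure(list(t_left = t_left, t_right = t_right,
                 session_length = session_length),
            class = "lick_record")
}
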