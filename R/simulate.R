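# Simulation scenarios: steady-to-steady and oscillating kinetic programs,
# noisy replicate sampling on regular grids, and CV-matched subsampling.

sigmoid <- function(x) 1 / (1 + exp(-x))

# b * (1 + (f - 1) * sigmoid((t - t0)/w)): baseline b, asymptotic fold f.
# Strictly positive for b > 0, f > 0 since the bracket lies in (min(1,f), max(1,f)).
shape_sigmoid <- function(b, f, t0, w) {
  force(b); force(f); force(t0); force(w)
  function(t) b * (1 + (f - 1) * sigmoid((t - t0) / w))
}

# Transient excursion (product of an on- and an off-sigmoid) returning to
# baseline; midpoints are kept >= 5 widths from the horizon ends so the
# endpoints sit within a few percent of baseline even at fold 8.
shape_impulse <- function(b, f, t_on, t_off, w_on, w_off) {
  force(b); force(f); force(t_on); force(t_off); force(w_on); force(w_off)
  function(t) b * (1 + (f - 1) * sigmoid((t - t_on) / w_on) *
                     sigmoid((t_off - t) / w_off))
}

# Log-sinusoid: b * exp(A * sin(2*pi*t/P + phi)); strictly positive.
shape_oscillating <- function(b, A, period, phase) {
  force(b); force(A); force(period); force(phase)
  function(t) b * exp(A * sin(2 * pi * t / period + phase))
}

shape_constant <- function(b) {
  force(b)
  function(t) rep(b, length(t))
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Scenario specification for the kinetic simulator
#'
#' Defines the study conditions under which synthetic genes are generated:
#' the scenario family, the number of genes, the time horizon, and the
#' parameter ranges of the kinetic programs. Defaults encode circadian-scale
#' mammalian kinetics: transcription baseline 0.05–5 a.u./min, splicing
#' 0.05–0.5/min (held constant per gene), degradation 0.005–0.1/min,
#' regulation fold-changes of 2–8 up or down, transitions over 0.5–9 h.
#'
#' @param scenario `"steady_to_steady"` or `"oscillating"`.
#' @param n_genes Number of genes to draw.
#' @param horizon Simulation horizon in minutes (default 1440 = 24 h).
#' @param alpha_baseline,beta_baseline,gamma_baseline Length-2 ranges
#'   (log-uniform draws) for the baseline rates.
#' @param fold_range Length-2 range for the fold-change *magnitude*
#'   (log-uniform); the direction (up/down) is drawn with equal probability.
#' @param midpoint_range Sigmoid midpoint range (minutes).
#' @param width_range Transition width range (minutes).
#' @param period_range,amplitude_range Oscillating scenario: period (minutes)
#'   and log-amplitude ranges.
#' @param beta_drift If `TRUE`, beta follows a shallow sigmoid (fold drawn in
#'   `[1/1.5, 1.5]`) instead of being constant.
#' @param seed Integer seed controlling all random draws.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("steady_to_steady", "oscillating"),
                          n_genes = 12,
                          horizon = 1440,
                          alpha_baseline = c(0.05, 5),
                          beta_baseline = c(0.05, 0.5),
                          gamma_baseline = c(0.005, 0.1),
                          fold_range = c(2, 8),
                          midpoint_range = c(240, 1080),
                          width_range = c(30, 120),
                          period_range = c(720, 1440),
                          amplitude_range = c(log(1.5), log(3)),
                          beta_drift = FALSE,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_genes >= 1, horizon > 0,
            all(alpha_baseline > 0), all(beta_baseline > 0),
            all(gamma_baseline > 0), all(fold_range > 0))
  structure(list(scenario = scenario, n_genes = n_genes, horizon = horizon,
                 alpha_baseline = alpha_baseline,
                 beta_baseline = beta_baseline,
                 gamma_baseline = gamma_baseline,
                 fold_range = fold_range,
                 midpoint_range = midpoint_range,
                 width_range = width_range,
                 period_range = period_range,
                 amplitude_range = amplitude_range,
                 beta_drift = beta_drift,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

draw_fold <- function(spec) {
  f <- runif_log(1, spec$fold_range[[1]], spec$fold_range[[2]])
  if (stats::runif(1) < 0.5) f else 1 / f
}

# One steady-to-steady rate program: sigmoid (sustained transition) or
# impulse (transient excursion returning to baseline), equal probability.
draw_s2s_rate <- function(spec, baseline) {
  f <- draw_fold(spec)
  if (stats::runif(1) < 0.5) {
    t0 <- stats::runif(1, spec$midpoint_range[[1]], spec$midpoint_range[[2]])
    w <- stats::runif(1, spec$width_range[[1]], spec$width_range[[2]])
    shape_sigmoid(baseline, f, t0, w)
  } else {
    w_on <- stats::runif(1, spec$width_range[[1]], min(90, spec$width_range[[2]]))
    w_off <- stats::runif(1, spec$width_range[[1]], min(90, spec$width_range[[2]]))
    t_on <- stats::runif(1, 5 * w_on, 600)
    t_off <- stats::runif(1, t_on + 240, spec$horizon - 5 * w_off)
    shape_impulse(baseline, f, t_on, t_off, w_on, w_off)
  }
}

draw_beta_fun <- function(spec) {
  b <- runif_log(1, spec$beta_baseline[[1]], spec$beta_baseline[[2]])
  if (isTRUE(spec$beta_drift)) {
    f <- runif_log(1, 1 / 1.5, 1.5)
    t0 <- stats::runif(1, spec$midpoint_range[[1]], spec$midpoint_range[[2]])
    w <- stats::runif(1, 120, 360)
    shape_sigmoid(b, f, t0, w)
  } else {
    shape_constant(b)
  }
}

#' Draw steady-to-steady kinetic programs
#'
#' Per gene, the transcription rate \eqn{\alpha(t)} and degradation rate
#' \eqn{\gamma(t)} are each (independently) a sigmoid transition to a new
#' steady level or a transient impulse returning to baseline; the splicing
#' rate \eqn{\beta(t)} is constant by default (see [scenario_spec()]).
#'
#' @param spec A [scenario_spec()] with `scenario = "steady_to_steady"`.
#' @return List of [kinetic_trajectory()] objects of length `spec$n_genes`.
#' @export
draw_steady_to_steady <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"),
            spec$scenario == "steady_to_steady")
  set.seed(spec$seed)
  lapply(seq_len(spec$n_genes), function(i) {
    a_b <- runif_log(1, spec$alpha_baseline[[1]], spec$alpha_baseline[[2]])
    g_b <- runif_log(1, spec$gamma_baseline[[1]], spec$gamma_baseline[[2]])
    kinetic_trajectory(draw_s2s_rate(spec, a_b),
                       draw_beta_fun(spec),
                       draw_s2s_rate(spec, g_b),
                       horizon = spec$horizon)
  })
}

#' Draw oscillating kinetic programs
#'
#' \eqn{\alpha(t)} and \eqn{\gamma(t)} are sinusoidal on a log scale
#' (`baseline * exp(A sin(2 pi t / P + phi))`) with circadian-scale periods;
#' \eqn{\beta(t)} as in the steady-to-steady scenario. Strictly positive by
#' construction.
#'
#' @param spec A [scenario_spec()] with `scenario = "oscillating"`.
#' @return List of [kinetic_trajectory()] objects.
#' @export
draw_oscillating <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"), spec$scenario == "oscillating")
  set.seed(spec$seed)
  draw_osc_rate <- function(baseline) {
    A <- stats::runif(1, spec$amplitude_range[[1]], spec$amplitude_range[[2]])
    P <- stats::runif(1, spec$period_range[[1]], spec$period_range[[2]])
    phi <- stats::runif(1, 0, 2 * pi)
    shape_oscillating(baseline, A, P, phi)
  }
  lapply(seq_len(spec$n_genes), function(i) {
    a_b <- runif_log(1, spec$alpha_baseline[[1]], spec$alpha_baseline[[2]])
    g_b <- runif_log(1, spec$gamma_baseline[[1]], spec$gamma_baseline[[2]])
    kinetic_trajectory(draw_osc_rate(a_b),
                       draw_beta_fun(spec),
                       draw_osc_rate(g_b),
                       horizon = spec$horizon)
  })
}

#' Gene time series: replicated noisy observations of one gene
#'
#' @param gene_id Gene label.
#' @param times Strictly increasing observation times (minutes), starting at 0.
#' @param U_obs,S_obs Matrices `length(times) x n_replicates` of observed
#'   unspliced / spliced values (`NA` allowed for missing cells in real data).
#' @param scale Optional named vector `c(U=, S=)` of the physical scale
#'   factors already divided out of the values (used to keep rate units
#'   consistent when data were max-normalized upstream).
#' @return An object of class `gene_time_series`.
#' @export
gene_time_series <- function(gene_id, times, U_obs, S_obs, scale = NULL) {
  U_obs <- as.matrix(U_obs); S_obs <- as.matrix(S_obs)
  if (length(times) < 2 || times[[1]] != 0 || any(diff(times) <= 0)) {
    stop("gene_time_series: times must be strictly increasing and start at 0")
  }
  if (nrow(U_obs) != length(times) || nrow(S_obs) != length(times)) {
    stop("gene_time_series: observation matrices must have one row per time point")
  }
  if (ncol(U_obs) != ncol(S_obs)) {
    stop("gene_time_series: U and S must have the same number of replicates")
  }
  structure(list(gene_id = gene_id, times = as.numeric(times),
                 U_obs = U_obs, S_obs = S_obs,
                 n_replicates = ncol(U_obs), scale = scale),
            class = "gene_time_series")
}

#' @export
print.gene_time_series <- function(x, ...) {
  cat(sprintf("<gene_time_series> %s: %d time points x %d replicates on [0, %g] min\n",
              x$gene_id, length(x$times), x$n_replicates, max(x$times)))
  invisible(x)
}

#' Sample noisy replicate observations from a dense state trajectory
#'
#' Observation times are `0, SI, 2*SI, ..., horizon`. Each replicate value is
#' the trajectory value plus Gaussian noise whose standard deviation is
#' `noise_frac` times the standard deviation of that channel's trajectory
#' over the dense grid (computed separately for U and S). Negative draws are
#' clipped to zero, since abundances are non-negative.
#'
#' @param state A dense `state_trajectory` (from [solve_forward()]) covering
#'   `[0, horizon]`.
#' @param sampling_interval Sampling interval SI in minutes; must divide the
#'   horizon (the design grids are SI = 60, 120 or 180 for a 1440-min day).
#' @param n_replicates Number of replicates (default 3).
#' @param noise_frac Noise level as a fraction of the trajectory SD
#'   (the design levels are 0.10, 0.20, 0.30).
#' @param seed Integer seed; the draw is bit-reproducible.
#' @param gene_id Label for the resulting series.
#' @return A [gene_time_series()].
#' @export
sample_observations <- function(state, sampling_interval, n_replicates = 3,
                                noise_frac = 0.1, seed = 1L,
                                gene_id = "gene") {
  stopifnot(inherits(state, "state_trajectory") || is.data.frame(state))
  horizon <- max(state$time)
  if (horizon %% sampling_interval != 0) {
    stop("sample_observations: sampling_interval must divide the horizon")
  }
  if (noise_frac < 0) stop("sample_observations: noise_frac must be >= 0")
  t_obs <- seq(0, horizon, by = sampling_interval)
  idx <- match(t_obs, state$time)
  if (anyNA(idx)) stop("sample_observations: state grid must contain all observation times")
  sd_u <- stats::sd(state$U) * noise_frac
  sd_s <- stats::sd(state$S) * noise_frac
  set.seed(as.integer(seed))
  n <- length(t_obs)
  U <- matrix(state$U[idx], n, n_replicates) +
    matrix(stats::rnorm(n * n_replicates, 0, sd_u), n, n_replicates)
  S <- matrix(state$S[idx], n, n_replicates) +
    matrix(stats::rnorm(n * n_replicates, 0, sd_s), n, n_replicates)
  U[U < 0] <- 0
  S[S < 0] <- 0
  gene_time_series(gene_id, t_obs, U, S)
}

#' Simulate a full scenario: kinetics, dense states, noisy observations
#'
#' Draws `spec$n_genes` kinetic programs, integrates the lifecycle ODEs from
#' the steady state implied by the t = 0 rates on a 1-min dense grid, and
#' samples noisy triplicate observations.
#'
#' @param spec A [scenario_spec()].
#' @param sampling_interval SI in minutes (60, 120 or 180 for the design grids).
#' @param noise_frac Noise fraction of trajectory SD.
#' @param n_replicates Replicates per time point (default 3).
#' @param grid_step Dense-grid step in minutes (default 1).
#' @return A list of `simulated_gene` objects, each with elements `gene_id`,
#'   `truth` ([kinetic_trajectory()]), `truth_grid` (data.frame `time`,
#'   `alpha`, `beta`, `gamma` on the dense grid), `state` (dense
#'   `state_trajectory`) and `observations` ([gene_time_series()]).
#' @export
simulate_scenario <- function(spec, sampling_interval = 180,
                              noise_frac = 0.3, n_replicates = 3,
                              grid_step = 1) {
  kins <- if (spec$scenario == "steady_to_steady") {
    draw_steady_to_steady(spec)
  } else {
    draw_oscillating(spec)
  }
  dense <- seq(0, spec$horizon, by = grid_step)
  lapply(seq_along(kins), function(i) {
    kin <- kins[[i]]
    gene_id <- sprintf("sim_gene_%03d", i)
    y0 <- steady_state(kin, 0)
    st <- solve_forward(kin, y0, dense)
    obs <- sample_observations(st, sampling_interval, n_replicates,
                               noise_frac, seed = spec$seed + 7919L * i,
                               gene_id = gene_id)
    structure(list(gene_id = gene_id, truth = kin,
                   truth_grid = data.frame(time = dense,
                                           alpha = kin$alpha(dense),
                                           beta = kin$beta(dense),
                                           gamma = kin$gamma(dense)),
                   state = st, observations = obs),
              class = "simulated_gene")
  })
}

#' Subsample simulated genes to match a reference CV distribution
#'
#' Weighted sampling without replacement where each pool gene's weight is the
#' ratio of the reference coefficient-of-variation (CV) histogram density to
#' the pool's own CV histogram density at that gene's CV (histogram-ratio
#' weighting). The CV of a simulated gene is `sd/mean` of its dense spliced
#' trajectory.
#'
#' @param pool List of `simulated_gene` objects.
#' @param reference_cv Numeric vector of reference CV values.
#' @param n Number of genes to select (`n <= length(pool)`).
#' @param seed Integer seed.
#' @param n_bins Number of shared histogram bins (default 20).
#' @return A list of `n` selected `simulated_gene` objects.
#' @export
cv_weighted_subsample <- function(pool, reference_cv, n, seed = 1L,
                                  n_bins = 20) {
  stopifnot(length(pool) >= n, length(reference_cv) > 0)
  if (n == length(pool)) return(pool)
  pool_cv <- vapply(pool, function(g) {
    stats::sd(g$state$S) / mean(g$state$S)
  }, numeric(1))
  breaks <- seq(min(c(pool_cv, reference_cv)) - 1e-9,
                max(c(pool_cv, reference_cv)) + 1e-9,
                length.out = n_bins + 1)
  h_ref <- graphics::hist(reference_cv, breaks = breaks, plot = FALSE)$density
  h_pool <- graphics::hist(pool_cv, breaks = breaks, plot = FALSE)$density
  bin <- findInterval(pool_cv, breaks, all.inside = TRUE)
  w <- h_ref[bin] / pmax(h_pool[bin], 1e-12)
  if (all(w <= 1e-12)) {
    warning("cv_weighted_subsample: no overlap between CV supports; falling back to uniform weights")
    w <- rep(1, length(pool))
  } else if (sum(w > 0) < n) {
    # not enough positively weighted genes to fill the draw: keep the
    # ratio weighting but add a small uniform floor
    w <- w + 1e-6 * max(w)
  }
  set.seed(as.integer(seed))
  idx <- sample.int(length(pool), n, replace = FALSE, prob = w)
  pool[idx]
}
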