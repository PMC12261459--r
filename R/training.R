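# Per-gene optimization: Adam with self-adaptive min-max weighting, then
# L-BFGS refinement with frozen weights, multi-restart ensembling.

#' Training configuration
#'
#' @param adam_max_iter Maximum Adam iterations (default 3000).
#' @param lbfgs_max_iter Maximum L-BFGS iterations (default 5000).
#' @param adam_lr Adam step size (default 1e-3).
#' @param lambda_init Initial adaptive weight for the ODE and auxiliary terms
#'   (default 0.01; `1/n_data` is a common alternative).
#' @param lambda_lr Gradient-ascent step for the adaptive weights; the
#'   ascent gradient of the total loss with respect to each weight is the
#'   corresponding component loss.
#' @param lambda_max Cap on the adaptive weights (numerical guard).
#' @param ascent_window Moving-window length (iterations) for the "total
#'   loss still decreasing" check that gates the ascent.
#' @param warmup_frac Fraction of the Adam iterations during which only the
#'   data module trains (kinetic-module gradients and the lambda ascent are
#'   held); fitting the observed patterns first keeps the kinetic modules
#'   from chasing the meaningless ODE residual of a still-random data fit
#'   toward the trivial zero-rate solution.
#' @param convergence_tol Relative total-loss change below which L-BFGS
#'   stops early (maps to `factr` of `optim`).
#' @param n_restarts Ensemble size: independent random initializations whose
#'   estimated trajectories are averaged (default 10).
#' @param use_init_anchor,use_steady_anchor Enable the optional
#'   initial-state data anchor / initial steady-state ODE anchor
#'   (recommended for perturbation time courses starting from steady state).
#' @param beta_prior_weight Weight of a small ridge penalty on the splicing
#'   module's raw output. The splicing rate's overall scale is only weakly
#'   identified by unspliced/spliced data (the loss is nearly flat along a
#'   ridge trading the splicing scale against the degradation trajectory),
#'   so without an anchor long optimizations drift along that ridge; this
#'   weakly-informative prior keeps beta at the transform midpoint unless
#'   the spliced-flux information in the data actively moves it.
#' @param collocation_scheme `"uniform"` or `"jittered"`.
#' @param seed Master seed; restart seeds are derived by fixed offsets.
#' @return An object of class `train_config`.
#' @export
train_config <- function(adam_max_iter = 3000L,
                         lbfgs_max_iter = 5000L,
                         adam_lr = 1e-3,
                         lambda_init = 0.01,
                         lambda_lr = 2,
                         lambda_max = 1e4,
                         ascent_window = 50L,
                         warmup_frac = 0.2,
                         convergence_tol = 1e-9,
                         n_restarts = 10L,
                         use_init_anchor = FALSE,
                         use_steady_anchor = FALSE,
                         beta_prior_weight = 2e-3,
                         collocation_scheme = "uniform",
                         seed = 1L) {
  stopifnot(adam_max_iter >= 1, lbfgs_max_iter >= 1, lambda_init > 0,
            n_restarts >= 1)
  structure(list(adam_max_iter = as.integer(adam_max_iter),
                 lbfgs_max_iter = as.integer(lbfgs_max_iter),
                 adam_lr = adam_lr, lambda_init = lambda_init,
                 lambda_lr = lambda_lr, lambda_max = lambda_max,
                 ascent_window = as.integer(ascent_window),
                 warmup_frac = warmup_frac,
                 convergence_tol = convergence_tol,
                 n_restarts = as.integer(n_restarts),
                 use_init_anchor = use_init_anchor,
                 use_steady_anchor = use_steady_anchor,
                 beta_prior_weight = beta_prior_weight,
                 collocation_scheme = collocation_scheme,
                 seed = as.integer(seed)),
            class = "train_config")
}

data_scale <- function(data) {
  cu <- max(data$U_obs, na.rm = TRUE)
  cs <- max(data$S_obs, na.rm = TRUE)
  if (cu <= 0 || cs <= 0) {
    stop("train: gene ", data$gene_id, " has no signal in one channel")
  }
  up <- if (is.null(data$scale)) 1 else data$scale[["U"]]
  sp <- if (is.null(data$scale)) 1 else data$scale[["S"]]
  c(U = cu * up, S = cs * sp)
}

#' Train a single restart of the PINN on one gene
#'
#' Phase 1 runs Adam descent on the network weights interleaved with
#' gradient-ascent steps on the two adaptive loss weights; the ascent is
#' active only while the total loss is still decreasing (moving-window
#' check). Phase 2 refines the weights with L-BFGS at frozen adaptive
#' weights. Abundances are normalized internally by the per-channel maxima;
#' the known scale ratio enters the ODE residual so rates keep their units.
#'
#' @param data A [gene_time_series()].
#' @param net_cfg A [network_config()] (defaults to one derived from the
#'   data).
#' @param train_cfg A [train_config()].
#' @param restart_seed Integer seed for this restart's initialization.
#' @return A list of class `pinn_fit` with the trained model, loss and
#'   lambda histories, convergence flags and the normalization scales.
#' @export
train_single <- function(data, net_cfg = NULL,
                         train_cfg = train_config(),
                         restart_seed = train_cfg$seed) {
  stopifnot(inherits(data, "gene_time_series"))
  if (is.null(net_cfg)) net_cfg <- network_config(length(data$times))
  scale <- data_scale(data)
  # rho links the separately scaled channels inside the spliced equation
  rho <- unname(scale[["U"]] / scale[["S"]])
  # normalize the observations by the in-sample maxima for the network
  norm_data <- data
  cu <- max(data$U_obs, na.rm = TRUE)
  cs <- max(data$S_obs, na.rm = TRUE)
  norm_data$U_obs <- data$U_obs / cu
  norm_data$S_obs <- data$S_obs / cs

  st <- engine_static(net_cfg, norm_data, scale = c(U = 1, S = 1), rho = rho,
                      use_init_anchor = train_cfg$use_init_anchor,
                      use_steady_anchor = train_cfg$use_steady_anchor,
                      collocation_scheme = train_cfg$collocation_scheme,
                      seed = restart_seed,
                      beta_prior_weight = train_cfg$beta_prior_weight)

  model <- pinn_model(net_cfg, lambda_init = train_cfg$lambda_init,
                      seed = restart_seed,
                      scale = c(U = cu, S = cs),
                      data_output_init = c(mean(st$ubar), mean(st$sbar)))
  par <- model_flatten(model)
  lambda <- c(ode = train_cfg$lambda_init, aux = train_cfg$lambda_init)

  # ---- phase 1: Adam on theta, gated Adam-normalized ascent on lambda ----
  m <- v <- numeric(length(par))
  m_l <- v_l <- numeric(2)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- train_cfg$adam_lr
  n_it <- train_cfg$adam_max_iter
  hist_total <- hist_data <- hist_ode <- hist_aux <- numeric(n_it)
  hist_l1 <- hist_l2 <- numeric(n_it)
  w <- train_cfg$ascent_window
  warmup <- floor(train_cfg$warmup_frac * n_it)
  n_data_par <- net_npar(net_cfg$data_width, 2L)
  failed <- FALSE
  for (it in seq_len(n_it)) {
    ev <- engine_eval(par, st, lambda)
    if (!is.finite(ev$total) || !all(is.finite(ev$grad))) {
      failed <- TRUE
      break
    }
    if (it <= warmup) ev$grad[-seq_len(n_data_par)] <- 0
    hist_total[it] <- ev$total
    hist_data[it] <- ev$data
    hist_ode[it] <- ev$ode
    hist_aux[it] <- ev$aux
    hist_l1[it] <- lambda[[1]]
    hist_l2[it] <- lambda[[2]]
    m <- b1 * m + (1 - b1) * ev$grad
    v <- b2 * v + (1 - b2) * ev$grad^2
    mhat <- m / (1 - b1^it)
    vhat <- v / (1 - b2^it)
    par <- par - lr * mhat / (sqrt(vhat) + eps)
    # lambda ascent gated on a decreasing loss trend
    ascend <- if (it <= warmup) FALSE else if (it <= warmup + 2 * w) TRUE else {
      mean(hist_total[(it - w + 1):it]) < mean(hist_total[(it - 2 * w + 1):(it - w)])
    }
    if (ascend) {
      # ascent gradient of the total loss w.r.t. each lambda is the
      # corresponding component loss; Adam-normalized so the effective step
      # is ~lambda_lr per iteration regardless of the loss scale
      gl <- c(ev$ode, ev$aux)
      m_l <- b1 * m_l + (1 - b1) * gl
      v_l <- b2 * v_l + (1 - b2) * gl^2
      step <- train_cfg$lambda_lr * (m_l / (1 - b1^it)) /
        (sqrt(v_l / (1 - b2^it)) + eps)
      lambda <- pmin(lambda + pmax(step, 0), train_cfg$lambda_max)
    }
  }
  adam_iters <- if (failed) it - 1L else n_it
  if (failed && adam_iters < 1L) {
    return(structure(list(gene_id = data$gene_id, failed = TRUE,
                          message = "non-finite loss at initialization",
                          seed = restart_seed),
                     class = "pinn_fit"))
  }

  # ---- phase 2: L-BFGS on theta, lambda frozen ----
  lbfgs_start <- NULL
  converged <- FALSE
  final_ev <- NULL
  if (!failed) {
    cache <- new.env(parent = emptyenv())
    fn <- function(p) {
      ev <- engine_eval(p, st, lambda)
      cache$last_p <- p
      cache$last <- ev
      if (!is.finite(ev$total)) return(1e10)
      ev$total
    }
    gr <- function(p) {
      ev <- if (!is.null(cache$last_p) && identical(p, cache$last_p)) {
        cache$last
      } else {
        engine_eval(p, st, lambda)
      }
      g <- ev$grad
      g[!is.finite(g)] <- 0
      g
    }
    lbfgs_start <- engine_eval(par, st, lambda, want_grad = FALSE)$total
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(
                          maxit = train_cfg$lbfgs_max_iter,
                          factr = max(train_cfg$convergence_tol /
                                        .Machine$double.eps, 1),
                          pgtol = 0
                        ))
    if (opt$value <= lbfgs_start && is.finite(opt$value)) {
      par <- opt$par
      converged <- opt$convergence == 0
    }
    final_ev <- engine_eval(par, st, lambda, want_grad = FALSE)
    if (!is.finite(final_ev$total)) failed <- TRUE
  }

  model$nets <- model_unflatten(par, net_cfg)
  model$lambda <- lambda
  structure(list(
    gene_id = data$gene_id,
    model = model,
    failed = failed,
    converged = converged,
    seed = restart_seed,
    lbfgs_start = lbfgs_start,
    final_loss = if (failed || is.null(final_ev)) NULL else final_ev,
    loss_history = data.frame(iter = seq_len(adam_iters),
                              total = hist_total[seq_len(adam_iters)],
                              data = hist_data[seq_len(adam_iters)],
                              ode = hist_ode[seq_len(adam_iters)],
                              aux = hist_aux[seq_len(adam_iters)]),
    lambda_history = data.frame(iter = seq_len(adam_iters),
                                lambda_ode = hist_l1[seq_len(adam_iters)],
                                lambda_aux = hist_l2[seq_len(adam_iters)])
  ), class = "pinn_fit")
}

#' Evaluate a trained restart on an arbitrary time grid
#'
#' @param fit A `pinn_fit` from [train_single()].
#' @param times Times in minutes within `[0, horizon]` (no extrapolation).
#' @return `data.frame` with columns `time`, `U_fit`, `S_fit`, `alpha`,
#'   `beta`, `gamma` in the units of the input data (the per-channel
#'   normalization is inverted; rates are per minute).
#' @export
predict_fit <- function(fit, times) {
  stopifnot(inherits(fit, "pinn_fit"), !isTRUE(fit$failed))
  horizon <- fit$model$cfg$horizon
  if (any(times < 0 | times > horizon)) {
    stop("predict_fit: times outside [0, ", horizon, "] are not supported (no extrapolation)")
  }
  if (is.unsorted(times, strictly = FALSE)) {
    stop("predict_fit: times must be non-decreasing")
  }
  p <- predict_pinn(fit$model, times)
  sc <- fit$model$scale
  data.frame(time = times,
             U_fit = p$U * sc[["U"]],
             S_fit = p$S * sc[["S"]],
             alpha = p$alpha * sc[["U"]],
             beta = p$beta,
             gamma = p$gamma)
}

#' Train an ensemble of restarts and average the estimated dynamics
#'
#' Runs [train_single()] under `n_restarts` seeds derived from the master
#' seed by fixed offsets and averages the five estimated trajectories
#' point-wise across the successful restarts, which damps the
#' initialization-dependent variability of individual fits.
#'
#' @param data A [gene_time_series()].
#' @param net_cfg A [network_config()] (default derived from the data).
#' @param train_cfg A [train_config()].
#' @param grid_step Dense output grid step in minutes (default 1).
#' @return An object of class `trained_gene_model` with elements `gene_id`,
#'   `mean_trajectory` (dense `data.frame`), `ensemble` (per-restart dense
#'   trajectories), `fits` (the `pinn_fit` objects), `n_failed` and
#'   `restart_seeds`.
#' @export
train_ensemble <- function(data, net_cfg = NULL,
                           train_cfg = train_config(),
                           grid_step = 1) {
  if (is.null(net_cfg)) net_cfg <- network_config(length(data$times))
  seeds <- train_cfg$seed + 101L * (seq_len(train_cfg$n_restarts) - 1L)
  fits <- lapply(seeds, function(s) {
    train_single(data, net_cfg, train_cfg, restart_seed = s)
  })
  ok <- !vapply(fits, function(f) isTRUE(f$failed), logical(1))
  if (!any(ok)) {
    stop("train_ensemble: all ", length(fits), " restarts failed for gene ",
         data$gene_id)
  }
  times <- seq(0, net_cfg$horizon, by = grid_step)
  ensemble <- lapply(fits[ok], predict_fit, times = times)
  mean_traj <- ensemble[[1]]
  if (length(ensemble) > 1) {
    for (cn in c("U_fit", "S_fit", "alpha", "beta", "gamma")) {
      mean_traj[[cn]] <- rowMeans(vapply(ensemble, function(e) e[[cn]],
                                         numeric(length(times))))
    }
  }
  structure(list(gene_id = data$gene_id,
                 mean_trajectory = mean_traj,
                 ensemble = ensemble,
                 fits = fits,
                 n_failed = sum(!ok),
                 restart_seeds = seeds),
            class = "trained_gene_model")
}

#' @export
print.trained_gene_model <- function(x, ...) {
  cat(sprintf("<trained_gene_model> %s: %d/%d restarts succeeded, dense grid of %d points\n",
              x$gene_id, length(x$ensemble), length(x$fits),
              nrow(x$mean_trajectory)))
  invisible(x)
}

#' Evaluate the ensemble-averaged dynamics on an arbitrary grid
#'
#' @param model A `trained_gene_model`.
#' @param times Times in minutes within `[0, horizon]`.
#' @return `data.frame` with `time`, `U_fit`, `S_fit`, `alpha`, `beta`,
#'   `gamma` averaged across the successful restarts.
#' @export
predict_dense <- function(model, times = NULL) {
  stopifnot(inherits(model, "trained_gene_model"))
  if (is.null(times)) return(model$mean_trajectory)
  ok_fits <- Filter(function(f) !isTRUE(f$failed), model$fits)
  trajs <- lapply(ok_fits, predict_fit, times = times)
  out <- trajs[[1]]
  if (length(trajs) > 1) {
    for (cn in c("U_fit", "S_fit", "alpha", "beta", "gamma")) {
      out[[cn]] <- rowMeans(vapply(trajs, function(e) e[[cn]],
                                   numeric(length(times))))
    }
  }
  out
}
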