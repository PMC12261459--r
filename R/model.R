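# Model state: the data module (one 2-output MLP for the unspliced/spliced
# state) plus three kinetic modules (one 1-output MLP per rate, passed
# through a strictly positive softplus transform), the self-adaptive loss
# weights, and the normalization bookkeeping that links network space to
# physical units.

#' Network configuration
#'
#' Architecture and output-transform settings for the PINN. The data module
#' has two tanh hidden layers of width `2 * n_data`; the kinetic modules use
#' the same architecture with width `min(2 * n_data, 32)`. Time is mapped
#' affinely from `[0, horizon]` to `[-1, 1]` before entering any network.
#' Kinetic-module raw outputs pass through `r_min + scale * softplus(raw)`,
#' with `scale` chosen so that a freshly initialized network (raw output near
#' 0) emits the configured mid-range rate.
#'
#' @param n_data Number of observation time points.
#' @param horizon Time horizon in minutes (default 1440).
#' @param data_width Width of the data module's hidden layers
#'   (default `2 * n_data`).
#' @param kinetic_width Width of the kinetic modules
#'   (default `min(2 * n_data, 32)`).
#' @param rate_mid Named vector of mid-range rates the transforms are centred
#'   on, in normalized-abundance units per minute. Defaults reflect
#'   mammalian mRNA kinetics with abundances scaled to a unit maximum:
#'   splicing ~0.16/min (minutes-scale), degradation ~0.022/min (hours-scale
#'   half-life), transcription ~0.1 normalized units/min.
#' @param rate_min Named vector of lower bounds added to the softplus output.
#' @param node_factor Collocation density: `node_factor * n_data` uniform
#'   points plus the observation times themselves.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_data,
                           horizon = 1440,
                           data_width = 2L * n_data,
                           kinetic_width = min(2L * n_data, 32L),
                           rate_mid = c(alpha = 0.1, beta = 0.158, gamma = 0.022),
                           rate_min = c(alpha = 1e-5, beta = 1e-4, gamma = 1e-5),
                           node_factor = 10L) {
  stopifnot(n_data >= 2, data_width >= 1, kinetic_width >= 1, horizon > 0,
            all(rate_mid > rate_min))
  sp0 <- log(2)  # softplus(0)
  structure(list(
    n_data = as.integer(n_data), horizon = horizon,
    data_width = as.integer(data_width),
    kinetic_width = as.integer(kinetic_width),
    rate_min = rate_min,
    rate_scale = (rate_mid - rate_min) / sp0,
    node_factor = as.integer(node_factor)
  ), class = "network_config")
}

time_to_tau <- function(t, horizon) 2 * t / horizon - 1

#' Build a collocation grid
#'
#' Collocation points are the times (beyond the observation times) where the
#' ODE residual is evaluated. The default scheme is a uniform grid on
#' `[0, horizon]`; `"jittered"` perturbs the interior points uniformly within
#' half a spacing (reproducibly under the given seed).
#'
#' @param horizon Time horizon in minutes.
#' @param n_node Number of collocation points (>= 2).
#' @param scheme `"uniform"` or `"jittered"`.
#' @param seed Seed for the jittered scheme.
#' @return Numeric vector of collocation times in `[0, horizon]`, sorted.
#' @export
make_collocation_grid <- function(horizon, n_node,
                                  scheme = c("uniform", "jittered"),
                                  seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(n_node >= 2)
  g <- seq(0, horizon, length.out = n_node)
  if (scheme == "jittered") {
    set.seed(as.integer(seed))
    h <- g[2] - g[1]
    inner <- seq_len(n_node - 2) + 1
    g[inner] <- g[inner] + stats::runif(length(inner), -h / 2, h / 2)
    g <- sort(pmin(pmax(g, 0), horizon))
  }
  g
}

#' Construct a PINN model state
#'
#' Initializes the data module and the three kinetic modules with random
#' weights (reproducible under `seed`) and sets the self-adaptive loss
#' weights to their initial value.
#'
#' @param cfg A [network_config()].
#' @param lambda_init Initial value for both adaptive weights
#'   (default 0.01; `1/n_data` is a common alternative).
#' @param seed Integer seed for weight initialization.
#' @param scale Named vector `c(U=, S=)`: physical value = network value *
#'   scale. Defaults to unit scales.
#' @param data_output_init Optional length-2 vector used to initialize the
#'   data module's output bias (typically the mean normalized observation
#'   per channel).
#' @return An object of class `pinn_model`.
#' @export
pinn_model <- function(cfg, lambda_init = 0.01, seed = 1L,
                       scale = c(U = 1, S = 1), data_output_init = NULL) {
  stopifnot(inherits(cfg, "network_config"), lambda_init > 0)
  set.seed(as.integer(seed))
  nets <- list(
    data = mlp_init(cfg$data_width, 2L),
    alpha = mlp_init(cfg$kinetic_width, 1L),
    beta = mlp_init(cfg$kinetic_width, 1L),
    gamma = mlp_init(cfg$kinetic_width, 1L)
  )
  if (!is.null(data_output_init)) nets$data$b3 <- as.numeric(data_output_init)
  structure(list(nets = nets, cfg = cfg,
                 lambda = c(ode = lambda_init, aux = lambda_init),
                 scale = scale, rho = unname(scale[["U"]] / scale[["S"]])),
            class = "pinn_model")
}

model_flatten <- function(model) {
  c(net_flatten(model$nets$data), net_flatten(model$nets$alpha),
    net_flatten(model$nets$beta), net_flatten(model$nets$gamma))
}

model_unflatten <- function(par, cfg) {
  nd <- net_npar(cfg$data_width, 2L)
  nk <- net_npar(cfg$kinetic_width, 1L)
  list(
    data = net_unflatten(par[seq_len(nd)], cfg$data_width, 2L),
    alpha = net_unflatten(par[nd + seq_len(nk)], cfg$kinetic_width, 1L),
    beta = net_unflatten(par[nd + nk + seq_len(nk)], cfg$kinetic_width, 1L),
    gamma = net_unflatten(par[nd + 2L * nk + seq_len(nk)], cfg$kinetic_width, 1L)
  )
}

#' Evaluate a PINN model (or a functional stand-in) at given times
#'
#' Returns the model-space predictions required by the loss terms: the state
#' `(U, S)`, its time derivatives, the three rates and the time derivative
#' of the splicing rate. For `pinn_model` objects the derivatives come from
#' the analytic forward-mode pass through the networks; for
#' [functional_model()] objects they come from the user-supplied closures.
#'
#' @param model A `pinn_model` or `functional_model`.
#' @param t Numeric vector of times in minutes.
#' @return A list with numeric vectors `U`, `S`, `dU_dt`, `dS_dt`, `alpha`,
#'   `beta`, `gamma`, `dbeta_dt` (all in model space).
#' @export
predict_pinn <- function(model, t) UseMethod("predict_pinn")

#' @export
predict_pinn.pinn_model <- function(model, t) {
  cfg <- model$cfg
  tau <- time_to_tau(t, cfg$horizon)
  kt <- 2 / cfg$horizon
  fd <- mlp_forward(model$nets$data, tau)
  fa <- mlp_forward(model$nets$alpha, tau)
  fb <- mlp_forward(model$nets$beta, tau)
  fg <- mlp_forward(model$nets$gamma, tau)
  list(
    U = fd$Y[, 1], S = fd$Y[, 2],
    dU_dt = fd$dY[, 1] * kt, dS_dt = fd$dY[, 2] * kt,
    alpha = rate_transform(fa$Y[, 1], cfg$rate_min[["alpha"]], cfg$rate_scale[["alpha"]]),
    beta = rate_transform(fb$Y[, 1], cfg$rate_min[["beta"]], cfg$rate_scale[["beta"]]),
    gamma = rate_transform(fg$Y[, 1], cfg$rate_min[["gamma"]], cfg$rate_scale[["gamma"]]),
    dbeta_dt = rate_transform_dr(fb$Y[, 1], cfg$rate_scale[["beta"]]) * fb$dY[, 1] * kt
  )
}

#' Functional model: closures standing in for trained networks
#'
#' Wraps arbitrary state and rate functions (with analytic derivatives) in
#' the same interface as a trained PINN, so the loss terms can be evaluated
#' against exactly known trajectories — e.g. the closed-form constant-rate
#' solution, for which the ODE residual must vanish.
#'
#' @param U,S Functions of time returning the state.
#' @param dU_dt,dS_dt Functions returning the state time derivatives.
#' @param alpha,beta,gamma Rate functions (strictly positive).
#' @param dbeta_dt Function returning the splicing-rate time derivative
#'   (default: identically 0).
#' @param lambda Length-2 adaptive weights `c(ode=, aux=)`.
#' @param rho Scale ratio entering the spliced equation (default 1).
#' @return An object of class `functional_model`.
#' @export
functional_model <- function(U, S, dU_dt, dS_dt, alpha, beta, gamma,
                             dbeta_dt = function(t) rep(0, length(t)),
                             lambda = c(ode = 1, aux = 1), rho = 1) {
  structure(list(funs = list(U = U, S = S, dU_dt = dU_dt, dS_dt = dS_dt,
                             alpha = alpha, beta = beta, gamma = gamma,
                             dbeta_dt = dbeta_dt),
                 lambda = lambda, scale = c(U = 1, S = 1), rho = rho),
            class = "functional_model")
}

#' @export
predict_pinn.functional_model <- function(model, t) {
  lapply(model$funs, function(f) f(t))
}

# --- loss terms (reference implementations used by tests and reporting) ----

model_scale <- function(model) {
  sc <- model$scale
  if (is.null(sc)) c(U = 1, S = 1) else sc
}

normalize_obs <- function(model, data) {
  sc <- model_scale(model)
  list(U = data$U_obs / sc[["U"]], S = data$S_obs / sc[["S"]])
}

#' Data loss: mean squared misfit at the observation times
#'
#' Mean over the observation times of the squared residual between the
#' model state and the observations, summed over the unspliced and spliced
#' components. Replicates are handled by averaging the squared error over
#' all replicate observations at each time point. With
#' `use_init_anchor = TRUE` the squared misfit at t = 0 (against the
#' replicate mean) is added once more as an anchor on the initial state.
#'
#' @param model A `pinn_model` or `functional_model`.
#' @param data A [gene_time_series()]; values are compared in model space
#'   (i.e. divided by `model$scale`).
#' @param use_init_anchor Add the initial-state data anchor term.
#' @return Non-negative scalar.
#' @export
data_loss <- function(model, data, use_init_anchor = FALSE) {
  obs <- normalize_obs(model, data)
  p <- predict_pinn(model, data$times)
  res_u <- obs$U - p$U
  res_s <- obs$S - p$S
  per_time <- rowMeans(res_u^2, na.rm = TRUE) + rowMeans(res_s^2, na.rm = TRUE)
  val <- mean(per_time)
  if (use_init_anchor) {
    y0 <- c(mean(obs$U[1, ], na.rm = TRUE), mean(obs$S[1, ], na.rm = TRUE))
    val <- val + (y0[[1]] - p$U[[1]])^2 + (y0[[2]] - p$S[[1]])^2
  }
  val
}

#' ODE loss: mean squared lifecycle residual at collocation points
#'
#' Mean over collocation points of the squared difference between the model
#' state's time derivative and the lifecycle right-hand side evaluated with
#' the model's own rates, summed over both state components. When the two
#' channels were scaled separately, the spliced equation carries the known
#' normalization ratio `rho` so that rates keep physical units, and its
#' residual is divided by `rho`, which evaluates both residual components on
#' a common physical scale (otherwise the unspliced equation, whose terms
#' are ~1/rho larger, would dominate the loss and its rate gradients). With
#' `use_steady_anchor = TRUE` the squared right-hand side at t = 0 is added,
#' anchoring the initial state to a steady state.
#'
#' @param model A `pinn_model` or `functional_model`.
#' @param grid Numeric vector of collocation times
#'   (see [make_collocation_grid()]).
#' @param use_steady_anchor Add the initial steady-state ODE anchor term.
#' @return Non-negative scalar.
#' @export
ode_loss <- function(model, grid, use_steady_anchor = FALSE) {
  p <- predict_pinn(model, grid)
  rho <- if (is.null(model$rho)) 1 else model$rho
  r_u <- p$dU_dt - (p$alpha - p$beta * p$U)
  r_s <- (p$dS_dt - (rho * p$beta * p$U - p$gamma * p$S)) / rho
  val <- mean(r_u^2 + r_s^2)
  if (use_steady_anchor) {
    p0 <- predict_pinn(model, 0)
    f_u <- p0$alpha[[1]] - p0$beta[[1]] * p0$U[[1]]
    f_s <- (rho * p0$beta[[1]] * p0$U[[1]] - p0$gamma[[1]] * p0$S[[1]]) / rho
    val <- val + f_u^2 + f_s^2
  }
  val
}

#' Auxiliary loss: mean absolute splicing-rate derivative
#'
#' Soft constraint encoding the assumption that splicing efficiency does not
#' change drastically over short timescales: the mean over collocation
#' points of `|d beta / dt|`.
#'
#' @inheritParams ode_loss
#' @return Non-negative scalar.
#' @export
aux_loss <- function(model, grid) {
  p <- predict_pinn(model, grid)
  mean(abs(p$dbeta_dt))
}

#' Total loss: data + weighted ODE + weighted auxiliary terms
#'
#' `L_total = L_data + lambda1 * L_ode + lambda2 * L_aux`, using the model's
#' current adaptive weights, with the optional initial-state anchors.
#'
#' @inheritParams data_loss
#' @inheritParams ode_loss
#' @param grid Collocation times.
#' @return Non-negative scalar.
#' @export
total_loss <- function(model, data, grid,
                       use_init_anchor = FALSE, use_steady_anchor = FALSE) {
  data_loss(model, data, use_init_anchor) +
    model$lambda[[1]] * ode_loss(model, grid, use_steady_anchor) +
    model$lambda[[2]] * aux_loss(model, grid)
}
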