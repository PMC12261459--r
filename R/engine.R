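# Fast combined loss + gradient evaluation used by the optimizers. The
# reference loss functions in model.R define the semantics; this engine
# computes the same quantities plus analytic gradients with respect to all
# network weights in a single pass (tests assert the two routes agree).

engine_static <- function(cfg, data, scale, rho,
                          use_init_anchor = FALSE, use_steady_anchor = FALSE,
                          collocation_scheme = "uniform", seed = 1L,
                          beta_prior_weight = 0) {
  t_d <- data$times
  u_obs <- data$U_obs / scale[["U"]]
  s_obs <- data$S_obs / scale[["S"]]
  ubar <- rowMeans(u_obs, na.rm = TRUE)
  sbar <- rowMeans(s_obs, na.rm = TRUE)
  # constant part of the replicate-averaged data loss (within-time spread)
  res_const <- mean(rowMeans((u_obs - ubar)^2, na.rm = TRUE) +
                    rowMeans((s_obs - sbar)^2, na.rm = TRUE))
  grid <- sort(unique(c(
    make_collocation_grid(cfg$horizon, cfg$node_factor * cfg$n_data,
                          scheme = collocation_scheme, seed = seed),
    t_d
  )))
  list(cfg = cfg,
       tau_d = time_to_tau(t_d, cfg$horizon),
       tau_c = time_to_tau(grid, cfg$horizon),
       grid = grid,
       i0 = which(grid == 0)[[1]],
       ubar = ubar, sbar = sbar, res_const = res_const,
       kt = 2 / cfg$horizon, rho = rho,
       use_init_anchor = use_init_anchor,
       use_steady_anchor = use_steady_anchor,
       beta_prior_weight = beta_prior_weight)
}

add_grads <- function(g1, g2) Map(`+`, g1, g2)

dsigmoid <- function(x) {
  p <- stats::plogis(x)
  p * (1 - p)
}

engine_eval <- function(par, st, lambda, want_grad = TRUE) {
  cfg <- st$cfg
  kt <- st$kt
  rho <- st$rho
  nets <- model_unflatten(par, cfg)

  fd_d <- mlp_forward(nets$data, st$tau_d)
  fd_c <- mlp_forward(nets$data, st$tau_c)
  fa <- mlp_forward(nets$alpha, st$tau_c)
  fb <- mlp_forward(nets$beta, st$tau_c)
  fg <- mlp_forward(nets$gamma, st$tau_c)

  mn <- cfg$rate_min; sc <- cfg$rate_scale
  a_raw <- fa$Y[, 1]; b_raw <- fb$Y[, 1]; g_raw <- fg$Y[, 1]
  a <- rate_transform(a_raw, mn[["alpha"]], sc[["alpha"]])
  b <- rate_transform(b_raw, mn[["beta"]], sc[["beta"]])
  g <- rate_transform(g_raw, mn[["gamma"]], sc[["gamma"]])

  u_c <- fd_c$Y[, 1]; s_c <- fd_c$Y[, 2]
  du <- fd_c$dY[, 1] * kt
  ds <- fd_c$dY[, 2] * kt
  r_u <- du - (a - b * u_c)
  r_s <- (ds - (rho * b * u_c - g * s_c)) / rho
  n_c <- length(st$tau_c)
  L_ode <- mean(r_u^2 + r_s^2)

  dbraw <- fb$dY[, 1]
  db_dt <- rate_transform_dr(b_raw, sc[["beta"]]) * dbraw * kt
  L_aux <- mean(abs(db_dt))

  u_d <- fd_d$Y[, 1]; s_d <- fd_d$Y[, 2]
  n_d <- length(st$tau_d)
  L_data <- mean((st$ubar - u_d)^2 + (st$sbar - s_d)^2) + st$res_const
  if (st$use_init_anchor) {
    L_data <- L_data + (st$ubar[[1]] - u_d[[1]])^2 + (st$sbar[[1]] - s_d[[1]])^2
  }
  if (st$use_steady_anchor) {
    i0 <- st$i0
    f_u0 <- a[[i0]] - b[[i0]] * u_c[[i0]]
    f_s0 <- (rho * b[[i0]] * u_c[[i0]] - g[[i0]] * s_c[[i0]]) / rho
    L_ode <- L_ode + f_u0^2 + f_s0^2
  }
  # weakly-informative prior on the splicing scale: penalizes the beta
  # module's raw output, anchoring beta to the transform midpoint along the
  # loss's nearly flat scale direction (see the methods vignette)
  mu <- st$beta_prior_weight
  L_prior <- mu * mean(b_raw^2)

  l1 <- lambda[[1]]; l2 <- lambda[[2]]
  total <- L_data + l1 * L_ode + l2 * L_aux + L_prior

  out <- list(total = total, data = L_data, ode = L_ode, aux = L_aux,
              prior = L_prior)
  if (!want_grad) return(out)

  # --- data-batch gradient of the data net ---
  GYd <- cbind(2 / n_d * (u_d - st$ubar), 2 / n_d * (s_d - st$sbar))
  if (st$use_init_anchor) {
    GYd[1, ] <- GYd[1, ] + 2 * c(u_d[[1]] - st$ubar[[1]], s_d[[1]] - st$sbar[[1]])
  }
  gd1 <- mlp_backward(nets$data, fd_d, GYd, NULL)

  # --- collocation-batch gradients ---
  cu <- l1 * 2 * r_u / n_c
  cs <- l1 * 2 * r_s / (n_c * rho)
  GYc <- cbind(cu * b - cs * rho * b, cs * g)
  GdYc <- cbind(cu * kt, cs * kt)
  Ga <- -cu
  Gb <- cu * u_c - cs * rho * u_c
  Gg <- cs * s_c
  if (st$use_steady_anchor) {
    i0 <- st$i0
    au <- l1 * 2 * f_u0
    as_ <- l1 * 2 * f_s0 / rho
    GYc[i0, 1] <- GYc[i0, 1] + au * (-b[[i0]]) + as_ * rho * b[[i0]]
    GYc[i0, 2] <- GYc[i0, 2] + as_ * (-g[[i0]])
    Ga[[i0]] <- Ga[[i0]] + au
    Gb[[i0]] <- Gb[[i0]] + au * (-u_c[[i0]]) + as_ * rho * u_c[[i0]]
    Gg[[i0]] <- Gg[[i0]] + as_ * (-s_c[[i0]])
  }
  gd2 <- mlp_backward(nets$data, fd_c, GYc, GdYc)

  ga <- mlp_backward(nets$alpha, fa,
                     cbind(Ga * rate_transform_dr(a_raw, sc[["alpha"]])), NULL)
  gg <- mlp_backward(nets$gamma, fg,
                     cbind(Gg * rate_transform_dr(g_raw, sc[["gamma"]])), NULL)

  # beta: the ODE residual touches its value; the auxiliary loss touches both
  # its value (through the softplus slope) and its raw time derivative.
  Gdb <- l2 * sign(db_dt) / n_c
  GY_b <- Gb * rate_transform_dr(b_raw, sc[["beta"]]) +
    Gdb * sc[["beta"]] * dsigmoid(b_raw) * dbraw * kt +
    2 * mu * b_raw / n_c
  GdY_b <- Gdb * sc[["beta"]] * stats::plogis(b_raw) * kt
  gb <- mlp_backward(nets$beta, fb, cbind(GY_b), cbind(GdY_b))

  out$grad <- c(net_flatten(add_grads(gd1, gd2)), net_flatten(ga),
                net_flatten(gb), net_flatten(gg))
  out
}
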