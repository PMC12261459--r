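# Helper: functional model wrapping the constant-rate closed form, whose ODE
# residual is analytically zero.
closed_form_model <- function(alpha, beta, gamma, y0, lambda = c(1, 1)) {
  functional_model(
    U = function(t) closed_form_constant(alpha, beta, gamma, y0, t)$U,
    S = function(t) closed_form_constant(alpha, beta, gamma, y0, t)$S,
    dU_dt = function(t) {
      u <- closed_form_constant(alpha, beta, gamma, y0, t)$U
      alpha - beta * u
    },
    dS_dt = function(t) {
      cf <- closed_form_constant(alpha, beta, gamma, y0, t)
      beta * cf$U - gamma * cf$S
    },
    alpha = function(t) rep(alpha, length(t)),
    beta = function(t) rep(beta, length(t)),
    gamma = function(t) rep(gamma, length(t)),
    lambda = lambda
  )
}

test_that("data loss follows the replicate-averaged squared-error convention", {
  fm <- closed_form_model(1, 2, 1, c(0, 0))
  ts <- seq(0, 1440, by = 180)
  cf <- closed_form_constant(1, 2, 1, c(0, 0), ts)
  noiseless <- gene_time_series("g", ts, cbind(cf$U, cf$U), cbind(cf$S, cf$S))
  # exact predictions give zero loss
  expect_equal(data_loss(fm, noiseless), 0)

  # single time point, Y = (1,1), prediction (0,0): component-summed MSE = 2
  zero_model <- functional_model(
    U = function(t) rep(0, length(t)), S = function(t) rep(0, length(t)),
    dU_dt = function(t) rep(0, length(t)), dS_dt = function(t) rep(0, length(t)),
    alpha = function(t) rep(1, length(t)), beta = function(t) rep(1, length(t)),
    gamma = function(t) rep(1, length(t)))
  one_pt <- gene_time_series("g", c(0, 1440), matrix(1, 2, 1), matrix(1, 2, 1))
  expect_equal(data_loss(zero_model, one_pt), 2)

  # doubling all residuals quadruples the loss (quadratic form)
  twice <- gene_time_series("g", ts, cbind(cf$U + 2, cf$U + 2),
                            cbind(cf$S, cf$S))
  once <- gene_time_series("g", ts, cbind(cf$U + 1, cf$U + 1),
                           cbind(cf$S, cf$S))
  expect_equal(data_loss(fm, twice), 4 * data_loss(fm, once))

  # the initial-state anchor doubles the t=0 contribution
  only0 <- gene_time_series("g", ts,
                            cbind(cf$U + c(1, rep(0, length(ts) - 1))),
                            cbind(cf$S))
  expect_equal(data_loss(fm, only0, use_init_anchor = TRUE),
               data_loss(fm, only0) + 1)
})

test_that("exact solutions certify the ODE loss machinery (consistency certificate)", {
  grid <- make_collocation_grid(1440, 145)
  # closed-form solution with the true constant rates: residual vanishes
  fm <- closed_form_model(1.3, 0.21, 0.035, c(0.5, 12))
  expect_lt(ode_loss(fm, grid), 1e-6)
  expect_equal(aux_loss(fm, grid), 0)
  # steady-state identity alpha = beta*c1, gamma = beta*c1/c2 gives residual 0
  ss <- functional_model(
    U = function(t) rep(2, length(t)), S = function(t) rep(8, length(t)),
    dU_dt = function(t) rep(0, length(t)), dS_dt = function(t) rep(0, length(t)),
    alpha = function(t) rep(0.3 * 2, length(t)),
    beta = function(t) rep(0.3, length(t)),
    gamma = function(t) rep(0.3 * 2 / 8, length(t)))
  expect_equal(ode_loss(ss, grid), 0)
  # the steady anchor is also zero there
  expect_equal(ode_loss(ss, grid, use_steady_anchor = TRUE), 0)
})

test_that("auxiliary loss is the mean absolute splicing-rate derivative", {
  grid <- make_collocation_grid(1440, 100)
  lin_beta <- function(k) functional_model(
    U = function(t) rep(1, length(t)), S = function(t) rep(1, length(t)),
    dU_dt = function(t) rep(0, length(t)), dS_dt = function(t) rep(0, length(t)),
    alpha = function(t) rep(1, length(t)),
    beta = function(t) 0.2 + k * t,
    gamma = function(t) rep(0.02, length(t)),
    dbeta_dt = function(t) rep(k, length(t)))
  expect_equal(aux_loss(lin_beta(0), grid), 0)
  expect_equal(aux_loss(lin_beta(1e-4), grid), 1e-4)
  # invariant to the sign of the slope
  expect_equal(aux_loss(lin_beta(-1e-4), grid), aux_loss(lin_beta(1e-4), grid))
})

test_that("total loss is the lambda-weighted combination of its parts", {
  grid <- make_collocation_grid(1440, 80)
  ts <- seq(0, 1440, by = 360)
  cf <- closed_form_constant(1, 0.2, 0.02, c(2, 20), ts)
  data <- gene_time_series("g", ts, cbind(cf$U + 0.5), cbind(cf$S))
  fm <- closed_form_model(1, 0.2, 0.02, c(2, 20), lambda = c(0, 0))
  expect_equal(total_loss(fm, data, grid), data_loss(fm, data))
  fm$lambda <- c(1.5, 2.5)
  expect_equal(total_loss(fm, data, grid),
               data_loss(fm, data) + 1.5 * ode_loss(fm, grid) +
                 2.5 * aux_loss(fm, grid))
  # all components zero -> zero
  exact <- gene_time_series("g", ts, cbind(cf$U), cbind(cf$S))
  expect_equal(total_loss(fm, exact, grid), 0, tolerance = 1e-10)
})

test_that("collocation grids are well-formed and reproducible", {
  g <- make_collocation_grid(1440, 145)
  expect_equal(diff(g)[1], 10)
  expect_true(all(g >= 0 & g <= 1440))
  j1 <- make_collocation_grid(1440, 50, scheme = "jittered", seed = 5)
  j2 <- make_collocation_grid(1440, 50, scheme = "jittered", seed = 5)
  expect_identical(j1, j2)
  expect_true(all(j1 >= 0 & j1 <= 1440))
  expect_false(identical(j1, make_collocation_grid(1440, 50)))
})

test_that("kinetic-module outputs are strictly positive for random weights", {
  cfg <- network_config(n_data = 9)
  ts <- seq(0, 1440, length.out = 31)
  mins <- vapply(1:1000, function(s) {
    m <- pinn_model(cfg, seed = s)
    p <- predict_pinn(m, ts)
    min(p$alpha, p$beta, p$gamma)
  }, numeric(1))
  expect_true(all(mins > 0))
})

test_that("network time derivatives match central finite differences", {
  cfg <- network_config(n_data = 9)
  m <- pinn_model(cfg, seed = 42)
  set.seed(1)
  ts <- sort(runif(100, 20, 1420))
  h <- 1e-3 * 1440 / 2  # 1e-3 in normalized time units
  p <- predict_pinn(m, ts)
  for (comp in c("U", "S")) {
    dn <- (predict_pinn(m, ts + h)[[comp]] -
             predict_pinn(m, ts - h)[[comp]]) / (2 * h)
    dd <- p[[paste0("d", comp, "_dt")]]
    # relative to the derivative's scale (point-wise relative error is
    # ill-defined where the derivative crosses zero)
    expect_lt(max(abs(dn - dd)) / max(abs(dn)), 1e-4)
  }
  dbn <- (predict_pinn(m, ts + h)$beta - predict_pinn(m, ts - h)$beta) / (2 * h)
  expect_lt(max(abs(dbn - p$dbeta_dt)) / max(abs(dbn)), 1e-4)
})

test_that("the training engine reproduces the reference losses and their gradients", {
  set.seed(3)
  cfg <- network_config(n_data = 5, data_width = 4, kinetic_width = 3,
                        node_factor = 3)
  ts <- seq(0, 1440, length.out = 5)
  gts <- gene_time_series("g", ts, matrix(runif(15), 5, 3),
                          matrix(runif(15), 5, 3))
  st <- rvinn:::engine_static(cfg, gts, scale = c(U = 1, S = 1), rho = 0.08,
                              use_init_anchor = TRUE, use_steady_anchor = TRUE)
  model <- pinn_model(cfg, seed = 11)
  model$rho <- 0.08
  par <- rvinn:::model_flatten(model)
  lam <- c(0.7, 0.3)
  ev <- rvinn:::engine_eval(par, st, lam)
  expect_equal(ev$data, data_loss(model, gts, use_init_anchor = TRUE))
  expect_equal(ev$ode, ode_loss(model, st$grid, use_steady_anchor = TRUE))
  expect_equal(ev$aux, aux_loss(model, st$grid))
  # analytic gradient against numerical differentiation
  h <- 1e-6
  idx <- seq(1, length(par), by = 7)
  ng <- vapply(idx, function(i) {
    p1 <- par; p1[i] <- p1[i] + h
    p2 <- par; p2[i] <- p2[i] - h
    (rvinn:::engine_eval(p1, st, lam, want_grad = FALSE)$total -
       rvinn:::engine_eval(p2, st, lam, want_grad = FALSE)$total) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ng - ev$grad[idx])), 1e-7)
})
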