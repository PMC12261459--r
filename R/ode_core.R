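#' Kinetic trajectory: time-varying rates of the mRNA lifecycle
#'
#' Bundles the three kinetic parameters of the mRNA lifecycle model —
#' transcription rate \eqn{\alpha(t)}, splicing rate \eqn{\beta(t)} and
#' degradation rate \eqn{\gamma(t)} — as vectorized functions of time
#' (minutes) that must return strictly positive, finite values.
#'
#' @param alpha,beta,gamma Vectorized functions `time -> rate`. Rates are in
#'   abundance units per minute (`alpha`) or `1/min` (`beta`, `gamma`).
#' @param horizon Upper end of the time domain in minutes over which the
#'   functions are expected to be valid (default 1440, i.e. 24 h).
#' @return An object of class `kinetic_trajectory`.
#' @examples
#' kin <- kinetic_trajectory(function(t) 2 + 0 * t,
#'                           function(t) rep(0.2, length(t)),
#'                           function(t) rep(0.02, length(t)))
#' kin$alpha(c(0, 720, 1440))
#' @export
kinetic_trajectory <- function(alpha, beta, gamma, horizon = 1440) {
  stopifnot(is.function(alpha), is.function(beta), is.function(gamma),
            is.numeric(horizon), horizon > 0)
  obj <- structure(list(alpha = alpha, beta = beta, gamma = gamma,
                        horizon = horizon),
                   class = "kinetic_trajectory")
  probe <- seq(0, horizon, length.out = 25)
  for (nm in c("alpha", "beta", "gamma")) {
    v <- obj[[nm]](probe)
    if (length(v) != length(probe) || !all(is.finite(v)) || any(v <= 0)) {
      stop(sprintf("kinetic trajectory '%s' must be vectorized, finite and strictly positive on [0, %g]",
                   nm, horizon))
    }
  }
  obj
}

#' Right-hand side of the mRNA lifecycle ODEs
#'
#' The two-state model of the mRNA lifecycle:
#' \deqn{dU/dt = \alpha - \beta U, \qquad dS/dt = \beta U - \gamma S}
#' where `U` is unspliced (pre-)mRNA and `S` is spliced (mature) mRNA
#' abundance.
#'
#' @param state Numeric vector `c(U, S)` (finite).
#' @param rates Numeric vector `c(alpha, beta, gamma)`, all strictly positive.
#' @return Numeric vector `c(dU/dt, dS/dt)`.
#' @examples
#' lifecycle_rhs(c(2, 4), c(2, 1, 0.5))  # steady state -> c(0, 0)
#' @export
lifecycle_rhs <- function(state, rates) {
  if (!all(is.finite(state)) || !all(is.finite(rates))) {
    stop("lifecycle_rhs: non-finite state or rates")
  }
  if (any(rates <= 0)) stop("lifecycle_rhs: rates must be strictly positive")
  u <- state[[1]]; s <- state[[2]]
  c(rates[[1]] - rates[[2]] * u, rates[[2]] * u - rates[[3]] * s)
}

#' Solve the lifecycle ODEs forward in time
#'
#' Numerically integrates the unspliced/spliced system under time-varying
#' kinetics using an adaptive stiff-capable solver (lsoda).
#'
#' @param kinetics A [kinetic_trajectory()].
#' @param y0 Numeric vector `c(U0, S0)`, both finite and non-negative.
#' @param times Strictly increasing numeric grid starting at 0 (minutes).
#' @param rtol,atol Solver tolerances (default `1e-8`).
#' @return A `data.frame` with columns `time`, `U`, `S`
#'   (class `state_trajectory`).
#' @export
solve_forward <- function(kinetics, y0, times, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(kinetics, "kinetic_trajectory"))
  if (!is.numeric(y0) || length(y0) != 2 || !all(is.finite(y0)) || any(y0 < 0)) {
    stop("solve_forward: y0 must be two finite non-negative numbers")
  }
  if (length(times) < 2 || times[[1]] != 0 || any(diff(times) <= 0)) {
    stop("solve_forward: times must be strictly increasing and start at 0")
  }
  deriv <- function(t, y, parms) {
    a <- kinetics$alpha(t); b <- kinetics$beta(t); g <- kinetics$gamma(t)
    list(c(a - b * y[[1]], b * y[[1]] - g * y[[2]]))
  }
  sol <- deSolve::ode(y = c(U = unname(y0[[1]]), S = unname(y0[[2]])),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[[1]] < 0) {
    stop("solve_forward: solver failed to converge (istate = ", istate[[1]], ")")
  }
  if (nrow(sol) < length(times) || !all(is.finite(sol))) {
    stop("solve_forward: solver returned an incomplete or non-finite solution")
  }
  out <- as.data.frame(sol)
  names(out) <- c("time", "U", "S")
  class(out) <- c("state_trajectory", class(out))
  out
}

#' Closed-form solution of the lifecycle ODEs for constant rates
#'
#' Analytic oracle used to validate numerical solutions. For constant
#' \eqn{\alpha,\beta,\gamma > 0}:
#' \deqn{U(t) = \alpha/\beta + (U_0-\alpha/\beta)e^{-\beta t}}
#' \deqn{S(t) = \alpha/\gamma + A e^{-\beta t} + B e^{-\gamma t}}
#' with \eqn{A = \beta(U_0-\alpha/\beta)/(\gamma-\beta)} and
#' \eqn{B = S_0 - \alpha/\gamma - A}. The confluent case \eqn{\beta = \gamma}
#' is handled by its limit form, which contains a \eqn{t e^{-\beta t}} term.
#'
#' @param alpha,beta,gamma Positive scalars.
#' @param y0 Numeric vector `c(U0, S0)`.
#' @param t Numeric vector of times (minutes).
#' @return A list with numeric vectors `U` and `S` evaluated at `t`.
#' @export
closed_form_constant <- function(alpha, beta, gamma, y0, t) {
  stopifnot(alpha > 0, beta > 0, gamma > 0, length(y0) == 2)
  u0 <- y0[[1]]; s0 <- y0[[2]]
  ustar <- alpha / beta
  sstar <- alpha / gamma
  U <- ustar + (u0 - ustar) * exp(-beta * t)
  if (beta == gamma) {
    S <- sstar + (s0 - sstar) * exp(-beta * t) +
      beta * (u0 - ustar) * t * exp(-beta * t)
  } else {
    A <- beta * (u0 - ustar) / (gamma - beta)
    B <- s0 - sstar - A
    S <- sstar + A * exp(-beta * t) + B * exp(-gamma * t)
  }
  list(U = U, S = S)
}

#' Constant-rate kinetic trajectory helper
#'
#' @param alpha,beta,gamma Positive scalars.
#' @param horizon Time horizon in minutes.
#' @return A [kinetic_trajectory()] whose three rates are constant in time.
#' @export
constant_kinetics <- function(alpha, beta, gamma, horizon = 1440) {
  force(alpha); force(beta); force(gamma)
  kinetic_trajectory(function(t) rep(alpha, length(t)),
                     function(t) rep(beta, length(t)),
                     function(t) rep(gamma, length(t)),
                     horizon = horizon)
}

#' Steady state implied by the rates at a given time
#'
#' @param kinetics A [kinetic_trajectory()].
#' @param t Time (minutes) at which to read the rates (default 0).
#' @return Numeric vector `c(U, S)` with `U = alpha/beta`, `S = alpha/gamma`.
#' @export
steady_state <- function(kinetics, t = 0) {
  a <- kinetics$alpha(t)
  c(U = a / kinetics$beta(t), S = a / kinetics$gamma(t))
}
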