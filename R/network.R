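# Minimal tanh multilayer perceptrons with analytic forward-mode time
# derivatives and reverse-mode weight gradients, vectorized over a batch of
# time points. All networks map a scalar (normalized time) to K outputs
# through two tanh hidden layers:
#
#   z1 = t w1' + b1 ; a1 = tanh(z1)
#   z2 = a1 W2 + b2 ; a2 = tanh(z2)
#   y  = a2 W3 + b3
#
# The time derivative dy/dt is propagated forward alongside the values, and
# the backward pass accumulates gradients of any loss that depends on both y
# and dy/dt. This is all the automatic differentiation the model needs; the
# networks are small enough (widths of a few tens) that dense matrix algebra
# in base R is fast.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

mlp_init <- function(width, k_out, seed_rng = NULL) {
  # Xavier-style init; input dimension is 1.
  list(
    w1 = stats::rnorm(width, 0, 1),
    b1 = stats::rnorm(width, 0, 0.5),
    W2 = matrix(stats::rnorm(width * width, 0, sqrt(1 / width)), width, width),
    b2 = rep(0, width),
    W3 = matrix(stats::rnorm(width * k_out, 0, sqrt(1 / width)), width, k_out),
    b3 = rep(0, k_out)
  )
}

# Forward pass over time batch tau (already normalized). Returns values Y
# (n x K), derivatives dY (n x K, w.r.t. tau) and the cache needed by the
# backward pass.
mlp_forward <- function(net, tau) {
  n <- length(tau)
  H <- length(net$w1)
  Z1 <- tcrossprod(tau, net$w1) + rep(net$b1, each = n)
  A1 <- tanh(Z1)
  D1 <- 1 - A1 * A1
  P1 <- matrix(net$w1, n, H, byrow = TRUE)
  dA1 <- D1 * P1
  Z2 <- A1 %*% net$W2 + rep(net$b2, each = n)
  A2 <- tanh(Z2)
  D2 <- 1 - A2 * A2
  dZ2 <- dA1 %*% net$W2
  dA2 <- D2 * dZ2
  Y <- A2 %*% net$W3 + rep(net$b3, each = n)
  dY <- dA2 %*% net$W3
  list(Y = Y, dY = dY,
       tau = tau, A1 = A1, D1 = D1, P1 = P1, dA1 = dA1,
       A2 = A2, D2 = D2, dZ2 = dZ2, dA2 = dA2)
}

# Reverse pass: GY = dL/dY, GdY = dL/d(dY/dtau), both n x K (either may be
# NULL). Returns gradient with the same shapes as the net.
mlp_backward <- function(net, fw, GY, GdY) {
  n <- length(fw$tau)
  K <- ncol(net$W3)
  H <- length(net$w1)
  if (is.null(GY)) GY <- matrix(0, n, K)
  if (is.null(GdY)) GdY <- matrix(0, n, K)

  gW3 <- crossprod(fw$A2, GY) + crossprod(fw$dA2, GdY)
  gb3 <- colSums(GY)
  GA2 <- tcrossprod(GY, net$W3)
  GdA2 <- tcrossprod(GdY, net$W3)

  # dA2 = D2 * dZ2 with D2 = 1 - A2^2
  GdZ2 <- GdA2 * fw$D2
  GA2 <- GA2 + GdA2 * fw$dZ2 * (-2 * fw$A2)

  GZ2 <- GA2 * fw$D2
  gW2 <- crossprod(fw$A1, GZ2) + crossprod(fw$dA1, GdZ2)
  gb2 <- colSums(GZ2)
  GA1 <- tcrossprod(GZ2, net$W2)
  GdA1 <- tcrossprod(GdZ2, net$W2)

  # dA1 = D1 * P1 with D1 = 1 - A1^2, P1 = w1 broadcast
  g_w1 <- colSums(GdA1 * fw$D1)
  GA1 <- GA1 + GdA1 * fw$P1 * (-2 * fw$A1)

  GZ1 <- GA1 * fw$D1
  g_w1 <- g_w1 + colSums(GZ1 * fw$tau)
  g_b1 <- colSums(GZ1)

  list(w1 = g_w1, b1 = g_b1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

# --- parameter flattening -------------------------------------------------

net_flatten <- function(net) {
  c(net$w1, net$b1, as.numeric(net$W2), net$b2, as.numeric(net$W3), net$b3)
}

net_unflatten <- function(par, width, k_out) {
  i <- 0
  take <- function(n) {
    out <- par[(i + 1):(i + n)]
    i <<- i + n
    out
  }
  list(
    w1 = take(width),
    b1 = take(width),
    W2 = matrix(take(width * width), width, width),
    b2 = take(width),
    W3 = matrix(take(width * k_out), width, k_out),
    b3 = take(k_out)
  )
}

net_npar <- function(width, k_out) {
  2 * width + width * width + width + width * k_out + k_out
}

# --- rate output transform ------------------------------------------------

# Strictly positive mapping: rate = r_min + scale * softplus(raw). `scale` is
# chosen so that raw = 0 (the initialization regime) maps to a configurable
# mid-range rate, centring the prior on field-scale kinetics.
rate_transform <- function(raw, r_min, scale) {
  r_min + scale * softplus(raw)
}

# d(rate)/d(raw) = scale * sigmoid(raw)
rate_transform_dr <- function(raw, scale) {
  scale * stats::plogis(raw)
}
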