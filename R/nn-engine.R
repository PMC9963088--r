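# Minimal 1D convolutional network engine.
#
# All activations are dense matrices of shape (N*L) x C: windows stacked
# sample-major (time index fastest within a window), channels as columns.
# The convolution/transposed-convolution kernels and the fused
# batchnorm+leaky-ReLU training path live in src/conv1d.cpp (im2col + BLAS
# gemm); pooling and zero-stuffing reduce to odd/even row selection because
# window lengths are always even, so row parity never crosses a window
# boundary.
#
# Weight layout for a k-tap convolution Cin -> Cout: matrix (k*Cin) x Cout,
# rows ordered tap-major (all input channels of tap 1, then tap 2, ...).

conv1d_fwd <- function(X, L, N, W, b) {
  conv1d_fwd_cpp(X, as.integer(L), as.integer(N), W, b)
}

conv1d_bwd <- function(dY, X, L, N, W) {
  conv1d_bwd_cpp(dY, X, as.integer(L), as.integer(N), W)
}

# transposed convolution, stride 2: zero-stuff then convolve (output 2L)
convt1d_fwd <- function(X, L, N, W, b) {
  convt1d_fwd_cpp(X, as.integer(L), as.integer(N), W, b)
}

convt1d_bwd <- function(dY, X, L, N, W) {
  convt1d_bwd_cpp(dY, X, as.integer(L), as.integer(N), W)
}

maxpool2_fwd <- function(X) {
  odd <- seq(1L, nrow(X), by = 2L)
  Xo <- X[odd, , drop = FALSE]
  Xe <- X[odd + 1L, , drop = FALSE]
  take <- Xo >= Xe # ties route to the earlier sample
  list(Y = Xo * take + Xe * !take, take = take)
}

maxpool2_bwd <- function(dY, take) {
  dX <- matrix(0, 2L * nrow(dY), ncol(dY))
  odd <- seq(1L, nrow(dX), by = 2L)
  dX[odd, ] <- dY * take
  dX[odd + 1L, ] <- dY * !take
  dX
}

# inference-mode batch normalisation (running statistics)
bn_eval <- function(X, gamma, beta, state, eps = 1e-3) {
  n <- nrow(X)
  inv_sd <- 1 / sqrt(state$run_var + eps)
  xhat <- (X - rep(state$run_mean, each = n)) * rep(inv_sd, each = n)
  xhat * rep(gamma, each = n) + rep(beta, each = n)
}

leaky_fwd <- function(X, slope = 0.25) {
  X * ((X > 0) + slope * (X <= 0))
}

leaky_bwd <- function(dY, X, slope = 0.25) {
  dY * ((X > 0) + slope * (X <= 0))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.9

# --- parameter initialisation ----------------------------------------------

xavier_uniform <- function(k, cin, cout) {
  fan_in <- k * cin
  fan_out <- k * cout
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(k * cin * cout, -limit, limit), k * cin, cout)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, opt, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}
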