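#' Configuration of the 1D segmentation U-Net
#'
#' The encoder applies six same-padded 1D convolutions with kernel sizes
#' 9, 9, 6, 6, 3, 3 and 16, 16, 32, 32, 64, 64 filters; each of the last five
#' is followed by batch normalisation and factor-2 max pooling, so the input
#' length shrinks by 2^5 at the bottleneck. The decoder mirrors the encoder
#' with five stride-2 transposed convolutions (kernels 3, 3, 6, 6, 9; filters
#' 64, 32, 32, 16, 16), each batch-normalised, with the matching encoder
#' feature map concatenated after every upsampling stage. A dropout of 0.25
#' acts on the first decoder convolution, all convolutions use leaky ReLU
#' activations (negative slope 0.25) except the final single-filter kernel-9
#' convolution, which applies a sigmoid to yield a per-sample R-peak
#' probability. With the defaults the network has exactly 79,409 trainable
#' parameters.
#'
#' @param input_length window length in samples; must be divisible by 32.
#' @param in_channels number of input channels (3 for the X, Y, Z
#'   vectorcardiogram axes; 1-8 supported for lead-subset experiments).
#' @param dropout_rate dropout rate on the first decoder convolution.
#' @param leaky_slope negative slope of the leaky ReLU activations.
#' @return An object of class `unet_config`.
#' @export
#' @examples
#' cfg <- unet_config()
#' cfg$input_length
unet_config <- function(input_length = 2048L, in_channels = 3L,
                        dropout_rate = 0.25, leaky_slope = 0.25) {
  input_length <- as.integer(input_length)
  in_channels <- as.integer(in_channels)
  if (input_length %% 32L != 0L || input_length < 32L) {
    vcg_abort("`input_length` must be a positive multiple of 32 (five pooling stages)",
              "vcg_bad_config")
  }
  if (in_channels < 1L || in_channels > 8L) {
    vcg_abort("`in_channels` must be between 1 and 8", "vcg_bad_config")
  }
  structure(
    list(
      input_length = input_length,
      in_channels = in_channels,
      dropout_rate = dropout_rate,
      leaky_slope = leaky_slope
    ),
    class = "unet_config"
  )
}

# Declarative layer schedule shared by build / forward / backward.
unet_arch <- function(config) {
  c0 <- config$in_channels
  list(
    enc = list(
      list(id = "enc1", k = 9L, cin = c0,  cout = 16L, bn = FALSE, pool = FALSE),
      list(id = "enc2", k = 9L, cin = 16L, cout = 16L, bn = TRUE,  pool = TRUE),
      list(id = "enc3", k = 6L, cin = 16L, cout = 32L, bn = TRUE,  pool = TRUE),
      list(id = "enc4", k = 6L, cin = 32L, cout = 32L, bn = TRUE,  pool = TRUE),
      list(id = "enc5", k = 3L, cin = 32L, cout = 64L, bn = TRUE,  pool = TRUE),
      list(id = "enc6", k = 3L, cin = 64L, cout = 64L, bn = TRUE,  pool = TRUE)
    ),
    # skip = index of the cached encoder tensor concatenated after upsampling:
    # dec1 gets the pooled enc5 output, ..., dec5 gets the enc1 output.
    dec = list(
      list(id = "dec1", k = 3L, cin = 64L,  cout = 64L, skip_ch = 64L, dropout = TRUE),
      list(id = "dec2", k = 3L, cin = 128L, cout = 32L, skip_ch = 32L, dropout = FALSE),
      list(id = "dec3", k = 6L, cin = 64L,  cout = 32L, skip_ch = 32L, dropout = FALSE),
      list(id = "dec4", k = 6L, cin = 64L,  cout = 16L, skip_ch = 16L, dropout = FALSE),
      list(id = "dec5", k = 9L, cin = 32L,  cout = 16L, skip_ch = 16L, dropout = FALSE)
    ),
    out = list(id = "out", k = 9L, cin = 32L, cout = 1L)
  )
}

#' Build the 1D segmentation U-Net
#'
#' Weights are drawn from the Xavier (Glorot) uniform distribution; biases
#' start at zero, batch-normalisation scales at one and shifts at zero.
#'
#' @param config a [unet_config()].
#' @param seed optional integer seed for weight initialisation.
#' @return An object of class `unet_model`.
#' @export
#' @examples
#' model <- build_unet(unet_config(), seed = 1)
#' count_parameters(model)
build_unet <- function(config = unet_config(), seed = NULL) {
  if (!inherits(config, "unet_config")) {
    vcg_abort("`config` must be a unet_config", "vcg_bad_config")
  }
  if (!is.null(seed)) set.seed(seed)
  arch <- unet_arch(config)
  params <- list()
  state <- list()
  add_conv <- function(l) {
    params[[paste0(l$id, "_W")]] <<- xavier_uniform(l$k, l$cin, l$cout)
    params[[paste0(l$id, "_b")]] <<- numeric(l$cout)
    if (isTRUE(l$bn) || grepl("^dec", l$id)) {
      params[[paste0(l$id, "_gamma")]] <<- rep(1, l$cout)
      params[[paste0(l$id, "_beta")]] <<- numeric(l$cout)
      state[[l$id]] <<- list(run_mean = numeric(l$cout),
                             run_var = rep(1, l$cout))
    }
  }
  for (l in arch$enc) add_conv(l)
  for (l in arch$dec) add_conv(l)
  params[["out_W"]] <- xavier_uniform(arch$out$k, arch$out$cin, arch$out$cout)
  # final bias starts at the logit of the expected label density (~2%: five
  # positive samples per beat period), the usual initialisation for heavily
  # imbalanced segmentation so early steps need not learn the class prior
  params[["out_b"]] <- -4
  structure(
    list(config = config, params = params, state = state, trained = FALSE),
    class = "unet_model"
  )
}

#' Count trainable parameters
#'
#' Counts convolution kernels and biases plus batch-normalisation scale and
#' shift parameters; batch-normalisation running statistics are not trained
#' and are excluded.
#'
#' @param model a `unet_model`.
#' @return Integer parameter count (79,409 for the default configuration).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model: input %d x %d, %s parameters%s>\n",
    x$config$input_length, x$config$in_channels,
    format(count_parameters(x), big.mark = ","),
    if (isTRUE(x$trained)) ", trained" else ", untrained"
  ))
  invisible(x)
}

# Forward pass over a stacked batch X ((N*L) x C). Returns probabilities and,
# when training, the caches needed for back-propagation.
unet_forward <- function(model, X, N, training = FALSE,
                         bn_momentum = BN_MOMENTUM) {
  config <- model$config
  arch <- unet_arch(config)
  p <- model$params
  slope <- config$leaky_slope
  L <- config$input_length
  cache <- list()
  skips <- list()
  cur <- X
  for (l in arch$enc) {
    z <- conv1d_fwd(cur, L, N, p[[paste0(l$id, "_W")]], p[[paste0(l$id, "_b")]])
    cc <- list(x_in = cur, L = L)
    if (l$bn) {
      gamma <- p[[paste0(l$id, "_gamma")]]
      beta <- p[[paste0(l$id, "_beta")]]
      if (training) {
        f <- bn_leaky_fwd_cpp(z, gamma, beta, slope, BN_EPS)
        st <- model$state[[l$id]]
        st$run_mean <- bn_momentum * st$run_mean + (1 - bn_momentum) * f$mu
        st$run_var <- bn_momentum * st$run_var + (1 - bn_momentum) * f$var
        model$state[[l$id]] <- st
        a <- f$Y
        cc$xhat <- f$xhat
        cc$var <- f$var
      } else {
        a <- leaky_fwd(bn_eval(z, gamma, beta, model$state[[l$id]]), slope)
      }
    } else {
      a <- leaky_fwd(z, slope)
      cc$pre_act <- z
    }
    if (l$pool) {
      mp <- maxpool2_fwd(a)
      cc$take <- mp$take
      cur <- mp$Y
      L <- L %/% 2L
    } else {
      cur <- a
    }
    if (!training) cc <- list()
    cache[[l$id]] <- cc
    skips[[l$id]] <- cur # post-pool feature (enc1: post-activation)
  }
  skip_src <- c("enc5", "enc4", "enc3", "enc2", "enc1")
  for (i in seq_along(arch$dec)) {
    l <- arch$dec[[i]]
    cc <- list(x_in = cur, L_in = L)
    z <- convt1d_fwd(cur, L, N, p[[paste0(l$id, "_W")]], p[[paste0(l$id, "_b")]])
    L <- L * 2L
    gamma <- p[[paste0(l$id, "_gamma")]]
    beta <- p[[paste0(l$id, "_beta")]]
    if (training) {
      f <- bn_leaky_fwd_cpp(z, gamma, beta, slope, BN_EPS)
      st <- model$state[[l$id]]
      st$run_mean <- bn_momentum * st$run_mean + (1 - bn_momentum) * f$mu
      st$run_var <- bn_momentum * st$run_var + (1 - bn_momentum) * f$var
      model$state[[l$id]] <- st
      a <- f$Y
      cc$xhat <- f$xhat
      cc$var <- f$var
    } else {
      a <- leaky_fwd(bn_eval(z, gamma, beta, model$state[[l$id]]), slope)
    }
    if (l$dropout && training && config$dropout_rate > 0) {
      keep <- 1 - config$dropout_rate
      mask <- matrix(rbinom(length(a), 1L, keep), nrow(a)) / keep
      a <- a * mask
      cc$drop_mask <- mask
    }
    cur <- cbind(a, skips[[skip_src[i]]])
    cc$own_ch <- l$cout
    if (!training) cc <- list()
    cache[[l$id]] <- cc
  }
  z <- conv1d_fwd(cur, L, N, p$out_W, p$out_b)
  prob <- sigmoid(z)
  if (training) {
    cache$out <- list(x_in = cur, L = L)
    list(prob = prob, cache = cache, model = model)
  } else {
    list(prob = prob)
  }
}

# Back-propagation from d(loss)/d(pre-sigmoid logits).
unet_backward <- function(model, cache, dlogit, N) {
  config <- model$config
  arch <- unet_arch(config)
  p <- model$params
  slope <- config$leaky_slope
  grads <- list()

  cc <- cache$out
  g <- conv1d_bwd(dlogit, cc$x_in, cc$L, N, p$out_W)
  grads$out_W <- g$dW
  grads$out_b <- g$db
  dcur <- g$dX

  skip_src <- c("enc5", "enc4", "enc3", "enc2", "enc1")
  dskip <- list() # gradients flowing into encoder features via skips
  for (i in rev(seq_along(arch$dec))) {
    l <- arch$dec[[i]]
    cc <- cache[[l$id]]
    own <- seq_len(cc$own_ch)
    da <- dcur[, own, drop = FALSE]
    dsk <- dcur[, -own, drop = FALSE]
    src <- skip_src[i]
    dskip[[src]] <- if (is.null(dskip[[src]])) dsk else dskip[[src]] + dsk
    if (!is.null(cc$drop_mask)) da <- da * cc$drop_mask
    bg <- bn_leaky_bwd_cpp(da, cc$xhat, p[[paste0(l$id, "_gamma")]],
                           cc$var, slope, BN_EPS,
                           p[[paste0(l$id, "_beta")]])
    grads[[paste0(l$id, "_gamma")]] <- bg$dgamma
    grads[[paste0(l$id, "_beta")]] <- bg$dbeta
    g <- convt1d_bwd(bg$dX, cc$x_in, cc$L_in, N, p[[paste0(l$id, "_W")]])
    grads[[paste0(l$id, "_W")]] <- g$dW
    grads[[paste0(l$id, "_b")]] <- g$db
    dcur <- g$dX
  }

  for (l in rev(arch$enc)) {
    cc <- cache[[l$id]]
    if (!is.null(dskip[[l$id]])) dcur <- dcur + dskip[[l$id]]
    if (l$pool) {
      da <- maxpool2_bwd(dcur, cc$take)
    } else {
      da <- dcur
    }
    if (l$bn) {
      bg <- bn_leaky_bwd_cpp(da, cc$xhat, p[[paste0(l$id, "_gamma")]],
                             cc$var, slope, BN_EPS,
                             p[[paste0(l$id, "_beta")]])
      grads[[paste0(l$id, "_gamma")]] <- bg$dgamma
      grads[[paste0(l$id, "_beta")]] <- bg$dbeta
      dz <- bg$dX
    } else {
      dz <- leaky_bwd(da, cc$pre_act, slope)
    }
    g <- conv1d_bwd(dz, cc$x_in, cc$L, N, p[[paste0(l$id, "_W")]])
    grads[[paste0(l$id, "_W")]] <- g$dW
    grads[[paste0(l$id, "_b")]] <- g$db
    dcur <- g$dX
  }
  grads
}

#' Per-sample R-peak probabilities for one or more windows
#'
#' Runs the network in evaluation mode (dropout off, batch normalisation using
#' its running statistics), so repeated calls on the same input are
#' bit-identical and independent of batch composition.
#'
#' @param model a `unet_model`.
#' @param window a single `input_length x in_channels` matrix, or a list of
#'   such matrices.
#' @return A numeric vector of probabilities in `[0, 1]` (or a list of such
#'   vectors when `window` is a list).
#' @export
predict_window <- function(model, window) {
  stopifnot(inherits(model, "unet_model"))
  single <- !is.list(window)
  wins <- if (single) list(window) else window
  L <- model$config$input_length
  C <- model$config$in_channels
  for (w in wins) {
    if (!is.matrix(w) || nrow(w) != L || ncol(w) != C) {
      vcg_abort(sprintf("window must be a %d x %d matrix", L, C),
                "vcg_bad_window")
    }
  }
  out <- vector("list", length(wins))
  chunk <- 64L
  i <- 1L
  while (i <= length(wins)) {
    idx <- i:min(i + chunk - 1L, length(wins))
    X <- do.call(rbind, wins[idx])
    prob <- unet_forward(model, X, length(idx), training = FALSE)$prob
    for (j in seq_along(idx)) {
      out[[idx[j]]] <- as.numeric(prob[((j - 1L) * L + 1L):(j * L), 1L])
    }
    i <- i + chunk
  }
  if (single) out[[1L]] else out
}
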