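# Layer primitives for the lightweight 1-D residual network.
#
# Activations are arrays laid out (channels, length, batch); weights for the
# standard convolution are (C_out, C_in * k), column blocks ordered by tap.
# All convolutions use stride 1 and "same" padding. The hot paths (standard
# and depthwise convolution, forward and backward) run in compiled code
# (src/kernels.cpp); the *_ref functions below are the plain-R reference
# implementations kept as an independent oracle for the compiled kernels.

pad_split <- function(k) {
  pl <- (k - 1L) %/% 2L
  c(pl, k - 1L - pl)
}

im2col <- function(x, k) {
  d <- dim(x)
  pl <- pad_split(k)[1]
  xp <- array(0, c(d[1], d[2] + k - 1L, d[3]))
  xp[, pl + seq_len(d[2]), ] <- x
  Xc <- matrix(0, d[1] * k, d[2] * d[3])
  for (j in seq_len(k)) {
    Xc[((j - 1L) * d[1] + 1L):(j * d[1]), ] <-
      matrix(xp[, j:(j + d[2] - 1L), , drop = FALSE], d[1], d[2] * d[3])
  }
  Xc
}

col2im <- function(dXc, k, d) {
  pl <- pad_split(k)[1]
  dxp <- array(0, c(d[1], d[2] + k - 1L, d[3]))
  for (j in seq_len(k)) {
    dxp[, j:(j + d[2] - 1L), ] <- dxp[, j:(j + d[2] - 1L), , drop = FALSE] +
      array(dXc[((j - 1L) * d[1] + 1L):(j * d[1]), ], c(d[1], d[2], d[3]))
  }
  dxp[, pl + seq_len(d[2]), , drop = FALSE]
}

conv1d_fwd_ref <- function(x, W, b, k) {
  d <- dim(x)
  Xc <- im2col(x, k)
  y <- W %*% Xc + b
  list(y = array(y, c(nrow(W), d[2], d[3])),
       cache = list(Xc = Xc, W = W, k = k, d = d))
}

conv1d_bwd_ref <- function(dy, cache) {
  d <- cache$d
  dY <- matrix(dy, nrow(cache$W), d[2] * d[3])
  dW <- dY %*% t(cache$Xc)
  db <- rowSums(dY)
  dXc <- t(cache$W) %*% dY
  dx <- col2im(dXc, cache$k, d)
  list(dx = dx, dW = dW, db = db)
}

dwconv_fwd_ref <- function(x, Wd, k) {
  d <- dim(x)
  pl <- pad_split(k)[1]
  xp <- array(0, c(d[1], d[2] + k - 1L, d[3]))
  xp[, pl + seq_len(d[2]), ] <- x
  y <- array(0, d)
  for (j in seq_len(k)) {
    y <- y + Wd[, j] * xp[, j:(j + d[2] - 1L), , drop = FALSE]
  }
  list(y = y, cache = list(xp = xp, Wd = Wd, k = k, d = d))
}

dwconv_bwd_ref <- function(dy, cache) {
  d <- cache$d
  k <- cache$k
  pl <- pad_split(k)[1]
  dWd <- matrix(0, d[1], k)
  dxp <- array(0, dim(cache$xp))
  for (j in seq_len(k)) {
    xs <- cache$xp[, j:(j + d[2] - 1L), , drop = FALSE]
    dWd[, j] <- rowSums(dy * xs, dims = 1)
    dxp[, j:(j + d[2] - 1L), ] <- dxp[, j:(j + d[2] - 1L), , drop = FALSE] +
      cache$Wd[, j] * dy
  }
  list(dx = dxp[, pl + seq_len(d[2]), , drop = FALSE], dWd = dWd)
}


# compiled wrappers: cache the input (im2col is rebuilt in C++)
conv1d_fwd <- function(x, W, b, k) {
  list(y = .conv1d_fwd_cpp(x, W, as.numeric(b), k),
       cache = list(x = x, W = W, k = k))
}

conv1d_bwd <- function(dy, cache) {
  r <- .conv1d_bwd_cpp(cache$x, cache$W, dy, cache$k)
  r$db <- as.numeric(r$db)
  r
}

dwconv_fwd <- function(x, Wd, k) {
  list(y = .dwconv_fwd_cpp(x, Wd, k),
       cache = list(x = x, Wd = Wd, k = k))
}

dwconv_bwd <- function(dy, cache) {
  .dwconv_bwd_cpp(cache$x, cache$Wd, dy, cache$k)
}

bn_fwd <- function(x, gamma, beta, state, training, eps = 1e-5,
                   momentum = 0.9) {
  if (training) {
    r <- .bn_train_fwd_cpp(x, gamma, beta, eps)
    state$mean <- momentum * state$mean + (1 - momentum) * as.numeric(r$mu)
    state$var <- momentum * state$var + (1 - momentum) * as.numeric(r$var)
    list(y = r$y, state = state,
         cache = list(xhat = r$xhat, istd = as.numeric(r$istd),
                      gamma = gamma))
  } else {
    istd <- 1 / sqrt(state$var + eps)
    xhat <- (x - state$mean) * istd
    list(y = gamma * xhat + beta, state = state,
         cache = list(xhat = xhat, istd = istd, gamma = gamma))
  }
}

# backward in terms of xhat only (biased batch variance):
# dx = gamma*istd * (dy - mean(dy) - xhat * mean(dy*xhat)), per channel
bn_bwd <- function(dy, cache) {
  r <- .bn_bwd_cpp(dy, cache$xhat, cache$gamma, cache$istd)
  r$dgamma <- as.numeric(r$dgamma)
  r$dbeta <- as.numeric(r$dbeta)
  r
}

relu_fwd <- function(x) {
  y <- .relu_fwd_cpp(x)
  list(y = y, cache = y)
}

relu_bwd <- function(dy, y) .relu_bwd_cpp(dy, y)

# Modified residual layer: conv -> BN -> ReLU -> separable conv
# (depthwise + pointwise) -> BN -> add shortcut (1x1 projection when the
# channel count changes) -> ReLU.
resnet_fwd <- function(x, p, s, training) {
  c1 <- conv1d_fwd(x, p$conv$W, p$conv$b, p$k)
  b1 <- bn_fwd(c1$y, p$bn1$gamma, p$bn1$beta, s$bn1, training)
  r1 <- relu_fwd(b1$y)
  dw <- dwconv_fwd(r1$y, p$dw$W, p$k)
  pw <- conv1d_fwd(dw$y, p$pw$W, p$pw$b, 1L)
  b2 <- bn_fwd(pw$y, p$bn2$gamma, p$bn2$beta, s$bn2, training)
  if (!is.null(p$proj)) {
    pr <- conv1d_fwd(x, p$proj$W, p$proj$b, 1L)
    shortcut <- pr$y
    pr_cache <- pr$cache
  } else {
    shortcut <- x
    pr_cache <- NULL
  }
  final_relu <- is.null(p$final_relu) || isTRUE(p$final_relu)
  y2 <- if (final_relu) .add_relu_fwd_cpp(b2$y, shortcut)
        else b2$y + shortcut
  list(y = y2,
       state = list(bn1 = b1$state, bn2 = b2$state),
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    dw = dw$cache, pw = pw$cache, b2 = b2$cache,
                    pr = pr_cache, r2 = y2, has_proj = !is.null(p$proj),
                    final_relu = final_relu))
}

resnet_bwd <- function(dy, cache) {
  dsum <- if (cache$final_relu) relu_bwd(dy, cache$r2) else dy
  g <- list()
  b2 <- bn_bwd(dsum, cache$b2)
  g$bn2 <- list(gamma = b2$dgamma, beta = b2$dbeta)
  pw <- conv1d_bwd(b2$dx, cache$pw)
  g$pw <- list(W = pw$dW, b = pw$db)
  dw <- dwconv_bwd(pw$dx, cache$dw)
  g$dw <- list(W = dw$dWd)
  dr1 <- relu_bwd(dw$dx, cache$r1)
  b1 <- bn_bwd(dr1, cache$b1)
  g$bn1 <- list(gamma = b1$dgamma, beta = b1$dbeta)
  c1 <- conv1d_bwd(b1$dx, cache$c1)
  g$conv <- list(W = c1$dW, b = c1$db)
  dx <- c1$dx
  if (cache$has_proj) {
    pr <- conv1d_bwd(dsum, cache$pr)
    g$proj <- list(W = pr$dW, b = pr$db)
    dx <- dx + pr$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = g)
}

resnet_init <- function(c_in, c_out, k, rng_sd = 0.1) {
  he <- function(fan_in) sqrt(2 / fan_in)
  p <- list(
    k = k,
    conv = list(W = matrix(stats::rnorm(c_out * c_in * k,
                                        sd = he(c_in * k)), c_out),
                b = numeric(c_out)),
    bn1 = list(gamma = rep(1, c_out), beta = numeric(c_out)),
    dw = list(W = matrix(stats::rnorm(c_out * k, sd = he(k)), c_out)),
    pw = list(W = matrix(stats::rnorm(c_out * c_out, sd = he(c_out)), c_out),
              b = numeric(c_out)),
    bn2 = list(gamma = rep(1, c_out), beta = numeric(c_out))
  )
  if (c_in != c_out) {
    p$proj <- list(W = matrix(stats::rnorm(c_out * c_in, sd = he(c_in)),
                              c_out),
                   b = numeric(c_out))
  }
  p
}

resnet_state_init <- function(c_out) {
  list(bn1 = list(mean = numeric(c_out), var = rep(1, c_out)),
       bn2 = list(mean = numeric(c_out), var = rep(1, c_out)))
}

resnet_n_params <- function(c_in, c_out, k) {
  trainable <- (k * c_in * c_out + c_out) + 2 * c_out +
    (k * c_out) + (c_out * c_out + c_out) + 2 * c_out +
    if (c_in != c_out) c_in * c_out + c_out else 0
  list(trainable = trainable, non_trainable = 4 * c_out)
}
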