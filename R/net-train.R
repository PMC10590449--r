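# Training harness: combined loss (MSE on the pulse waveform,
# cross-entropy on the pseudo-spectrum), backpropagation through both
# blocks, and the Adam optimizer. All randomness (initialization, epoch
# shuffling) is seeded, so two runs with the same seed produce identical
# loss curves.

tree_zeros <- function(g) {
  if (is.list(g)) lapply(g, tree_zeros) else g * 0
}

adam_update <- function(p, g, m, v, lr, beta1, beta2, eps, t) {
  if (is.list(g)) {
    for (nm in names(g)) {
      upd <- adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                         lr, beta1, beta2, eps, t)
      p[[nm]] <- upd$p; m[[nm]] <- upd$m; v[[nm]] <- upd$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

stack_batch <- function(dataset, idx, L, n_grid) {
  B <- length(idx)
  nb <- nrow(dataset[[idx[1]]]$x)
  x <- array(0, c(nb, L, B))
  y_wave <- matrix(0, L, B)
  y_spec <- matrix(0, n_grid, B)
  for (j in seq_along(idx)) {
    s <- dataset[[idx[j]]]
    x[, , j] <- s$x
    y_wave[, j] <- s$waveform
    y_spec[, j] <- s$spectrum
  }
  list(x = x, y_wave = y_wave, y_spec = y_spec)
}

#' Train the pulse/pseudo-spectrum network
#'
#' Minimizes `mse(pulse, waveform label) + lambda * crossentropy(spectrum,
#' spectrum label)` with Adam. Micro-motion inputs are normalized with
#' [normalize_micromotions()] before entering the network, matching
#' inference. Separate models are trained per application window length
#' (sleep: 900 samples; meditation: 240).
#'
#' @param model A `pulse_net` from [build_network()].
#' @param dataset Non-empty list of samples, each a list with `x`
#'   (16 x L micro-motion matrix), `waveform` (length-L pulse label) and
#'   `spectrum` (length-189 normalized spectrum label), e.g. from
#'   [make_training_corpus()].
#' @param epochs,batch_size,lr Adam schedule; `lr` may be a single rate
#'   or a vector of per-epoch rates (e.g. a cosine-decay schedule).
#' @param lambda Weight of the spectrum cross-entropy term.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param seed Seed for epoch shuffling.
#' @param verbose Print the loss once per `verbose` epochs (0 = silent).
#' @return List with the trained `model` and `history` (data frame of
#'   per-epoch mean training losses: total, mse, ce).
#' @export
train_network <- function(model, dataset, epochs = 60L, batch_size = 16L,
                          lr = 1e-3, lambda = 1, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-8, seed = 1L, verbose = 0L) {
  if (length(dataset) == 0) stop("dataset is empty")
  sp <- model$spec
  for (s in dataset) {
    if (ncol(s$x) != sp$L || length(s$waveform) != sp$L ||
        length(s$spectrum) != sp$n_grid)
      stop("label/input length mismatch with the model specification")
  }
  dataset <- lapply(dataset, function(s) {
    s$x <- normalize_micromotions(s$x)
    s
  })
  n <- length(dataset)
  opt_m <- NULL
  opt_v <- NULL
  t_step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        mse = numeric(0), ce = numeric(0))
  lr_sched <- if (length(lr) == 1) rep(lr, epochs)
              else stats::approx(seq_along(lr), lr,
                                 xout = seq(1, length(lr),
                                            length.out = epochs))$y
  orders <- with_seed(seed,
    lapply(seq_len(epochs), function(e) sample.int(n)))
  for (e in seq_len(epochs)) {
    lr_e <- lr_sched[e]
    ord <- orders[[e]]
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- ep_mse <- ep_ce <- 0
    for (idx in batches) {
      bt <- stack_batch(dataset, idx, sp$L, sp$n_grid)
      B <- length(idx)
      fw <- net_forward(model, bt$x, training = TRUE)
      model$state <- fw$state
      resid <- fw$pulse - bt$y_wave
      mse <- mean(resid^2)
      ce <- -mean(colSums(bt$y_spec * fw$logprobs))
      dpulse <- 2 * resid / (sp$L * B)
      dlogits <- lambda * (sweep(fw$probs, 2, colSums(bt$y_spec), `*`) -
                             bt$y_spec) / B
      grads <- net_backward(model, fw$cache, dpulse, dlogits)
      if (is.null(opt_m)) {
        opt_m <- tree_zeros(grads)
        opt_v <- tree_zeros(grads)
      }
      t_step <- t_step + 1L
      upd <- adam_update(model$params, grads, opt_m, opt_v,
                         lr_e, beta1, beta2, eps, t_step)
      model$params <- upd$p
      opt_m <- upd$m
      opt_v <- upd$v
      w <- B / n
      ep_loss <- ep_loss + (mse + lambda * ce) * w
      ep_mse <- ep_mse + mse * w
      ep_ce <- ep_ce + ce * w
    }
    history <- rbind(history, data.frame(epoch = e, loss = ep_loss,
                                         mse = ep_mse, ce = ep_ce))
    if (verbose > 0 && e %% verbose == 0)
      message(sprintf("epoch %3d  loss %.5f (mse %.5f, ce %.5f)",
                      e, ep_loss, ep_mse, ep_ce))
  }
  list(model = model, history = history)
}
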