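# Network assembly and inference for the lightweight pulse / pseudo-spectrum
# estimator. Block 1 maps the 16 micro-motion waveforms (shared-weight
# residual branches + summation) to a single pulse waveform; block 2 maps
# the pulse through a residual layer, a parameter-free multi-scale FFT bank
# (1 full, 2 half, 4 quarter segments, all zero-padded to 1024 and cropped
# to the 35-200 bpm band), two residual layers and a softmax to a
# normalized 189-bin pseudo-spectrum.

fft_pad_to <- 1024L
fft_crop <- 40:228  # 1-based indices of the 0-based bins 39..227

split_segments <- function(L, parts) {
  bounds <- floor(seq(0, L, length.out = parts + 1))
  lapply(seq_len(parts), function(i) (bounds[i] + 1):bounds[i + 1])
}

segment_plan <- function(L) {
  c(split_segments(L, 1), split_segments(L, 2), split_segments(L, 4))
}

#' Multi-scale magnitude spectra of a pulse waveform
#'
#' Splits the waveform into 1, 2 and 4 equal segments (7 branches: full,
#' half 1-2, quarter 1-4, in that fixed order), zero-pads each segment to
#' 1024 points, takes the FFT magnitude, and crops each spectrum to the
#' 189 bins of the 35-200 bpm band (see [hr_grid()]). Segment-wise spectra
#' make the heart tone recoverable from partial windows when body motion
#' corrupts the rest, which is what makes the head robust to
#' non-stationary interference.
#'
#' @param pulse Numeric waveform of length L <= 1024.
#' @return 7 x 189 matrix of magnitude spectra (concatenated length 1323).
#' @export
multiscale_spectrum <- function(pulse) {
  L <- length(pulse)
  if (L > fft_pad_to) stop("waveform longer than the 1024-point FFT")
  segs <- segment_plan(L)
  out <- matrix(0, length(segs), length(fft_crop))
  for (i in seq_along(segs)) {
    z <- stats::fft(c(pulse[segs[[i]]],
                      numeric(fft_pad_to - length(segs[[i]]))))
    out[i, ] <- abs(z)[fft_crop]
  }
  out
}

fftbank_fwd <- function(h) {
  d <- dim(h)  # (1, L, B)
  segs <- segment_plan(d[2])
  nb <- length(segs)
  y <- array(0, c(nb, length(fft_crop), d[3]))
  zs <- array(0i, c(fft_pad_to, nb, d[3]))
  for (b in seq_len(d[3])) {
    for (i in seq_len(nb)) {
      z <- stats::fft(c(h[1, segs[[i]], b],
                        numeric(fft_pad_to - length(segs[[i]]))))
      zs[, i, b] <- z
      y[i, , b] <- abs(z)[fft_crop]
    }
  }
  list(y = y, cache = list(zs = zs, segs = segs, d = d))
}

fftbank_bwd <- function(dy, cache) {
  d <- cache$d
  segs <- cache$segs
  dh <- array(0, d)
  for (b in seq_len(d[3])) {
    for (i in seq_along(segs)) {
      zc <- cache$zs[fft_crop, i, b]
      m <- abs(zc)
      u <- complex(fft_pad_to)
      u[fft_crop] <- ifelse(m > 0, dy[i, , b] * Conj(zc) / m, 0i)
      g <- Re(stats::fft(u))[seq_along(segs[[i]])]
      dh[1, segs[[i]], b] <- dh[1, segs[[i]], b] + g
    }
  }
  dh
}

#' Build the lightweight pulse/pseudo-spectrum network
#'
#' Constructs the two-block residual network for input windows of L
#' samples (16 micro-motion waveforms at 15 Hz; L = 900 for 60 s sleep
#' windows, L = 240 for 16 s meditation windows; any L <= 1024 works).
#' All layers are convolutional, so the parameter count is independent of
#' L. Default widths and kernels: 24 filters in block 1 (kernel 3), output
#' convolution kernel 11, head residual layers with kernels 19 / 9 / 5 and
#' 10 filters on the concatenated spectra.
#'
#' @param L Input window length in samples (<= 1024).
#' @param n_branch Number of micro-motion input waveforms (16).
#' @param filters Block-1 channel width.
#' @param k1 Kernel of the four block-1 residual layers.
#' @param k_out Kernel of the pulse output convolution.
#' @param k5 Kernel of the pre-FFT head residual layer.
#' @param k6,k7 Kernels of the two post-FFT residual layers.
#' @param head_filters Channel width of the first post-FFT residual layer.
#' @param seed Seed for weight initialization.
#' @return A `pulse_net` model object.
#' @export
build_network <- function(L, n_branch = 16L, filters = 24L, k1 = 3L,
                          k_out = 11L, k5 = 19L, k6 = 9L, k7 = 5L,
                          head_filters = 10L, seed = 1L) {
  if (L > fft_pad_to)
    stop("input length exceeds the 1024-point zero-padding convention")
  if (L < 8) stop("input window too short")
  Fc <- as.integer(filters)
  H <- as.integer(head_filters)
  params <- with_seed(seed, list(
    b1 = resnet_init(1L, Fc, k1),
    b2 = resnet_init(Fc, Fc, k1),
    b3 = resnet_init(Fc, Fc, k1),
    trunk = resnet_init(Fc, Fc, k1),
    out = list(W = matrix(stats::rnorm(Fc * k_out, sd = sqrt(2 / (Fc * k_out))),
                          1L),
               b = 0, k = as.integer(k_out)),
    h1 = resnet_init(1L, 1L, k5),
    h2 = resnet_init(7L, H, k6),
    h3 = resnet_init(H, 1L, k7)
  ))
  # the logits layer feeds the softmax with its pre-activation sum: a
  # one-sided clamp there can saturate the head at a uniform fixed point
  # with zero gradient (dying-ReLU trap), so its output ReLU is disabled
  params$h3$final_relu <- FALSE
  state <- list(b1 = resnet_state_init(Fc), b2 = resnet_state_init(Fc),
                b3 = resnet_state_init(Fc), trunk = resnet_state_init(Fc),
                h1 = resnet_state_init(1L), h2 = resnet_state_init(H),
                h3 = resnet_state_init(1L))
  structure(list(
    spec = list(L = as.integer(L), n_branch = as.integer(n_branch),
                filters = Fc, k1 = as.integer(k1), k_out = as.integer(k_out),
                k5 = as.integer(k5), k6 = as.integer(k6), k7 = as.integer(k7),
                head_filters = H, n_grid = length(fft_crop)),
    params = params, state = state),
    class = "pulse_net")
}

count_leaves <- function(x) {
  if (is.list(x)) sum(vapply(x, count_leaves, numeric(1))) else length(x)
}

#' Parameter counts of a network
#'
#' @param model A `pulse_net`.
#' @return List with `total`, `trainable` (weights, biases, batch-norm
#'   scales/shifts) and `non_trainable` (batch-norm moving statistics).
#' @export
count_parameters <- function(model) {
  drop_meta <- function(p) {
    if (is.list(p))
      lapply(p[setdiff(names(p), c("k", "final_relu"))], drop_meta)
    else p
  }
  trainable <- count_leaves(drop_meta(model$params))
  non_trainable <- count_leaves(model$state)
  list(total = trainable + non_trainable, trainable = trainable,
       non_trainable = non_trainable)
}

branch_sum_fwd <- function(y, n_branch) {
  d <- dim(y)
  B <- d[3] %/% n_branch
  y4 <- array(y, c(d[1], d[2], n_branch, B))
  s <- array(0, c(d[1], d[2], B))
  for (i in seq_len(n_branch))
    s <- s + array(y4[, , i, ], c(d[1], d[2], B))
  s
}

net_forward <- function(model, x, training = FALSE) {
  sp <- model$spec
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (d[1] != sp$n_branch || d[2] != sp$L)
    stop("input must be ", sp$n_branch, " x ", sp$L)
  B <- d[3]
  p <- model$params
  s <- model$state
  cache <- list(B = B)
  # block 1: shared-weight branches as an enlarged batch
  xb <- array(aperm(x, c(2, 1, 3)), c(1L, sp$L, sp$n_branch * B))
  f1 <- resnet_fwd(xb, p$b1, s$b1, training); s$b1 <- f1$state
  f2 <- resnet_fwd(f1$y, p$b2, s$b2, training); s$b2 <- f2$state
  f3 <- resnet_fwd(f2$y, p$b3, s$b3, training); s$b3 <- f3$state
  summed <- branch_sum_fwd(f3$y, sp$n_branch)
  ft <- resnet_fwd(summed, p$trunk, s$trunk, training); s$trunk <- ft$state
  oc <- conv1d_fwd(ft$y, p$out$W, p$out$b, p$out$k)
  pulse <- oc$y  # (1, L, B)
  # block 2
  h1 <- resnet_fwd(pulse, p$h1, s$h1, training); s$h1 <- h1$state
  fb <- fftbank_fwd(h1$y)
  h2 <- resnet_fwd(fb$y, p$h2, s$h2, training); s$h2 <- h2$state
  h3 <- resnet_fwd(h2$y, p$h3, s$h3, training); s$h3 <- h3$state
  logits <- matrix(h3$y, sp$n_grid, B)
  lm <- apply(logits, 2, max)
  shifted <- sweep(logits, 2, lm)
  el <- exp(shifted)
  logprobs <- sweep(shifted, 2, log(colSums(el)))  # stable log-softmax
  probs <- exp(logprobs)
  cache <- c(cache, list(f1 = f1$cache, f2 = f2$cache, f3 = f3$cache,
                         trunk = ft$cache, out = oc$cache, h1 = h1$cache,
                         fb = fb$cache, h2 = h2$cache, h3 = h3$cache))
  list(pulse = matrix(pulse, sp$L, B), probs = probs,
       logprobs = logprobs, cache = cache, state = s)
}

net_backward <- function(model, cache, dpulse, dlogits) {
  sp <- model$spec
  B <- cache$B
  grads <- list()
  dh3 <- array(dlogits, c(1L, sp$n_grid, B))
  b3 <- resnet_bwd(dh3, cache$h3); grads$h3 <- b3$grads
  b2 <- resnet_bwd(b3$dx, cache$h2); grads$h2 <- b2$grads
  dfb <- fftbank_bwd(b2$dx, cache$fb)
  b1h <- resnet_bwd(dfb, cache$h1); grads$h1 <- b1h$grads
  dpulse_total <- b1h$dx + array(dpulse, c(1L, sp$L, B))
  oc <- conv1d_bwd(dpulse_total, cache$out)
  grads$out <- list(W = oc$dW, b = oc$db)
  bt <- resnet_bwd(oc$dx, cache$trunk); grads$trunk <- bt$grads
  # broadcast the summed gradient back to every branch
  dsum <- bt$dx
  dbranch <- array(0, c(sp$filters, sp$L, sp$n_branch * B))
  d4 <- array(dbranch, c(sp$filters, sp$L, sp$n_branch, B))
  for (i in seq_len(sp$n_branch)) d4[, , i, ] <- dsum
  dbranch <- array(d4, c(sp$filters, sp$L, sp$n_branch * B))
  g3 <- resnet_bwd(dbranch, cache$f3); grads$b3 <- g3$grads
  g2 <- resnet_bwd(g3$dx, cache$f2); grads$b2 <- g2$grads
  g1 <- resnet_bwd(g2$dx, cache$f1); grads$b1 <- g1$grads
  grads
}

#' @export
print.pulse_net <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf(
    "<pulse_net> L=%d, %d branches, %d filters; %d parameters (%d trainable)\n",
    x$spec$L, x$spec$n_branch, x$spec$filters, pc$total, pc$trainable))
  invisible(x)
}

#' Heart rate and confidence from a pseudo-spectrum
#'
#' The heart rate is the frequency of the global peak of the normalized
#' pseudo-spectrum; the confidence is the ratio of that peak's amplitude
#' to the amplitude of the second-highest local peak (capped when the
#' spectrum is unimodal). Two equal peaks give confidence 1 (ambiguous); a
#' flat spectrum is flagged undetermined.
#'
#' @param spectrum Non-negative vector over the heart-rate grid.
#' @param grid Frequency grid in bpm (default [hr_grid()]).
#' @param cap Confidence value assigned to unimodal spectra.
#' @return List with `hr` (bpm), `confidence` and `determined`.
#' @export
hr_from_pseudospectrum <- function(spectrum, grid = hr_grid(), cap = 100) {
  if (length(spectrum) != length(grid))
    stop("spectrum length must match the grid")
  if (max(spectrum) - min(spectrum) <= .Machine$double.eps * max(1, max(spectrum)))
    return(list(hr = NA_real_, confidence = NA_real_, determined = FALSE))
  i_peak <- which.max(spectrum)
  n <- length(spectrum)
  s <- spectrum
  is_local <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) s[i] > s[i - 1] else s[i] > s[i + 1]
    right <- if (i < n) s[i] >= s[i + 1] else s[i] >= s[i - 1]
    left && right
  }, logical(1))
  cand <- setdiff(which(is_local), i_peak)
  # drop shoulder bins belonging to the main peak
  cand <- cand[abs(cand - i_peak) > 1]
  conf <- if (length(cand) == 0) cap else {
    second <- max(s[cand])
    if (second <= 0) cap else min(cap, s[i_peak] / second)
  }
  list(hr = grid[i_peak], confidence = conf, determined = TRUE)
}

#' Run the network on one micro-motion window
#'
#' Normalizes the 16 waveforms (zero mean, unit maximum absolute value),
#' runs a deterministic inference-mode forward pass, and reads the heart
#' rate and confidence off the pseudo-spectrum peak.
#'
#' @param micromotions A `micromotion_set` (or a 16 x L matrix).
#' @param model A trained `pulse_net` with matching input length.
#' @return A `pulse_estimate`: `pulse` (length L), `pseudo_spectrum`
#'   (length 189, sums to 1), `hr` (bpm), `confidence`, `determined`.
#' @export
infer_pulse <- function(micromotions, model) {
  d <- if (inherits(micromotions, "micromotion_set")) micromotions$d
       else micromotions
  if (ncol(d) != model$spec$L)
    stop("micromotion length ", ncol(d), " does not match model input ",
         model$spec$L)
  x <- normalize_micromotions(d)
  fw <- net_forward(model, x, training = FALSE)
  spec <- fw$probs[, 1]
  peak <- hr_from_pseudospectrum(spec)
  structure(list(pulse = fw$pulse[, 1], pseudo_spectrum = spec,
                 hr = peak$hr, confidence = peak$confidence,
                 determined = peak$determined),
            class = "pulse_estimate")
}

#' @export
print.pulse_estimate <- function(x, ...) {
  if (x$determined)
    cat(sprintf("<pulse_estimate> hr=%.1f bpm (confidence %.2f)\n",
                x$hr, x$confidence))
  else cat("<pulse_estimate> undetermined\n")
  invisible(x)
}

#' Save / load a network
#'
#' `save_network()` writes the model to an RDS checkpoint and a
#' framework-neutral JSON description of the layer shapes alongside it;
#' `load_network()` restores the checkpoint.
#'
#' @param model A `pulse_net`.
#' @param path Checkpoint path (`.rds`).
#' @return `load_network()` returns the model; `save_network()` the path,
#'   invisibly.
#' @export
save_network <- function(model, path) {
  saveRDS(model, path)
  shapes <- rapply(model$params, function(x) dim(x) %||% length(x),
                   how = "list")
  jsonlite::write_json(list(spec = model$spec, shapes = shapes),
                       sub("\\.rds$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_network
#' @export
load_network <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "pulse_net"))
  model
}
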