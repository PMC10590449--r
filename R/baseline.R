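#' Band-pass-filter benchmark heart-rate estimator
#'
#' The conventional alternative to the learned estimator: each of the 16
#' micro-motion waveforms is band-pass filtered to 40--200 bpm
#' (zero-phase 4th-order Butterworth), its zero-padded magnitude spectrum
#' is computed on the common 35--200 bpm grid, and the candidate with the
#' highest peak-to-average ratio (PAR) wins. The estimate is undetermined
#' when the best PAR falls below the decision threshold.
#'
#' This estimator has a well-known failure mode that motivates the learned
#' approach: respiration harmonics falling inside the pass band routinely
#' out-power the weak heart tone.
#'
#' @param micromotions A `micromotion_set` or 16 x L matrix (metres).
#' @param sample_rate Hz (15 unless a set is supplied).
#' @param band Pass band in bpm.
#' @param order Butterworth order.
#' @param par_threshold Minimum PAR for a determined estimate.
#' @return List with `hr` (bpm or NA), `confidence` (the best PAR),
#'   `determined`, `best_bin` (waveform index).
#' @export
bpf_estimate_hr <- function(micromotions, sample_rate = 15,
                            band = c(40, 200), order = 4,
                            par_threshold = 3) {
  d <- if (inherits(micromotions, "micromotion_set")) {
    sample_rate <- micromotions$sample_rate
    micromotions$d
  } else micromotions
  if (all(d == 0))
    return(list(hr = NA_real_, confidence = NA_real_, determined = FALSE,
                best_bin = NA_integer_))
  wn <- band / 60 / (sample_rate / 2)
  bf <- signal::butter(order, wn, type = "pass")
  grid <- hr_grid()
  best <- list(par = -Inf, hr = NA_real_, bin = NA_integer_)
  for (k in seq_len(nrow(d))) {
    x <- d[k, ] - mean(d[k, ])
    if (all(x == 0)) next
    xf <- signal::filtfilt(bf, x)
    sp <- abs(stats::fft(c(xf, numeric(1024 - length(xf)))))[fft_crop]
    if (all(sp == 0)) next
    par <- max(sp) / mean(sp)
    if (par > best$par)
      best <- list(par = par, hr = grid[which.max(sp)], bin = k)
  }
  if (!is.finite(best$par) || best$par < par_threshold)
    return(list(hr = NA_real_, confidence = best$par, determined = FALSE,
                best_bin = best$bin))
  list(hr = best$hr, confidence = best$par, determined = TRUE,
       best_bin = best$bin)
}
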