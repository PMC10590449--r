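#' Remove static clutter from range profiles
#'
#' Subtracts the temporal mean profile (per range bin, per receiver) from
#' every chirp, cancelling stationary background reflections and
#' transmit/receive leakage. Afterwards each bin's temporal mean is zero to
#' numerical precision.
#'
#' @param profiles A `range_profile_series`.
#' @return A `range_profile_series` with the mean profile removed.
#' @export
clutter_filter <- function(profiles) {
  stopifnot(inherits(profiles, "range_profile_series"))
  p <- profiles$profiles
  if (dim(p)[1] < 2) stop("need at least 2 chirps for clutter filtering")
  mean_profile <- apply(p, c(2, 3), mean)
  out <- sweep(p, c(2, 3), mean_profile, `-`)
  profiles$profiles <- out
  profiles
}

#' Cell-averaging CFAR threshold factor
#'
#' Closed-form scaling for a cell-averaging CFAR with `n_train` training
#' cells on exponentially distributed (single-look complex-Gaussian) power:
#' alpha = M * (Pfa^(-1/M) - 1).
#' @param n_train Total number of training cells M.
#' @param pfa Design false-alarm probability per cell.
#' @return Threshold multiplier alpha.
#' @export
cfar_threshold_factor <- function(n_train, pfa) {
  n_train * (pfa^(-1 / n_train) - 1)
}

#' Cell-averaging CFAR detector on a power profile
#'
#' For each cell the noise level is estimated as the mean of `train`
#' training cells on each side, separated by `guard` guard cells; a cell is
#' detected if its power exceeds alpha times that estimate. Training
#' windows are clipped at the profile edges (one-sided where necessary).
#'
#' @param power Non-negative power profile (vector over range bins).
#' @param pfa Design per-cell false-alarm probability.
#' @param train Training cells per side.
#' @param guard Guard cells per side.
#' @return Logical vector of detections.
#' @export
cfar_detect <- function(power, pfa = 1e-3, train = 8L, guard = 2L) {
  n <- length(power)
  det <- logical(n)
  for (i in seq_len(n)) {
    lo <- seq(i - guard - train, i - guard - 1)
    hi <- seq(i + guard + 1, i + guard + train)
    cells <- power[c(lo[lo >= 1], hi[hi <= n])]
    if (length(cells) == 0) next
    alpha <- cfar_threshold_factor(length(cells), pfa)
    det[i] <- power[i] > alpha * mean(cells)
  }
  det
}

#' Detect a user in clutter-filtered range profiles
#'
#' Forms the power range profile by summing |.|^2 over receivers and
#' averaging over the analysis window, then runs the CA-CFAR detector.
#' The user's bin is the detected bin with maximal power.
#'
#' @param profiles Clutter-filtered `range_profile_series`.
#' @param pfa,train,guard CFAR parameters, see [cfar_detect()].
#' @param min_bin Lowest bin considered (bins below carry residual
#'   leakage at very short range); 0-based.
#' @return List with `present`, `range_bin` (0-based), `distance` (m) and
#'   the `power` profile.
#' @export
detect_user <- function(profiles, pfa = 1e-3, train = 8L, guard = 2L,
                        min_bin = 3L) {
  stopifnot(inherits(profiles, "range_profile_series"))
  p <- profiles$profiles
  power <- apply(abs(p)^2, 2, sum) / dim(p)[1]  # sum rx, mean over time
  if (all(power == 0))
    return(list(present = FALSE, range_bin = NA_integer_,
                distance = NA_real_, power = power))
  det <- cfar_detect(power, pfa = pfa, train = train, guard = guard)
  det[seq_len(min(min_bin, length(det)))] <- FALSE
  if (!any(det))
    return(list(present = FALSE, range_bin = NA_integer_,
                distance = NA_real_, power = power))
  bin0 <- which(det)[which.max(power[det])] - 1L  # 0-based
  list(present = TRUE, range_bin = bin0,
       distance = bin0 * profiles$bin_size, power = power)
}

#' Assess user stillness from the peak-bin Doppler spectrum
#'
#' Takes the detected bin's clutter-filtered signal and computes, in
#' overlapping short sub-windows (Hann-tapered Doppler FFTs, summed over
#' receivers), the ratio of low-Doppler energy (|f| <= f_low, DC
#' excluded) to high-Doppler energy (|f| > f_low). The stillness
#' statistic is the minimum ratio over sub-windows: a still user must be
#' still throughout, while a transient body-motion event collapses the
#' ratio in the sub-windows it touches even when the rest of the window
#' is quiet. Vital-sign micro-motion keeps Doppler energy low; gross
#' motion (jerky, with strong echo modulation from the moving body)
#' spreads it high.
#'
#' @param profiles Clutter-filtered `range_profile_series`.
#' @param range_bin Detected user bin (0-based).
#' @param f_low Doppler split frequency in Hz.
#' @param threshold Stillness decision threshold on the minimum ratio.
#' @param subwin_s Sub-window length in seconds (hop = half a window).
#' @return List with `still` and `stillness_ratio` (the minimum ratio).
#' @export
assess_stillness <- function(profiles, range_bin, f_low = 3,
                             threshold = 2, subwin_s = 4) {
  stopifnot(inherits(profiles, "range_profile_series"))
  sig <- profiles$profiles[, range_bin + 1L, , drop = FALSE]
  L <- dim(sig)[1]
  if (all(abs(sig) == 0)) stop("zero signal at the detected bin")
  fs <- profiles$sample_rate
  sub <- min(L, as.integer(round(subwin_s * fs)))
  hop <- max(1L, sub %/% 2L)
  w <- signal::hanning(sub)
  freq <- (seq_len(sub) - 1) / sub * fs
  freq[freq > fs / 2] <- freq[freq > fs / 2] - fs
  low_band <- abs(freq) <= f_low & freq != 0
  high_band <- abs(freq) > f_low
  starts <- seq(1L, L - sub + 1L, by = hop)
  ratios <- vapply(starts, function(s) {
    low_e <- 0
    high_e <- 0
    for (i in seq_len(dim(sig)[3])) {
      sp <- abs(stats::fft(sig[s:(s + sub - 1L), 1, i] * w))^2
      low_e <- low_e + sum(sp[low_band])
      high_e <- high_e + sum(sp[high_band])
    }
    if (high_e > 0) low_e / high_e else Inf
  }, numeric(1))
  ratio <- min(ratios)
  list(still = ratio >= threshold, stillness_ratio = ratio)
}

#' Presence, distance and stillness in one call
#'
#' Runs [clutter_filter()], [detect_user()] and [assess_stillness()] and
#' returns the gate that downstream heart-rate blocks honour: micro-motion
#' extraction and rate estimation only run when a present, still user is
#' found.
#'
#' @param profiles A `range_profile_series` (raw; clutter is filtered
#'   internally).
#' @param config Optional list overriding `cfar.pfa`, `cfar.train`,
#'   `cfar.guard`, `stillness.f_low`, `stillness.threshold`.
#' @return A `presence_result` list: `present`, `still`, `range_bin`,
#'   `distance`, `stillness_ratio`, plus the filtered profiles.
#' @export
presence_detect <- function(profiles, config = list()) {
  cfg <- utils::modifyList(list(
    cfar.pfa = 1e-3, cfar.train = 8L, cfar.guard = 2L,
    stillness.f_low = 3, stillness.threshold = 2,
    stillness.subwin_s = 4), config)
  filt <- clutter_filter(profiles)
  det <- detect_user(filt, pfa = cfg$cfar.pfa, train = cfg$cfar.train,
                     guard = cfg$cfar.guard)
  res <- list(present = det$present, still = FALSE,
              range_bin = det$range_bin, distance = det$distance,
              stillness_ratio = NA_real_, filtered = filt)
  if (det$present) {
    st <- assess_stillness(filt, det$range_bin,
                           f_low = cfg$stillness.f_low,
                           threshold = cfg$stillness.threshold,
                           subwin_s = cfg$stillness.subwin_s)
    res$still <- st$still
    res$stillness_ratio <- st$stillness_ratio
  }
  class(res) <- "presence_result"
  res
}

#' @export
print.presence_result <- function(x, ...) {
  cat(sprintf("<presence_result> present=%s still=%s", x$present, x$still))
  if (x$present)
    cat(sprintf(" bin=%d (%.2f m) ratio=%.1f",
                x$range_bin, x$distance, x$stillness_ratio))
  cat("\n")
  invisible(x)
}
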