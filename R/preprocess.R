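#' Average chirps within bursts and decimate to 15 Hz
#'
#' The 20 chirps of each burst are averaged, then adjacent bursts
#' (pairs (1,2), (3,4), ...) are averaged, decimating the burst rate from
#' 30 to 15 Hz and improving SNR by the factor of samples combined. A
#' trailing unpaired burst is dropped.
#'
#' @param cube A `radar_cube` (see [synthesize_cube()]).
#' @return List with `data` (matrix stack [decimated chirp, fast-time
#'   sample, rx]), `t` (timestamps, s) and `config`.
#' @export
average_and_decimate <- function(cube) {
  stopifnot(inherits(cube, "radar_cube"))
  d <- dim(cube$adc)
  if (d[1] < 2) stop("need at least 2 bursts to decimate")
  radar <- cube$config
  # mean over chirps (dim 2); colMeans over the permuted array is C-speed
  per_burst <- colMeans(aperm(cube$adc, c(2, 1, 3, 4)))
  n_out <- d[1] %/% 2
  idx_a <- 2 * seq_len(n_out) - 1
  out <- (per_burst[idx_a, , , drop = FALSE] +
          per_burst[idx_a + 1, , , drop = FALSE]) / 2
  list(data = out, t = decimated_times(radar, n_out, cube$t0),
       config = radar)
}

#' Range FFT of the decimated chirp series
#'
#' Applies an FFT along fast time (the samples within a chirp), turning
#' each real-valued chirp into a complex range profile. Real input makes
#' the negative-frequency half redundant, so the one-sided spectrum
#' (samples_per_chirp/2 + 1 bins) is kept. Range bins are 0-based:
#' distance = bin * bin_size.
#'
#' @param averaged Output of [average_and_decimate()].
#' @param window `"rectangular"` (default) or `"hann"` fast-time taper.
#' @return A `range_profile_series`: complex array `profiles`
#'   [chirp l, range bin, rx], `sample_rate` (Hz), `bin_size` (m), `t`.
#' @export
range_fft <- function(averaged, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  x <- averaged$data
  d <- dim(x)
  radar <- averaged$config
  if (d[2] != radar$samples_per_chirp)
    stop("fast-time length does not match samples_per_chirp")
  n_bins <- d[2] %/% 2 + 1
  if (window == "hann") {
    w <- signal::hanning(d[2])
    x <- sweep(x, 2, w, `*`)
  }
  profiles <- array(0i, dim = c(d[1], n_bins, d[3]))
  for (i in seq_len(d[3])) {
    sp <- t(stats::mvfft(t(x[, , i])))
    profiles[, , i] <- sp[, seq_len(n_bins)]
  }
  structure(list(profiles = profiles,
                 sample_rate = radar$burst_rate / 2,
                 bin_size = radar$bin_size,
                 t = averaged$t,
                 config = radar),
            class = "range_profile_series")
}

#' Full preprocessing: cube to 15 Hz complex range profiles
#'
#' @param cube A `radar_cube`.
#' @param window Fast-time taper, see [range_fft()].
#' @return A `range_profile_series`.
#' @export
preprocess_cube <- function(cube, window = "rectangular") {
  range_fft(average_and_decimate(cube), window = window)
}

#' @export
print.range_profile_series <- function(x, ...) {
  d <- dim(x$profiles)
  cat(sprintf(
    "<range_profile_series> %d chirps @ %g Hz, %d range bins (%.3f m), %d rx\n",
    d[1], x$sample_rate, d[2], x$bin_size, d[3]))
  invisible(x)
}
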