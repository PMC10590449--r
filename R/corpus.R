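#' Synthetic micro-motion training corpus
#'
#' Generates labelled windows for network training without running the
#' full radar chain per window: each window draws a heart rate, a
#' respiration rate/pattern and an SNR, evaluates the chest-displacement
#' model on the 15 Hz grid, and distributes it over 16 range bins with a
#' smooth cross-bin gain envelope (the torso echo straddles a few bins)
#' plus independent per-bin displacement noise set by the SNR. Labels come
#' from [make_reference_labels()] on the same beat times.
#'
#' Defaults emulate the meditation-style study conditions: heart rate
#' uniform in 45--115 bpm, respiration 6--30 breaths/min with regular,
#' deep and rapid patterns, millimetre breathing amplitude over a 0.2 mm
#' heartbeat pulse train, SNR swept over 5--25 dB.
#'
#' @param n Number of windows.
#' @param L Window length in samples at 15 Hz (240 = 16 s meditation
#'   windows, 900 = 60 s sleep windows).
#' @param hr_range,resp_range,snr_range Uniform sampling ranges (bpm,
#'   breaths/min, dB).
#' @param motion_fraction Fraction of windows containing a body-motion
#'   ramp (trains rejection of non-stationary interference).
#' @param sample_rate Hz (15).
#' @param seed Integer seed; the corpus is reproducible.
#' @return List of samples, each with `x` (16 x L), `waveform` (L),
#'   `spectrum` (189), `hr` (window-mean bpm) and `scene`.
#' @export
make_training_corpus <- function(n, L = 240L, hr_range = c(45, 115),
                                 resp_range = c(6, 30),
                                 snr_range = c(5, 25),
                                 motion_fraction = 0.15,
                                 sample_rate = 15, seed = 1L) {
  t_grid <- (seq_len(L) - 1) / sample_rate
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      hr <- stats::runif(1, hr_range[1], hr_range[2])
      pattern <- sample(c("regular", "deep", "rapid"), 1,
                        prob = c(0.6, 0.2, 0.2))
      scene <- scene_config(
        respiration = list(rate = stats::runif(1, resp_range[1],
                                               resp_range[2]),
                           amplitude = stats::runif(1, 2e-3, 6e-3),
                           pattern = pattern,
                           shape_power = sample(1:3, 1)),
        heart = list(hr_trace = hr,
                     pulse_amplitude = stats::runif(1, 1e-4, 4e-4),
                     pulse_width = 0.08),
        motion_events = if (stats::runif(1) < motion_fraction) {
          list(list(start = stats::runif(1, 0, max(t_grid) * 0.7),
                    duration = stats::runif(1, 0.5, 2),
                    displacement = stats::runif(1, 2e-3, 8e-3)))
        } else list(),
        snr_db = stats::runif(1, snr_range[1], snr_range[2]),
        seed = i)
      disp <- chest_displacement(scene, t_grid)
      if (length(disp$beat_times) < 2) stop("window too short for beats")
      # cross-bin gain envelope centred between bins 7..10
      centre <- stats::runif(1, 7, 10)
      width <- stats::runif(1, 1.0, 2.5)
      gains <- exp(-((1:16) - centre)^2 / (2 * width^2))
      # a couple of bins catch limb/torso echoes with respiration only
      resp_gains <- 0.3 * gains * stats::rbinom(16, 1, 0.3)
      # displacement-domain noise calibrated against the radar chain:
      # burst averaging + MRC + circle fit leave residuals of ~0.2-9 % of
      # the displacement spread at the subject bin (higher off-peak), only
      # weakly dependent on echo SNR; the echo SNR scales this mildly
      sigma_frac <- (0.02 + 0.1 * (1 - gains)) *
        10^(-(scene$snr_db - 15) / 20)
      x <- matrix(0, 16, L)
      for (k in 1:16) {
        x[k, ] <- gains[k] * disp$total +
          resp_gains[k] * disp$respiration +
          stats::rnorm(L, sd = stats::sd(disp$total) * sigma_frac[k] *
                         stats::runif(1, 0.7, 1.3))
      }
      lab <- make_reference_labels(disp$beat_times, t_grid)
      list(x = x, waveform = lab$waveform, spectrum = lab$spectrum,
           hr = lab$mean_hr, scene = scene)
    })
  })
}
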