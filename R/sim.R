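#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

speed_of_light <- 299792458

#' Heartbeat times implied by a heart-rate trace
#'
#' Integrates the instantaneous heart rate to a beat phase and places one
#' beat at every integer phase crossing, so a time-varying trace (e.g. a
#' post-exercise decay) yields correctly drifting beat intervals.
#'
#' @param hr_trace Scalar bpm, or `list(t =, bpm =)` breakpoints
#'   (linearly interpolated).
#' @param t_end End of the interval (s); beats are generated on [0, t_end].
#' @param phase0 Initial beat phase in cycles (0 puts the first beat at
#'   the first integer crossing).
#' @return Numeric vector of beat times in seconds.
#' @export
beat_times_from_trace <- function(hr_trace, t_end, phase0 = 0.5) {
  tt <- seq(0, t_end, by = 1 / 240)
  rate <- if (is.list(hr_trace)) {
    stats::approx(hr_trace$t, hr_trace$bpm, xout = tt, rule = 2)$y
  } else rep(hr_trace, length(tt))
  phase <- phase0 +
    c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 / 60 * diff(tt)))
  n_beats <- floor(phase[length(phase)])
  if (n_beats < 1) return(numeric(0))
  stats::approx(phase, tt, xout = seq_len(n_beats))$y
}

#' Chest-wall displacement of a synthetic scene
#'
#' Evaluates the radial chest displacement a radar would observe:
#' respiration (a sinusoid raised to an even power, so that realistic
#' harmonics appear), a Gaussian-pulse heartbeat train, and smooth
#' body-motion ramps. The components are returned individually so they can
#' serve as exact ground truth.
#'
#' Patterns: `"regular"` uses the configured rate/amplitude; `"deep"`
#' multiplies the amplitude by 2.5; `"rapid"` forces the rate to at least
#' 25 breaths per minute.
#'
#' @param scene A [scene_config()].
#' @param t Strictly increasing time grid in seconds.
#' @return List with `total`, `respiration`, `heart`, `motion` (all metres,
#'   same length as `t`) and `beat_times` (s).
#' @export
chest_displacement <- function(scene, t) {
  stopifnot(inherits(scene, "scene_config"))
  if (length(t) > 1 && any(diff(t) <= 0)) stop("t must be strictly increasing")
  resp <- scene$respiration
  rate <- resp$rate
  amp <- resp$amplitude
  if (resp$pattern == "deep") amp <- amp * 2.5
  if (resp$pattern == "rapid") rate <- max(rate, 25)
  m <- as.integer(resp$shape_power)
  if (m < 1) stop("shape_power must be a positive integer")
  f_r <- rate / 60
  # 2*sin(pi f t)^(2m) - 1: fundamental at f_r, even-power harmonics for m > 1,
  # exact sinusoid of amplitude `amp` for m = 1; peak-to-peak 2*amp.
  d_resp <- amp * (2 * sin(pi * f_r * t)^(2 * m) - 1)

  beats <- beat_times_from_trace(scene$heart$hr_trace, max(t))
  sigma <- scene$heart$pulse_width / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  d_heart <- numeric(length(t))
  for (tk in beats) {
    idx <- which(abs(t - tk) < 5 * sigma)
    d_heart[idx] <- d_heart[idx] +
      scene$heart$pulse_amplitude * exp(-(t[idx] - tk)^2 / (2 * sigma^2))
  }

  d_motion <- numeric(length(t))
  for (j in seq_along(scene$motion_events)) {
    ev <- scene$motion_events[[j]]
    tau <- (t - ev$start) / ev$duration
    ramp <- ifelse(tau <= 0, 0, ifelse(tau >= 1, 1, (1 - cos(pi * tau)) / 2))
    d_motion <- d_motion + ev$displacement * ramp
    # body motion is jerky, not a clean glide: band-limited jitter rides on
    # the ramp while the event lasts (deterministic given the scene seed)
    jitter_rms <- ev$jitter_rms %||%
      min(8e-3, max(2e-3, 0.15 * abs(ev$displacement)))
    if (jitter_rms > 0) {
      band <- ev$jitter_band %||% c(2, 6)
      n_comp <- 24L
      pars <- with_seed(scene$seed + 1000L * j, list(
        f = stats::runif(n_comp, band[1], band[2]),
        ph = stats::runif(n_comp, 0, 2 * pi)))
      jit <- numeric(length(t))
      for (kk in seq_len(n_comp)) {
        jit <- jit + sin(2 * pi * pars$f[kk] * t + pars$ph[kk])
      }
      jit <- jit * jitter_rms * sqrt(2 / n_comp)
      active <- tau > 0 & tau < 1
      # fade the jitter in and out with the ramp's raised-cosine window
      weight <- ifelse(active, sin(pi * pmin(pmax(tau, 0), 1))^2, 0)
      d_motion <- d_motion + jit * weight
    }
  }

  list(total = d_resp + d_heart + d_motion,
       respiration = d_resp, heart = d_heart, motion = d_motion,
       beat_times = beats)
}

#' Timestamps of the decimated (15 Hz) chirp series
#'
#' Each output chirp is the average of all chirps in two adjacent bursts;
#' its timestamp is the mean of the averaged chirps' start times.
#' @keywords internal
decimated_times <- function(radar, n_out, t0 = 0) {
  chirp_offsets <- (seq_len(radar$chirps_per_burst) - 1) / radar$chirp_rate
  mean_off <- mean(chirp_offsets)
  burst_pairs <- (seq_len(n_out) - 1) * 2
  t0 + (burst_pairs + 0.5) / radar$burst_rate + mean_off
}

#' The 35-200 bpm pseudo-spectrum frequency grid
#'
#' All spectra in the pipeline are zero-padded to 1024 points at the 15 Hz
#' decimated rate, giving a granularity of 15*60/1024 = 0.879 bpm/bin; the
#' band of interest keeps bins 39..227 (0-based), the 189 bins falling in
#' 35--200 bpm (the last grid bin at or below each band edge is included).
#'
#' @return Numeric vector of 189 frequencies in bpm.
#' @export
hr_grid <- function() {
  (39:227) * (15 * 60 / 1024)
}

#' Reference labels for supervised training
#'
#' Converts ground-truth beat times to the two label types the network is
#' trained on: a unit-amplitude Gaussian-pulse waveform that preserves beat
#' timing while discarding pulse morphology, and a normalized Gaussian bump
#' on the 35--200 bpm grid centred at the window-mean heart rate.
#'
#' @param beat_times Increasing beat times (s), non-empty.
#' @param t_grid Time grid of the window (s), typically 15 Hz.
#' @param gaussian_width FWHM (s) of the label pulses.
#' @param spectrum_sigma_bpm Standard deviation (bpm) of the spectrum
#'   label bump.
#' @return List with `waveform` (length of `t_grid`), `spectrum`
#'   (length 189, sums to 1), `mean_hr` (bpm) and `beat_times`.
#' @export
make_reference_labels <- function(beat_times, t_grid, gaussian_width = 0.3,
                                  spectrum_sigma_bpm = 2.5) {
  if (length(beat_times) == 0) stop("beat_times must be non-empty")
  if (any(diff(beat_times) <= 0)) stop("beat_times must be increasing")
  sigma <- gaussian_width / (2 * sqrt(2 * log(2)))
  waveform <- numeric(length(t_grid))
  for (tk in beat_times) {
    waveform <- waveform + exp(-(t_grid - tk)^2 / (2 * sigma^2))
  }
  if (length(beat_times) >= 2) {
    mean_hr <- 60 / mean(diff(beat_times))
  } else {
    mean_hr <- NA_real_
  }
  grid <- hr_grid()
  if (is.na(mean_hr)) {
    spectrum <- rep(1 / length(grid), length(grid))
  } else {
    spectrum <- exp(-(grid - mean_hr)^2 / (2 * spectrum_sigma_bpm^2))
    spectrum <- spectrum / sum(spectrum)
  }
  list(waveform = waveform, spectrum = spectrum, mean_hr = mean_hr,
       beat_times = beat_times)
}

#' Echo-amplitude envelope during body-motion events
#'
#' Gross body motion does not only sweep phase: the moving torso and limbs
#' raise and modulate the radar cross-section. During each motion event
#' the subject echo is multiplied by a raised-cosine-weighted amplitude
#' boost plus band-limited amplitude modulation (deterministic given the
#' scene seed). Outside events the envelope is 1.
#' @keywords internal
motion_envelope <- function(scene, t) {
  env <- rep(1, length(t))
  for (j in seq_along(scene$motion_events)) {
    ev <- scene$motion_events[[j]]
    tau <- (t - ev$start) / ev$duration
    weight <- ifelse(tau > 0 & tau < 1, sin(pi * pmin(pmax(tau, 0), 1))^2, 0)
    boost <- ev$boost %||% 4
    am_depth <- ev$am_depth %||% 0.8
    band <- ev$am_band %||% c(1, 7)
    n_comp <- 24L
    pars <- with_seed(scene$seed + 2000L * j, list(
      f = stats::runif(n_comp, band[1], band[2]),
      ph = stats::runif(n_comp, 0, 2 * pi)))
    am <- numeric(length(t))
    for (kk in seq_len(n_comp)) {
      am <- am + sin(2 * pi * pars$f[kk] * t + pars$ph[kk])
    }
    am <- am * sqrt(2 / n_comp)
    env <- env * (1 + (boost - 1) * weight) * (1 + am_depth * am * weight)
  }
  env
}

#' Steering phases of the L-shaped receive array
#'
#' One-way receive phase of each element for a plane wave from direction
#' cosines (u, v) at the centre frequency.
#' @keywords internal
steering_phases <- function(radar, direction) {
  lambda <- speed_of_light / radar$f0
  2 * pi / lambda * (radar$rx_positions %*% direction)[, 1]
}

#' Synthesize a raw FMCW radar cube with ground truth
#'
#' Generates the dechirped real-valued ADC samples a stretch-processed FMCW
#' receiver would record for the configured scene: for every reflector, a
#' fast-time beat tone at the frequency its range maps to, a slow-time
#' carrier phase 4*pi*f0*R(t)/c that encodes micro-motion, a per-receiver
#' geometric phase from the L-shaped array, and white Gaussian receiver
#' noise scaled to the requested SNR against the subject echo.
#'
#' @param scene A [scene_config()].
#' @param radar A [radar_config()].
#' @param duration Seconds of data; at least one burst.
#' @return List with `cube` (class `radar_cube`: `adc` array
#'   [burst, chirp, sample, rx], `t0`, `config`) and `labels`
#'   (ground truth at the decimated 15 Hz rate: `t`, `displacement_truth`,
#'   components, `beat_times`, `hr_trace`, plus window-label helpers via
#'   [make_reference_labels()]).
#' @export
synthesize_cube <- function(scene, radar = radar_config(), duration = 60) {
  stopifnot(inherits(scene, "scene_config"), inherits(radar, "radar_config"))
  n_burst <- floor(duration * radar$burst_rate)
  if (n_burst < 1) stop("duration must cover at least one burst")
  max_range <- (radar$samples_per_chirp / 2 - 1) * radar$bin_size
  if (scene$subject_distance > max_range)
    stop("subject beyond unambiguous range (", round(max_range, 2), " m)")

  nc <- radar$chirps_per_burst
  ns <- radar$samples_per_chirp
  # slow-time instant of every chirp
  t_chirp <- rep((seq_len(n_burst) - 1) / radar$burst_rate, each = nc) +
    rep((seq_len(nc) - 1) / radar$chirp_rate, times = n_burst)

  disp <- chest_displacement(scene, t_chirp)

  # reflector table: range trace, amplitude, direction
  reflectors <- list(list(
    range = scene$subject_distance + disp$total,
    amplitude = scene$subject_amplitude * motion_envelope(scene, t_chirp),
    direction = scene$subject_direction))
  for (cl in scene$clutter) {
    reflectors[[length(reflectors) + 1]] <- list(
      range = rep(cl$range, length(t_chirp)), amplitude = cl$amplitude,
      direction = c(0, 0))
  }
  # gross body motion involves the whole extended body: during each event,
  # transient scatterers (arms, shoulders, torso edges) appear over ~0.3 m
  # of range around the subject, with jittered ranges and modulated echoes
  for (j in seq_along(scene$motion_events)) {
    ev <- scene$motion_events[[j]]
    tau <- (t_chirp - ev$start) / ev$duration
    weight <- ifelse(tau > 0 & tau < 1,
                     sin(pi * pmin(pmax(tau, 0), 1))^2, 0)
    if (all(weight == 0)) next
    boost <- ev$boost %||% 4
    offsets <- c(-0.12, -0.06, 0.06, 0.12, 0.2, 0.28)
    for (s_i in seq_along(offsets)) {
      pars <- with_seed(scene$seed + 3000L * j + 17L * s_i, list(
        f = stats::runif(12L, 2, 7), ph = stats::runif(12L, 0, 2 * pi),
        fa = stats::runif(12L, 2, 7), pa = stats::runif(12L, 0, 2 * pi)))
      rj <- numeric(length(t_chirp))
      am <- numeric(length(t_chirp))
      for (kk in 1:12) {
        rj <- rj + sin(2 * pi * pars$f[kk] * t_chirp + pars$ph[kk])
        am <- am + sin(2 * pi * pars$fa[kk] * t_chirp + pars$pa[kk])
      }
      rj <- rj * 4e-3 * sqrt(2 / 12)
      am <- am * sqrt(2 / 12)
      reflectors[[length(reflectors) + 1]] <- list(
        range = scene$subject_distance + offsets[s_i] +
          0.5 * ev$displacement * pmin(pmax(tau, 0), 1) + rj,
        amplitude = 0.4 * boost * scene$subject_amplitude * weight *
          (1 + 0.6 * am),
        direction = scene$subject_direction)
    }
  }
  if (!is.null(scene$second_person)) {
    sp <- scene$second_person
    sp_amp <- if (is.null(sp$amplitude)) 0.5 else sp$amplitude
    sp_motion <- if (is.null(sp$amplitude_motion)) 3e-3 else sp$amplitude_motion
    sp_rate <- if (is.null(sp$rate)) 14 else sp$rate
    reflectors[[length(reflectors) + 1]] <- list(
      range = sp$range + sp_motion * sin(2 * pi * sp_rate / 60 * t_chirp),
      amplitude = sp_amp,
      direction = if (is.null(sp$direction)) c(0.3, 0) else sp$direction)
  }

  n_fast <- seq_len(ns) - 1
  n_chirps_total <- n_burst * nc
  adc <- array(0, dim = c(n_chirps_total, ns, radar$n_rx))
  for (refl in reflectors) {
    f_beat <- refl$range / radar$bin_size * radar$adc_rate / ns
    carrier <- 4 * pi * radar$f0 * refl$range / speed_of_light
    psi <- steering_phases(radar, refl$direction)
    base_phase <- outer(2 * pi * f_beat / radar$adc_rate, n_fast) + carrier
    for (i in seq_len(radar$n_rx)) {
      adc[, , i] <- adc[, , i] + refl$amplitude * cos(base_phase + psi[i])
    }
  }
  if (is.finite(scene$snr_db)) {
    noise_sd <- sqrt(scene$subject_amplitude^2 / 2 / 10^(scene$snr_db / 10))
    adc <- adc + with_seed(scene$seed,
      array(stats::rnorm(length(adc), sd = noise_sd), dim = dim(adc)))
  }
  dim(adc) <- c(nc, n_burst, ns, radar$n_rx)
  adc <- aperm(adc, c(2, 1, 3, 4))  # [burst, chirp, sample, rx]

  # ground truth at the decimated 15 Hz rate
  n_out <- n_burst %/% 2
  t15 <- decimated_times(radar, n_out)
  truth <- chest_displacement(scene, t15)
  hr_tr <- scene$heart$hr_trace
  hr15 <- if (is.list(hr_tr)) {
    stats::approx(hr_tr$t, hr_tr$bpm, xout = t15, rule = 2)$y
  } else rep(hr_tr, n_out)

  cube <- structure(list(adc = adc, t0 = 0, config = radar,
                         scene = scene), class = "radar_cube")
  labels <- list(t = t15,
                 displacement_truth = truth$total,
                 respiration = truth$respiration,
                 heart = truth$heart,
                 motion = truth$motion,
                 beat_times = disp$beat_times,
                 hr_trace = hr15)
  list(cube = cube, labels = labels)
}

#' @export
print.radar_cube <- function(x, ...) {
  d <- dim(x$adc)
  cat(sprintf(
    "<radar_cube> %d bursts x %d chirps x %d samples x %d rx (%.1f s)\n",
    d[1], d[2], d[3], d[4], d[1] / x$config$burst_rate))
  invisible(x)
}
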