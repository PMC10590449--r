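#' Radar operating configuration
#'
#' Construct the operating-parameter set of the 60 GHz FMCW radar front end:
#' chirp/burst geometry, sweep band, sampling rates and the L-shaped
#' three-element receive array. Defaults correspond to a miniaturized
#' consumer radar chip sweeping 58--63.5 GHz (bandwidth 5.5 GHz, range
#' resolution c/2B ~ 2.7 cm), 256 ADC samples per chirp at 2 MHz, 20 chirps
#' per burst at a 3000 Hz chirp rate, and a 30 Hz burst rate.
#'
#' @param f_start Sweep start frequency in Hz.
#' @param f_stop Sweep stop frequency in Hz.
#' @param samples_per_chirp ADC samples per chirp.
#' @param chirps_per_burst Chirps in one burst.
#' @param adc_rate ADC sampling rate in Hz.
#' @param chirp_rate Chirp repetition rate in Hz.
#' @param burst_rate Burst repetition rate in Hz.
#' @param n_rx Number of receive antennas.
#' @param rx_spacing Receive element spacing in metres (L-shaped array:
#'   element 1 at the corner, element 2 along x, element 3 along y).
#' @param tx_power Transmit power in watts (metadata only).
#'
#' @return An object of class `radar_config` with derived fields
#'   `bandwidth`, `f0` (centre frequency, midpoint of the sweep),
#'   `bin_size` (range-bin width c/2B in metres), `duty_cycle`, and
#'   `rx_positions` (n_rx x 2 matrix, metres).
#' @export
radar_config <- function(f_start = 58e9, f_stop = 63.5e9,
                         samples_per_chirp = 256L, chirps_per_burst = 20L,
                         adc_rate = 2e6, chirp_rate = 3000, burst_rate = 30,
                         n_rx = 3L, rx_spacing = 2.5e-3, tx_power = 5e-3) {
  if (f_stop <= f_start) stop("f_stop must exceed f_start")
  bandwidth <- f_stop - f_start
  duty_cycle <- samples_per_chirp * chirps_per_burst / adc_rate * burst_rate
  if (duty_cycle <= 0 || duty_cycle >= 1)
    stop("active duty cycle must lie in (0, 1); got ", duty_cycle)
  rx_positions <- rbind(c(0, 0), c(rx_spacing, 0), c(0, rx_spacing))
  if (n_rx != 3L) {
    # generalize the L shape: fill along x then y
    rx_positions <- cbind(
      c(0, rx_spacing * seq_len(max(0, n_rx - 1))),
      0
    )[seq_len(n_rx), , drop = FALSE]
  }
  structure(list(
    f_start = f_start, f_stop = f_stop, bandwidth = bandwidth,
    f0 = (f_start + f_stop) / 2,
    samples_per_chirp = as.integer(samples_per_chirp),
    chirps_per_burst = as.integer(chirps_per_burst),
    adc_rate = adc_rate, chirp_rate = chirp_rate, burst_rate = burst_rate,
    n_rx = as.integer(n_rx), rx_positions = rx_positions,
    tx_power = tx_power,
    bin_size = 299792458 / (2 * bandwidth),
    duty_cycle = duty_cycle
  ), class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat("<radar_config>\n")
  cat(sprintf("  sweep: %.1f-%.1f GHz (B = %.2f GHz, f0 = %.3f GHz)\n",
              x$f_start / 1e9, x$f_stop / 1e9, x$bandwidth / 1e9, x$f0 / 1e9))
  cat(sprintf("  range resolution: %.4f m\n", x$bin_size))
  cat(sprintf("  %d samples/chirp @ %.0f kHz ADC, %d chirps/burst, %g Hz bursts\n",
              x$samples_per_chirp, x$adc_rate / 1e3, x$chirps_per_burst,
              x$burst_rate))
  cat(sprintf("  duty cycle: %.2f%%, %d rx\n", 100 * x$duty_cycle, x$n_rx))
  invisible(x)
}

#' Synthetic scene configuration
#'
#' Describe a radar scene for the simulator: one breathing subject plus
#' optional body-motion events, static clutter and a second person.
#' Respiration dominates heartbeat displacement by one to two orders of
#' magnitude, as it does on a real chest wall, so the defaults put a
#' millimetre-scale breathing motion over a sub-millimetre heartbeat
#' pulse train.
#'
#' @param subject_distance Radial distance sensor-to-torso in metres
#'   (0.3--1.5 m is the supported monitoring range).
#' @param respiration List with `rate` (breaths per minute), `amplitude`
#'   (metres, peak), `pattern` (`"regular"`, `"deep"` or `"rapid"`), and
#'   optionally `shape_power` (even integer; the sinusoid is raised to
#'   this power to create realistic harmonics).
#' @param heart List with `hr_trace` (bpm; a scalar, or a list with `t`
#'   and `bpm` for a time-varying rate), `pulse_amplitude` (metres) and
#'   `pulse_width` (seconds, Gaussian FWHM of one heartbeat pulse).
#' @param motion_events List of events, each a list with `start` (s),
#'   `duration` (s) and `displacement` (metres; a smooth ramp of this
#'   total excursion is added during the event).
#' @param clutter List of static reflectors, each `list(range =, amplitude =)`.
#' @param second_person Optional second reflector:
#'   `list(range =, amplitude =, rate =, amplitude_motion =)` (a breathing
#'   bystander).
#' @param subject_direction Unit-less direction cosines `c(u, v)` of the
#'   subject relative to boresight (0, 0 = boresight); sets the
#'   per-receiver geometric phases of the L-shaped array.
#' @param snr_db Per-receiver SNR in dB, defined against the subject echo
#'   power.
#' @param subject_amplitude Echo amplitude of the subject reflector
#'   (arbitrary linear units).
#' @param seed Integer seed; the same scene with the same seed synthesizes
#'   bit-identical data.
#'
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(subject_distance = 0.6,
                         respiration = list(rate = 15, amplitude = 4e-3,
                                            pattern = "regular"),
                         heart = list(hr_trace = 72, pulse_amplitude = 2e-4,
                                      pulse_width = 0.08),
                         motion_events = list(),
                         clutter = list(),
                         second_person = NULL,
                         subject_direction = c(0, 0),
                         snr_db = 20,
                         subject_amplitude = 1,
                         seed = 1L) {
  respiration <- utils::modifyList(
    list(rate = 15, amplitude = 4e-3, pattern = "regular", shape_power = 2L),
    respiration)
  heart <- utils::modifyList(
    list(hr_trace = 72, pulse_amplitude = 2e-4, pulse_width = 0.08), heart)
  if (!respiration$pattern %in% c("regular", "deep", "rapid"))
    stop("unknown respiration pattern: ", respiration$pattern)
  hr <- heart$hr_trace
  hr_vals <- if (is.list(hr)) hr$bpm else hr
  if (any(hr_vals < 35 | hr_vals > 200))
    stop("hr_trace must lie in [35, 200] bpm")
  if (heart$pulse_amplitude > 0 && respiration$amplitude > 0 &&
      respiration$amplitude < 5 * heart$pulse_amplitude)
    warning("respiration amplitude should dominate the heartbeat pulse ",
            "amplitude by one to two orders of magnitude")
  structure(list(
    subject_distance = subject_distance,
    respiration = respiration, heart = heart,
    motion_events = motion_events, clutter = clutter,
    second_person = second_person,
    subject_direction = subject_direction,
    snr_db = snr_db, subject_amplitude = subject_amplitude,
    seed = as.integer(seed)
  ), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  subject at %.2f m, respiration %s %.1f bpm (%.1f mm), snr %g dB\n",
              x$subject_distance, x$respiration$pattern, x$respiration$rate,
              1e3 * x$respiration$amplitude, x$snr_db))
  hr <- x$heart$hr_trace
  if (is.list(hr)) cat(sprintf("  heart: time-varying %.0f-%.0f bpm",
                               min(hr$bpm), max(hr$bpm)))
  else cat(sprintf("  heart: %.0f bpm", hr))
  cat(sprintf(", pulse %.2f mm / %.0f ms\n",
              1e3 * x$heart$pulse_amplitude, 1e3 * x$heart$pulse_width))
  if (length(x$motion_events))
    cat(sprintf("  %d motion event(s)\n", length(x$motion_events)))
  if (!is.null(x$second_person)) cat("  second person present\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
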