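test_that("respiration-only displacement has the configured amplitude and rate", {
  sc <- scene_config(
    respiration = list(rate = 15, amplitude = 4e-3, pattern = "regular",
                       shape_power = 1L),
    heart = list(pulse_amplitude = 0), seed = 1)
  t <- seq(0, 60, by = 1 / 15)
  d <- chest_displacement(sc, t)
  expect_equal(diff(range(d$respiration)), 8e-3, tolerance = 1e-6)
  expect_equal(d$heart, rep(0, length(t)))
  sp <- abs(stats::fft(d$total - mean(d$total)))
  freqs_bpm <- (seq_along(t) - 1) / length(t) * 15 * 60
  half <- seq_len(length(t) %/% 2)
  expect_equal(freqs_bpm[half][which.max(sp[half])], 15, tolerance = 0.5)
})

test_that("heartbeat-only displacement puts its fundamental at the heart rate", {
  sc <- scene_config(respiration = list(amplitude = 0),
                     heart = list(hr_trace = 72, pulse_amplitude = 2e-4))
  t <- seq(0, 60, by = 1 / 15)
  d <- chest_displacement(sc, t)
  x <- d$total - mean(d$total)
  sp <- abs(stats::fft(x))
  freqs_bpm <- (seq_along(t) - 1) / length(t) * 15 * 60
  inband <- freqs_bpm > 30 & freqs_bpm < 110
  expect_equal(freqs_bpm[inband][which.max(sp[inband])], 72, tolerance = 1)
})

test_that("displacement is deterministic and linear in pulse amplitude", {
  t <- seq(0, 16, by = 1 / 15)
  sc <- scene_config(seed = 9,
                     motion_events = list(list(start = 4, duration = 2,
                                               displacement = 0.02)))
  d1 <- chest_displacement(sc, t)
  d2 <- chest_displacement(sc, t)
  expect_identical(d1, d2)

  sc_a <- scene_config(heart = list(pulse_amplitude = 2e-4), seed = 5)
  sc_b <- scene_config(heart = list(pulse_amplitude = 4e-4), seed = 5)
  expect_equal(chest_displacement(sc_b, t)$heart,
               2 * chest_displacement(sc_a, t)$heart, tolerance = 1e-12)
})

test_that("unknown respiration pattern and out-of-range HR are rejected", {
  expect_error(scene_config(respiration = list(pattern = "sigh")),
               "unknown respiration pattern")
  expect_error(scene_config(heart = list(hr_trace = 220)), "35, 200")
})

test_that("time-varying heart-rate traces drift the beat intervals", {
  tr <- list(t = c(0, 60), bpm = c(110, 60))
  beats <- beat_times_from_trace(tr, 60)
  gaps <- diff(beats)
  expect_lt(gaps[1], gaps[length(gaps)])  # slowing heart -> widening gaps
  expect_equal(60 / gaps[1], 110, tolerance = 8)
  expect_equal(60 / gaps[length(gaps)], 60, tolerance = 8)
})

test_that("reference labels preserve beat timing and normalize the spectrum", {
  t_grid <- seq(0, 4, by = 1 / 15)
  lab <- make_reference_labels(c(0.5, 1.5, 2.5), t_grid)
  # three pulses: local maxima of the waveform at the beat times
  peaks <- t_grid[which(diff(sign(diff(lab$waveform))) == -2) + 1]
  expect_length(peaks, 3)
  expect_equal(peaks, c(0.5, 1.5, 2.5), tolerance = 1 / 15)
  expect_equal(hr_grid()[which.max(lab$spectrum)], 60, tolerance = 0.9)
  expect_equal(sum(lab$spectrum), 1, tolerance = 1e-12)

  irr <- make_reference_labels(c(0.5, 1.4, 2.5), t_grid)
  peaks_irr <- t_grid[which(diff(sign(diff(irr$waveform))) == -2) + 1]
  expect_equal(peaks_irr, c(0.5, 1.4, 2.5), tolerance = 1 / 15)

  expect_error(make_reference_labels(numeric(0), t_grid), "non-empty")
  for (bt in list(c(1, 2, 3), c(0.2, 0.9, 1.1, 3))) {
    expect_equal(sum(make_reference_labels(bt, t_grid)$spectrum), 1,
                 tolerance = 1e-12)
  }
})

test_that("a static target lands in the range bin its distance implies", {
  radar <- radar_config()
  sc <- scene_config(subject_distance = 0.6,
                     respiration = list(amplitude = 0),
                     heart = list(pulse_amplitude = 0),
                     snr_db = Inf, seed = 1)
  out <- synthesize_cube(sc, radar, duration = 1)
  prof <- preprocess_cube(out$cube)
  power <- apply(abs(prof$profiles)^2, 2, sum)
  expect_equal(which.max(power) - 1L, 22L)  # 0.6 m / (c/2B)
  # static-only scene: clutter filter output is ~0 everywhere
  filt <- clutter_filter(prof)
  expect_lt(max(abs(filt$profiles)), 1e-8 * max(abs(prof$profiles)))
})

test_that("per-receiver phases match the steering geometry of the L-array", {
  radar <- radar_config()
  dir <- c(0.25, -0.1)
  sc <- scene_config(subject_distance = 0.6,
                     respiration = list(amplitude = 0),
                     heart = list(pulse_amplitude = 0),
                     subject_direction = dir, snr_db = Inf, seed = 1)
  out <- synthesize_cube(sc, radar, duration = 1)
  prof <- preprocess_cube(out$cube)$profiles
  peak <- which.max(apply(abs(prof)^2, 2, sum))
  z <- prof[1, peak, ]
  measured <- Arg(z * Conj(z[1]))
  # independent steering oracle: one-way phase 2*pi/lambda * (p . u)
  lambda <- 299792458 / radar$f0
  expected <- 2 * pi / lambda * (radar$rx_positions %*% dir)[, 1]
  expected <- expected - expected[1]
  wrap <- function(x) Arg(exp(1i * x))
  expect_equal(wrap(measured), wrap(expected), tolerance = 1e-3)
})

test_that("cube synthesis is deterministic given scene, radar and seed", {
  sc <- scene_config(seed = 42)
  a <- synthesize_cube(sc, radar_config(), duration = 1)
  b <- synthesize_cube(sc, radar_config(), duration = 1)
  expect_identical(a$cube$adc, b$cube$adc)
  expect_identical(a$labels, b$labels)
})

test_that("subjects beyond the unambiguous range are rejected", {
  expect_error(synthesize_cube(scene_config(subject_distance = 4),
                               radar_config(), duration = 1),
               "unambiguous range")
})

test_that("ground-truth labels are independent of the radar signal path", {
  sc <- scene_config(seed = 2)
  lab_hi <- synthesize_cube(sc, radar_config(), duration = 2)$labels
  sc_noisy <- sc
  sc_noisy$snr_db <- -10
  lab_lo <- synthesize_cube(sc_noisy, radar_config(), duration = 2)$labels
  expect_identical(lab_hi$displacement_truth, lab_lo$displacement_truth)
  expect_identical(lab_hi$beat_times, lab_lo$beat_times)
})
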