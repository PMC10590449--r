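# Shared fixtures. Cube synthesis is the slow part, so scenes used by
# several tests are cached per session.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# a small radar config (shorter fast-time) for tests that only exercise
# window logic / timing, keeping the same band, rates and bin size
small_radar <- function() {
  radar_config(samples_per_chirp = 64L, adc_rate = 5e5)
}

breathing_cube <- function() {
  cached("breathing_cube", {
    sc <- scene_config(subject_distance = 0.6, seed = 3)
    synthesize_cube(sc, radar_config(), duration = 16)
  })
}

breathing_profiles <- function() {
  cached("breathing_profiles", preprocess_cube(breathing_cube()$cube))
}

breathing_presence <- function() {
  cached("breathing_presence", presence_detect(breathing_profiles()))
}

# tiny network configuration used wherever the test exercises behaviour
# (symmetry, determinism, learning) rather than the published size
tiny_net <- function(L = 60, seed = 2) {
  build_network(L = L, n_branch = 4L, filters = 4L, k1 = 3L, k_out = 3L,
                k5 = 5L, k6 = 3L, k7 = 3L, head_filters = 3L, seed = seed)
}

tiny_sample <- function(L = 60, hr = 72, seed = 1) {
  t_grid <- (seq_len(L) - 1) / 15
  sc <- scene_config(heart = list(hr_trace = hr), seed = seed)
  disp <- chest_displacement(sc, t_grid)
  lab <- make_reference_labels(disp$beat_times, t_grid)
  x <- matrix(rep(disp$total, 4), 4, byrow = TRUE) +
    matrix(stats::rnorm(4 * L, sd = 1e-4), 4)
  list(x = x, waveform = lab$waveform, spectrum = lab$spectrum,
       hr = lab$mean_hr)
}
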