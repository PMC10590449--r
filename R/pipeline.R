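#' Window geometry per application
#' @keywords internal
app_windows <- function(app = c("sleep", "meditation")) {
  app <- match.arg(app)
  if (app == "sleep") list(window_s = 60, step_s = 15)
  else list(window_s = 16, step_s = 4)
}

subset_profiles <- function(profiles, idx) {
  out <- profiles
  out$profiles <- profiles$profiles[idx, , , drop = FALSE]
  out$t <- profiles$t[idx]
  out
}

#' End-to-end heart-rate detection on a radar session
#'
#' Slides the application's analysis window over the session (sleep: 60 s
#' windows every 15 s; meditation: 16 s windows every 4 s, both at the
#' 15 Hz decimated rate) and runs, per window: presence detection
#' (clutter filter + CA-CFAR + stillness gate), micro-motion extraction
#' (MRC beamforming + circle-fit phase), and heart-rate estimation with
#' either the trained network or the band-pass baseline. Windows that
#' fail the presence/stillness gate are emitted undetermined. The raw
#' sequence is then confidence-gated and smoothed by
#' [smooth_hr_series()]. A window's estimate is stamped at the window end
#' (the first estimate of a sleep session arrives at 60 s).
#'
#' @param cube A `radar_cube` or a path readable by [read_cube()].
#' @param app `"sleep"` or `"meditation"`.
#' @param model A trained `pulse_net` (required for `method = "nn"`) with
#'   input length matching the app window.
#' @param method `"nn"` or `"bpf"`.
#' @param config Optional presence-detection overrides (see
#'   [presence_detect()]) plus `conf_threshold` for post-processing.
#' @return List with `series` (smoothed `hr_series`), `raw` (unsmoothed),
#'   and `log` (per-window data frame: t, present, still,
#'   stillness_ratio, range_bin, hr, confidence).
#' @export
run_detection <- function(cube, app = c("sleep", "meditation"),
                          model = NULL, method = c("nn", "bpf"),
                          config = list()) {
  app <- match.arg(app)
  method <- match.arg(method)
  if (is.character(cube)) cube <- read_cube(cube)$cube
  if (!inherits(cube, "radar_cube")) stop("malformed cube input")
  if (method == "nn" && is.null(model))
    stop("method 'nn' requires a trained model")
  win <- app_windows(app)
  profiles <- preprocess_cube(cube)
  fs <- profiles$sample_rate
  L <- as.integer(round(win$window_s * fs))
  step <- as.integer(round(win$step_s * fs))
  if (method == "nn" && model$spec$L != L)
    stop("model input length ", model$spec$L,
         " does not match the ", app, " window (", L, " samples)")
  n <- dim(profiles$profiles)[1]
  if (n < L) stop("session shorter than one analysis window")
  starts <- seq(1L, n - L + 1L, by = step)
  conf_threshold <- config$conf_threshold %||% 1.5
  log <- data.frame(t = numeric(0), present = logical(0), still = logical(0),
                    stillness_ratio = numeric(0), range_bin = integer(0),
                    hr = numeric(0), confidence = numeric(0))
  t_out <- hr_out <- conf_out <- numeric(length(starts))
  det_out <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + L - 1L)
    wprof <- subset_profiles(profiles, idx)
    pres <- presence_detect(wprof, config)
    t_end <- (starts[i] + L - 1L) / fs
    hr <- NA_real_; conf <- NA_real_; det <- FALSE
    if (pres$present && pres$still) {
      mm <- extract_micromotions(pres)
      est <- if (method == "nn") infer_pulse(mm, model)
             else bpf_estimate_hr(mm)
      if (isTRUE(est$determined)) {
        hr <- est$hr; conf <- est$confidence; det <- TRUE
      }
    }
    t_out[i] <- t_end; hr_out[i] <- hr; conf_out[i] <- conf
    det_out[i] <- det
    log <- rbind(log, data.frame(
      t = t_end, present = pres$present, still = pres$still,
      stillness_ratio = pres$stillness_ratio,
      range_bin = if (pres$present) pres$range_bin else NA_integer_,
      hr = hr, confidence = conf))
  }
  raw <- hr_series(t_out, hr_out, conf_out, det_out)
  smoothed <- smooth_hr_series(raw, profile = app,
                               conf_threshold = conf_threshold)
  list(series = smoothed, raw = raw, log = log)
}

#' Write / read a radar cube container
#'
#' Serializes a cube (plus optional ground-truth labels) to the package's
#' native `.rds` container holding the `adc` array, `t0`, the radar
#' configuration and, when present, the scene configuration (as YAML) and
#' labels. Round trips are bit-exact.
#'
#' @param cube A `radar_cube`.
#' @param path Path ending in `.rds`.
#' @param labels Optional label list from [synthesize_cube()].
#' @export
write_cube <- function(cube, path, labels = NULL) {
  stopifnot(inherits(cube, "radar_cube"))
  if (!grepl("\\.rds$", path, ignore.case = TRUE))
    stop("unknown cube container extension (expected .rds): ", path)
  payload <- list(adc = cube$adc, t0 = cube$t0,
                  config = unclass(cube$config),
                  scene_yaml = if (!is.null(cube$scene))
                    yaml::as.yaml(unclass(cube$scene)) else NULL,
                  labels = labels)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_cube
#' @return `read_cube()` returns a list with `cube` and `labels`.
#' @export
read_cube <- function(path) {
  if (!grepl("\\.rds$", path, ignore.case = TRUE))
    stop("unknown cube container extension (expected .rds): ", path)
  payload <- readRDS(path)
  for (field in c("adc", "t0", "config")) {
    if (is.null(payload[[field]]))
      stop("cube container missing required dataset '", field, "'")
  }
  config <- payload$config
  class(config) <- "radar_config"
  cube <- structure(list(adc = payload$adc, t0 = payload$t0,
                         config = config,
                         scene = if (!is.null(payload$scene_yaml))
                           yaml::yaml.load(payload$scene_yaml) else NULL),
                    class = "radar_cube")
  list(cube = cube, labels = payload$labels)
}
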