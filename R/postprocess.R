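#' Heart-rate time series
#'
#' @param t Uniform timestamps (s).
#' @param hr Heart rates (bpm; NA where absent).
#' @param confidence Confidence values (peak ratio).
#' @param determined Logical mask; forced FALSE wherever `hr` is NA.
#' @return An `hr_series` object (also a data frame).
#' @export
hr_series <- function(t, hr, confidence = rep(Inf, length(t)),
                      determined = !is.na(hr)) {
  stopifnot(length(t) == length(hr), length(hr) == length(confidence),
            length(hr) == length(determined))
  determined <- determined & !is.na(hr)
  structure(data.frame(t = t, hr = hr, confidence = confidence,
                       determined = determined),
            class = c("hr_series", "data.frame"))
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> %d samples, %.0f%% determined\n",
              nrow(x), 100 * mean(x$determined)))
  NextMethod()
}

running_median <- function(x, n) {
  if (n <= 1 || length(x) < 2) return(x)
  half_lo <- (n - 1L) %/% 2L
  half_hi <- n - 1L - half_lo
  vapply(seq_along(x), function(i) {
    stats::median(x[max(1, i - half_lo):min(length(x), i + half_hi)])
  }, numeric(1))
}

gaussian_smooth <- function(x, n) {
  if (n <= 1 || length(x) < 2) return(x)
  sigma <- n / 2
  half <- ceiling(2 * sigma)
  kern <- exp(-(-half:half)^2 / (2 * sigma^2))
  vapply(seq_along(x), function(i) {
    idx <- max(1, i - half):min(length(x), i + half)
    w <- kern[idx - i + half + 1]
    sum(w * x[idx]) / sum(w)
  }, numeric(1))
}

#' Confidence gating, gap interpolation and smoothing of an HR series
#'
#' Post-processing of the raw per-window heart-rate sequence:
#' low-confidence samples are discarded; runs of discarded samples no
#' longer than the median-filter length are recovered by linear
#' interpolation between their determined neighbours; longer runs are
#' declared undetermined. Each contiguous determined span is then median
#' filtered and Gaussian smoothed. Filter lengths are given in seconds
#' and converted to samples from the series step: the sleep profile uses
#' a 10 min median / 1 min Gaussian over 15 s steps (40 / 4 samples), the
#' meditation profile 20 s / 20 s over 4 s steps (5 / 5 samples). Filters
#' shrink to the available samples at span edges.
#'
#' @param series An [hr_series()] on a uniform time grid.
#' @param profile `"sleep"` or `"meditation"` (sets the filter lengths).
#' @param conf_threshold Minimum confidence for a sample to be kept.
#' @param median_s,gaussian_s Optional filter-length overrides in seconds.
#' @return A smoothed `hr_series`.
#' @export
smooth_hr_series <- function(series, profile = c("sleep", "meditation"),
                             conf_threshold = 1.5,
                             median_s = NULL, gaussian_s = NULL) {
  profile <- match.arg(profile)
  stopifnot(inherits(series, "hr_series"))
  n <- nrow(series)
  if (n < 2) return(series)
  steps <- diff(series$t)
  step <- steps[1]
  if (any(abs(steps - step) > 1e-6 * max(step, 1)))
    stop("series must be on a uniform time grid")
  defaults <- if (profile == "sleep") c(600, 60) else c(20, 20)
  med_n <- max(1L, round((median_s %||% defaults[1]) / step))
  gau_n <- max(1L, round((gaussian_s %||% defaults[2]) / step))

  keep <- series$determined & !is.na(series$hr) &
    (is.na(series$confidence) | series$confidence >= conf_threshold)
  hr <- ifelse(keep, series$hr, NA_real_)

  # recover short gaps by linear interpolation; long gaps stay undetermined
  r <- rle(is.na(hr))
  pos <- cumsum(c(1, r$lengths))
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    i0 <- pos[j]; i1 <- pos[j + 1] - 1
    if (r$lengths[j] <= med_n && i0 > 1 && i1 < n) {
      hr[i0:i1] <- stats::approx(c(i0 - 1, i1 + 1),
                                 c(hr[i0 - 1], hr[i1 + 1]),
                                 xout = i0:i1)$y
    }
  }
  determined <- !is.na(hr)

  # median + Gaussian filtering per contiguous determined span
  r <- rle(determined)
  pos <- cumsum(c(1, r$lengths))
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    i0 <- pos[j]; i1 <- pos[j + 1] - 1
    hr[i0:i1] <- gaussian_smooth(running_median(hr[i0:i1], med_n), gau_n)
  }
  hr_series(series$t, hr, series$confidence, determined)
}

#' Write / read an HR series as CSV
#'
#' Columns: `t_s`, `hr_bpm`, `confidence`, `determined`.
#' @param series An `hr_series`.
#' @param path Output CSV path.
#' @export
write_hr_csv <- function(series, path) {
  df <- data.frame(t_s = series$t, hr_bpm = series$hr,
                   confidence = series$confidence,
                   determined = series$determined)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hr_csv
#' @export
read_hr_csv <- function(path) {
  df <- utils::read.csv(path)
  hr_series(df$t_s, df$hr_bpm, df$confidence, as.logical(df$determined))
}
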