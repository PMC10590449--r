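#' Heart-rate accuracy metrics
#'
#' Compares an estimated HR series against a reference: MAE (mean absolute
#' error, bpm), MAPE (mean absolute percentage error, as a fraction), the
#' 95th percentiles of the absolute and percentage error distributions,
#' the coefficient of determination
#' R^2 = 1 - sum(hr - hr_hat)^2 / sum(hr - mean(hr))^2 (negative when the
#' estimator is worse than predicting the mean), and the recall rate
#' (determined samples / total samples). Error metrics use determined
#' sample pairs only; recall uses all aligned samples. Estimate
#' timestamps are snapped to the nearest reference sample within half a
#' reference step; unmatched samples are excluded.
#'
#' @param reference,estimate [hr_series()] objects.
#' @return A `metrics_report` list: `mae`, `mape`, `ae95`, `ape95`,
#'   `r_squared`, `recall`, `n_determined`, `n_total`.
#' @export
compute_metrics <- function(reference, estimate) {
  stopifnot(inherits(reference, "hr_series"), inherits(estimate, "hr_series"))
  step <- if (nrow(reference) > 1) stats::median(diff(reference$t)) else Inf
  idx <- vapply(estimate$t, function(tt) {
    j <- which.min(abs(reference$t - tt))
    if (abs(reference$t[j] - tt) <= step / 2) j else NA_integer_
  }, integer(1))
  ok <- !is.na(idx)
  n_total <- sum(ok)
  ref_ok <- reference[idx[ok], ]
  est_ok <- estimate[ok, ]
  det <- est_ok$determined & ref_ok$determined &
    !is.na(est_ok$hr) & !is.na(ref_ok$hr)
  n_det <- sum(det)
  rep <- list(mae = NA_real_, mape = NA_real_, ae95 = NA_real_,
              ape95 = NA_real_, r_squared = NA_real_,
              recall = if (n_total > 0) n_det / n_total else 0,
              n_determined = n_det, n_total = n_total)
  if (n_det > 0) {
    hr <- ref_ok$hr[det]
    hh <- est_ok$hr[det]
    ae <- abs(hr - hh)
    ape <- ae / hr
    rep$mae <- mean(ae)
    rep$mape <- mean(ape)
    rep$ae95 <- unname(stats::quantile(ae, 0.95, type = 7))
    rep$ape95 <- unname(stats::quantile(ape, 0.95, type = 7))
    denom <- sum((hr - mean(hr))^2)
    rep$r_squared <- if (denom > 0) 1 - sum((hr - hh)^2) / denom
                     else NA_real_
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  MAE %.2f bpm   AE95 %.2f bpm\n", x$mae, x$ae95))
  cat(sprintf("  MAPE %.2f%%    APE95 %.2f%%\n",
              100 * x$mape, 100 * x$ape95))
  cat(sprintf("  R^2 %.3f      recall %.1f%% (%d/%d)\n",
              x$r_squared, 100 * x$recall, x$n_determined, x$n_total))
  invisible(x)
}
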