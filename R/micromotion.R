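#' Sample covariance of a multi-channel complex signal
#'
#' Q = (1/L) * sum_l [x(l) - xbar][x(l) - xbar]^H with xbar the sample
#' mean over chirps; the mean term is the stationary residue at the range
#' bin. Q is Hermitian positive semi-definite by construction.
#'
#' @param x Complex matrix, channels x chirps (3 x L).
#' @return Complex Hermitian PSD matrix (channels x channels).
#' @export
compute_covariance <- function(x) {
  if (!is.matrix(x)) stop("x must be a channels x chirps matrix")
  L <- ncol(x)
  if (L < 2) stop("need at least 2 chirps (L >= 2)")
  xc <- x - rowMeans(x)
  (xc %*% Conj(t(xc))) / L
}

#' Dominant eigenvector by power iteration
#'
#' Iterates v <- Qv / ||Qv|| from a seeded random start until the Rayleigh
#' quotient stabilizes. The global phase is fixed so that the first
#' component of largest magnitude is real-positive, making the result
#' deterministic and comparable across solvers.
#'
#' @param Q Hermitian PSD matrix, nonzero.
#' @param max_iter Iteration cap.
#' @param tol Relative eigenvalue-change stopping tolerance.
#' @param seed Seed for the random start.
#' @return Unit-norm complex eigenvector of the largest eigenvalue.
#' @export
dominant_eigenvector <- function(Q, max_iter = 1000L, tol = 1e-15, seed = 1L) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  if (all(abs(Q) == 0)) stop("Q is zero; no dominant eigenvector")
  n <- nrow(Q)
  v <- with_seed(seed, complex(real = stats::rnorm(n),
                               imaginary = stats::rnorm(n)))
  v <- v / sqrt(sum(abs(v)^2))
  lambda <- Re(Conj(v) %*% Q %*% v)[1]
  for (k in seq_len(max_iter)) {
    w <- (Q %*% v)[, 1]
    nw <- sqrt(sum(abs(w)^2))
    if (nw == 0) break
    v <- w / nw
    lambda_new <- Re(Conj(v) %*% Q %*% v)[1]
    if (abs(lambda_new - lambda) <= tol * max(abs(lambda), 1e-300)) {
      lambda <- lambda_new
      break
    }
    lambda <- lambda_new
  }
  # fix global phase: largest-magnitude component real-positive
  k0 <- which.max(abs(v))
  v <- v * Conj(v[k0]) / abs(v[k0])
  v
}

#' Maximum-ratio combining of receiver channels
#'
#' y(l) = w^H x(l): projects the three receiver channels onto the dominant
#' covariance eigenvector, maximizing the SNR of the combined scalar
#' sequence under the rank-1 reflection model.
#'
#' @param x Complex channels x chirps matrix.
#' @param w Complex weight vector (unit norm).
#' @return Complex vector of length ncol(x).
#' @export
mrc_combine <- function(x, w) {
  if (length(w) != nrow(x)) stop("weight length must match channel count")
  as.vector(Conj(w) %*% x)
}

#' Algebraic (Kasa) least-squares circle fit in the complex plane
#'
#' Minimizes sum_l (|y(l) - eta|^2 - r)^2 over the centre eta and the
#' squared-radius-like parameter r; expanding the square makes the problem
#' linear in (Re eta, Im eta, r - |eta|^2), so the minimizer is closed
#' form. The radius is reported as sqrt(max(r, 0)).
#'
#' @param y Complex vector (>= 3 points, not collinear).
#' @return List with `eta` (complex centre), `radius`, `r` (the raw
#'   squared-radius parameter) and `objective` (the attained sum of
#'   squares).
#' @export
fit_circle <- function(y) {
  if (length(y) < 3) stop("need at least 3 points")
  a <- Re(y); b <- Im(y)
  z <- a^2 + b^2
  # model: z = 2*a*p + 2*b*q + c0, with eta = p + iq, c0 = r - |eta|^2
  X <- cbind(2 * a, 2 * b, 1)
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12)
    stop("degenerate circle fit: points are collinear or coincident")
  beta <- solve(XtX, crossprod(X, z))
  eta <- complex(real = beta[1], imaginary = beta[2])
  r <- beta[3] + beta[1]^2 + beta[2]^2
  obj <- sum((abs(y - eta)^2 - r)^2)
  list(eta = eta, radius = sqrt(max(r, 0)), r = r, objective = obj)
}

#' Displacement from the unwrapped phase around the fitted circle centre
#'
#' d(l) = c / (4*pi*f0) * unwrap(angle(y(l) - eta)). The factor converts
#' the two-way carrier phase at the centre frequency to radial
#' displacement in metres; unwrapping keeps consecutive phase increments
#' below pi in magnitude so sub-wavelength motion is tracked continuously.
#'
#' @param y Complex combined signal.
#' @param eta Fitted circle centre.
#' @param f0 Centre frequency in Hz.
#' @return Displacement in metres (known up to a constant offset).
#' @export
extract_phase <- function(y, eta, f0) {
  z <- y - eta
  if (any(abs(z) == 0)) stop("y(l) equals the circle centre at some l")
  phi <- signal::unwrap(Arg(z))
  speed_of_light / (4 * pi * f0) * phi
}

#' Extract 16 micro-motion waveforms around the detected user
#'
#' For each of the 16 range bins centred on the detected bin
#' (detected - 7 .. detected + 8), the per-bin pipeline is: sample
#' covariance over receivers, dominant eigenvector (power iteration), MRC
#' combination, closed-form circle fit, and phase extraction. Bins near
#' the profile edge shift the window inward with a warning. The operation
#' honours the presence gate: it refuses to run unless a present, still
#' user was detected.
#'
#' @param presence A `presence_result` from [presence_detect()] (carries
#'   the clutter-filtered profiles and the gate).
#' @param n_bins Number of bins extracted (16).
#' @return A `micromotion_set`: `d` (n_bins x L metres), `bins` (0-based
#'   indices), `w` (weights, 3 x n_bins), `eta`, `radius`, `L`,
#'   `sample_rate`, `t`.
#' @export
extract_micromotions <- function(presence, n_bins = 16L) {
  stopifnot(inherits(presence, "presence_result"))
  if (!isTRUE(presence$present) || !isTRUE(presence$still))
    stop("gating contract: micro-motion extraction requires a present, ",
         "still user")
  profiles <- presence$filtered
  p <- profiles$profiles
  n_range <- dim(p)[2]
  L <- dim(p)[1]
  f0 <- profiles$config$f0
  first <- presence$range_bin - (n_bins %/% 2 - 1L)  # detected - 7, 0-based
  if (first < 0L || first + n_bins > n_range) {
    first <- max(0L, min(first, n_range - n_bins))
    warning("bin window shifted to fit the range profile")
  }
  bins <- first + seq_len(n_bins) - 1L
  d <- matrix(0, n_bins, L)
  w <- matrix(0i, dim(p)[3], n_bins)
  eta <- complex(n_bins)
  radius <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    x <- t(p[, bins[k] + 1L, ])  # channels x chirps
    ok <- tryCatch({
      Q <- compute_covariance(x)
      wk <- dominant_eigenvector(Q)
      y <- mrc_combine(x, wk)
      fit <- fit_circle(y)
      d[k, ] <- extract_phase(y, fit$eta, f0)
      w[, k] <- wk
      eta[k] <- fit$eta
      radius[k] <- fit$radius
      TRUE
    }, error = function(e) FALSE)
    # a degenerate bin (e.g. the near-zero DC bin) carries no micro-motion
    # information; leave its waveform at zero rather than failing the set
    if (!ok) {
      d[k, ] <- 0
      w[, k] <- 0i
      eta[k] <- 0i
      radius[k] <- 0
    }
  }
  structure(list(d = d, bins = bins, w = w, eta = eta, radius = radius,
                 L = L, sample_rate = profiles$sample_rate,
                 t = profiles$t),
            class = "micromotion_set")
}

#' @export
print.micromotion_set <- function(x, ...) {
  cat(sprintf("<micromotion_set> %d bins x %d chirps @ %g Hz, bins %d..%d\n",
              nrow(x$d), x$L, x$sample_rate, min(x$bins), max(x$bins)))
  invisible(x)
}

#' Normalize micro-motion waveforms for the network input
#'
#' Per waveform: remove the mean and scale to unit maximum absolute value
#' (all-zero waveforms stay zero).
#'
#' @param d Matrix n_bins x L.
#' @return Matrix of the same shape.
#' @export
normalize_micromotions <- function(d) {
  d <- d - rowMeans(d)
  m <- apply(abs(d), 1, max)
  m[m == 0] <- 1
  d / m
}
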