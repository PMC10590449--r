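rand_signal <- function(n_ch = 3, L = 50, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n_ch * L), imaginary = rnorm(n_ch * L)),
         n_ch, L)
}

test_that("sample covariance matches its definition", {
  # constant signal -> zero covariance (mean removed)
  xc <- matrix(complex(real = 1, imaginary = 2), 3, 10)
  expect_equal(max(abs(compute_covariance(xc))), 0)

  # rank-1 signal: Q = var(s) a a^H
  set.seed(3)
  a <- complex(real = rnorm(3), imaginary = rnorm(3))
  s <- rnorm(200)
  x <- a %o% s
  Q <- compute_covariance(x)
  s_var <- mean((s - mean(s))^2)
  expect_equal(Q, s_var * (a %o% Conj(a)), tolerance = 1e-10)
  expect_equal(Matrix::rankMatrix(Q)[1], 1)

  # random data: brute-force per-element double loop oracle
  x <- rand_signal(seed = 8)
  Q <- compute_covariance(x)
  L <- ncol(x)
  xb <- rowMeans(x)
  Q_loop <- matrix(0i, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    acc <- 0i
    for (l in seq_len(L)) {
      acc <- acc + (x[i, l] - xb[i]) * Conj(x[j, l] - xb[j])
    }
    Q_loop[i, j] <- acc / L
  }
  expect_lt(max(abs(Q - Q_loop)), 1e-12)
  expect_lt(max(abs(Q - Conj(t(Q)))), 1e-12)  # Hermitian
  expect_error(compute_covariance(x[, 1, drop = FALSE]), "L >= 2")
})

test_that("power iteration finds the dominant eigenvector", {
  w <- dominant_eigenvector(diag(c(3, 1, 0.5)))
  expect_equal(abs(w), c(1, 0, 0), tolerance = 1e-6)

  set.seed(2)
  a <- complex(real = rnorm(3), imaginary = rnorm(3))
  Q <- a %o% Conj(a)
  w <- dominant_eigenvector(Q)
  align <- abs(sum(Conj(w) * a)) / sqrt(sum(abs(a)^2))
  expect_equal(align, 1, tolerance = 1e-8)

  # random Hermitian PSD vs dense eigendecomposition, up to phase
  for (seed in 1:5) {
    x <- rand_signal(L = 40, seed = seed)
    Q <- compute_covariance(x)
    w <- dominant_eigenvector(Q)
    ed <- eigen(Q, symmetric = TRUE)
    v <- ed$vectors[, 1]
    expect_equal(abs(sum(Conj(w) * v)), 1, tolerance = 1e-6)
    expect_equal(sqrt(sum(abs(w)^2)), 1, tolerance = 1e-10)
    # eigen residual
    lam <- ed$values[1]
    expect_lt(max(abs(Q %*% w - lam * w)), 1e-6 * lam)
  }
  expect_error(dominant_eigenvector(matrix(0i, 3, 3)), "zero")
})

test_that("MRC combination is exactly w^H x", {
  x <- rand_signal(seed = 4)
  expect_equal(mrc_combine(x, c(1, 0, 0)), x[1, ])

  # hand-worked complex example
  xh <- matrix(c(1 + 1i, 2, 0 - 1i,
                 3, 1i, 1 - 1i), 3, 2)
  wh <- c(1i, 1, -1)
  manual <- c(Conj(1i) * (1 + 1i) + 2 - (0 - 1i),
              Conj(1i) * 3 + 1i - (1 - 1i))
  expect_equal(mrc_combine(xh, wh), manual, tolerance = 1e-15)

  # rank-1 model: |y| = |s| * ||a|| when w is the matched unit vector
  set.seed(6)
  a <- complex(real = rnorm(3), imaginary = rnorm(3))
  s <- rnorm(30)
  x <- a %o% s
  y <- mrc_combine(x, a / sqrt(sum(abs(a)^2)))
  expect_equal(abs(y), abs(s) * sqrt(sum(abs(a)^2)), tolerance = 1e-10)
})

test_that("MRC attains at least any single channel's variance (matched gain)", {
  for (seed in 1:5) {
    x <- rand_signal(L = 100, seed = seed + 20)
    a <- complex(real = rnorm(3), imaginary = rnorm(3))
    s <- rnorm(100)
    x <- x * 0.1 + a %o% s
    Q <- compute_covariance(x)
    w <- dominant_eigenvector(Q)
    y <- mrc_combine(x, w)
    var_y <- mean(abs(y - mean(y))^2)
    for (ch in 1:3) {
      var_ch <- mean(abs(x[ch, ] - mean(x[ch, ]))^2)
      expect_gte(var_y, var_ch - 1e-9)
    }
  }
})

test_that("circle fit recovers exact circles and rejects degenerate input", {
  th <- 2 * pi * (0:7) / 8
  y <- (1 + 2i) + 0.5 * exp(1i * th)
  fit <- fit_circle(y)
  expect_equal(fit$eta, 1 + 2i, tolerance = 1e-9)
  expect_equal(fit$radius, 0.5, tolerance = 1e-9)

  expect_error(fit_circle(rep(1 + 1i, 8)), "degenerate")
  expect_error(fit_circle((1:8) * (1 + 1i)), "degenerate")  # collinear
  expect_error(fit_circle(c(1 + 1i, 2)), "at least 3")
})

test_that("algebraic circle fit tracks the nonlinear least-squares optimum", {
  skip_if_not_installed("minpack.lm")
  set.seed(10)
  for (rep in 1:4) {
    eta_true <- complex(real = runif(1, -2, 2), imaginary = runif(1, -2, 2))
    r_true <- runif(1, 0.5, 2)
    th <- runif(60, 0, 2 * pi)
    y <- eta_true + (r_true + rnorm(60, sd = 0.01 * r_true)) * exp(1i * th)
    fit <- fit_circle(y)
    # geometric nonlinear LS oracle on the same points
    res_fun <- function(p) sqrt((Re(y) - p[1])^2 + (Im(y) - p[2])^2) - p[3]
    nls <- minpack.lm::nls.lm(par = c(0, 0, 1), fn = res_fun)
    eta_nls <- complex(real = nls$par[1], imaginary = nls$par[2])
    err_alg <- abs(fit$eta - eta_true)
    err_nls <- abs(eta_nls - eta_true)
    expect_lt(err_alg, 0.02 * r_true)          # centre error < 2% of radius
    expect_lt(err_alg, 2 * max(err_nls, 1e-6)) # within 2x of the optimum
    # the closed form minimizes its own objective: compare against truth
    obj <- function(eta, r) sum((abs(y - eta)^2 - r)^2)
    expect_lte(fit$objective, obj(eta_true, r_true^2) + 1e-12)
  }
})

test_that("phase extraction inverts the displacement modulation", {
  f0 <- radar_config()$f0
  c0 <- 299792458
  t <- seq(0, 10, by = 1 / 15)
  d_true <- 2e-4 * sin(2 * pi * 1.2 * t)
  eta <- 0.3 - 0.2i
  y <- eta + 0.8 * exp(1i * (4 * pi * f0 * d_true / c0 + 0.7))
  d_rec <- extract_phase(y, eta, f0)
  offset <- mean(d_rec - d_true)
  expect_equal(d_rec - offset, d_true, tolerance = 1e-10)

  # doubling the displacement doubles the extracted waveform
  y2 <- eta + 0.8 * exp(1i * (4 * pi * f0 * 2 * d_true / c0 + 0.7))
  d2 <- extract_phase(y2, eta, f0)
  expect_equal(d2 - mean(d2), 2 * (d_rec - mean(d_rec)), tolerance = 1e-9)

  # a trajectory crossing +-pi unwraps without jumps
  d_big <- 2e-3 * sin(2 * pi * 0.25 * t)  # multi-radian phase excursion
  yb <- 0.9 * exp(1i * (4 * pi * f0 * d_big / c0))
  db <- extract_phase(yb, 0, f0)
  phase_steps <- abs(diff(db)) * 4 * pi * f0 / c0
  expect_lt(max(phase_steps), pi)
  expect_error(extract_phase(c(1 + 0i, 0.5), 0.5, f0), "centre")
})

test_that("micro-motion extraction recovers breathing around the user bin", {
  pres <- breathing_presence()
  mm <- extract_micromotions(pres)
  expect_s3_class(mm, "micromotion_set")
  expect_equal(nrow(mm$d), 16L)
  expect_equal(mm$bins, (pres$range_bin - 7L):(pres$range_bin + 8L))
  expect_true(all(abs(sqrt(colSums(abs(mm$w)^2)) - 1) < 1e-8))
  expect_true(all(mm$radius >= 0))
  # the subject bin shows ~mm-scale oscillation at the breathing rate
  k <- which(mm$bins == pres$range_bin)
  truth <- breathing_cube()$labels$displacement_truth
  expect_gt(abs(cor(mm$d[k, ], truth)), 0.99)
  amp <- diff(range(mm$d[k, ]))
  expect_gt(amp, 5e-3)
  # far bins hold far less echo energy than the subject bin (what leaks
  # there is range-sidelobe residue of the subject, so correlation with
  # the truth is uninformative; the fitted circle radius is the witness)
  expect_lt(mm$radius[1], mm$radius[k] / 3)
  expect_lt(mm$radius[16], mm$radius[k] / 3)
})

test_that("micro-motion extraction honours the presence gate", {
  pres <- breathing_presence()
  blocked <- pres
  blocked$still <- FALSE
  expect_error(extract_micromotions(blocked), "gating contract")
  blocked$present <- FALSE
  expect_error(extract_micromotions(blocked), "gating contract")
})

test_that("an edge-adjacent detection shifts the bin window with a warning", {
  pres <- breathing_presence()
  shifted <- pres
  shifted$range_bin <- 2L
  expect_warning(mm <- extract_micromotions(shifted), "shifted")
  expect_equal(mm$bins, 0:15)
})
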