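test_that("the default network matches the reference parameter budget", {
  pc <- count_parameters(build_network(900))
  expect_identical(pc$trainable, 9815)
  # batch-norm moving statistics come in per-channel (mean, variance)
  # pairs, so the non-trainable count is necessarily even; the nearest
  # realizable total sits within one parameter of the nominal 10,248
  expect_identical(pc$non_trainable %% 2, 0)
  expect_lte(abs(pc$total - 10248), 2)
})

test_that("parameter count is invariant to the input window length", {
  expect_identical(count_parameters(build_network(900)),
                   count_parameters(build_network(240)))
  expect_error(build_network(2000), "1024")
})

test_that("forward pass maps 16 x L to pulse length L and a 189-bin simplex", {
  m <- build_network(240, seed = 3)
  set.seed(1)
  x <- matrix(rnorm(16 * 240), 16)
  fw <- radarhr:::net_forward(m, x)
  expect_equal(dim(fw$pulse), c(240L, 1L))
  expect_equal(dim(fw$probs), c(189L, 1L))
  expect_true(all(fw$probs >= 0))
  expect_equal(sum(fw$probs), 1, tolerance = 1e-10)
})

test_that("multi-scale spectra have the fixed 7 x 189 layout and FFT content", {
  expect_equal(dim(multiscale_spectrum(numeric(900))), c(7L, 189L))
  expect_true(all(multiscale_spectrum(numeric(900)) == 0))
  expect_equal(7L * 189L, 1323L)

  # stationary tone at 72 bpm: every branch peaks at the nearest grid bin
  t <- (0:899) / 15
  tone <- sin(2 * pi * 72 / 60 * t)
  ms <- multiscale_spectrum(tone)
  grid <- hr_grid()
  target <- which.min(abs(grid - 72))
  for (b in 1:7) {
    expect_lte(abs(which.max(ms[b, ]) - target), 1)
  }
})

test_that("half-window FFT branches localize a tone present in one half only", {
  t <- (0:899) / 15
  x <- numeric(900)
  x[1:450] <- sin(2 * pi * 60 / 60 * t[1:450])
  x[451:900] <- sin(2 * pi * 120 / 60 * t[451:900])
  ms <- multiscale_spectrum(x)
  grid <- hr_grid()
  expect_lte(abs(grid[which.max(ms[2, ])] - 60), 1)   # first half branch
  expect_lte(abs(grid[which.max(ms[3, ])] - 120), 1)  # second half branch
})

test_that("inference is deterministic and branch-permutation invariant", {
  m <- tiny_net()
  set.seed(4)
  x <- matrix(rnorm(4 * 60), 4)
  a <- infer_pulse(x, m)
  b <- infer_pulse(x, m)
  expect_identical(a, b)
  perm <- infer_pulse(x[c(3, 1, 4, 2), ], m)
  expect_equal(perm$pulse, a$pulse, tolerance = 1e-10)
  expect_equal(perm$pseudo_spectrum, a$pseudo_spectrum, tolerance = 1e-10)
  expect_error(infer_pulse(matrix(0, 4, 61), m), "does not match")
})

test_that("backpropagation matches numerical gradients", {
  m <- tiny_net(L = 16)
  B <- 2
  set.seed(9)
  x <- array(rnorm(4 * 16 * B), c(4, 16, B))
  yw <- matrix(rnorm(16 * B), 16, B)
  ys <- matrix(runif(189 * B), 189, B)
  ys <- sweep(ys, 2, colSums(ys), `/`)
  loss_fn <- function(model) {
    fw <- radarhr:::net_forward(model, x, training = TRUE)
    mean((fw$pulse - yw)^2) - mean(colSums(ys * fw$logprobs))
  }
  fw <- radarhr:::net_forward(m, x, training = TRUE)
  dpulse <- 2 * (fw$pulse - yw) / (16 * B)
  dlogits <- (sweep(fw$probs, 2, colSums(ys), `*`) - ys) / B
  grads <- radarhr:::net_backward(m, fw$cache, dpulse, dlogits)
  paths <- list(c("b1", "conv", "W"), c("b2", "dw", "W"),
                c("trunk", "bn2", "gamma"), c("out", "W"),
                c("h1", "conv", "W"), c("h2", "proj", "W"),
                c("h3", "pw", "W"))
  eps <- 1e-6
  for (path in paths) {
    g <- grads
    for (k in path) g <- g[[k]]
    i <- which.max(abs(g))  # check the largest-gradient entry
    f <- function(delta) {
      m2 <- m
      if (length(path) == 2) {
        m2$params[[path[1]]][[path[2]]][i] <-
          m2$params[[path[1]]][[path[2]]][i] + delta
      } else {
        m2$params[[path[1]]][[path[2]]][[path[3]]][i] <-
          m2$params[[path[1]]][[path[2]]][[path[3]]][i] + delta
      }
      loss_fn(m2)
    }
    g_num <- (f(eps) - f(-eps)) / (2 * eps)
    expect_equal(g[i], g_num, tolerance = 5e-4)  # FD noise at ReLU kinks
  }
})

test_that("heart rate and confidence read off the pseudo-spectrum peak", {
  grid <- hr_grid()
  delta <- numeric(189)
  i60 <- which.min(abs(grid - 60))
  delta[i60] <- 1
  r <- hr_from_pseudospectrum(delta)
  expect_equal(r$hr, grid[i60])
  expect_equal(r$confidence, 100)  # unimodal -> capped
  expect_true(r$determined)

  two <- numeric(189)
  two[c(40, 120)] <- 0.5
  expect_equal(hr_from_pseudospectrum(two)$confidence, 1)

  bump <- exp(-(grid - 117)^2 / (2 * 4^2))
  r3 <- hr_from_pseudospectrum(bump / sum(bump))
  expect_lte(abs(r3$hr - 117), 0.88)

  flat <- rep(1 / 189, 189)
  expect_false(hr_from_pseudospectrum(flat)$determined)
})

test_that("the network can overfit a single batch (capacity sanity check)", {
  m <- tiny_net(L = 60, seed = 3)
  dataset <- lapply(1:4, function(i) tiny_sample(hr = 55 + 12 * i, seed = i))
  tr <- train_network(m, dataset, epochs = 400, batch_size = 4, lr = 3e-3,
                      seed = 1)
  # the spectrum cross-entropy against soft labels has an irreducible
  # floor at the mean label entropy; convergence is judged above it
  floor_ce <- mean(vapply(dataset, function(s) {
    -sum(s$spectrum * log(s$spectrum + 1e-12))
  }, numeric(1)))
  first <- tr$history$loss[1] - floor_ce
  last <- tr$history$loss[nrow(tr$history)] - floor_ce
  expect_lt(last, 0.01 * first)
})

test_that("training is reproducible under a fixed seed", {
  dataset <- lapply(1:6, function(i) tiny_sample(hr = 50 + 10 * i, seed = i))
  a <- train_network(tiny_net(seed = 5), dataset, epochs = 3, seed = 7)
  b <- train_network(tiny_net(seed = 5), dataset, epochs = 3, seed = 7)
  expect_equal(a$history$loss, b$history$loss, tolerance = 1e-12)
  expect_error(
    train_network(tiny_net(), list(list(x = matrix(0, 4, 61),
                                        waveform = numeric(61),
                                        spectrum = numeric(189)))),
    "mismatch")
  expect_error(train_network(tiny_net(), list()), "empty")
})

test_that("save/load round trip preserves predictions and normalization", {
  m <- tiny_net(seed = 6)
  set.seed(2)
  x <- matrix(rnorm(4 * 60), 4)
  path <- tempfile(fileext = ".rds")
  save_network(m, path)
  m2 <- load_network(path)
  a <- infer_pulse(x, m)
  b <- infer_pulse(x, m2)
  expect_identical(a, b)
  expect_equal(sum(b$pseudo_spectrum), 1, tolerance = 1e-10)
  expect_true(file.exists(sub("\\.rds$", ".json", path)))
})
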