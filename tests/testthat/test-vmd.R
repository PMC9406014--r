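test_that("mirror extension and centre cropping are exact inverses", {
  expect_equal(mirror_extend(c(1, 2, 3, 4)), c(2, 1, 1, 2, 3, 4, 4, 3))
  expect_true(all(mirror_extend(rep(7, 10)) == 7))
  set.seed(11)
  for (n in c(17, 8, 33)) {
    x <- rnorm(n)
    expect_identical(crop_center(mirror_extend(x), n), x)
  }
  expect_error(crop_center(1:10, 4), "length")
})

test_that("a single tone is recovered with its FFT-peak frequency", {
  t <- 0:255
  x <- cos(2 * pi * 8 * t / 256)
  ms <- vmd(x, K = 1, alpha = 2000, tau = 0)
  expect_equal(ms$omegas[1], fft_peak_freq(x), tolerance = 1e-3)
  inner <- 27:230                       # away from the 10% edge region
  expect_gt(cor(ms$modes[1, inner], x[inner]), 0.99)
})

test_that("a constant signal is a zero-frequency fixed point", {
  x <- rep(1, 64)
  ms <- vmd(x, K = 1, dc_mode = TRUE)
  expect_identical(ms$omegas[1], 0)
  expect_lt(max(abs(ms$modes[1, ] - x)), 1e-6)
})

test_that("two well-separated tones are split into one mode each", {
  t <- 0:511
  x <- cos(2 * pi * 5 * t / 512) + 0.8 * cos(2 * pi * 60 * t / 512)
  ms <- vmd(x, K = 2, alpha = 2000)
  # oracle: ideal FFT band-pass split at the spectral midpoint
  mid <- (5 / 512 + 60 / 512) / 2
  lo <- fft_bandpass(x, 1e-9, mid)      # exclude DC, keep the 5-cycle tone
  hi <- fft_bandpass(x, mid, 0.5 + 1e-9)
  expect_equal(ms$omegas, c(5 / 512, 60 / 512), tolerance = 2e-3)
  expect_gt(cor(ms$modes[1, ], lo), 0.99)
  expect_gt(cor(ms$modes[2, ], hi), 0.99)
})

test_that("mode sum reconstructs the definitions and the input signal", {
  expect_equal(reconstruct(list(modes = rbind(c(1, 2), c(3, 4)))), c(4, 6))
  r <- c(0.3, -1, 2, 5)
  expect_equal(reconstruct(list(modes = rbind(r))), r)
  expect_error(reconstruct(list(modes = NULL)), "empty")

  dat <- noiseless_mixture(m = 4, seed = 0)
  for (K in 3:7) {
    for (i in seq_len(4)) {
      x <- dat$X[i, ]
      ms <- vmd(x, K = K, alpha = 2000, tau = 0)
      expect_lt(sqrt(sum((x - reconstruct(ms))^2)) / sqrt(sum(x^2)), 0.05)
    }
  }
})

test_that("centre frequencies are sorted and stay in [0, 0.5]", {
  set.seed(42)
  for (rep in 1:5) {
    x <- as.vector(arima.sim(list(ar = 0.9), 128))
    ms <- vmd(x, K = 4, max_iter = 80, omega_init = "random", seed = rep)
    expect_true(all(diff(ms$omegas) >= 0))
    expect_true(all(ms$omegas >= 0 & ms$omegas <= 0.5))
    expect_identical(dim(ms$modes), c(4L, 128L))
  }
})

test_that("decomposition is deterministic for identical input and config", {
  x <- sin(seq(0, 10, length.out = 100)) + 0.1 * cos(seq(0, 90, length.out = 100))
  a <- vmd(x, K = 3, omega_init = "random", seed = 5)
  b <- vmd(x, K = 3, omega_init = "random", seed = 5)
  expect_identical(a$modes, b$modes)
  expect_identical(a$omegas, b$omegas)
})

test_that("modes scale linearly with signal amplitude at fixed iterations", {
  x <- noiseless_mixture(m = 1, seed = 2)$X[1, ]
  a <- vmd(x, K = 3, max_iter = 30, tol = 1e-30)
  b <- vmd(3.5 * x, K = 3, max_iter = 30, tol = 1e-30)
  expect_equal(b$modes, 3.5 * a$modes, tolerance = 1e-10)
  expect_equal(b$omegas, a$omegas, tolerance = 1e-12)
})

test_that("invalid inputs and over-decomposition are rejected", {
  expect_error(vmd(c(1, NA, 3, 4, 5, 6, 7, 8), K = 1), "finite")
  expect_error(vmd(rnorm(8), K = 5), "over-decomposition")
  expect_error(vmd(rnorm(4), K = 1), "length")
  expect_error(vmd(rnorm(16), K = 1, alpha = -1), "alpha")
})
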