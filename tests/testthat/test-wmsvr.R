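test_that("mode matrices recombine per-sample decompositions faithfully", {
  dat <- noiseless_mixture(m = 3, seed = 1)
  X <- dat$X[c(1, 2, 2), ]              # rows 2 and 3 identical

  stack <- build_mode_matrices(X, K = 3)
  ms1 <- vmd(X[1, ], K = 3)
  for (k in 1:3)
    expect_equal(stack$U[[k]][1, ], ms1$modes[k, ], tolerance = 1e-12)

  for (k in 1:3)
    expect_identical(stack$U[[k]][2, ], stack$U[[k]][3, ])

  # recombined modes still sum back to the spectra
  total <- Reduce(`+`, stack$U)
  rel <- sqrt(rowSums((X - total)^2) / rowSums(X^2))
  expect_true(all(rel <= 0.05))
})

test_that("ensemble weights follow the inverse-fourth-power law", {
  expect_equal(wmsvr_weights(rep(2.7, 5)), rep(1 / 5, 5))
  expect_equal(wmsvr_weights(c(1, 2)), c(16 / 17, 1 / 17))
  w <- wmsvr_weights(c(0.3, 0.7, 1.9), power = 4)
  expect_lt(abs(sum(w) - 1), 1e-12)
  expect_true(all(w >= 0))
  expect_warning(w0 <- wmsvr_weights(c(0, 1)), "zero RMSECV")
  expect_equal(w0, c(1, 0))
  expect_error(wmsvr_weights(c(-1, 2)), "nonnegative")
})

test_that("prediction is the weighted mean of sub-model predictions", {
  # two constant sub-models (2 and 4) with weights 3:1 predict 2.5
  const_model <- function(v) structure(
    list(b = 0, b0 = v, gamma = 1, sigma2 = 1,
         X_train = matrix(0, 1, 16), y_mean = v), class = "lssvr")
  fake <- structure(list(
    submodels = list(const_model(2), const_model(4)),
    weights = c(0.75, 0.25), rmsecv_per_mode = c(1, 2),
    cfg = list(K = 2L, alpha = 2000, tau = 0, tol = 1e-7, max_iter = 50L,
               omega_init = "uniform", seed = 0L, dc_mode = FALSE),
    gamma = 1, sigma2 = 1, weight_power = 4, n_train = 1L, n_vars = 16L
  ), class = "wmsvr")
  Xnew <- matrix(rnorm(32), 2, 16)
  expect_equal(predict(fake, Xnew), c(2.5, 2.5))
  fake$weights <- c(1, 0)
  expect_equal(predict(fake, Xnew), c(2, 2))
})

test_that("K = 1 ensemble equals plain LSSVR on the single mode matrix", {
  dat <- noiseless_mixture(m = 10, seed = 4)
  X <- dat$X; y <- dat$y
  fit <- wmsvr(X, y, K = 1, tau = 0, gamma = 50, sigma2 = 4)
  stack <- build_mode_matrices(X, K = 1, tau = 0)
  ref <- lssvr(stack$U[[1]], y, gamma = 50, sigma2 = 4)
  Xnew <- dat$X[c(3, 8), ]
  stack_new <- build_mode_matrices(Xnew, K = 1, tau = 0)
  expect_equal(predict(fit, Xnew), predict(ref, stack_new$U[[1]]),
               tolerance = 1e-10)
  expect_equal(fit$weights, 1)
})

test_that("permuting prediction rows permutes outputs identically", {
  dat <- noiseless_mixture(m = 12, seed = 5)
  fit <- wmsvr(dat$X[1:8, ], dat$y[1:8], K = 2, gamma = 50)
  Xnew <- dat$X[9:12, ]
  p <- c(3, 1, 4, 2)
  expect_equal(predict(fit, Xnew)[p], predict(fit, Xnew[p, ]),
               tolerance = 1e-12)
})

test_that("ensemble calibrates a linear mixture accurately end to end", {
  lib <- spectral_library("uvvis_oil_like", seed = 0)
  des <- sample_fractions(60, nrow(lib$pure_spectra), "dirichlet",
                          target_component = 1, seed = 0)
  dat <- synthesize_spectra(lib, des, noise_sd = 0.01, baseline_amp = 0,
                            nonlinearity = 0, seed = 0)
  sp <- kennard_stone(dat$X, 40)
  fit <- wmsvr(dat$X[sp$train, ], dat$y[sp$train], K = 3)
  r <- pearson_r(dat$y[sp$test], predict(fit, dat$X[sp$test, ]))
  expect_gte(r, 0.95)
})

test_that("mode-number selection scans, tie-breaks and degenerates correctly", {
  expect_identical(vmdcal:::pick_k(c(2, 3, 4, 5), c(5, 3, 3, 7)), 3)
  expect_identical(vmdcal:::pick_k(3, 1.4), 3)

  dat <- noiseless_mixture(m = 12, seed = 3)
  one <- select_k(dat$X, dat$y, K_range = 3, gamma = 50)
  expect_identical(one$K, 3L)
  expect_identical(nrow(one$curve), 1L)

  # slow composition bands plus an injected high-frequency nuisance:
  # more than one mode should pay off, and the argmin is a true minimum
  set.seed(3)
  nuis <- outer(runif(12, 0.2, 0.6),
                sin(2 * pi * 60 * seq_len(ncol(dat$X)) / ncol(dat$X)))
  Xn <- dat$X + nuis
  sel <- select_k(Xn, dat$y, K_range = 2:5, gamma = 50)
  expect_gte(sel$K, 2)
  expect_lte(sel$curve$error[sel$curve$K == sel$K],
             sel$curve$error[1])
  expect_lte(sel$curve$error[sel$curve$K == sel$K],
             sel$curve$error[nrow(sel$curve)])
  expect_error(select_k(dat$X, dat$y, K_range = integer(0)), "non-empty")
})
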