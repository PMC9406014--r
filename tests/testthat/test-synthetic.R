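test_that("component libraries are reproducible, nonnegative, unit-peak", {
  for (preset in c("uvvis_oil_like", "nir_herb_like")) {
    a <- spectral_library(preset, seed = 0)
    b <- spectral_library(preset, seed = 0)
    expect_identical(a, b)
    expect_true(all(a$pure_spectra >= 0))
    expect_equal(unname(apply(a$pure_spectra, 1, max)),
                 rep(1, nrow(a$pure_spectra)))
    # overlapping but distinguishable profiles
    cc <- cor(t(a$pure_spectra))
    offdiag <- cc[upper.tri(cc)]
    expect_true(all(offdiag > 0.2 & offdiag < 0.95))
  }
  lib <- spectral_library("uvvis_oil_like", seed = 0)
  expect_identical(length(lib$axis), 421L)
  lib2 <- spectral_library("nir_herb_like", seed = 0)
  expect_identical(length(lib2$axis), 1001L)
})

test_that("mixture designs live on the simplex", {
  d <- sample_fractions(40, 5, "dirichlet", seed = 2)
  expect_true(all(abs(rowSums(d$fractions) - 1) < 1e-12))
  expect_true(all(d$fractions >= 0))
  expect_identical(d$fractions, sample_fractions(40, 5, "dirichlet", seed = 2)$fractions)

  g <- sample_fractions(51, 4, "grid", target_component = 2)
  expect_equal(g$fractions[, 2], seq(0, 1, by = 0.02))
  expect_true(all(abs(rowSums(g$fractions) - 1) < 1e-12))
})

test_that("with corruptions off, spectra are exact convex combinations", {
  lib <- spectral_library("uvvis_oil_like", seed = 0)
  des <- sample_fractions(10, 6, "dirichlet", seed = 3)
  dat <- synthesize_spectra(lib, des, noise_sd = 0, baseline_amp = 0,
                            nonlinearity = 0, seed = 3)
  expect_equal(dat$X, des$fractions %*% lib$pure_spectra, tolerance = 1e-14)
  expect_equal(dat$y, 100 * des$fractions[, 1])

  # zero target fraction leaves no trace of the target profile
  g <- sample_fractions(11, 6, "grid", target_component = 1)
  datg <- synthesize_spectra(lib, g, noise_sd = 0, baseline_amp = 0,
                             nonlinearity = 0, seed = 0)
  x0 <- datg$X[1, ]                     # target fraction exactly 0
  beta <- qr.solve(t(lib$pure_spectra), x0)
  expect_lt(abs(beta[1]), 1e-10)
})

test_that("noiseless linear mixtures are exactly rank-limited", {
  lib <- spectral_library("uvvis_oil_like", seed = 0)
  c <- nrow(lib$pure_spectra)
  des <- sample_fractions(30, c, "dirichlet", seed = 4)
  dat <- synthesize_spectra(lib, des, noise_sd = 0, baseline_amp = 0,
                            nonlinearity = 0, seed = 4)
  sv <- svd(dat$X)$d
  expect_lte(sum(sv > 1e-9 * sv[1]), c)
  # the simplex constraint removes one degree of freedom: c-1 LVs suffice
  sp <- kennard_stone(dat$X, 20)
  fit <- pls_fit(dat$X[sp$train, ], dat$y[sp$train], ncomp = c - 1)
  expect_lt(rmsep(dat$y[sp$test], predict(fit, dat$X[sp$test, ])), 1e-8)
})

test_that("generator output is seed-reproducible with all corruptions on", {
  lib <- spectral_library("nir_herb_like", seed = 0)
  des <- sample_fractions(8, 4, "dirichlet", seed = 5)
  a <- synthesize_spectra(lib, des, seed = 7)
  b <- synthesize_spectra(lib, des, seed = 7)
  expect_identical(a$X, b$X)
  d <- synthesize_spectra(lib, des, seed = 8)
  expect_false(identical(a$X, d$X))
})

test_that("the default benchmark supports a strong PLS baseline", {
  dat <- synthetic_benchmark(seed = 0)
  sp <- kennard_stone(dat$X, 50)
  lv <- select_lv_mccv_ftest(dat$X[sp$train, ], dat$y[sp$train], max_lv = 8)
  fit <- pls_fit(dat$X[sp$train, ], dat$y[sp$train], ncomp = lv)
  r <- pearson_r(dat$y[sp$test], predict(fit, dat$X[sp$test, ]))
  expect_gt(r, 0.9)
})
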