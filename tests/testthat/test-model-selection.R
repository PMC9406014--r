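test_that("Kennard-Stone picks extremes first, then max-min candidates", {
  X <- matrix(0:10, ncol = 1)
  expect_setequal(kennard_stone(X, 2)$train, c(1, 11))   # points 0 and 10
  ks3 <- kennard_stone(X, 3)
  expect_setequal(ks3$train, c(1, 11, 6))                # adds the midpoint 5
  expect_setequal(ks3$test, setdiff(1:11, ks3$train))

  all_in <- kennard_stone(X, 11)
  expect_setequal(all_in$train, 1:11)
  expect_identical(all_in$test, integer(0))

  expect_warning(kennard_stone(matrix(1, 4, 2), 2), "identical")
})

test_that("Kennard-Stone matches the brute-force max-min oracle", {
  set.seed(100)
  for (rep in 1:10) {
    m <- sample(5:20, 1)
    X <- matrix(rnorm(2 * m), m, 2)
    n_train <- sample(2:(m - 1), 1)
    expect_setequal(kennard_stone(X, n_train)$train, ks_oracle(X, n_train))
  }
})

test_that("Kennard-Stone is permutation-covariant", {
  set.seed(101)
  X <- matrix(rnorm(30), 15, 2)
  p <- sample(15)
  sel <- kennard_stone(X, 6)$train
  sel_p <- kennard_stone(X[p, ], 6)$train
  expect_setequal(match(sel, p), sel_p)
})

test_that("PSO minimises the sphere and is fully seeded", {
  sphere <- function(th) sum(th^2)
  res <- pso_optimize(sphere, c(-5, -5), c(5, 5), swarm_size = 20,
                      n_iter = 50, seed = 7)
  expect_lt(res$value, 1e-3)
  expect_true(all(diff(res$trace) <= 0))

  res2 <- pso_optimize(sphere, c(-5, -5), c(5, 5), swarm_size = 20,
                       n_iter = 50, seed = 7)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$par, res2$par)

  flat <- pso_optimize(function(th) 4.2, c(0, 0), c(1, 1), n_iter = 5, seed = 1)
  expect_identical(flat$value, 4.2)
  expect_true(all(flat$par >= 0 & flat$par <= 1))

  # non-finite objective values do not halt the search
  spiky <- function(th) if (th[1] < 0) NaN else sum(th^2)
  resp <- pso_optimize(spiky, -5, 5, n_iter = 30, seed = 2)
  expect_true(is.finite(resp$value))
})

test_that("prediction metrics evaluate their formulas", {
  expect_identical(rmsep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rmsep(c(0, 0), c(1, 1)), 1)
  expect_equal(rmsep(c(0, 3), c(4, 3)), 2 * sqrt(2))
  expect_error(rmsep(numeric(0), numeric(0)), "nonzero")

  y <- c(1, 2, 3)
  expect_equal(pearson_r(y, 2 * y + 1), 1)
  expect_equal(pearson_r(y, -y), -1)
  yh <- c(1, 2, 4)
  manual <- sum((y - mean(y)) * (yh - mean(yh))) /
    sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(pearson_r(y, yh), manual, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1), c(1, 2)), "zero variance")
})

test_that("LSSVR tuning improves on an untuned width", {
  dat <- noiseless_mixture(m = 16, seed = 8)
  folds <- cv_folds(16, "kfold", k = 4, seed = 1)
  tuned <- tune_lssvr(dat$X, dat$y, folds = folds, swarm_size = 8,
                      n_iter = 10, seed = 3)
  base <- rmsecv(dat$X, dat$y, gamma = 100, folds = folds)
  expect_lte(tuned$value, base + 1e-9)
  expect_true(tuned$gamma > 0 && tuned$sigma2 > 0)
})
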