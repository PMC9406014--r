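#' Kennard-Stone sample partitioning
#'
#' Deterministic max-min-distance selection of a representative training
#' set: start from the two samples farthest apart (Euclidean distance on
#' the raw spectra), then repeatedly add the candidate whose minimum
#' distance to the already-selected set is largest. Ties break towards the
#' lowest row index. The remaining samples form the prediction set.
#'
#' @param X numeric matrix, m x n.
#' @param n_train number of training samples to select (2..m).
#' @return list with integer vectors `train` and `test` (disjoint, covering
#'   `1..m`; `train` in selection order).
#' @export
kennard_stone <- function(X, n_train) {
  X <- check_matrix(X)
  m <- nrow(X)
  n_train <- as.integer(n_train)
  if (n_train < 2 || n_train > m)
    stop_config("'n_train' must be between 2 and nrow(X)")

  D <- as.matrix(stats::dist(X))
  if (max(D) == 0)
    warning("all samples identical: Kennard-Stone selection is arbitrary (deterministic by index)")

  # farthest pair, lowest indices on ties
  hit <- which(D == max(D), arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  if (nrow(hit) == 0) hit <- matrix(c(1L, 2L), 1)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- as.integer(hit[1, ])

  remaining <- setdiff(seq_len(m), sel)
  while (length(sel) < n_train) {
    dmin <- apply(D[remaining, sel, drop = FALSE], 1, min)
    pick <- remaining[which.max(dmin)]    # which.max -> first (lowest index) on ties
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(train = sel, test = remaining)
}

#' Particle swarm optimisation over a box
#'
#' Global-best PSO: velocities combine inertia (linearly scheduled from
#' `inertia[1]` to `inertia[2]`), a cognitive pull towards each particle's
#' personal best and a social pull towards the swarm best. Velocities are
#' clamped to the box width and positions clipped to the bounds. A particle
#' whose objective evaluates non-finite gets value `+Inf` and the search
#' continues. Fully seeded: identical seeds give identical traces.
#'
#' @param objective function of a numeric parameter vector returning a
#'   scalar to minimise.
#' @param lower,upper numeric bound vectors (finite, `lower < upper`).
#' @param swarm_size particles. Default 20.
#' @param n_iter iterations. Default 50.
#' @param inertia length-2 start/end inertia weights. Default `c(0.9, 0.4)`.
#' @param c1,c2 cognitive and social acceleration constants. Default 2.
#' @param seed RNG seed.
#' @return list with `par` (best position), `value` (best objective), and
#'   `trace` (best value after each iteration, non-increasing).
#' @export
pso_optimize <- function(objective, lower, upper, swarm_size = 20,
                         n_iter = 50, inertia = c(0.9, 0.4), c1 = 2, c2 = 2,
                         seed = 1L) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  d <- length(lower)
  if (length(upper) != d || !all(is.finite(c(lower, upper))) ||
      any(lower >= upper))
    stop_config("bounds must be finite with lower < upper")

  eval1 <- function(p) {
    v <- tryCatch(objective(p), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  width <- upper - lower
  pos <- matrix(stats::runif(swarm_size * d), swarm_size, d)
  pos <- sweep(sweep(pos, 2, width, "*"), 2, lower, "+")
  vel <- matrix(stats::runif(swarm_size * d, -1, 1), swarm_size, d)
  vel <- sweep(vel, 2, width, "*") * 0.1

  pval <- apply(pos, 1, eval1)
  pbest <- pos
  pbest_val <- pval
  g <- which.min(pbest_val)
  gbest <- pbest[g, ]
  gbest_val <- pbest_val[g]

  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    w <- inertia[1] + (inertia[2] - inertia[1]) * (it - 1) / max(n_iter - 1, 1)
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    vel <- w * vel +
      c1 * r1 * (pbest - pos) +
      c2 * r2 * (matrix(gbest, swarm_size, d, byrow = TRUE) - pos)
    vel <- pmin(pmax(vel, matrix(-width, swarm_size, d, byrow = TRUE)),
                matrix(width, swarm_size, d, byrow = TRUE))
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lower, swarm_size, d, byrow = TRUE)),
                matrix(upper, swarm_size, d, byrow = TRUE))
    val <- apply(pos, 1, eval1)
    improved <- val < pbest_val
    pbest[improved, ] <- pos[improved, , drop = FALSE]
    pbest_val[improved] <- val[improved]
    g <- which.min(pbest_val)
    if (pbest_val[g] < gbest_val) {
      gbest <- pbest[g, ]
      gbest_val <- pbest_val[g]
    }
    trace[it] <- gbest_val
  }
  list(par = gbest, value = gbest_val, trace = trace)
}

#' Tune LSSVR hyperparameters by particle swarm search
#'
#' Searches \eqn{(\gamma, \sigma^2)} on a log10 scale over
#' \eqn{[10^{-2}, 10^4]^2} by default. The default objective is the
#' training-set RMSECV (leak-free); with `validation_mode = TRUE` and a held-out
#' set supplied, the prediction-set RMSEP is minimised instead — that
#' mirrors the original protocol but leaks the test set into tuning, so it
#' is not the default.
#'
#' @inheritParams lssvr
#' @param X_val,y_val held-out set for `validation_mode`.
#' @param log10_bounds 2 x 2 matrix of log10 bounds, rows = (gamma, sigma2).
#' @param folds CV folds for the default objective.
#' @param validation_mode tune against the held-out set instead of CV.
#' @param ... further arguments passed to [pso_optimize()].
#' @return list with `gamma`, `sigma2`, `value`, and the PSO `trace`.
#' @export
tune_lssvr <- function(X, y, X_val = NULL, y_val = NULL,
                       log10_bounds = matrix(c(-2, 4, -2, 4), 2, byrow = TRUE),
                       folds = NULL, validation_mode = FALSE, ...) {
  X <- check_matrix(X)
  if (validation_mode && (is.null(X_val) || is.null(y_val)))
    stop_config("validation_mode = TRUE requires X_val and y_val")
  if (is.null(folds)) folds <- cv_folds(nrow(X))
  obj <- function(theta) {
    gamma <- 10^theta[1]; sigma2 <- 10^theta[2]
    if (validation_mode) {
      fit <- lssvr(X, y, gamma = gamma, sigma2 = sigma2)
      rmsep(y_val, predict(fit, X_val))
    } else {
      rmsecv(X, y, gamma = gamma, sigma2 = sigma2, folds = folds)
    }
  }
  res <- pso_optimize(obj, lower = log10_bounds[, 1], upper = log10_bounds[, 2], ...)
  list(gamma = 10^res$par[1], sigma2 = 10^res$par[2],
       value = res$value, trace = res$trace)
}

#' Root mean square error of prediction
#'
#' @param y,yhat numeric vectors of equal nonzero length.
#' @return \eqn{\sqrt{\mathrm{mean}((y - \hat y)^2)}}.
#' @export
rmsep <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat))
    stop_invalid("'y' and 'yhat' must have equal nonzero length")
  sqrt(mean((y - yhat)^2))
}

#' Pearson correlation between prepared and predicted values
#'
#' @param y,yhat numeric vectors, length >= 2, both with nonzero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(y, yhat) {
  if (length(y) < 2 || length(y) != length(yhat))
    stop_invalid("'y' and 'yhat' must have equal length >= 2")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop_invalid("correlation undefined: zero variance")
  stats::cor(y, yhat)
}
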