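#' Partial least squares regression (univariate y, NIPALS)
#'
#' Mean-centres `X` and `y`, then extracts latent variables by the NIPALS
#' algorithm with deflation of `X` and `y` after each component. For a
#' single response the weight vector of each component is the (normalised)
#' covariance direction `t(X) %*% y`. Regression coefficients are stored
#' cumulatively for every rank up to `ncomp`, so one fit serves all smaller
#' models.
#'
#' @param X numeric matrix, m x n.
#' @param y numeric response vector of length m.
#' @param ncomp number of latent variables, at most `min(m - 1, n)`.
#' @return An object of class `"pls_fit"` with score/weight/loading
#'   matrices `T`, `W`, `P`, response loadings `q`, coefficient paths
#'   `coefficients` (n x ncomp), `x_mean`, `y_mean`, `ncomp`.
#' @export
pls_fit <- function(X, y, ncomp) {
  X <- check_matrix(X)
  y <- as.numeric(y)
  m <- nrow(X); n <- ncol(X)
  if (length(y) != m) stop_invalid("length(y) must equal nrow(X)")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1) stop_config("'ncomp' must be >= 1")
  if (ncomp > min(m - 1, n))
    stop_config(sprintf("'ncomp' = %d exceeds the rank bound min(m-1, n) = %d",
                        ncomp, min(m - 1, n)))

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean

  W <- matrix(0, n, ncomp)
  P <- matrix(0, n, ncomp)
  Tm <- matrix(0, m, ncomp)
  q <- numeric(ncomp)
  scale0 <- sqrt(sum(E^2)) * sqrt(sum(f^2)) + 1e-300
  ncomp_eff <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-14 * scale0) break        # X-y covariance exhausted
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    if (tt <= (1e-14 * scale0)^2) break    # deflated X has no energy left
    p <- crossprod(E, t_a) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p)
    f <- f - q[a] * t_a
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t_a
    ncomp_eff <- a
  }

  # B_l = W_l (P_l' W_l)^-1 q_l for every rank l; P'W is unit upper
  # triangular, so the full-rank inverse yields all partial-rank vectors
  B <- matrix(0, n, ncomp)
  if (ncomp_eff > 0) {
    i <- seq_len(ncomp_eff)
    R <- W[, i, drop = FALSE] %*%
      solve(crossprod(P[, i, drop = FALSE], W[, i, drop = FALSE]))
    acc <- numeric(n)
    for (a in i) {
      acc <- acc + R[, a] * q[a]
      B[, a] <- acc
    }
    if (ncomp_eff < ncomp)
      B[, (ncomp_eff + 1L):ncomp] <- B[, ncomp_eff]
  }

  structure(list(coefficients = B, W = W, P = P, T = Tm, q = q,
                 x_mean = x_mean, y_mean = y_mean, ncomp = ncomp,
                 ncomp_eff = ncomp_eff),
            class = "pls_fit")
}

#' Predict from a PLS fit
#'
#' @param object a `"pls_fit"`.
#' @param newdata numeric matrix with the training column count.
#' @param ncomp rank(s) at which to predict; default the fitted maximum.
#' @param ... unused.
#' @return a vector (single `ncomp`) or matrix (one column per rank).
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- check_matrix(newdata, "newdata")
  if (ncol(newdata) != length(object$x_mean))
    stop_invalid("newdata column count does not match the fit")
  if (any(ncomp < 1 | ncomp > object$ncomp))
    stop_config("'ncomp' out of fitted range")
  Xc <- sweep(newdata, 2, object$x_mean)
  out <- Xc %*% object$coefficients[, ncomp, drop = FALSE] + object$y_mean
  if (length(ncomp) == 1) drop(out) else out
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("PLS (NIPALS): %d latent variables, %d variables, %d samples\n",
              x$ncomp, nrow(x$coefficients), nrow(x$T)))
  invisible(x)
}

#' @export
coef.pls_fit <- function(object, ncomp = object$ncomp, ...) {
  object$coefficients[, ncomp]
}

#' Latent-variable selection by Monte Carlo CV and an F-test
#'
#' For each rank `1..max_lv`, the cross-validated RMSE is estimated from
#' `n_splits` random train/validation splits (a fraction `split_frac` held
#' out each time, fixed seed). Let \eqn{\ell^*} be the rank with minimum
#' RMSECV. The selected rank is the smallest \eqn{\ell} whose variance
#' ratio \eqn{\mathrm{RMSECV}(\ell)^2 / \mathrm{RMSECV}(\ell^*)^2} stays
#' below the F critical value at level `alpha_f`, with degrees of freedom
#' equal to the total number of held-out predictions on both sides — the
#' parsimony convention of Haaland and Thomas: take the simplest model not
#' significantly worse than the best.
#'
#' @inheritParams pls_fit
#' @param max_lv largest candidate rank.
#' @param n_splits number of Monte Carlo splits. Default 50.
#' @param split_frac fraction of samples held out per split. Default 0.2.
#' @param alpha_f significance level of the F criterion. Default 0.25.
#' @param seed split-generation seed.
#' @return the selected number of latent variables (integer), with the
#'   RMSECV curve attached as attribute `"rmsecv"`.
#' @export
select_lv_mccv_ftest <- function(X, y, max_lv, n_splits = 50,
                                 split_frac = 0.2, alpha_f = 0.25,
                                 seed = 1L) {
  X <- check_matrix(X)
  y <- as.numeric(y)
  m <- nrow(X)
  max_lv <- as.integer(max_lv)
  if (max_lv < 1) stop_config("'max_lv' must be >= 1")
  if (n_splits < 2) stop_config("'n_splits' must be >= 2")
  h <- round(split_frac * m)
  if (h < 1 || m - h < max_lv + 1)
    stop_config("degenerate split sizes for the requested 'max_lv'")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  splits <- replicate(n_splits, sample.int(m, h), simplify = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  sse <- numeric(max_lv)
  n_pred <- 0L
  for (f in splits) {
    fit <- pls_fit(X[-f, , drop = FALSE], y[-f], ncomp = max_lv)
    pred <- predict(fit, X[f, , drop = FALSE], ncomp = seq_len(max_lv))
    pred <- matrix(pred, nrow = length(f))
    sse <- sse + colSums((y[f] - pred)^2)
    n_pred <- n_pred + length(f)
  }
  rmse <- sqrt(sse / n_pred)
  l_star <- which.min(rmse)
  crit <- stats::qf(1 - alpha_f, n_pred, n_pred)
  denom <- max(rmse[l_star]^2, 1e-300)
  ok <- (rmse^2 / denom) < crit
  sel <- which(ok)[1]
  if (is.na(sel)) sel <- l_star       # crit = 1 at alpha_f = 0.5: keep the argmin
  structure(as.integer(sel), rmsecv = rmse)
}
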