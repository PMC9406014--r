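#' Gaussian radial basis function kernel
#'
#' \eqn{k(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))}.
#'
#' @param xi,xj numeric vectors of equal length.
#' @param sigma2 kernel width parameter \eqn{\sigma^2} (> 0).
#' @return a scalar in (0, 1].
#' @export
rbf_kernel <- function(xi, xj, sigma2) {
  if (length(xi) != length(xj)) stop_invalid("'xi' and 'xj' must have equal length")
  if (!all(is.finite(xi)) || !all(is.finite(xj)))
    stop_invalid("kernel inputs must be finite")
  if (!is.numeric(sigma2) || sigma2 <= 0) stop_config("'sigma2' must be > 0")
  exp(-sum((xi - xj)^2) / (2 * sigma2))
}

# Gram matrix between the rows of X and X2 (defaults to X vs itself).
rbf_gram <- function(X, X2 = X, sigma2) {
  d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma2))
}

# Median of squared pairwise distances between training rows: the standard
# width heuristic used when sigma2 is not supplied.
median_heuristic <- function(X) {
  m <- nrow(X)
  if (m < 2) return(1)
  d2 <- as.vector(stats::dist(X))^2
  s <- stats::median(d2[d2 > 0])
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Least-squares support vector regression
#'
#' Fits LSSVR with the RBF kernel by one dense symmetric solve of
#' \deqn{\begin{bmatrix} 0 & 1^T \\ 1 & K + \gamma^{-1} I \end{bmatrix}
#'       \begin{bmatrix} b_0 \\ b \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ y \end{bmatrix}}
#' where \eqn{K} is the kernel Gram matrix of the training rows. The first
#' row of the system forces \eqn{\sum_i b_i = 0}. The prediction function is
#' \eqn{f(x) = b_0 + \sum_i b_i k(x, x_i)}.
#'
#' Targets are centred internally for conditioning and the centring exactly
#' inverted on prediction; the stored `b0` is on the original scale of `y`.
#'
#' @param X numeric matrix, m x n (rows = samples, columns = wavelengths).
#' @param y numeric target vector of length m (e.g. adulterant mass %).
#' @param gamma regularisation weight \eqn{\gamma} (> 0). Default 100.
#' @param sigma2 RBF width \eqn{\sigma^2}; if `NULL` (default) the median of
#'   squared pairwise training distances is used.
#'
#' @return An object of class `"lssvr"` with elements `b` (support
#'   coefficients, summing to zero), `b0`, `gamma`, `sigma2`, `X_train`,
#'   `y_mean`.
#'
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' y <- rowSums(X) + rnorm(8, sd = 0.1)
#' fit <- lssvr(X, y, gamma = 100, sigma2 = 10)
#' predict(fit, X)
#' @export
lssvr <- function(X, y, gamma = 100, sigma2 = NULL) {
  X <- check_matrix(X)
  y <- as.numeric(y)
  if (!all(is.finite(y))) stop_invalid("'y' must be finite")
  m <- nrow(X)
  if (length(y) != m) stop_invalid("length(y) must equal nrow(X)")
  if (!is.numeric(gamma) || gamma <= 0 || !is.finite(gamma))
    stop_config("'gamma' must be a positive finite number")
  if (is.null(sigma2)) sigma2 <- median_heuristic(X)
  if (sigma2 <= 0 || !is.finite(sigma2)) stop_config("'sigma2' must be > 0")

  y_mean <- mean(y)
  yc <- y - y_mean

  G <- rbf_gram(X, sigma2 = sigma2)
  A <- matrix(0, m + 1, m + 1)
  A[1, 2:(m + 1)] <- 1
  A[2:(m + 1), 1] <- 1
  A[2:(m + 1), 2:(m + 1)] <- G + diag(1 / gamma, m)
  sol <- tryCatch(solve(A, c(0, yc)),
                  error = function(e) stop_numerical(paste0(
                    "LSSVR system is numerically singular (", conditionMessage(e),
                    "); consider decreasing gamma")))

  structure(list(
    b = sol[-1], b0 = sol[1] + y_mean,
    gamma = gamma, sigma2 = sigma2,
    X_train = X, y_mean = y_mean
  ), class = "lssvr")
}

#' Predict from a fitted LSSVR model
#'
#' @param object an `"lssvr"` fit.
#' @param newdata numeric matrix with the same number of columns as the
#'   training spectra.
#' @param ... unused.
#' @return numeric vector of predictions, one per row of `newdata`.
#' @export
predict.lssvr <- function(object, newdata, ...) {
  newdata <- check_matrix(newdata, "newdata")
  if (ncol(newdata) != ncol(object$X_train))
    stop_invalid(sprintf("newdata has %d columns; model was trained on %d",
                         ncol(newdata), ncol(object$X_train)))
  Kx <- rbf_gram(newdata, object$X_train, sigma2 = object$sigma2)
  drop(Kx %*% object$b) + object$b0
}

#' @export
print.lssvr <- function(x, ...) {
  cat(sprintf("LSSVR: %d support samples, %d variables; gamma = %g, sigma2 = %g\n",
              nrow(x$X_train), ncol(x$X_train), x$gamma, x$sigma2))
  invisible(x)
}

#' @export
coef.lssvr <- function(object, ...) c(b0 = object$b0, b = object$b)

#' @export
residuals.lssvr <- function(object, ...) {
  # fitted values on the stored training spectra vs the (re-centred) targets
  # are not stored; recompute from the system: y = f(X_train) + b/gamma
  object$b / object$gamma
}

#' Cross-validation fold assignment
#'
#' `scheme = "auto"` uses leave-one-out for m <= 60 samples and seeded
#' 10-fold otherwise — datasets in this application are tens of samples.
#'
#' @param m number of samples.
#' @param scheme `"auto"`, `"loo"`, or `"kfold"`.
#' @param k number of folds for `"kfold"`.
#' @param seed seed for the fold shuffle.
#' @return list of integer index vectors, one per held-out fold.
#' @export
cv_folds <- function(m, scheme = c("auto", "loo", "kfold"), k = 10, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "auto") scheme <- if (m <= 60) "loo" else "kfold"
  if (scheme == "loo") return(as.list(seq_len(m)))
  k <- min(as.integer(k), m)
  if (k < 2) stop_config("'k' must be >= 2 for k-fold CV")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  idx <- sample.int(m)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  split(idx, rep_len(seq_len(k), m))
}

#' Root mean square error of cross-validation for LSSVR
#'
#' Each fold is held out once, the model refit on the remainder, and the
#' pooled held-out squared errors averaged:
#' \eqn{\mathrm{RMSECV} = \sqrt{\frac{1}{m}\sum_i (y_i - \hat y_{-i})^2}}.
#'
#' @inheritParams lssvr
#' @param folds a list of held-out index vectors (see [cv_folds()]), or
#'   `NULL` for the `"auto"` scheme.
#' @return nonnegative scalar.
#' @export
rmsecv <- function(X, y, gamma = 100, sigma2 = NULL, folds = NULL) {
  X <- check_matrix(X)
  m <- nrow(X)
  if (is.null(folds)) folds <- cv_folds(m)
  if (is.null(sigma2)) sigma2 <- median_heuristic(X)
  held <- sort(unique(unlist(folds)))
  if (!identical(held, seq_len(m)))
    stop_invalid("'folds' must partition 1..m")
  if (any(vapply(folds, length, 1L) >= m))
    stop_invalid("a fold equal to the full sample set leaves nothing to train on")
  se <- numeric(0)
  for (f in folds) {
    fit <- lssvr(X[-f, , drop = FALSE], y[-f], gamma = gamma, sigma2 = sigma2)
    se <- c(se, (y[f] - predict(fit, X[f, , drop = FALSE]))^2)
  }
  sqrt(mean(se))
}
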