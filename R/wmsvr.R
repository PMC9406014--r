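#' Decompose every spectrum and recombine modes into mode matrices
#'
#' Applies [vmd()] independently to each row of `X` and recombines the
#' results: the k-th (frequency-sorted) mode of sample i becomes row i of
#' mode matrix \eqn{U_k}, so each \eqn{U_k} has the same number of samples
#' and variables as `X`. Sorting modes by ascending centre frequency makes
#' "mode k" comparable across samples.
#'
#' @param X numeric matrix, m x n.
#' @param K number of modes per spectrum.
#' @param ... further arguments passed to [vmd()] (`alpha`, `tau`, ...).
#' @return An object of class `"mode_stack"`: list with `U` (list of K
#'   m x n matrices), `omegas` (m x K matrix of per-sample centre
#'   frequencies), and the decomposition configuration.
#' @export
build_mode_matrices <- function(X, K, ...) {
  X <- check_matrix(X)
  m <- nrow(X); n <- ncol(X)
  U <- replicate(K, matrix(0, m, n), simplify = FALSE)
  omegas <- matrix(0, m, K)
  cfg <- NULL
  for (i in seq_len(m)) {
    ms <- tryCatch(vmd(X[i, ], K = K, ...), error = function(e)
      stop_invalid(sprintf("decomposition failed for sample %d: %s",
                           i, conditionMessage(e))))
    for (k in seq_len(K)) U[[k]][i, ] <- ms$modes[k, ]
    omegas[i, ] <- ms$omegas
    if (is.null(cfg))
      cfg <- ms[c("K", "alpha", "tau", "tol", "max_iter", "omega_init",
                  "seed", "dc_mode")]
  }
  structure(list(U = U, omegas = omegas, cfg = cfg), class = "mode_stack")
}

#' Sub-model weights from cross-validation errors
#'
#' Weights are proportional to the inverse fourth power of each sub-model's
#' RMSECV, renormalised to sum to 1: accurate sub-models dominate, noisy
#' high-frequency modes are down-weighted steeply. A sub-model with zero
#' cross-validation error receives all the weight (with a warning), since
#' the inverse power is unbounded there.
#'
#' @param rmsecv_k vector of per-mode cross-validation errors (>= 0).
#' @param power the inverse-power exponent; default 4.
#' @return nonnegative weight vector summing to 1.
#' @export
wmsvr_weights <- function(rmsecv_k, power = 4) {
  if (length(rmsecv_k) == 0 || any(rmsecv_k < 0) || any(!is.finite(rmsecv_k)))
    stop_invalid("'rmsecv_k' must be finite and nonnegative")
  zero <- rmsecv_k == 0
  if (any(zero)) {
    warning("sub-model with zero RMSECV: it receives all the weight")
    w <- as.numeric(zero)
    return(w / sum(w))
  }
  w <- rmsecv_k^(-power)
  w / sum(w)
}

#' Weighted multiscale support vector regression
#'
#' The VMD-WMSVR calibration model. Each training spectrum is decomposed
#' into `K` narrow-band modes by variational mode decomposition; the k-th
#' modes of all samples are recombined into a mode matrix \eqn{U_k}; one
#' LSSVR sub-model is fitted per \eqn{(U_k, y)}; and predictions are
#' combined by a weighted average with weights proportional to
#' \eqn{\mathrm{RMSECV}_k^{-4}} (normalised). Cross-validation folds are
#' shared across the K sub-models so the weights compare like with like.
#'
#' All sub-models share one \eqn{(\gamma, \sigma^2)} pair. When `sigma2` is
#' `NULL`, the median heuristic is evaluated once on the raw training
#' spectra and reused for every sub-model.
#'
#' @inheritParams lssvr
#' @param K number of VMD modes (sub-models). Default 5.
#' @param alpha,tau,tol,max_iter,omega_init,seed,dc_mode decomposition
#'   settings, see [vmd()].
#' @param cv fold scheme for the sub-model weights, see [cv_folds()].
#' @param folds explicit fold list overriding `cv`.
#' @param weight_power inverse-power exponent for the weights. Default 4.
#'
#' @return An object of class `"wmsvr"`: list with `submodels` (K `"lssvr"`
#'   fits), `weights`, `rmsecv_per_mode`, the VMD configuration `cfg`, and
#'   `gamma`, `sigma2`.
#'
#' @examples
#' lib <- spectral_library("uvvis_oil_like", seed = 0)
#' des <- sample_fractions(24, nrow(lib$pure_spectra), "dirichlet", seed = 0)
#' dat <- synthesize_spectra(lib, des, seed = 0)
#' fit <- wmsvr(dat$X, dat$y, K = 3)
#' fit
#' @export
wmsvr <- function(X, y, K = 5, alpha = 2000, tau = 0, tol = 1e-7,
                  max_iter = 500, omega_init = "uniform", seed = 0L,
                  dc_mode = FALSE, gamma = 100, sigma2 = NULL,
                  cv = "auto", folds = NULL, weight_power = 4) {
  X <- check_matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_invalid("length(y) must equal nrow(X)")
  if (K > ncol(X) / 2) stop_config("K exceeds n/2: over-decomposition")

  stack <- build_mode_matrices(X, K = K, alpha = alpha, tau = tau, tol = tol,
                               max_iter = max_iter, omega_init = omega_init,
                               seed = seed, dc_mode = dc_mode)
  if (is.null(sigma2)) sigma2 <- median_heuristic(X)
  if (is.null(folds)) folds <- cv_folds(nrow(X), scheme = cv)

  submodels <- vector("list", K)
  cv_err <- numeric(K)
  for (k in seq_len(K)) {
    submodels[[k]] <- lssvr(stack$U[[k]], y, gamma = gamma, sigma2 = sigma2)
    cv_err[k] <- rmsecv(stack$U[[k]], y, gamma = gamma, sigma2 = sigma2,
                        folds = folds)
  }
  structure(list(
    submodels = submodels,
    weights = wmsvr_weights(cv_err, power = weight_power),
    rmsecv_per_mode = cv_err,
    cfg = stack$cfg,
    train_omegas = stack$omegas,
    gamma = gamma, sigma2 = sigma2, weight_power = weight_power,
    n_train = nrow(X), n_vars = ncol(X)
  ), class = "wmsvr")
}

#' Predict adulterant content from new spectra
#'
#' New spectra are decomposed and recombined with the same VMD
#' configuration as the training set; each sub-model predicts from its mode
#' matrix and the predictions are averaged with the ensemble weights:
#' \eqn{\hat y = \sum_k w_k \hat y_k}.
#'
#' @param object a `"wmsvr"` fit.
#' @param newdata numeric matrix, p x n (same wavelength grid as training).
#' @param ... unused.
#' @return numeric vector of length p.
#' @export
predict.wmsvr <- function(object, newdata, ...) {
  newdata <- check_matrix(newdata, "newdata")
  if (ncol(newdata) != object$n_vars)
    stop_invalid(sprintf("newdata has %d columns; model was trained on %d",
                         ncol(newdata), object$n_vars))
  cfg <- object$cfg
  stack <- build_mode_matrices(newdata, K = cfg$K, alpha = cfg$alpha,
                               tau = cfg$tau, tol = cfg$tol,
                               max_iter = cfg$max_iter,
                               omega_init = cfg$omega_init, seed = cfg$seed,
                               dc_mode = cfg$dc_mode)
  yhat <- numeric(nrow(newdata))
  for (k in seq_len(cfg$K))
    yhat <- yhat + object$weights[k] * predict(object$submodels[[k]], stack$U[[k]])
  yhat
}

#' @export
print.wmsvr <- function(x, ...) {
  cat(sprintf("VMD-WMSVR ensemble: K = %d sub-models, %d training samples, %d variables\n",
              x$cfg$K, x$n_train, x$n_vars))
  cat(sprintf("  gamma = %g, sigma2 = %g, weight exponent = %g\n",
              x$gamma, x$sigma2, x$weight_power))
  cat("  weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.wmsvr <- function(x, ...) {
  graphics::barplot(x$weights, names.arg = signif(colMeans(x$train_omegas), 2),
                    xlab = "mean centre frequency (cycles/sample)",
                    ylab = "ensemble weight", ...)
  invisible(x)
}

#' @export
summary.wmsvr <- function(object, ...) {
  tab <- data.frame(
    mode = seq_along(object$weights),
    mean_omega = colMeans(object$train_omegas),
    rmsecv = object$rmsecv_per_mode,
    weight = object$weights
  )
  structure(list(table = tab, cfg = object$cfg,
                 gamma = object$gamma, sigma2 = object$sigma2),
            class = "summary.wmsvr")
}

#' @export
print.summary.wmsvr <- function(x, ...) {
  cat("VMD-WMSVR sub-model summary\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Choose the mode number K by an error scan
#'
#' Fits one ensemble per candidate `K` and evaluates a prediction-error
#' criterion; the `K` with the minimum criterion wins, ties broken towards
#' the smaller `K` (parsimony). The default criterion is the
#' cross-validated error of the weighted ensemble on the training set
#' (leak-free). With `validation_mode = TRUE` and a held-out set supplied, the
#' scan instead minimises RMSEP on that set — this mirrors the original
#' protocol of scanning K against the prediction set, which leaks the test
#' set into model selection and is therefore not the default.
#'
#' @inheritParams wmsvr
#' @param K_range integer vector of candidate mode numbers (each >= 2,
#'   at most n/2).
#' @param X_val,y_val held-out spectra and targets; required when
#'   `validation_mode = TRUE`.
#' @param validation_mode scan against the held-out set instead of CV.
#' @return list with `K` (the selected mode number) and `curve`
#'   (data.frame of K vs criterion value).
#' @export
select_k <- function(X, y, K_range, X_val = NULL, y_val = NULL,
                     validation_mode = FALSE, alpha = 2000, tau = 0, tol = 1e-7,
                     max_iter = 500, omega_init = "uniform", seed = 0L,
                     dc_mode = FALSE, gamma = 100, sigma2 = NULL,
                     cv = "auto", weight_power = 4) {
  if (length(K_range) == 0) stop_invalid("'K_range' must be non-empty")
  K_range <- sort(unique(as.integer(K_range)))
  X <- check_matrix(X)
  if (any(K_range < 1) || any(K_range > ncol(X) / 2))
    stop_config("K_range must lie within [1, n/2]")
  if (validation_mode && (is.null(X_val) || is.null(y_val)))
    stop_config("validation_mode = TRUE requires X_val and y_val")
  folds <- cv_folds(nrow(X), scheme = cv)
  err <- numeric(length(K_range))
  for (j in seq_along(K_range)) {
    if (validation_mode) {
      fit <- wmsvr(X, y, K = K_range[j], alpha = alpha, tau = tau, tol = tol,
                   max_iter = max_iter, omega_init = omega_init, seed = seed,
                   dc_mode = dc_mode, gamma = gamma, sigma2 = sigma2,
                   folds = folds, weight_power = weight_power)
      err[j] <- rmsep(y_val, predict(fit, X_val))
    } else {
      err[j] <- wmsvr_cv_error(X, y, K = K_range[j], folds = folds,
                               alpha = alpha, tau = tau, tol = tol,
                               max_iter = max_iter, omega_init = omega_init,
                               seed = seed, dc_mode = dc_mode, gamma = gamma,
                               sigma2 = sigma2, weight_power = weight_power)
    }
  }
  list(K = pick_k(K_range, err),
       curve = data.frame(K = K_range, error = err))
}

# argmin over the scanned K values, ties resolved towards the smaller K
pick_k <- function(K_range, err) {
  ord <- order(K_range)
  K_range <- K_range[ord]; err <- err[ord]
  K_range[which(err == min(err))[1]]
}

# Cross-validated RMSE of the weighted ensemble sharing one decomposition:
# each spectrum is decomposed once, the K sub-models are cross-validated on
# shared folds, and the held-out per-mode predictions are combined with the
# RMSECV^-power weights.
wmsvr_cv_error <- function(X, y, K, folds, alpha, tau, tol, max_iter,
                           omega_init, seed, dc_mode, gamma, sigma2,
                           weight_power) {
  stack <- build_mode_matrices(X, K = K, alpha = alpha, tau = tau, tol = tol,
                               max_iter = max_iter, omega_init = omega_init,
                               seed = seed, dc_mode = dc_mode)
  if (is.null(sigma2)) sigma2 <- median_heuristic(X)
  m <- nrow(X)
  P <- matrix(0, m, K)
  for (k in seq_len(K)) {
    Uk <- stack$U[[k]]
    for (f in folds) {
      fit <- lssvr(Uk[-f, , drop = FALSE], y[-f], gamma = gamma, sigma2 = sigma2)
      P[f, k] <- predict(fit, Uk[f, , drop = FALSE])
    }
  }
  cv_err <- sqrt(colMeans((y - P)^2))
  w <- wmsvr_weights(cv_err, power = weight_power)
  sqrt(mean((y - drop(P %*% w))^2))
}
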