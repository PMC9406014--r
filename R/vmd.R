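#' Variational mode decomposition of a spectrum
#'
#' Decomposes a real-valued signal (e.g. one absorbance spectrum) into `K`
#' narrow-band mode components \eqn{u_k} with centre frequencies
#' \eqn{\omega_k}. The modes jointly minimise the sum of their estimated
#' bandwidths subject to (softly, for `tau = 0`) summing to the input signal.
#' The problem is solved by ADMM in the frequency domain: each mode is
#' updated by Wiener filtering of the current residual around its centre
#' frequency, each centre frequency by the power-weighted mean frequency of
#' its mode, and the Lagrange multiplier by dual ascent with step `tau`.
#'
#' The signal is mirror-extended to twice its length before the FFT and the
#' modes cropped back afterwards, which suppresses boundary distortion. All
#' updates operate on the nonnegative-frequency half-axis; conjugate symmetry
#' is restored before the inverse transform so the returned modes are real.
#'
#' @param x numeric vector, length >= 8; the signal to decompose.
#' @param K number of modes (>= 1, at most `length(x)/2`).
#' @param alpha bandwidth penalty of the quadratic term; larger values give
#'   narrower modes. Default 2000.
#' @param tau dual-ascent step for the Lagrange multiplier. `tau = 0`
#'   (default) drops exact reconstruction in favour of noise robustness.
#' @param tol relative convergence tolerance on the summed squared mode
#'   updates. Default `1e-7`.
#' @param max_iter maximum ADMM sweeps. Default 500.
#' @param omega_init `"uniform"` (default; k-th of K spread over
#'   \[0, 0.5\]), `"zero"`, or `"random"`.
#' @param seed integer seed used when `omega_init = "random"`.
#' @param dc_mode if `TRUE`, pin the first centre frequency at 0 so mode 1
#'   tracks the baseline/DC content.
#' @param axis optional numeric axis (wavelength in nm or wavenumber in
#'   cm^-1), strictly monotonic, same length as `x`; used only for labelling.
#'
#' @return An object of class `"vmd"`: a list with `modes` (K x n matrix,
#'   rows ordered by ascending centre frequency), `omegas` (centre
#'   frequencies in cycles/sample, each in \[0, 0.5\]), `n_iterations`,
#'   `converged`, and the configuration used.
#'
#' @examples
#' t <- 0:255
#' x <- cos(2 * pi * 8 * t / 256)
#' m <- vmd(x, K = 1)
#' m$omegas            # close to 8/256
#' @export
vmd <- function(x, K, alpha = 2000, tau = 0, tol = 1e-7, max_iter = 500,
                omega_init = c("uniform", "zero", "random"), seed = 0L,
                dc_mode = FALSE, axis = NULL) {
  if (!is.numeric(x) || !all(is.finite(x)))
    stop_invalid("'x' must be a finite numeric vector")
  n <- length(x)
  if (n < 8) stop_invalid("'x' must have length >= 8")
  K <- as.integer(K)
  if (K < 1) stop_config("'K' must be a positive integer")
  if (K > n / 2)
    stop_config(sprintf("K = %d exceeds n/2 = %g: over-decomposition", K, n / 2))
  if (!is.numeric(alpha) || alpha <= 0) stop_config("'alpha' must be > 0")
  if (tau < 0) stop_config("'tau' must be >= 0")
  if (tol <= 0) stop_config("'tol' must be > 0")
  omega_init <- match.arg(omega_init)
  if (!is.null(axis)) {
    if (length(axis) != n) stop_invalid("'axis' length must match 'x'")
    if (!(all(diff(axis) > 0) || all(diff(axis) < 0)))
      stop_invalid("'axis' must be strictly monotonic")
  }

  xe <- mirror_extend(x)
  N <- length(xe)                       # always 2n, even
  H <- N %/% 2L + 1L
  freqs <- (0:(N %/% 2L)) / N           # cycles/sample on the half-axis
  xhat_plus <- stats::fft(xe)[seq_len(H)]

  omega0 <- switch(omega_init,
    uniform = 0.5 * (seq_len(K) - 1) / K,
    zero    = rep(0, K),
    random  = {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(as.integer(seed))
      w <- sort(stats::runif(K, 0, 0.5))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      w
    })
  if (dc_mode) omega0[1] <- 0

  res <- .vmd_admm_cpp(xhat_plus, freqs, omega0, alpha, tau, tol,
                       as.integer(max_iter), dc_mode)

  # restore conjugate symmetry, invert, crop back to the original support
  modes <- matrix(0, K, n)
  for (k in seq_len(K)) {
    full <- complex(N)
    half <- res$u_hat[k, ]
    full[seq_len(H)] <- half
    if (H > 2) full[N:(H + 1L)] <- Conj(half[2:(H - 1L)])
    uk <- Re(stats::fft(full, inverse = TRUE)) / N
    modes[k, ] <- crop_center(uk, n)
  }

  ord <- order(res$omega)
  structure(list(
    modes = modes[ord, , drop = FALSE],
    omegas = res$omega[ord],
    n_iterations = res$n_iterations,
    converged = res$converged,
    K = K, alpha = alpha, tau = tau, tol = tol, max_iter = max_iter,
    omega_init = omega_init, seed = as.integer(seed), dc_mode = dc_mode,
    axis = axis
  ), class = "vmd")
}

#' Sum the modes of a decomposition back into a signal
#'
#' @param ms a `"vmd"` object (or any list with a `modes` matrix).
#' @return numeric vector: the elementwise sum of the mode rows.
#' @export
reconstruct <- function(ms) {
  if (is.null(ms$modes) || nrow(ms$modes) == 0)
    stop_invalid("empty mode set: nothing to reconstruct")
  colSums(ms$modes)
}

#' Mirror-extend a signal for boundary-free frequency analysis
#'
#' Prepends the reversed first half and appends the reversed second half, so
#' the extended signal has length `2n` and is continuous at both ends.
#' [crop_center()] inverts the operation exactly.
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector of length `2 * length(x)`.
#' @export
mirror_extend <- function(x) {
  n <- length(x)
  if (n < 2) stop_invalid("'x' must have length >= 2")
  h <- n %/% 2L
  c(rev(x[seq_len(h)]), x, rev(x[(h + 1L):n]))
}

#' @rdname mirror_extend
#' @param xe a vector produced by `mirror_extend`.
#' @param n the original length.
#' @export
crop_center <- function(xe, n) {
  if (length(xe) != 2L * n)
    stop_invalid("'xe' must have length 2*n")
  h <- n %/% 2L
  xe[(h + 1L):(h + n)]
}

#' @export
print.vmd <- function(x, ...) {
  cat(sprintf("Variational mode decomposition: K = %d modes over %d points\n",
              x$K, ncol(x$modes)))
  cat(sprintf("  centre frequencies (cycles/sample): %s\n",
              paste(signif(x$omegas, 4), collapse = ", ")))
  cat(sprintf("  %d iterations, %sconverged (tol = %g, alpha = %g, tau = %g)\n",
              x$n_iterations, if (x$converged) "" else "NOT ", x$tol,
              x$alpha, x$tau))
  invisible(x)
}

#' @export
plot.vmd <- function(x, ...) {
  ax <- if (is.null(x$axis)) seq_len(ncol(x$modes)) else x$axis
  K <- nrow(x$modes)
  op <- graphics::par(mfrow = c(K + 1, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(ax, reconstruct(x), type = "l", ylab = "sum", ...)
  for (k in seq_len(K))
    graphics::plot(ax, x$modes[k, ], type = "l",
                   ylab = sprintf("u%d (%.3g)", k, x$omegas[k]))
  invisible(x)
}
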