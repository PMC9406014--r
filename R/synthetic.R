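# Synthetic adulterated-mixture spectra: Beer-Lambert linear mixing of
# smooth overlapping band profiles, with optional saturation nonlinearity,
# polynomial baseline drift and heteroscedastic noise. Emulates small
# UV-Vis oil-blend and NIR herb-powder calibration sets.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  force(expr)
}

#' Library of pure-component band profiles
#'
#' Two presets emulating the instruments typical of adulterant
#' quantification studies:
#' \describe{
#'   \item{`uvvis_oil_like`}{6 components on a 421-point 380-800 nm grid
#'     (1 nm steps), each a sum of 2-4 Gaussian absorption bands with
#'     widths 10-60 nm — vegetable-oil-like visible spectra.}
#'   \item{`nir_herb_like`}{4 components on a 1001-point 12,000-4,000
#'     cm^-1 grid (8 cm^-1 steps, i.e. the instrument's 2 cm^-1 grid
#'     decimated fourfold), with broad overtone-like bands concentrated
#'     below 8,000 cm^-1 where NIR spectra of plant powders fluctuate
#'     most.}
#' }
#' Profiles are nonnegative and unit-peak normalised; band positions and
#' widths are drawn reproducibly from `seed`.
#'
#' @param preset `"uvvis_oil_like"` or `"nir_herb_like"`.
#' @param seed RNG seed. Default 0.
#' @return list with `axis`, `pure_spectra` (components x points), `names`.
#' @export
spectral_library <- function(preset = c("uvvis_oil_like", "nir_herb_like"),
                             seed = 0L) {
  preset <- match.arg(preset)
  with_seed(seed, {
    # every component shares a broad common envelope (same chemical family:
    # triglyceride oils, plant polysaccharides) plus its own bands, so
    # profiles overlap substantially yet remain distinguishable
    if (preset == "uvvis_oil_like") {
      axis <- seq(380, 800, by = 1)
      nc <- 6L
      envelope <- exp(-(axis - 560)^2 / (2 * 140^2))
      S <- t(vapply(seq_len(nc), function(i) {
        nb <- sample(2:4, 1)
        centers <- stats::runif(nb, 400, 780)
        widths <- stats::runif(nb, 10, 60)
        amps <- stats::runif(nb, 0.3, 1)
        prof <- 2 * envelope + rowSums(vapply(seq_len(nb), function(b)
          amps[b] * exp(-(axis - centers[b])^2 / (2 * widths[b]^2)),
          numeric(length(axis))))
        prof / max(prof)
      }, numeric(length(axis))))
      nm <- paste0("oil", seq_len(nc))
    } else {
      axis <- seq(12000, 4000, length.out = 1001)
      nc <- 4L
      envelope <- exp(-(axis - 5600)^2 / (2 * 1400^2))
      S <- t(vapply(seq_len(nc), function(i) {
        nb <- sample(3:5, 1)
        # overtone/combination bands mostly in the 4,000-8,000 cm^-1 region
        centers <- c(stats::runif(nb - 1, 4200, 8000),
                     stats::runif(1, 8000, 11000))
        widths <- stats::runif(nb, 150, 600)
        amps <- c(stats::runif(nb - 1, 0.4, 1), stats::runif(1, 0.05, 0.2))
        prof <- 0.8 * envelope + rowSums(vapply(seq_len(nb), function(b)
          amps[b] * exp(-(axis - centers[b])^2 / (2 * widths[b]^2)),
          numeric(length(axis))))
        prof / max(prof)
      }, numeric(length(axis))))
      nm <- c("PN", "RAO", "RC", "CL")
    }
    list(axis = axis, pure_spectra = S, names = nm, preset = preset,
         seed = as.integer(seed))
  })
}

#' Mixture designs on the simplex
#'
#' `"dirichlet"` draws rows uniformly on the simplex (Dirichlet with
#' concentration 1), emulating blends mixed in arbitrary mass proportions.
#' `"grid"` sweeps the target component evenly from 0 to 1 (with `m = 51`
#' this is a 2% interval) and splits the remainder equally among the other
#' components.
#'
#' @param m number of samples.
#' @param c number of components (>= 2).
#' @param scheme `"dirichlet"` or `"grid"`.
#' @param target_component index of the analyte component. Default 1.
#' @param seed RNG seed.
#' @return list with `fractions` (m x c, rows summing to 1) and
#'   `target_component`.
#' @export
sample_fractions <- function(m, c, scheme = c("dirichlet", "grid"),
                             target_component = 1L, seed = 0L) {
  scheme <- match.arg(scheme)
  if (m < 1 || c < 2) stop_config("need m >= 1 samples and c >= 2 components")
  tc <- as.integer(target_component)
  if (tc < 1 || tc > c) stop_config("'target_component' out of range")
  F <- with_seed(seed, {
    if (scheme == "dirichlet") {
      G <- matrix(stats::rexp(m * c), m, c)
      G / rowSums(G)
    } else {
      ft <- if (m == 1) 0.5 else seq(0, 1, length.out = m)
      F <- matrix((1 - ft) / (c - 1), m, c)
      F[, tc] <- ft
      F
    }
  })
  list(fractions = F, target_component = tc, scheme = scheme,
       seed = as.integer(seed))
}

#' Synthesize mixture spectra with known adulterant content
#'
#' Builds `X = F S` (fractions times pure profiles: Beer-Lambert linear
#' mixing), then optionally applies, in order:
#' \enumerate{
#'   \item a saturation nonlinearity \eqn{x \mapsto (1 - e^{-\beta x})/\beta}
#'     with \eqn{\beta = 3 \cdot \mathrm{nonlinearity}} (detector /
#'     Beer-law departure; \eqn{\beta \to 0} recovers linearity);
#'   \item a random cubic-polynomial baseline per sample, scaled by
#'     `baseline_amp`;
#'   \item heteroscedastic Gaussian noise with sd
#'     \eqn{\mathrm{noise\_sd} \cdot (0.5 + |x|)}.
#' }
#' The target is the analyte's mass fraction in percent (0-100).
#'
#' @param lib a [spectral_library()].
#' @param design a [sample_fractions()] design.
#' @param noise_sd noise scale. Default 0.002 absorbance units.
#' @param baseline_amp baseline drift amplitude. Default 0.01.
#' @param nonlinearity saturation strength in \[0, 1). Default 0.3.
#' @param seed RNG seed for baseline and noise.
#' @return list with `X` (m x n), `y` (target %, length m), `axis`,
#'   `fractions`.
#' @export
synthesize_spectra <- function(lib, design, noise_sd = 0.002,
                               baseline_amp = 0.01, nonlinearity = 0.3,
                               seed = 0L) {
  S <- lib$pure_spectra
  F <- design$fractions
  if (ncol(F) != nrow(S))
    stop_invalid("design has a different component count than the library")
  if (nonlinearity < 0 || nonlinearity >= 1)
    stop_config("'nonlinearity' must be in [0, 1)")
  X <- F %*% S
  m <- nrow(X); n <- ncol(X)
  if (nonlinearity > 0) {
    beta <- 3 * nonlinearity
    X <- (1 - exp(-beta * X)) / beta
  }
  X <- with_seed(seed, {
    if (baseline_amp > 0) {
      tgrid <- seq(0, 1, length.out = n)
      coefs <- matrix(stats::rnorm(m * 4), m, 4)
      X <- X + baseline_amp *
        coefs %*% rbind(rep(1, n), tgrid, tgrid^2, tgrid^3)
    }
    if (noise_sd > 0)
      X <- X + stats::rnorm(m * n, sd = noise_sd * (0.5 + abs(X)))
    X
  })
  list(X = unname(as.matrix(X)),
       y = 100 * F[, design$target_component],
       axis = lib$axis, fractions = F)
}

#' The default end-to-end benchmark dataset
#'
#' 75 NIR-herb-like mixture samples with the generator defaults
#' (`noise_sd = 0.002`, `baseline_amp = 0.01`, `nonlinearity = 0.3`),
#' Dirichlet mixture design, analyte = component 2 ("RAO"). One seed
#' controls the library, design and corruption draws.
#'
#' @param seed replicate seed.
#' @param m number of samples. Default 75.
#' @return as [synthesize_spectra()].
#' @export
synthetic_benchmark <- function(seed = 0L, m = 75L) {
  lib <- spectral_library("nir_herb_like", seed = 0L)
  des <- sample_fractions(m, nrow(lib$pure_spectra), "dirichlet",
                          target_component = 2L, seed = seed)
  synthesize_spectra(lib, des, seed = seed + 1L)
}
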