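# Delimited-text I/O. Spectra files are CSV: first column "id", remaining
# column names the numeric axis (wavelength nm / wavenumber cm^-1), one row
# per sample. Target files are two-column CSV (id, target %). Models are
# stored as JSON so a fit is reproducible byte-for-byte.

#' Read a spectra matrix from CSV
#'
#' @param path CSV file: first column sample ids, header of the remaining
#'   columns the numeric axis values (strictly monotonic).
#' @return list with `X` (m x n matrix), `axis`, `ids`.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop_format(conditionMessage(e)))
  if (ncol(df) < 2) stop_format("spectra file needs an id column plus data columns")
  ids <- as.character(df[[1]])
  axis <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (any(is.na(axis)))
    stop_format("spectra header must be numeric axis values")
  if (!(all(diff(axis) > 0) || all(diff(axis) < 0)))
    stop_format("spectra axis header must be strictly monotonic")
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X) || anyNA(X)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1,
                       function(r) anyNA(suppressWarnings(as.numeric(r)))))[1]
    stop_format(sprintf("non-numeric spectral value in row %s (id '%s')",
                        bad, ids[bad]))
  }
  dimnames(X) <- NULL
  list(X = X, axis = axis, ids = ids)
}

#' @rdname read_spectra
#' @param X m x n spectra matrix.
#' @param axis numeric axis (length n).
#' @param ids sample identifiers (length m); defaults to `s1..sm`.
#' @export
write_spectra <- function(X, axis, path, ids = NULL) {
  X <- check_matrix(X)
  if (length(axis) != ncol(X)) stop_invalid("'axis' length must match ncol(X)")
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(X)))
  df <- data.frame(id = ids, X, check.names = FALSE)
  colnames(df) <- c("id", format(axis, trim = TRUE, digits = 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read targets and align them to a spectra file's ids
#'
#' @param path two-column CSV (id, target).
#' @param ids optional id vector to align against; every id must be
#'   present in the file.
#' @return named numeric vector of targets (in `ids` order when given).
#' @export
read_targets <- function(path, ids = NULL) {
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop_format(conditionMessage(e)))
  if (ncol(df) < 2) stop_format("target file needs (id, target) columns")
  y <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(y)) stop_format("non-numeric target value")
  names(y) <- as.character(df[[1]])
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(y))
    if (length(missing))
      stop_format(paste("targets missing for id(s):",
                        paste(missing, collapse = ", ")))
    y <- y[ids]
  }
  y
}

#' @rdname read_targets
#' @param yhat predictions to write.
#' @export
write_predictions <- function(ids, yhat, path) {
  utils::write.csv(data.frame(id = ids, prediction = yhat), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a mode decomposition to two-block delimited text
#'
#' Block one is the K x n mode matrix (comma-separated), block two the K
#' centre frequencies; blocks are separated by a blank line.
#'
#' @param ms a `"vmd"` object.
#' @param path output file.
#' @export
write_modeset <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(ms$modes, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = ",")), con)
  writeLines("", con)
  writeLines(paste(format(ms$omegas, trim = TRUE, digits = 17),
                   collapse = ","), con)
  invisible(path)
}

#' @rdname write_modeset
#' @export
read_modeset <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "")[1]
  if (is.na(sep)) stop_format("mode-set file must contain two blank-line separated blocks")
  modes <- do.call(rbind, lapply(lines[seq_len(sep - 1)], function(l)
    as.numeric(strsplit(l, ",")[[1]])))
  omegas <- as.numeric(strsplit(lines[sep + 1], ",")[[1]])
  structure(list(modes = modes, omegas = omegas), class = "vmd")
}

#' Save or load a fitted model as JSON
#'
#' Numbers are written at full precision, so refits under identical seeds
#' and configuration serialize byte-for-byte identically.
#'
#' @param model an `"lssvr"` or `"wmsvr"` fit.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  to_json_list <- function(m) {
    if (inherits(m, "lssvr")) {
      list(type = "lssvr", b = m$b, b0 = m$b0, gamma = m$gamma,
           sigma2 = m$sigma2, y_mean = m$y_mean,
           X_train = apply(m$X_train, 1, identity, simplify = FALSE))
    } else if (inherits(m, "wmsvr")) {
      list(type = "wmsvr", cfg = m$cfg, gamma = m$gamma, sigma2 = m$sigma2,
           weight_power = m$weight_power, weights = m$weights,
           rmsecv_per_mode = m$rmsecv_per_mode, n_train = m$n_train,
           n_vars = m$n_vars,
           train_omegas = apply(m$train_omegas, 1, identity, simplify = FALSE),
           submodels = lapply(m$submodels, to_json_list))
    } else stop_invalid("unsupported model class")
  }
  jsonlite::write_json(to_json_list(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  from_json_list <- function(l) {
    if (identical(l$type, "lssvr")) {
      structure(list(b = as.numeric(l$b), b0 = l$b0, gamma = l$gamma,
                     sigma2 = l$sigma2,
                     X_train = do.call(rbind, lapply(l$X_train, as.numeric)),
                     y_mean = l$y_mean), class = "lssvr")
    } else if (identical(l$type, "wmsvr")) {
      structure(list(submodels = lapply(l$submodels, from_json_list),
                     weights = as.numeric(l$weights),
                     rmsecv_per_mode = as.numeric(l$rmsecv_per_mode),
                     cfg = l$cfg,
                     train_omegas = do.call(rbind, lapply(l$train_omegas, as.numeric)),
                     gamma = l$gamma, sigma2 = l$sigma2,
                     weight_power = l$weight_power,
                     n_train = l$n_train, n_vars = l$n_vars),
                class = "wmsvr")
    } else stop_format("unrecognised model JSON")
  }
  from_json_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Default experiment configuration
#'
#' Flat named list of every tunable: synthetic-data settings, the
#' Kennard-Stone train size, VMD settings, LSSVR hyperparameters, the mode
#' scan range, and switches for tuning and the baselines.
#'
#' @param ... overrides of the defaults (unknown keys are rejected).
#' @return named list.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    seed = 0L,
    preset = "nir_herb_like", m = 75L,
    noise_sd = 0.002, baseline_amp = 0.01, nonlinearity = 0.3,
    target_component = 2L,
    ks_train_frac = 2 / 3,
    vmd_K = 5L, vmd_alpha = 2000, vmd_tau = 0, vmd_tol = 1e-7,
    vmd_max_iter = 500L,
    svr_gamma = 100, svr_sigma2 = NA_real_,
    cv_scheme = "auto",
    select_k = FALSE, k_range = 2:7,
    tune = FALSE, pso_swarm = 20L, pso_iter = 50L,
    pls_max_lv = 10L, mccv_splits = 50L, mccv_frac = 0.2,
    mccv_alpha_f = 0.25,
    run_wmsvr = TRUE, run_lssvr = TRUE, run_pls = TRUE,
    validation_mode = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_config(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  cfg
}

#' Run the full calibration workflow
#'
#' Simulate (or accept) a dataset, split it by Kennard-Stone, optionally
#' tune \eqn{(\gamma, \sigma^2)} and scan the mode number, then fit the
#' configured methods (PLS with MCCV+F-test rank selection, single LSSVR
#' on the raw spectra, VMD-WMSVR) and evaluate RMSEP and R on the
#' prediction set. Deterministic under a fixed `seed`.
#'
#' @param config list from [experiment_config()].
#' @param data optional list with `X`, `y` (skips simulation).
#' @param out_dir if non-`NULL`, write the report table, the K curve and
#'   the resolved configuration there as CSV/JSON.
#' @return list with `report` (data.frame: method, rmsep, r, parameter),
#'   `k_curve` (or `NULL`), `split`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), data = NULL,
                           out_dir = NULL) {
  cfg <- config
  if (is.null(data)) {
    lib <- spectral_library(cfg$preset, seed = 0L)
    des <- sample_fractions(cfg$m, nrow(lib$pure_spectra), "dirichlet",
                            target_component = cfg$target_component,
                            seed = cfg$seed)
    data <- synthesize_spectra(lib, des, noise_sd = cfg$noise_sd,
                               baseline_amp = cfg$baseline_amp,
                               nonlinearity = cfg$nonlinearity,
                               seed = cfg$seed + 1L)
  }
  X <- data$X; y <- data$y
  m <- nrow(X)

  split <- kennard_stone(X, n_train = round(cfg$ks_train_frac * m))
  Xtr <- X[split$train, , drop = FALSE]; ytr <- y[split$train]
  Xte <- X[split$test, , drop = FALSE]; yte <- y[split$test]

  sigma2 <- if (is.na(cfg$svr_sigma2)) NULL else cfg$svr_sigma2
  gamma <- cfg$svr_gamma
  if (isTRUE(cfg$tune)) {
    tuned <- tune_lssvr(Xtr, ytr,
                        X_val = if (cfg$validation_mode) Xte else NULL,
                        y_val = if (cfg$validation_mode) yte else NULL,
                        validation_mode = cfg$validation_mode,
                        swarm_size = cfg$pso_swarm, n_iter = cfg$pso_iter,
                        seed = cfg$seed)
    gamma <- tuned$gamma; sigma2 <- tuned$sigma2
  }

  k_curve <- NULL
  K <- cfg$vmd_K
  if (isTRUE(cfg$select_k)) {
    ksel <- select_k(Xtr, ytr, K_range = cfg$k_range,
                     X_val = if (cfg$validation_mode) Xte else NULL,
                     y_val = if (cfg$validation_mode) yte else NULL,
                     validation_mode = cfg$validation_mode,
                     alpha = cfg$vmd_alpha, tau = cfg$vmd_tau,
                     tol = cfg$vmd_tol, max_iter = cfg$vmd_max_iter,
                     gamma = gamma, sigma2 = sigma2, cv = cfg$cv_scheme)
    K <- ksel$K; k_curve <- ksel$curve
  }

  rows <- list()
  if (isTRUE(cfg$run_pls)) {
    max_lv <- min(cfg$pls_max_lv, nrow(Xtr) - ceiling(cfg$mccv_frac * nrow(Xtr)) - 2)
    lv <- select_lv_mccv_ftest(Xtr, ytr, max_lv = max_lv,
                               n_splits = cfg$mccv_splits,
                               split_frac = cfg$mccv_frac,
                               alpha_f = cfg$mccv_alpha_f, seed = cfg$seed)
    fit <- pls_fit(Xtr, ytr, ncomp = lv)
    p <- predict(fit, Xte)
    rows$pls <- data.frame(method = "PLS", rmsep = rmsep(yte, p),
                           r = pearson_r(yte, p),
                           parameter = sprintf("LV=%d", lv))
  }
  if (isTRUE(cfg$run_lssvr)) {
    fit <- lssvr(Xtr, ytr, gamma = gamma, sigma2 = sigma2)
    p <- predict(fit, Xte)
    rows$svr <- data.frame(method = "LSSVR", rmsep = rmsep(yte, p),
                           r = pearson_r(yte, p),
                           parameter = sprintf("gamma=%.4g, sigma2=%.4g",
                                               fit$gamma, fit$sigma2))
  }
  if (isTRUE(cfg$run_wmsvr)) {
    fit <- wmsvr(Xtr, ytr, K = K, alpha = cfg$vmd_alpha, tau = cfg$vmd_tau,
                 tol = cfg$vmd_tol, max_iter = cfg$vmd_max_iter,
                 gamma = gamma, sigma2 = sigma2, cv = cfg$cv_scheme)
    p <- predict(fit, Xte)
    rows$wmsvr <- data.frame(method = "VMD-WMSVR", rmsep = rmsep(yte, p),
                             r = pearson_r(yte, p),
                             parameter = sprintf("K=%d, gamma=%.4g, sigma2=%.4g",
                                                 K, fit$gamma, fit$sigma2))
  }
  report <- do.call(rbind, unname(rows))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    if (!is.null(k_curve))
      utils::write.csv(k_curve, file.path(out_dir, "k_curve.csv"),
                       row.names = FALSE)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, k_curve = k_curve, split = split, config = cfg)
}
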