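## CSV + JSON-sidecar dialect for all on-disk artefacts. Data volumes are
## desk-scale (<= 1e4 spectra x 401 points), so human-inspectable text
## formats are preferred over binary containers.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

sidecar_path <- function(path) {
  if (grepl("\\.csv$", path)) sub("\\.csv$", ".json", path) else paste0(path, ".json")
}

#' Write a spectra series to CSV with a JSON sidecar
#'
#' First CSV row: the wavelength grid; every following row: timestamp then
#' one value per wavelength. The sidecar (same path with `.json`) stores
#' the kind, the bright/dark references and any metadata, so intensity
#' data round-trips losslessly.
#'
#' @param series a [spectra_series].
#' @param path CSV file path.
#' @return the CSV path, invisibly.
#' @export
write_spectra <- function(series, path) {
  stopifnot(inherits(series, "spectra_series"))
  header <- paste(c("wavelength", fmt_num(series$wavelengths)), collapse = ",")
  body <- paste(fmt_num(series$timestamps),
                apply(matrix(fmt_num(series$values), nrow(series$values)), 1,
                      paste, collapse = ","),
                sep = ",")
  writeLines(c(header, body), path)
  meta <- series$meta
  meta$optics <- if (!is.null(meta$optics)) unclass(meta$optics)
  jsonlite::write_json(
    list(kind = series$kind,
         bright_ref = series$bright_ref, dark_ref = series$dark_ref,
         meta = meta),
    sidecar_path(path), auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a spectra series written by [write_spectra()]
#'
#' @param path CSV file path; the JSON sidecar must sit next to it (it is
#'   mandatory for intensity data, which cannot be interpreted without its
#'   reference spectra).
#' @param validate_grid if not `NULL`, the expected number of wavelength
#'   points (e.g. 401); a mismatch is an error.
#' @return a [spectra_series].
#' @export
read_spectra <- function(path, validate_grid = NULL) {
  if (!file.exists(path)) stop("read_spectra: file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("read_spectra: file has no data rows: ", path)
  split_row <- strsplit(lines, ",", fixed = TRUE)
  W <- length(split_row[[1]]) - 1
  bad <- which(vapply(split_row, length, integer(1)) != W + 1)
  if (length(bad) > 0) {
    stop(sprintf("read_spectra: ragged row(s) at line(s) %s in %s",
                 paste(utils::head(bad, 5), collapse = ", "), path))
  }
  wl <- as.numeric(split_row[[1]][-1])
  if (!is.null(validate_grid) && W != validate_grid) {
    stop(sprintf("read_spectra: expected %d wavelength points, found %d", validate_grid, W))
  }
  num <- matrix(as.numeric(unlist(split_row[-1])), ncol = W + 1, byrow = TRUE)
  if (anyNA(num)) {
    badrow <- which(apply(num, 1, anyNA))
    stop(sprintf("read_spectra: non-numeric value(s) at line(s) %s in %s",
                 paste(utils::head(badrow + 1, 5), collapse = ", "), path))
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop(sprintf("read_spectra: expected JSON sidecar not found: %s", sc))
  }
  j <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (identical(j$kind, "intensity") && (is.null(j$bright_ref) || is.null(j$dark_ref))) {
    stop(sprintf("read_spectra: intensity data but sidecar %s lacks bright/dark references", sc))
  }
  meta <- if (is.null(j$meta)) list() else j$meta
  spectra_series(wl, num[, 1], num[, -1, drop = FALSE], j$kind,
                 j$bright_ref, j$dark_ref, meta)
}

#' Write a drying run (trajectory CSV + JSON metadata)
#'
#' The CSV holds the time grid and the state trajectories; the sidecar
#' holds the bed configuration, generating resistance parameters, isotherm
#' and simulation settings, plus the LOD table when attached.
#'
#' @param run a [drying_run].
#' @param path CSV file path.
#' @return the CSV path, invisibly.
#' @export
write_drying_run <- function(run, path) {
  stopifnot(inherits(run, "drying_run"))
  df <- data.frame(time = run$time, f_w = run$f_w, F_w = run$F_w,
                   T_bed = run$T_bed, T_in = run$T_in,
                   Ndot_w = run$Ndot_w, a_w = run$a_w,
                   omega_tot = run$omega_tot)
  utils::write.table(do.call(cbind, lapply(df, fmt_num)), path, sep = ",",
                     row.names = FALSE, col.names = names(df), quote = FALSE)
  jsonlite::write_json(
    list(bed = unclass(run$bed), truth = unclass(run$truth),
         isotherm = unclass(run$isotherm), params = run$params,
         lod = run$lod),
    sidecar_path(path), auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a drying run written by [write_drying_run()]
#'
#' @param path CSV file path (JSON sidecar required).
#' @return a [drying_run].
#' @export
read_drying_run <- function(path) {
  if (!file.exists(path)) stop("read_drying_run: file not found: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("read_drying_run: expected JSON sidecar not found: ", sc)
  df <- utils::read.csv(path)
  j <- jsonlite::read_json(sc, simplifyVector = TRUE)
  bed <- do.call(bed_config, j$bed[setdiff(names(j$bed), "phi_g")])
  truth <- do.call(resistance_fit, j$truth)
  iso <- gab_params(j$isotherm$m_o, j$isotherm$C_GAB, j$isotherm$k_w,
                    j$isotherm$name, j$isotherm$mass %||% NA_real_)
  lod <- if (!is.null(j$lod) && length(j$lod) > 0) as.data.frame(j$lod)
  structure(list(time = df$time, f_w = df$f_w, F_w = df$F_w,
                 T_bed = df$T_bed, T_in = df$T_in,
                 Ndot_w = df$Ndot_w, a_w = df$a_w, omega_tot = df$omega_tot,
                 bed = bed, truth = truth, isotherm = iso, lod = lod,
                 params = j$params),
            class = "drying_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read loss-on-drying samples (2-column CSV)
#'
#' @param lod data.frame with `time` and `f_w_obs`.
#' @param path CSV file path.
#' @return the path ([write_lod()]) or the data.frame ([read_lod()]).
#' @export
write_lod <- function(lod, path) {
  utils::write.table(cbind(time = fmt_num(lod$time), f_w_obs = fmt_num(lod$f_w_obs)),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lod
#' @export
read_lod <- function(path) {
  if (!file.exists(path)) stop("read_lod: file not found: ", path)
  utils::read.csv(path)
}

#' Serialize a fitted model to JSON
#'
#' Supports [pls_model], [mspc_model] and [resistance_fit] objects. All
#' numeric state is written at full precision, so a reloaded model
#' reproduces predictions to machine accuracy.
#'
#' @param model the fitted model object.
#' @param path JSON file path.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path) {
  cls <- class(model)[1]
  if (!cls %in% c("pls_model", "mspc_model", "resistance_fit")) {
    stop("save_model: unsupported class ", cls)
  }
  payload <- unclass(model)
  if (cls == "pls_model") {
    payload$weights <- as.data.frame(payload$weights)
    payload$x_loadings <- as.data.frame(payload$x_loadings)
    payload$scores <- NULL
    payload$residuals <- as.numeric(payload$residuals)
  }
  if (cls == "mspc_model") {
    payload$loadings <- as.data.frame(payload$loadings)
    payload$limits <- as.list(payload$limits)   # keep the q95/q99 names
  }
  if (cls == "resistance_fit") {
    payload$std_errors <- as.list(attr(model, "std_errors"))
  }
  jsonlite::write_json(list(class = cls, payload = payload), path,
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file path.
#' @return the reconstructed model object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("load_model: file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$payload
  switch(j$class,
    pls_model = structure(list(
      weights = as.matrix(p$weights), x_loadings = as.matrix(p$x_loadings),
      y_loadings = p$y_loadings, scores = NULL,
      b = p$b, b0 = p$b0, x_mean = p$x_mean, y_mean = p$y_mean,
      n_lv = p$n_lv, residuals = p$residuals,
      wavelength_grid = p$wavelength_grid), class = "pls_model"),
    mspc_model = structure(list(
      loadings = as.matrix(p$loadings), x_mean = p$x_mean, n_pc = p$n_pc,
      residual_eigenvalues = p$residual_eigenvalues,
      limits = stats::setNames(unlist(p$limits), names(p$limits)),
      snv_applied = isTRUE(p$snv_applied)), class = "mspc_model"),
    resistance_fit = {
      out <- resistance_fit(p$omega_ext, p$omega_max, p$f_w_crit, p$f_w_end)
      if (length(p$std_errors) > 0) attr(out, "std_errors") <- unlist(p$std_errors)
      out
    },
    stop("load_model: unknown class in file: ", j$class))
}

#' Assemble and validate a pipeline configuration
#'
#' Every numeric setting is checked against the preconditions of the
#' module that consumes it, before any computation starts. File-based
#' inputs (when not simulating) must exist; requesting PLS training
#' without an LOD file is a configuration error.
#'
#' @param seed integer seed controlling the whole pipeline.
#' @param out output directory for artefacts, or `NULL` to skip writing.
#' @param simulate generate the batches synthetically (default). When
#'   `FALSE`, `spectra_path`, `run_path` and `lod_path` must point to
#'   files written by the corresponding writers.
#' @param spectra_path,run_path,lod_path input files when `simulate = FALSE`.
#' @param gas_flow,duration,n_calibration,lod_interval,lod_noise synthetic
#'   batch settings.
#' @param block,window preprocessing settings.
#' @param max_lv,folds PLS settings.
#' @param n_pc,alpha,run_length,endpoint_criterion MSPC settings (the
#'   end-point criterion is the moisture fraction, default 2%, that
#'   selects training spectra).
#' @param half_window,inlet mass-transfer settings.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out = NULL, simulate = TRUE,
                            spectra_path = NULL, run_path = NULL, lod_path = NULL,
                            gas_flow = 600, duration = 7200,
                            n_calibration = 4, lod_interval = 400, lod_noise = 0.02,
                            block = 10, window = 75,
                            max_lv = 6, folds = 5,
                            n_pc = "auto", alpha = c(0.95, 0.99), run_length = 10,
                            endpoint_criterion = 0.02,
                            half_window = 36, inlet = "auto") {
  stopifnot(block >= 1, window >= 1, folds >= 2, max_lv >= 1,
            run_length >= 1, half_window >= 1,
            lod_interval > 0, lod_noise >= 0, duration > 0,
            gas_flow > 0, n_calibration >= 1)
  if (any(alpha <= 0 | alpha >= 1)) stop("pipeline_config: alpha must lie in (0, 1)")
  if (endpoint_criterion <= 0 || endpoint_criterion >= 1) {
    stop("pipeline_config: endpoint_criterion must lie in (0, 1)")
  }
  if (!simulate) {
    if (is.null(spectra_path) || !file.exists(spectra_path)) {
      stop("pipeline_config: simulate = FALSE requires an existing spectra_path")
    }
    if (is.null(run_path) || !file.exists(run_path)) {
      stop("pipeline_config: simulate = FALSE requires an existing run_path")
    }
    if (is.null(lod_path) || !file.exists(lod_path)) {
      stop("pipeline_config: PLS training requested but no LOD file available")
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full monitoring pipeline
#'
#' Executes, deterministically for a given seed: batch simulation (or file
#' loading), spectral preprocessing, PLS calibration and moisture
#' prediction, MSPC model building and end-point detection, and the
#' mass-transfer-resistance analysis. Artefacts (spectra, runs, models,
#' charts, report) are written under `config$out` when set.
#'
#' @param config a [pipeline_config].
#' @return report list: relative prediction error (% vs the noise-free
#'   trajectory, warm-up excluded), latent variables used, MSPC component
#'   count and end-point time, resistance parameters with standard errors,
#'   and the settings used.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  set.seed(cfg$seed)
  iso <- aggregate_isotherm(placebo_formulation())$params
  if (cfg$simulate) {
    cal <- lapply(seq_len(cfg$n_calibration), function(i) {
      synthetic_batch(seed = cfg$seed + i, bed = bed_config(gas_flow = cfg$gas_flow),
                      isotherm = iso, duration = cfg$duration,
                      lod_interval = cfg$lod_interval, lod_noise = cfg$lod_noise,
                      vary = TRUE)
    })
    val <- synthetic_batch(seed = cfg$seed + 1000L,
                           bed = bed_config(gas_flow = cfg$gas_flow),
                           isotherm = iso, duration = cfg$duration,
                           lod_interval = cfg$lod_interval, lod_noise = cfg$lod_noise,
                           vary = FALSE)
  } else {
    run <- read_drying_run(cfg$run_path)
    val <- list(run = run, spectra = read_spectra(cfg$spectra_path),
                lod = read_lod(cfg$lod_path))
    cal <- list(val)
  }
  ## preprocessing: PLS branch (no SNV) and MSPC branch (SNV)
  cal_abs <- lapply(cal, function(b) preprocess_spectra(b$spectra, cfg$block, cfg$window))
  val_abs <- preprocess_spectra(val$spectra, cfg$block, cfg$window)
  ## PLS calibration and validation-batch prediction
  pls <- train_moisture_model(cal_abs, lapply(cal, `[[`, "lod"),
                              max_lv = cfg$max_lv, folds = cfg$folds)
  fw_pred <- predict_moisture(pls, val_abs)
  keep <- !val_abs$meta$warmup
  fw_true <- run_state_at(val$run, val_abs$timestamps)$f_w
  e_rel <- relative_error(fw_pred[keep], fw_true[keep])
  ## MSPC: train on calibration end-point spectra (true moisture < criterion)
  noc <- lapply(seq_along(cal), function(i) {
    sn <- snv(cal_abs[[i]])
    fw <- run_state_at(cal[[i]]$run, sn$timestamps)$f_w
    sn$values[fw < cfg$endpoint_criterion & !sn$meta$warmup, , drop = FALSE]
  })
  X_noc <- do.call(rbind, noc)
  if (nrow(X_noc) < 10) {
    stop("run_pipeline: calibration batches never reached the end-point criterion; no MSPC training set")
  }
  mspc <- build_mspc(X_noc, n_pc = cfg$n_pc, alpha = cfg$alpha)
  chart <- q_chart(mspc, snv(val_abs), run_length = cfg$run_length)
  ## mass transfer on the NIR-predicted moisture of the validation batch
  moist <- data.frame(time = val_abs$timestamps, f_w = fw_pred)[keep, ]
  mtr <- analyze_run(val$run, isotherm = iso, moisture = moist,
                     half_window = cfg$half_window, inlet = cfg$inlet)
  se <- attr(mtr$fit, "std_errors")
  report <- list(
    seed = cfg$seed,
    pls = list(n_lv = pls$n_lv, e_rel_percent = e_rel,
               n_calibration_pairs = length(pls$residuals)),
    mspc = list(n_pc = mspc$n_pc, limits = as.list(mspc$limits),
                endpoint_index = attr(chart, "endpoint_index"),
                endpoint_time_s = attr(chart, "endpoint_time"),
                endpoint_time_min = attr(chart, "endpoint_time") / 60),
    mass_transfer = list(omega_ext = mtr$fit$omega_ext,
                         omega_max = mtr$fit$omega_max,
                         f_w_crit = mtr$fit$f_w_crit,
                         f_w_end = mtr$fit$f_w_end,
                         std_errors = as.list(se),
                         c_g_in = mtr$c_g_in, inlet_method = mtr$inlet_method),
    settings = cfg[c("gas_flow", "duration", "n_calibration", "lod_interval",
                     "lod_noise", "block", "window", "max_lv", "folds",
                     "run_length", "endpoint_criterion", "half_window")])
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    write_drying_run(val$run, file.path(cfg$out, "validation_run.csv"))
    write_lod(val$lod, file.path(cfg$out, "validation_lod.csv"))
    save_model(pls, file.path(cfg$out, "pls_model.json"))
    save_model(mspc, file.path(cfg$out, "mspc_model.json"))
    save_model(mtr$fit, file.path(cfg$out, "resistance_fit.json"))
    utils::write.csv(chart, file.path(cfg$out, "q_chart.csv"), row.names = FALSE)
    utils::write.csv(mtr$trace, file.path(cfg$out, "mtr_trace.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE)
  }
  report
}
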