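#' Fit a PLS1 regression by NIPALS
#'
#' Classical NIPALS with deflation for a single response. Each component
#' iterates the weight vector to convergence (change < 1e-10, at most 500
#' iterations; for a single response the loop converges immediately but is
#' kept for clarity and degenerate cases), extracts scores and loadings,
#' and deflates both blocks. The regression vector on the original
#' (uncentred) scale is \eqn{b = W (P^T W)^{-1} q} with intercept
#' \eqn{b_0 = \bar y - \bar x \cdot b}.
#'
#' @param X N x W predictor matrix (spectra in rows).
#' @param y length-N response (here: log10 moisture fraction).
#' @param n_lv number of latent variables; <= min(N - 1, W).
#' @param center centre X and y internally (default). Pass `FALSE` when
#'   the caller has already centred both; the stored means are then zero.
#' @param wavelengths optional wavelength grid carried along so
#'   predictions can verify grid compatibility.
#' @return object of class `pls_model`: `weights`, `x_loadings`,
#'   `y_loadings`, `scores`, `b`, `b0`, `x_mean`, `y_mean`, `n_lv`,
#'   `residuals` (training residuals of y) and `wavelength_grid`.
#' @export
fit_pls_nipals <- function(X, y, n_lv, center = TRUE, wavelengths = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X); W <- ncol(X)
  if (length(y) != N) stop("fit_pls_nipals: X and y sizes disagree")
  if (n_lv < 1 || n_lv > min(N - 1, W)) {
    stop(sprintf("fit_pls_nipals: n_lv must lie in [1, %d]", min(N - 1, W)))
  }
  if (stats::sd(y) == 0) stop("fit_pls_nipals: y has zero variance")
  x_mean <- if (center) colMeans(X) else numeric(W)
  y_mean <- if (center) mean(y) else 0
  Xd <- sweep(X, 2, x_mean)
  yd <- y - y_mean
  Xc <- Xd; yc <- yd
  Wm <- Pm <- matrix(0, W, n_lv)
  Tm <- matrix(0, N, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    u <- yd
    w <- drop(crossprod(Xd, u))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      stop(sprintf("fit_pls_nipals: X exhausted at component %d (weight vector vanished)", a))
    }
    w <- w / nw
    for (it in seq_len(500)) {
      tt <- drop(Xd %*% w)
      qa <- sum(yd * tt) / sum(tt^2)
      u <- yd * qa
      w_new <- drop(crossprod(Xd, u))
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < 1e-10) {
        w <- w_new
        break
      }
      w <- w_new
    }
    tt <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, tt)) / sum(tt^2)
    qa <- sum(yd * tt) / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, p)
    yd <- yd - qa * tt
    Wm[, a] <- w; Pm[, a] <- p; Tm[, a] <- tt; q[a] <- qa
  }
  b <- drop(Wm %*% solve(crossprod(Pm, Wm), q))
  b0 <- y_mean - sum(x_mean * b)
  structure(list(weights = Wm, x_loadings = Pm, y_loadings = q, scores = Tm,
                 b = b, b0 = b0, x_mean = x_mean, y_mean = y_mean,
                 n_lv = n_lv, residuals = yc - drop(Xc %*% b),
                 wavelength_grid = wavelengths),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d latent variables, %d wavelengths, training RMSE(y) = %.3g\n",
              x$n_lv, length(x$b), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Choose the number of latent variables by blocked cross-validation
#'
#' Contiguous-block cross-validation (blocks of consecutive rows, which
#' respects time order and avoids leakage between neighbouring spectra of
#' the same batch) over 1..max_lv components. Returns the smallest number
#' of latent variables whose CV RMSE is within one standard error of the
#' minimum, so noise is not chased.
#'
#' @param X predictor matrix, `y` response (uncentred; centring is redone
#'   inside each training fold).
#' @param y numeric response.
#' @param max_lv largest model order to consider.
#' @param folds number of contiguous blocks, >= 2.
#' @return the selected number of latent variables.
#' @export
select_n_lv <- function(X, y, max_lv, folds = 5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  N <- nrow(X)
  if (folds < 2) stop("select_n_lv: folds must be >= 2")
  if (max_lv > min(N - ceiling(N / folds) - 1, ncol(X))) {
    stop("select_n_lv: max_lv exceeds the rank available after holding out a fold")
  }
  fold_id <- cut(seq_len(N), breaks = folds, labels = FALSE)
  err <- matrix(NA_real_, folds, max_lv)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    for (a in seq_len(max_lv)) {
      m <- fit_pls_nipals(X[tr, , drop = FALSE], y[tr], a)
      pred <- drop(X[!tr, , drop = FALSE] %*% m$b) + m$b0
      err[k, a] <- mean((pred - y[!tr])^2)
    }
  }
  rmse <- sqrt(colMeans(err))
  se <- apply(sqrt(err), 2, stats::sd) / sqrt(folds)
  best <- which.min(rmse)
  min(which(rmse <= rmse[best] + se[best]))
}

#' Predict moisture from absorbance spectra
#'
#' Applies the regression vector to centred spectra and back-transforms
#' the log10 response: \eqn{\hat f_w = 10^{(x - \bar x) b + \bar y}}.
#' Predictions outside (0, 1) are kept but flagged.
#'
#' @param model a [pls_model].
#' @param spectra a length-W vector, an N x W matrix, or an absorbance
#'   [spectra_series] (whose grid is then checked against the model's).
#' @return numeric vector of predicted wet-basis moisture fractions with
#'   attribute `out_of_range` (logical vector).
#' @export
predict_moisture <- function(model, spectra) {
  stopifnot(inherits(model, "pls_model"))
  if (inherits(spectra, "spectra_series")) {
    if (!is.null(model$wavelength_grid) &&
        !isTRUE(all.equal(spectra$wavelengths, model$wavelength_grid))) {
      stop(sprintf(
        "predict_moisture: wavelength grid mismatch (model %.0f-%.0f nm, spectra %.0f-%.0f nm)",
        min(model$wavelength_grid), max(model$wavelength_grid),
        min(spectra$wavelengths), max(spectra$wavelengths)))
    }
    X <- spectra$values
  } else {
    X <- if (is.matrix(spectra)) spectra else matrix(spectra, nrow = 1)
  }
  if (ncol(X) != length(model$b)) {
    stop(sprintf("predict_moisture: spectra have %d points, model expects %d",
                 ncol(X), length(model$b)))
  }
  yhat <- drop(sweep(X, 2, model$x_mean) %*% model$b) + model$y_mean
  fw <- 10^yhat
  attr(fw, "out_of_range") <- fw <= 0 | fw >= 1
  fw
}

#' Root-mean-square relative prediction error
#'
#' \deqn{e_{rel} = \sqrt{\frac{1}{N}\sum_i
#'   \left(\frac{pred_i - ref_i}{ref_i}\right)^2} \times 100\%}
#'
#' @param pred,ref moisture fractions of equal length; `ref` > 0.
#' @return the error in percent.
#' @export
relative_error <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  if (any(ref <= 0)) stop("relative_error: reference values must be > 0")
  100 * sqrt(mean(((pred - ref) / ref)^2))
}

#' Pair LOD reference samples with preprocessed spectra
#'
#' Matches each loss-on-drying observation to the spectrum whose timestamp
#' is nearest, discarding pairs more than `max_gap` seconds apart.
#'
#' @param spectra an absorbance [spectra_series].
#' @param lod data.frame with `time` and `f_w_obs`.
#' @param max_gap largest tolerated time difference, s.
#' @return data.frame with `row` (spectrum index), `time`, `f_w_obs`, `gap`.
#' @export
pair_lod_spectra <- function(spectra, lod, max_gap = 30) {
  stopifnot(inherits(spectra, "spectra_series"))
  idx <- vapply(lod$time, function(t) which.min(abs(spectra$timestamps - t)),
                integer(1))
  gap <- abs(spectra$timestamps[idx] - lod$time)
  keep <- gap <= max_gap
  data.frame(row = idx[keep], time = lod$time[keep],
             f_w_obs = lod$f_w_obs[keep], gap = gap[keep])
}

#' Train the moisture calibration from spectra and LOD samples
#'
#' The calibration work-flow: pair each LOD sample with its nearest
#' preprocessed spectrum, regress the log10 moisture on the spectra with
#' NIPALS PLS, selecting the model order by blocked cross-validation.
#'
#' @param spectra an absorbance [spectra_series] (or a list of them, one
#'   per calibration batch; rows are pooled and blocks respect batches).
#' @param lod a data.frame (or list of data.frames) of LOD observations.
#' @param max_lv largest model order considered.
#' @param folds cross-validation blocks.
#' @param max_gap pairing tolerance, s.
#' @return a [pls_model]; the pairing table(s) are attached as
#'   attribute `pairs`.
#' @export
train_moisture_model <- function(spectra, lod, max_lv = 6, folds = 5,
                                 max_gap = 30) {
  if (inherits(spectra, "spectra_series")) spectra <- list(spectra)
  if (is.data.frame(lod)) lod <- list(lod)
  stopifnot(length(spectra) == length(lod))
  Xs <- list(); ys <- list(); pairs <- list()
  for (i in seq_along(spectra)) {
    pr <- pair_lod_spectra(spectra[[i]], lod[[i]], max_gap)
    if (nrow(pr) == 0) stop(sprintf("train_moisture_model: no usable pairs in batch %d", i))
    Xs[[i]] <- spectra[[i]]$values[pr$row, , drop = FALSE]
    ys[[i]] <- log10(pr$f_w_obs)
    pairs[[i]] <- pr
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  max_lv <- min(max_lv, nrow(X) - ceiling(nrow(X) / folds) - 1, ncol(X))
  n_lv <- select_n_lv(X, y, max_lv, folds)
  model <- fit_pls_nipals(X, y, n_lv, wavelengths = spectra[[1]]$wavelengths)
  attr(model, "pairs") <- pairs
  model
}
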