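#' Build a PCA-based MSPC model from end-point spectra
#'
#' Principal components are taken from the singular value decomposition of
#' the column-centred matrix of normal-operating-condition end-point
#' spectra (after SNV, applied by the caller). The residual eigenvalues
#' (those beyond the retained components, from the training residual
#' covariance) feed the Jackson-Mudholkar control limits on the
#' Q-statistic. When `n_pc = "auto"`, the order is chosen by row-wise
#' cross-validated PRESS: each held-out row is projected on loadings
#' fitted without it and the squared reconstruction error is accumulated;
#' the order with minimum PRESS over `1..max_pc` wins.
#'
#' @param X_endpoint N x W matrix (or absorbance [spectra_series]) of
#'   preprocessed end-point spectra.
#' @param n_pc number of principal components, or `"auto"`.
#' @param max_pc search ceiling for the automatic choice.
#' @param alpha confidence levels for the control limits.
#' @return object of class `mspc_model`: orthonormal `loadings`
#'   (n_pc x W), `x_mean`, `n_pc`, `residual_eigenvalues`, and `limits`
#'   (named vector of Q limits).
#' @export
build_mspc <- function(X_endpoint, n_pc = "auto", max_pc = 5,
                       alpha = c(0.95, 0.99)) {
  if (inherits(X_endpoint, "spectra_series")) X_endpoint <- X_endpoint$values
  X <- as.matrix(X_endpoint)
  N <- nrow(X)
  if (N < 3) stop("build_mspc: too few end-point spectra")
  if (any(apply(X, 1, stats::sd) == 0)) stop("build_mspc: degenerate (constant) spectrum in training set")
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  if (identical(n_pc, "auto")) {
    ## row-wise PRESS with element-wise deletion: held-out rows have their
    ## coordinates split into groups; each group is predicted from the
    ## remaining coordinates through the training loadings. Plain
    ## projection PRESS would decrease monotonically with the order.
    max_pc <- min(max_pc, N - 2, ncol(X))
    folds <- min(10, N)
    fold_id <- rep_len(seq_len(folds), N)        # interleaved, mixes batches
    coord_id <- rep_len(seq_len(7), ncol(X))
    press <- numeric(max_pc)
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      mu <- colMeans(X[tr, , drop = FALSE])
      sv <- svd(sweep(X[tr, , drop = FALSE], 2, mu), nu = 0, nv = max_pc)
      Xo <- sweep(X[!tr, , drop = FALSE], 2, mu)
      for (a in seq_len(max_pc)) {
        V <- sv$v[, seq_len(a), drop = FALSE]
        for (g in seq_len(7)) {
          miss <- coord_id == g
          Vo <- V[!miss, , drop = FALSE]
          sc <- Xo[, !miss, drop = FALSE] %*% Vo %*%
            solve(crossprod(Vo) + diag(1e-12, a))
          pred <- sc %*% t(V[miss, , drop = FALSE])
          press[a] <- press[a] + sum((Xo[, miss, drop = FALSE] - pred)^2)
        }
      }
    }
    n_pc <- which.min(press)
  }
  if (n_pc >= N) stop("build_mspc: n_pc must be < number of training spectra")
  sv <- svd(Xc, nu = 0)
  P <- t(sv$v[, seq_len(n_pc), drop = FALSE])       # n_pc x W, orthonormal rows
  eig <- sv$d^2 / (N - 1)                           # eigenvalues of cov(Xc)
  resid_eig <- eig[-seq_len(n_pc)]
  resid_eig <- resid_eig[resid_eig > 1e-12 * eig[1]]
  limits <- if (length(resid_eig) > 0) {
    vapply(alpha, function(a) jm_limit(resid_eig, a), numeric(1))
  } else {
    rep(0, length(alpha))
  }
  names(limits) <- sprintf("q%g", 100 * alpha)
  structure(list(loadings = P, x_mean = x_mean, n_pc = n_pc,
                 residual_eigenvalues = resid_eig, limits = limits,
                 snv_applied = TRUE),
            class = "mspc_model")
}

#' @export
print.mspc_model <- function(x, ...) {
  cat(sprintf("mspc_model: %d principal components, %d wavelengths; Q limits: %s\n",
              x$n_pc, ncol(x$loadings),
              paste(sprintf("%s = %.4g", names(x$limits), x$limits), collapse = ", ")))
  invisible(x)
}

#' Q-statistic (squared prediction error) of a new spectrum
#'
#' Residual sum of squares of the centred spectrum after projection onto
#' the model plane: \eqn{e = x (I - P^T P)}, \eqn{Q = e e^T}.
#'
#' @param model an [mspc_model].
#' @param x_new a length-W preprocessed spectrum, or an N x W matrix.
#' @return Q value(s), >= 0.
#' @export
q_statistic <- function(model, x_new) {
  stopifnot(inherits(model, "mspc_model"))
  X <- if (is.matrix(x_new)) x_new else matrix(x_new, nrow = 1)
  if (ncol(X) != ncol(model$loadings)) {
    stop(sprintf("q_statistic: spectrum has %d points, model expects %d",
                 ncol(X), ncol(model$loadings)))
  }
  Xc <- sweep(X, 2, model$x_mean)
  scores <- Xc %*% t(model$loadings)
  E <- Xc - scores %*% model$loadings
  drop(rowSums(E^2))
}

#' Jackson-Mudholkar control limit for the Q-statistic
#'
#' Closed-form upper quantile of the distribution of a weighted sum of
#' chi-square(1) variables, from the first three moments of the residual
#' eigenvalues: \eqn{\theta_i = \sum_j \lambda_j^i},
#' \eqn{h_0 = 1 - 2\theta_1\theta_3 / (3\theta_2^2)},
#' \deqn{Q_\alpha = \theta_1 \left[ \frac{c_\alpha\sqrt{2\theta_2 h_0^2}}
#'   {\theta_1} + 1 + \frac{\theta_2 h_0 (h_0 - 1)}{\theta_1^2}
#'   \right]^{1/h_0}.}
#'
#' The power-normal transform behind the formula requires h0 > 0; for
#' heavily skewed residual spectra h0 can turn negative, where the formula
#' loses monotonicity in alpha. In that regime the limit falls back to the
#' two-moment chi-square approximation \eqn{Q_\alpha = g\,\chi^2_h(\alpha)}
#' with \eqn{g = \theta_2/\theta_1} and \eqn{h = \theta_1^2/\theta_2},
#' which is exact for equal eigenvalues and always monotone.
#'
#' @param residual_eigenvalues eigenvalues of the training residual
#'   covariance (those not retained in the model); at least one positive.
#' @param alpha confidence level in (0, 1), typically 0.95 or 0.99.
#' @return the Q control limit.
#' @export
jm_limit <- function(residual_eigenvalues, alpha = 0.95) {
  lam <- residual_eigenvalues[residual_eigenvalues > 0]
  if (length(lam) == 0) stop("jm_limit: no positive residual eigenvalues (no residual space)")
  if (alpha <= 0 || alpha >= 1) stop("jm_limit: alpha must lie in (0, 1)")
  th1 <- sum(lam); th2 <- sum(lam^2); th3 <- sum(lam^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (h0 <= 0) {
    return(th2 / th1 * stats::qchisq(alpha, th1^2 / th2))
  }
  ca <- stats::qnorm(alpha)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Detect the drying end-point from a Q-statistic trace
#'
#' The end-point is declared at the first run of `run_length` consecutive
#' observations below the control limit. The reported index is, by
#' default, the first observation of that run (`report = "first"`); the
#' conservative alternative `report = "last"` gives the observation that
#' completes the run.
#'
#' @param q_trace time-ordered Q values.
#' @param limit control limit (normally the 95% Jackson-Mudholkar limit).
#' @param run_length required consecutive sub-limit observations; >= 1.
#' @param report `"first"` or `"last"` observation of the detecting run.
#' @return 1-based index of the end-point, or `NA_integer_` if the batch
#'   never satisfies the rule (off-specification).
#' @export
detect_endpoint <- function(q_trace, limit, run_length = 10,
                            report = c("first", "last")) {
  report <- match.arg(report)
  if (length(q_trace) == 0) stop("detect_endpoint: empty trace")
  if (run_length < 1) stop("detect_endpoint: run_length must be >= 1")
  below <- q_trace < limit
  r <- rle(below)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0) return(NA_integer_)
  start <- ends[hit[1]] - r$lengths[hit[1]] + 1L
  if (report == "first") start else start + run_length - 1L
}

#' Q-statistic control chart for a monitored batch
#'
#' Projects every spectrum of a batch onto the MSPC model and tabulates
#' the chart: Q value, both control limits, the below-limit flag, and the
#' detected end-point (as an attribute).
#'
#' @param model an [mspc_model].
#' @param spectra preprocessed absorbance [spectra_series] (same
#'   preprocessing as the training spectra, SNV included).
#' @param run_length consecutive-observation rule for the end-point.
#' @return data.frame with `time`, `Q`, `limit95`, `limit99`, `below`;
#'   attributes `endpoint_index` and `endpoint_time` (NA when the batch
#'   never meets the rule).
#' @export
q_chart <- function(model, spectra, run_length = 10) {
  stopifnot(inherits(spectra, "spectra_series"))
  q <- q_statistic(model, spectra$values)
  lim95 <- model$limits[["q95"]]
  lim99 <- if ("q99" %in% names(model$limits)) model$limits[["q99"]] else NA_real_
  out <- data.frame(time = spectra$timestamps, Q = q,
                    limit95 = lim95, limit99 = lim99, below = q < lim95)
  idx <- detect_endpoint(q, lim95, run_length)
  attr(out, "endpoint_index") <- idx
  attr(out, "endpoint_time") <- if (is.na(idx)) NA_real_ else spectra$timestamps[idx]
  out
}
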