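#' Time series of NIR spectra on a fixed wavelength grid
#'
#' @param wavelengths strictly increasing wavelength grid, nm (length W).
#' @param timestamps non-decreasing acquisition times, s (length N).
#' @param values N x W numeric matrix of detector counts (`kind =
#'   "intensity"`) or absorbance units (`kind = "absorbance"`).
#' @param kind `"intensity"` or `"absorbance"`.
#' @param bright_ref,dark_ref length-W reference spectra; required for
#'   intensity data, where `bright_ref > dark_ref` elementwise.
#' @param meta free-form list of provenance metadata.
#' @return object of class `spectra_series`.
#' @export
spectra_series <- function(wavelengths, timestamps, values,
                           kind = c("intensity", "absorbance"),
                           bright_ref = NULL, dark_ref = NULL, meta = list()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(is.numeric(wavelengths), is.numeric(timestamps))
  if (any(diff(wavelengths) <= 0)) stop("spectra_series: wavelengths must be strictly increasing")
  if (length(timestamps) > 1 && any(diff(timestamps) < 0)) {
    stop("spectra_series: timestamps must be non-decreasing")
  }
  if (nrow(values) != length(timestamps) || ncol(values) != length(wavelengths)) {
    stop(sprintf("spectra_series: values must be %d x %d, got %d x %d",
                 length(timestamps), length(wavelengths), nrow(values), ncol(values)))
  }
  if (kind == "intensity") {
    if (is.null(bright_ref) || is.null(dark_ref)) {
      stop("spectra_series: intensity data needs bright_ref and dark_ref")
    }
    stopifnot(length(bright_ref) == length(wavelengths),
              length(dark_ref) == length(wavelengths))
    if (any(bright_ref <= dark_ref)) {
      stop("spectra_series: bright_ref must exceed dark_ref at every wavelength")
    }
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 timestamps = as.numeric(timestamps),
                 values = unname(values), kind = kind,
                 bright_ref = if (!is.null(bright_ref)) as.numeric(bright_ref),
                 dark_ref = if (!is.null(dark_ref)) as.numeric(dark_ref),
                 meta = meta),
            class = "spectra_series")
}

#' @export
print.spectra_series <- function(x, ...) {
  cat(sprintf("spectra_series: %d %s spectra, %d wavelengths (%.0f-%.0f nm), t = %.0f..%.0f s\n",
              nrow(x$values), x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Average non-overlapping blocks of raw scans
#'
#' Individual scans from a fluidised bed are dominated by particle motion;
#' consecutive blocks of `block` intensity scans are averaged into a single
#' raw spectrum (default 10 scans, one spectrum per ~10 s at 1 scan/s).
#' Output timestamps are block means; a trailing partial block is dropped.
#'
#' @param raw intensity [spectra_series] with at least `block` scans.
#' @param block scans per block.
#' @return an intensity [spectra_series] with `floor(N/block)` spectra.
#' @export
block_average <- function(raw, block = 10) {
  stopifnot(inherits(raw, "spectra_series"))
  if (raw$kind != "intensity") stop("block_average: input must be intensity spectra")
  n <- nrow(raw$values)
  if (n < block) stop(sprintf("block_average: need at least %d scans, got %d", block, n))
  nb <- n %/% block
  grp <- rep(seq_len(nb), each = block)
  keep <- seq_len(nb * block)
  vals <- rowsum(raw$values[keep, , drop = FALSE], grp) / block
  ts <- as.numeric(rowsum(matrix(raw$timestamps[keep]), grp)) / block
  spectra_series(raw$wavelengths, ts, vals, "intensity",
                 raw$bright_ref, raw$dark_ref, raw$meta)
}

#' Transform intensity to absorbance using the reference spectra
#'
#' \eqn{A = -\log_{10}((I - dark)/(bright - dark))} per wavelength.
#' Non-physical transmittances (I <= dark) are clipped at 1e-6 and the
#' number of clipped points is recorded in `meta$clipped_points` and
#' reported by a warning.
#'
#' @param avg intensity [spectra_series] with both references.
#' @return absorbance [spectra_series].
#' @export
to_absorbance <- function(avg) {
  stopifnot(inherits(avg, "spectra_series"))
  if (avg$kind != "intensity") stop("to_absorbance: input must be intensity spectra")
  trans <- sweep(sweep(avg$values, 2, avg$dark_ref), 2,
                 avg$bright_ref - avg$dark_ref, "/")
  n_clip <- sum(trans <= 1e-6)
  if (n_clip > 0) {
    warning(sprintf("to_absorbance: %d non-positive transmittance points clipped at 1e-6", n_clip))
    trans[trans <= 1e-6] <- 1e-6
  }
  meta <- avg$meta
  meta$clipped_points <- n_clip
  spectra_series(avg$wavelengths, avg$timestamps, -log10(trans), "absorbance",
                 avg$bright_ref, avg$dark_ref, meta)
}

#' Causal moving-average filter over spectra
#'
#' Each output spectrum is the mean of the current and the `window - 1`
#' prior spectra (default 75, i.e. a 750 s memory at one spectrum per
#' 10 s). During warm-up the window expands from 1, preserving the series
#' length; the warm-up rows are flagged in `meta$warmup` (logical vector).
#'
#' @param abs_series absorbance [spectra_series].
#' @param window filter length in spectra, >= 1.
#' @return filtered absorbance [spectra_series] of the same length.
#' @export
moving_average <- function(abs_series, window = 75) {
  stopifnot(inherits(abs_series, "spectra_series"))
  if (abs_series$kind != "absorbance") stop("moving_average: input must be absorbance spectra")
  if (window < 1) stop("moving_average: window must be >= 1")
  n <- nrow(abs_series$values)
  cs <- apply(abs_series$values, 2, cumsum)
  cs <- rbind(0, cs)                           # cs[i+1,] = sum of rows 1..i
  lo <- pmax(seq_len(n) - window, 0)           # window covers rows lo+1 .. i
  out <- (cs[seq_len(n) + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) /
    (seq_len(n) - lo)
  meta <- abs_series$meta
  meta$warmup <- seq_len(n) < window
  spectra_series(abs_series$wavelengths, abs_series$timestamps, out, "absorbance",
                 abs_series$bright_ref, abs_series$dark_ref, meta)
}

#' Standard normal variate normalisation
#'
#' Centres and scales each spectrum individually to zero mean and unit
#' standard deviation across its wavelengths, removing multiplicative
#' scatter and baseline-offset effects. Used for the process-control
#' branch of the pipeline only.
#'
#' @param abs_series absorbance [spectra_series]; every spectrum must have
#'   nonzero standard deviation.
#' @return SNV-normalised absorbance [spectra_series].
#' @export
snv <- function(abs_series) {
  stopifnot(inherits(abs_series, "spectra_series"))
  if (abs_series$kind != "absorbance") stop("snv: input must be absorbance spectra")
  m <- rowMeans(abs_series$values)
  s <- apply(abs_series$values, 1, stats::sd)
  bad <- which(s == 0)
  if (length(bad) > 0) {
    stop("snv: zero-variance spectrum at row(s) ", paste(bad, collapse = ", "))
  }
  vals <- (abs_series$values - m) / s
  meta <- abs_series$meta
  meta$snv <- TRUE
  spectra_series(abs_series$wavelengths, abs_series$timestamps, vals, "absorbance",
                 abs_series$bright_ref, abs_series$dark_ref, meta)
}

#' Mean-centre a spectral matrix
#'
#' Subtracts the column mean, computing it when not supplied, and returns
#' the mean used so new spectra can be centred identically at prediction
#' time.
#'
#' @param X numeric matrix (rows = spectra).
#' @param mean optional pre-computed column-mean vector of length `ncol(X)`.
#' @return list with `X` (centred matrix) and `mean` (the vector used).
#' @export
mean_center <- function(X, mean = NULL) {
  X <- as.matrix(X)
  if (is.null(mean)) {
    mean <- colMeans(X)
  } else if (length(mean) != ncol(X)) {
    stop(sprintf("mean_center: mean has length %d but X has %d columns",
                 length(mean), ncol(X)))
  }
  list(X = sweep(X, 2, mean), mean = as.numeric(mean))
}

#' Run the standard preprocessing pipeline
#'
#' Fixed order: [block_average()] then [to_absorbance()] then
#' [moving_average()], with [snv()] appended when `use_snv = TRUE`
#' (the process-control branch). Mean-centring is left to the modelling
#' functions, which must store the mean.
#'
#' @param raw intensity [spectra_series] at the native scan rate.
#' @param block scans per block average.
#' @param window moving-average length in block-averaged spectra.
#' @param use_snv apply SNV after the moving average.
#' @return absorbance [spectra_series].
#' @export
preprocess_spectra <- function(raw, block = 10, window = 75, use_snv = FALSE) {
  out <- moving_average(to_absorbance(block_average(raw, block)), window)
  if (use_snv) out <- snv(out)
  out
}
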