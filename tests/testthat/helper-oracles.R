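## Independent oracles used to cross-check the package implementations.

## PLS1 by SIMPLS (de Jong 1993): builds the weight basis from the SVD of
## the successively projected cross-product, a different algebra from the
## NIPALS deflation it checks. Returns the regression vector and intercept
## on the uncentred scale.
oracle_simpls <- function(X, y, n_lv) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  s <- drop(crossprod(Xc, yc))
  R <- matrix(0, ncol(X), n_lv)
  V <- matrix(0, ncol(X), n_lv)
  for (a in seq_len(n_lv)) {
    r <- s
    t_ <- drop(Xc %*% r)
    nt <- sqrt(sum(t_^2))
    r <- r / nt
    t_ <- t_ / nt
    p <- drop(crossprod(Xc, t_))
    v <- p
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * sum(v * s)
    R[, a] <- r
    V[, a] <- v
  }
  Tm <- Xc %*% R
  q <- drop(crossprod(Tm, yc))            # t's orthonormal in SIMPLS scaling
  b <- drop(R %*% q)
  list(b = b, b0 = y_mean - sum(x_mean * b))
}

## Brute-force Q statistic: x (I - P'P)(I - P'P)' x' with the projector
## formed explicitly.
oracle_q <- function(P, x_centred) {
  M <- diag(ncol(P)) - t(P) %*% P
  drop(x_centred %*% M %*% t(M) %*% t(x_centred))
}

## Noise-free absorbance surface of the optics model, written out
## independently of the generator internals.
oracle_absorbance <- function(f_w, T_bed, optics) {
  wl <- optics$wavelength_grid
  amp <- optics$absorbance_per_moisture * optics$response_gamma *
    log(1 + f_w / optics$response_gamma)
  centre <- optics$water_band_center + optics$temp_shift * (T_bed - 25)
  amp * exp(-0.5 * ((wl - centre) / optics$water_band_width)^2) +
    optics$baseline_offset + optics$baseline_slope * (wl - wl[1])
}
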