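test_that("one predictor reduces PLS to ordinary least squares", {
  set.seed(21)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2.5 * x[, 1] + rnorm(30, 0, 0.1)
  m <- fit_pls_nipals(x, y, 1)
  ols <- cov(x[, 1], y) / var(x[, 1]) * (29 / 29)
  expect_equal(m$b, unname(ols), tolerance = 1e-12)
  expect_equal(m$b0, mean(y) - ols * mean(x), tolerance = 1e-12)
})

test_that("a two-factor response is recovered exactly with two components", {
  set.seed(22)
  Tm <- matrix(rnorm(40), 20, 2)
  P <- matrix(rnorm(16), 2, 8)
  X <- Tm %*% P
  y <- drop(Tm %*% c(1.5, -0.7)) + 3
  m <- fit_pls_nipals(X, y, 2)
  expect_lt(max(abs(m$residuals)), 1e-10)
  pred <- drop(X %*% m$b) + m$b0
  expect_equal(pred, y, tolerance = 1e-8)
})

test_that("NIPALS agrees with the SIMPLS oracle on random problems", {
  set.seed(23)
  for (rep in 1:50) {
    X <- matrix(rnorm(200), 20, 10)
    y <- rnorm(20)
    n_lv <- sample(1:5, 1)
    m <- fit_pls_nipals(X, y, n_lv)
    o <- oracle_simpls(X, y, n_lv)
    Xnew <- matrix(rnorm(50), 5, 10)
    expect_equal(drop(Xnew %*% m$b) + m$b0,
                 drop(Xnew %*% o$b) + o$b0, tolerance = 1e-8)
  }
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(24)
  X <- matrix(rnorm(600), 30, 20)
  y <- rnorm(30)
  m <- fit_pls_nipals(X, y, 5)
  G <- crossprod(m$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
})

test_that("shifting the response moves only the intercept", {
  set.seed(25)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  m1 <- fit_pls_nipals(X, y, 3)
  m2 <- fit_pls_nipals(X, y + 10, 3)
  expect_equal(m1$b, m2$b, tolerance = 1e-10)
  expect_equal(m2$b0 - m1$b0, 10, tolerance = 1e-10)
})

test_that("cross-validated order selection finds structure, resists noise", {
  set.seed(26)
  Tm <- matrix(rnorm(120), 60, 2)
  X <- Tm %*% matrix(rnorm(30), 2, 15) + matrix(rnorm(900, 0, 1e-6), 60, 15)
  y <- drop(Tm %*% c(1, -2))
  expect_equal(select_n_lv(X, y, max_lv = 5, folds = 5), 2)

  picks <- replicate(20, {
    Xn <- matrix(rnorm(300), 30, 10)
    yn <- rnorm(30)
    select_n_lv(Xn, yn, max_lv = 4, folds = 5)
  })
  expect_gte(mean(picks == 1), 0.9)

  expect_equal(select_n_lv(X, y, max_lv = 1, folds = 5), 1)
})

test_that("moisture prediction back-transforms and validates the grid", {
  set.seed(27)
  wl <- seq(1750, 1850, by = 10)
  X <- matrix(rnorm(length(wl) * 15, 0.5, 0.1), 15, length(wl))
  fw <- runif(15, 0.02, 0.3)
  m <- fit_pls_nipals(X, log10(fw), 3, wavelengths = wl)
  expect_equal(predict_moisture(m, m$x_mean), 10^m$y_mean,
               tolerance = 1e-12, ignore_attr = TRUE)
  sp <- spectra_series(wl + 100, 1:2, X[1:2, ], "absorbance")
  expect_error(predict_moisture(m, sp), "grid mismatch")
})

test_that("relative error reproduces its defining examples", {
  ref <- c(0.1, 0.2, 0.3)
  expect_identical(relative_error(ref, ref), 0)
  expect_equal(relative_error(1.1 * ref, ref), 10, tolerance = 1e-12)
  expect_equal(relative_error(c(1.2, 0.9, 1.0), c(1, 1, 1)),
               100 * sqrt(0.05 / 3), tolerance = 1e-10)
  expect_equal(round(relative_error(c(1.2, 0.9, 1.0), c(1, 1, 1)), 2), 12.91)
  expect_error(relative_error(ref, c(0, 0.2, 0.3)), "> 0")
})

test_that("LOD pairing matches nearest spectra within the tolerance", {
  wl <- seq(1750, 1760)
  sp <- spectra_series(wl, seq(5, 95, by = 10),
                       matrix(rnorm(110), 10, 11), "absorbance")
  lod <- data.frame(time = c(6, 52, 200), f_w_obs = c(0.3, 0.2, 0.1))
  pr <- pair_lod_spectra(sp, lod, max_gap = 30)
  expect_equal(pr$row, c(1, 6))           # 200 s is > 30 s from any spectrum
  expect_equal(pr$gap, c(1, 3))
})

test_that("regression vector reproduces sequential score prediction", {
  set.seed(28)
  X <- matrix(rnorm(300), 30, 10)
  y <- rnorm(30)
  m <- fit_pls_nipals(X, y, 4)
  ## walk a training row through the deflation algebra component by component
  x <- X[7, ] - m$x_mean
  yhat <- m$y_mean
  for (a in 1:4) {
    t_a <- sum(x * m$weights[, a])
    yhat <- yhat + t_a * m$y_loadings[a]
    x <- x - t_a * m$x_loadings[, a]
  }
  expect_equal(yhat, drop((X[7, ] - m$x_mean) %*% m$b) + m$y_mean,
               tolerance = 1e-8)
})
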