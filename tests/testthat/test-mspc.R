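rand_endpoint_data <- function(n = 40, w = 12, rank = 2, noise = 1e-4, seed = 31) {
  set.seed(seed)
  Tm <- matrix(rnorm(n * rank), n, rank) %*% diag(c(3, 1)[seq_len(rank)], rank)
  P <- qr.Q(qr(matrix(rnorm(w * rank), w, rank)))
  Tm %*% t(P) + matrix(rnorm(n * w, 0, noise), n, w)
}

test_that("cross-validation recovers the true component count", {
  X <- rand_endpoint_data()
  m <- build_mspc(X, n_pc = "auto")
  expect_equal(m$n_pc, 2)
})

test_that("loadings are orthonormal and a saturated model leaves no residual", {
  X <- rand_endpoint_data(noise = 0.05)
  m <- build_mspc(X, n_pc = 4)
  expect_equal(m$loadings %*% t(m$loadings), diag(4), tolerance = 1e-10)

  set.seed(32)
  Xi <- matrix(rnorm(6 * 5), 6, 5)           # independent rows, n_pc = N - 1
  mi <- build_mspc(Xi, n_pc = 5)
  expect_lt(max(q_statistic(mi, Xi)), 1e-20)
  expect_true(all(mi$limits == 0) || length(mi$residual_eigenvalues) == 0)
})

test_that("Q statistic matches the brute-force projector oracle", {
  X <- rand_endpoint_data(n = 30, w = 6, noise = 0.1)
  m <- build_mspc(X, n_pc = 2)
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(6)
    expect_equal(q_statistic(m, x), oracle_q(m$loadings, rbind(x - m$x_mean)),
                 tolerance = 1e-12)
  }
  ## in-plane spectra have Q = 0; orthogonal ones keep their full norm
  inplane <- m$x_mean + drop(c(1, -2) %*% m$loadings)
  expect_lt(q_statistic(m, inplane), 1e-20)
  ortho <- drop((diag(6) - t(m$loadings) %*% m$loadings) %*% rnorm(6))
  expect_equal(q_statistic(m, m$x_mean + ortho), sum(ortho^2), tolerance = 1e-10)
  ## adding any in-plane component leaves Q unchanged
  x <- rnorm(6)
  expect_equal(q_statistic(m, x + drop(c(3, 1) %*% m$loadings)),
               q_statistic(m, x), tolerance = 1e-10)
})

test_that("Jackson-Mudholkar limit: hand value, Monte Carlo, homogeneity", {
  hand <- (7 / 9 + qnorm(0.95) * sqrt(2) / 3)^3
  expect_equal(jm_limit(1, 0.95), hand, tolerance = 1e-12)
  expect_equal(jm_limit(1, 0.95), 3.75, tolerance = 1e-3)
  ## chi-square(1) 95th percentile is 3.841; JM should be within 5%
  expect_lt(abs(jm_limit(1, 0.95) - qchisq(0.95, 1)) / qchisq(0.95, 1), 0.05)
  lam <- c(0.9, 0.4, 0.1)
  expect_equal(jm_limit(7 * lam, 0.95), 7 * jm_limit(lam, 0.95), tolerance = 1e-10)
  expect_error(jm_limit(c(0, 0)), "eigenvalues")
})

test_that("the limit grows with confidence for benign and skewed spectra", {
  set.seed(34)
  for (i in 1:20) {
    lam <- rexp(sample(2:12, 1))^sample(1:3, 1)   # includes very skewed sets
    expect_gt(jm_limit(lam, 0.99), jm_limit(lam, 0.95))
  }
})

test_that("the 95% limit yields a ~5% false-alarm rate on Gaussian nulls", {
  lam <- c(1, 0.5, 0.2, 0.1)
  set.seed(35)
  q <- colSums(lam * matrix(rnorm(4 * 1e5)^2, 4))
  rate <- mean(q > jm_limit(lam, 0.95))
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("the run rule finds the first sustained sub-limit stretch", {
  expect_equal(detect_endpoint(c(rep(2, 5), rep(0.5, 10)), 1), 6L)
  expect_identical(detect_endpoint(c(rep(0.5, 9), 2, rep(0.5, 9)), 1), NA_integer_)
  expect_identical(detect_endpoint(rep(2, 40), 1), NA_integer_)
  expect_equal(detect_endpoint(c(rep(2, 5), rep(0.5, 10)), 1, report = "last"), 15L)
  expect_equal(detect_endpoint(rep(0.5, 3), 1, run_length = 2), 1L)
  expect_error(detect_endpoint(numeric(0), 1), "empty")
})

test_that("MSPC models survive a JSON round trip bit-for-bit in behaviour", {
  X <- rand_endpoint_data(noise = 0.02)
  m <- build_mspc(X, n_pc = 2)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  xs <- matrix(rnorm(5 * 12), 5, 12)
  expect_equal(q_statistic(m2, xs), q_statistic(m, xs), tolerance = 1e-12)
  expect_equal(m2$limits, m$limits, tolerance = 1e-12)
})
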