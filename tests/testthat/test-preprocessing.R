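make_intensity <- function(vals, ts = seq_len(nrow(vals))) {
  w <- ncol(vals)
  spectra_series(seq(1800, length.out = w), ts, vals, "intensity",
                 bright_ref = rep(10000, w), dark_ref = rep(500, w))
}

test_that("block averaging pools non-overlapping blocks and drops the tail", {
  one <- matrix(rep(c(1000, 2000, 3000), each = 10), 10, 3)
  b <- block_average(make_intensity(one), 10)
  expect_equal(nrow(b$values), 1)
  expect_equal(b$values[1, ], c(1000, 2000, 3000))
  expect_equal(b$timestamps, mean(1:10))

  x25 <- matrix(seq_len(25), 25, 4)
  b25 <- block_average(make_intensity(x25), 10)
  expect_equal(nrow(b25$values), 2)          # scans 21-25 dropped
  expect_equal(b25$values[, 1], c(mean(1:10), mean(11:20)))

  alt <- matrix(rep(c(800, 1200), 5), 10, 2)  # alternating a, b
  expect_equal(block_average(make_intensity(alt), 10)$values[1, ], c(1000, 1000))

  expect_error(block_average(make_intensity(x25[1:5, ]), 10), "at least 10")
})

test_that("absorbance transform reproduces exact transmittance anchors", {
  w <- 3
  I <- rbind(rep(10000, w),                       # at bright: A = 0
             rep(500 + 0.1 * 9500, w),            # T = 0.1: A = 1
             rep(500 + 0.5 * 9500, w))            # T = 0.5: A = 0.30103
  a <- to_absorbance(make_intensity(I))
  expect_equal(a$kind, "absorbance")
  expect_equal(a$values[1, ], rep(0, w), tolerance = 1e-12)
  expect_equal(a$values[2, ], rep(1, w), tolerance = 1e-12)
  expect_equal(a$values[3, ], rep(0.30103, w), tolerance = 1e-5)

  Ibad <- rbind(rep(400, w), rep(9000, w))        # below dark: clipped
  expect_warning(ab <- to_absorbance(make_intensity(Ibad)), "clipped")
  expect_equal(ab$meta$clipped_points, w)
  expect_equal(ab$values[1, ], rep(6, w))          # -log10(1e-6)
})

abs_series <- function(vals, ts = seq_len(nrow(vals))) {
  spectra_series(seq(1800, length.out = ncol(vals)), ts, vals, "absorbance")
}

test_that("causal moving average: warm-up, impulse, step response", {
  const <- matrix(2.5, 100, 3)
  expect_equal(moving_average(abs_series(const), 75)$values, const)

  imp <- matrix(0, 100, 1); imp[1, 1] <- 1
  out <- moving_average(abs_series(imp), 75)$values[, 1]
  expect_equal(out[75], 1 / 75)
  expect_equal(out[76], 0)
  expect_equal(out[1], 1)                    # expanding window at warm-up

  k <- 10
  stp <- matrix(0, 120, 1); stp[k:120, 1] <- 1
  outs <- moving_average(abs_series(stp), 75)$values[, 1]
  expect_lt(outs[k + 73], 1)
  expect_equal(outs[k + 74], 1)              # full by index k + window - 1

  expect_error(moving_average(abs_series(const), 0), "window")
})

test_that("moving average is linear in its input", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5)
  Y <- matrix(rnorm(200), 40, 5)
  fa <- function(m) moving_average(abs_series(m), 7)$values
  expect_equal(fa(2 * X + 3 * Y), 2 * fa(X) + 3 * fa(Y), tolerance = 1e-12)
})

test_that("SNV normalises each spectrum and is affine-invariant", {
  set.seed(4)
  X <- matrix(rnorm(60, 1, 0.3), 6, 10)
  s <- snv(abs_series(X))
  expect_equal(unname(rowMeans(s$values)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(s$values, 1, sd)), rep(1, 6), tolerance = 1e-12)

  Xa <- 3.2 * X + 0.7
  expect_equal(snv(abs_series(Xa))$values, s$values, tolerance = 1e-12)
  Xn <- -2 * X + 1
  expect_equal(snv(abs_series(Xn))$values, -s$values, tolerance = 1e-12)

  Xz <- X; Xz[4, ] <- 1
  expect_error(snv(abs_series(Xz)), "row\\(s\\) 4")
})

test_that("mean centring returns a reusable mean", {
  set.seed(5)
  X <- matrix(rnorm(50), 10, 5)
  mc <- mean_center(X)
  expect_equal(unname(colMeans(mc$X)), rep(0, 5), tolerance = 1e-14)
  xnew <- rnorm(5)
  rec <- mean_center(matrix(xnew, 1), mc$mean)
  expect_equal(drop(rec$X) + rec$mean, xnew, tolerance = 1e-14)
  expect_equal(mean_center(matrix(xnew, 1))$X, matrix(0, 1, 5))
  expect_error(mean_center(X, mean = 1:3), "length")
})

test_that("the pipeline recovers the generator's absorbance on clean data", {
  run <- static_run(f_w0 = 0.30, duration = 900)
  sp <- generate_spectra(run, quiet_optics())
  rec <- preprocess_spectra(sp, block = 10, window = 75)
  truth <- oracle_absorbance(0.30, 25, quiet_optics())
  for (i in c(1, nrow(rec$values))) {
    expect_equal(rec$values[i, ], truth, tolerance = 1e-10)
  }
})
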