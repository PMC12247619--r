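test_that("demean and polynomial detrending remove what they claim", {
  expect_equal(demean(rep(7, 50)), rep(0, 50))
  x <- sin(1:100)
  expect_equal(mean(demean(x)), 0, tolerance = 1e-15)
  # an exact cubic is annihilated
  t <- seq_len(400)
  cubic <- 2 + 0.5 * t - 0.01 * t^2 + 1e-5 * t^3
  expect_lt(max(abs(detrend_poly(cubic, 3))), 1e-8 * max(abs(cubic)))
  # order 0 is demeaning
  expect_equal(detrend_poly(x, 0), demean(x))
  # residual orthogonal to the polynomial basis, variance never increased
  set.seed(1)
  y <- cubic + rnorm(400)
  r <- detrend_poly(y, 3)
  basis <- cbind(1, stats::poly(t, 3))
  expect_lt(max(abs(crossprod(basis, r))), 1e-6)
  expect_lte(var(r), var(y))
})

test_that("zero-phase bandpass preserves the passband and rejects the stopband", {
  fs <- 10; n <- 6400
  f <- filter_spec(0.01, 0.1, 4096, fs)
  tt <- (0:(n - 1)) / fs
  gain_phase <- function(freq) {
    y <- bandpass_zero_phase(sin(2 * pi * freq * tt), f)
    v <- attr(y, "valid")
    X <- cbind(sin(2 * pi * freq * tt), cos(2 * pi * freq * tt))
    cf <- qr.coef(qr(X[v, ]), y[v])
    c(gain = sqrt(sum(cf^2)), phase = atan2(-cf[2], cf[1]))
  }
  gp_pass <- gain_phase(0.05)
  expect_gt(gp_pass["gain"], 0.99)
  expect_lt(gp_pass["gain"], 1.01)
  expect_lt(abs(gp_pass["phase"]), 0.01)
  expect_lt(gain_phase(1.0)["gain"], 0.01)
})

test_that("group-delay compensation yields a symmetric, centred impulse response", {
  fs <- 10; n <- 6400
  f <- filter_spec(0.01, 0.1, 4096, fs)
  x <- numeric(n); x[3000] <- 1
  y <- bandpass_zero_phase(x, f)
  expect_equal(which.max(y), 3000)
  k <- 1:800
  expect_lt(max(abs(y[3000 + k] - y[3000 - k])), 1e-12)
  # linearity to machine precision
  set.seed(2)
  a <- rnorm(n); b <- rnorm(n)
  lhs <- bandpass_zero_phase(2 * a - 3 * b, f)
  rhs <- 2 * bandpass_zero_phase(a, f) - 3 * bandpass_zero_phase(b, f)
  expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-10)
  # zero-phase: band-limited input cross-correlates with its output at lag 0
  xb <- sin(2 * pi * 0.05 * (0:(n - 1)) / fs) + 0.5 * sin(2 * pi * 0.03 * (0:(n - 1)) / fs)
  yb <- bandpass_zero_phase(xb, f)
  v <- attr(yb, "valid")
  cc <- stats::ccf(xb[v], yb[v], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("short signals cap the filter order instead of failing silently", {
  fs <- 5
  f <- filter_spec(0.01, 0.1, 4096, fs)
  x <- sin(2 * pi * 0.05 * (0:3199) / fs)
  expect_warning(y <- bandpass_zero_phase(x, f), "capped")
  expect_length(y, 3200)
  expect_error(bandpass_zero_phase(x, f, allow_short = FALSE), "order")
  expect_error(filter_spec(0.01, 0.1, 4095, fs), "even")
  expect_error(filter_spec(0.2, 0.1, 4096, fs), "high_hz")
})

test_that("z-scoring standardizes and rejects degenerate traces", {
  set.seed(3)
  x <- rnorm(500, mean = 10, sd = 4)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)
  # affine invariance (positive scale)
  expect_equal(zscore(3 * x + 100), z, tolerance = 1e-10)
  expect_error(zscore(rep(2, 10)), "constant")
})

test_that("tSNR is mean over whole-series SD, scale-invariant, and calibrated", {
  p <- stim_paradigm()
  spec <- laminar_response_spec(n_depth = 10, amplitude_profile = 0,
                                baseline_profile = 100, noise_sd_profile = 4,
                                drift_coeffs = 0, seed = 9)
  s <- simulate_series(spec, p)
  tsnr <- compute_tsnr(s)
  expect_true(all(abs(tsnr$values - 25) / 25 < 0.05))
  s2 <- s; s2$data <- 3.7 * s$data
  expect_equal(compute_tsnr(s2)$values, tsnr$values, tolerance = 1e-12)
  expect_error(compute_tsnr(matrix(1, 2, 100)), "constant")
})

test_that("the conditioning chain removes polynomial drift and keeps the baseline", {
  p <- small_paradigm()
  nt <- p$n_timepoints
  u <- seq(0, 1, length.out = nt)
  dat <- rbind(100 + 5 * u - 8 * u^3, 200 + 3 * u^2)
  s <- linescan_series(dat, tr_ms = p$tr_ms, depth_res_um = 50)
  out <- preprocess_series(s, f = NULL)
  # cubic drift removed exactly; per-depth mean restored
  expect_equal(out$data[1, ], rep(mean(dat[1, ]), nt), tolerance = 1e-8)
  expect_equal(rowMeans(out$data), rowMeans(dat), tolerance = 1e-10)
  stages <- vapply(out$meta$provenance, `[[`, "", "stage")
  expect_equal(stages, c("demean", "detrend_poly", "restore_baseline_mean"))
  # with filtering enabled the stage and its design values are recorded
  out2 <- preprocess_series(s, f = filter_spec(order = 100,
                                               fs_hz = 1000 / p$tr_ms))
  stages2 <- vapply(out2$meta$provenance, `[[`, "", "stage")
  expect_true("bandpass_zero_phase" %in% stages2)
})
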