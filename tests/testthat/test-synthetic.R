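test_that("amplitude profiles honor the peak contract", {
  grid <- depth_grid(40, 50)
  l4 <- make_amplitude_profile("l4_peak", peak_pct = 10, peak_depth_mm = 0.9,
                               width_mm = 0.4, grid = grid)
  expect_equal(max(l4$values), 10)
  expect_lte(abs(l4$depth_mm[which.max(l4$values)] - 0.9), 0.025 + 1e-12)
  surf <- make_amplitude_profile("surface_peak", peak_pct = 30, width_mm = 0.4,
                                 grid = grid)
  expect_equal(which.max(surf$values), 1)
  expect_equal(max(surf$values), 30)
  # infinite width -> flat profile at the peak value
  flat <- make_amplitude_profile("l4_peak", peak_pct = 7, width_mm = Inf,
                                 grid = grid)
  expect_equal(flat$values, rep(7, 40))
  # custom passes through unchanged
  v <- sin(seq_along(grid))
  expect_equal(make_amplitude_profile("custom", grid = grid, values = v)$values, v)
})

test_that("series generation is a pure function of the spec and seed", {
  p <- small_paradigm()
  spec <- laminar_response_spec(n_depth = 8, amplitude_profile = 5,
                                noise_sd_profile = 2, seed = 42)
  s1 <- simulate_series(spec, p)
  s2 <- simulate_series(spec, p)
  expect_identical(s1$data, s2$data)
  spec2 <- laminar_response_spec(n_depth = 8, amplitude_profile = 5,
                                 noise_sd_profile = 2, seed = 43)
  expect_false(identical(s1$data, simulate_series(spec2, p)$data))
  # the generator must not disturb the caller's RNG stream
  set.seed(7); a <- rnorm(1)
  set.seed(7); invisible(simulate_series(spec, p)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("noiseless series reproduce their ground truth through percent change", {
  p <- stim_paradigm()  # full 32-epoch paradigm at TR 100 ms
  amp <- make_amplitude_profile("l4_peak", peak_pct = 10, peak_depth_mm = 0.9,
                                width_mm = 0.4)
  spec <- laminar_response_spec(amplitude_profile = amp, noise_sd_profile = 0,
                                drift_coeffs = 0, seed = 1)
  s <- simulate_series(spec, p)
  avg <- epoch_average(percent_change(s, p), p)
  rec <- apply(avg$data, 1, max)
  # the response tail from the previous epoch leaks into the 1-s pre-stim
  # baseline (~1e-3 of peak), so recovery is near-exact, not exact
  expect_lt(max(abs(rec - spec$amplitude_profile)), 0.05)
  # with a response that is exactly zero in every pre-stim window the
  # round trip is exact to numerical precision
  r <- rep(c(rep(0, p$n_pre), rep(1, 20), rep(0, p$n_per_epoch - p$n_pre - 20)),
           p$n_epochs)
  dat <- spec$baseline_profile %o% rep(1, p$n_timepoints) *
    (1 + (spec$amplitude_profile / 100) %o% r)
  avg2 <- epoch_average(percent_change(dat, p), p)
  expect_lt(max(abs(apply(avg2, 1, max) - spec$amplitude_profile)), 1e-9)
})

test_that("energy accounting holds without drift and noise", {
  p <- small_paradigm()
  spec <- laminar_response_spec(n_depth = 6, amplitude_profile = 8,
                                baseline_profile = c(50, 80, 100, 120, 150, 200),
                                noise_sd_profile = 0, drift_coeffs = 0, seed = 1)
  s <- simulate_series(spec, p)
  reg <- build_design_regressor(p)
  expect_equal(rowMeans(s$data),
               spec$baseline_profile * (1 + spec$amplitude_profile / 100 * mean(reg)),
               tolerance = 1e-12)
})

test_that("designed noise levels yield the designed tSNR", {
  p <- stim_paradigm()  # 6400 timepoints
  spec <- laminar_response_spec(amplitude_profile = 0, noise_sd_profile = 100 / 30,
                                baseline_profile = 100, drift_coeffs = 0, seed = 11)
  tsnr <- compute_tsnr(simulate_series(spec, p))
  expect_true(all(abs(tsnr$values - 30) / 30 < 0.05))
})

test_that("2D line images give exact background fractions and nominal FWHM", {
  img <- simulate_line_image_2d(roi_width_mm = 1.5, edge_sigma_mm = 0,
                                background_frac = 0.05, noise_sd = 0)
  expect_equal(background_fraction(img)$fraction_pct, 5.0)
  prof <- colMeans(img$data)
  dy <- img$fov_mm[2] / ncol(img$data)
  expect_lt(abs(profile_fwhm(prof, dy) - 1.5), dy)
  # blurred edges: convolution of a 1.5 mm box with a 0.2 mm Gaussian keeps
  # the half-maximum width within one pixel of the box width
  img2 <- simulate_line_image_2d(roi_width_mm = 1.5, edge_sigma_mm = 0.2,
                                 background_frac = 0.05, noise_sd = 0)
  expect_lt(abs(profile_fwhm(colMeans(img2$data), dy) - 1.5), dy)
  # seeded noise is reproducible
  n1 <- simulate_line_image_2d(noise_sd = 0.02, seed = 5)
  n2 <- simulate_line_image_2d(noise_sd = 0.02, seed = 5)
  expect_identical(n1$data, n2$data)
})
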