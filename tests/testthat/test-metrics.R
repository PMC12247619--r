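test_that("percent change is zero for constant series and ignores stimulus windows in S0", {
  p <- small_paradigm()
  const <- matrix(100, 3, p$n_timepoints)
  expect_equal(percent_change(const, p), matrix(0, 3, p$n_timepoints))
  # S0 depends only on pre-stimulation samples
  box <- build_boxcar(p)
  perturbed <- const + 50 * rep(1, 3) %o% box
  pct <- percent_change(perturbed, p)
  pre_idx <- which(rep(seq_len(p$n_per_epoch), p$n_epochs) <= p$n_pre)
  expect_equal(pct[, pre_idx], matrix(0, 3, length(pre_idx)))
  expect_error(percent_change(const[, -1], p), "tile")
  expect_error(percent_change(matrix(-1, 1, p$n_timepoints), p), "baseline")
})

test_that("epoch averaging folds time correctly and shrinks iid noise", {
  p <- small_paradigm(n_epochs = 32, tr_ms = 500)
  one_epoch <- matrix(seq_len(2 * p$n_per_epoch), nrow = 2)
  periodic <- one_epoch[, rep(seq_len(p$n_per_epoch), p$n_epochs)]
  expect_equal(epoch_average(periodic, p), one_epoch)
  # single epoch is the identity
  p1 <- small_paradigm(n_epochs = 1)
  m1 <- matrix(rnorm(2 * p1$n_timepoints), 2)
  expect_equal(epoch_average(m1, p1), m1)
  # 32 iid epochs: SD shrinks by ~sqrt(32)
  set.seed(4)
  noise <- matrix(rnorm(p$n_timepoints), 1)
  ratio <- sd(noise) / sd(epoch_average(noise, p))
  expect_lt(abs(ratio - sqrt(32)) / sqrt(32), 0.15)
})

test_that("normalization conventions behave as documented", {
  m <- matrix(c(1, 2, 4, 3), 2)
  expect_equal(max(normalize_map(m)), 1)
  expect_equal(normalize_map(m), m / 4)
  expect_equal(normalize_map(5 * m), normalize_map(m))
  expect_equal(normalize_map(matrix(3, 2, 2)), matrix(1, 2, 2))
  # max(mean + SD) convention
  expect_equal(normalize_profiles_meansd(c(1, 2, 3), c(0, 0, 1)),
               c(0.25, 0.5, 0.75))
  expect_equal(normalize_profiles_meansd(c(1, 2, 3), c(0, 0, 0)),
               c(1, 2, 3) / 3)
  expect_lte(max(normalize_profiles_meansd(c(5, 1), c(2, 0))), 1)
})

test_that("peak layer detection maps the maximal depth to its layer with shallow tie-break", {
  grid <- depth_grid(40, 50)
  p <- stim_paradigm(n_epochs = 2)
  amp_l4 <- make_amplitude_profile("l4_peak", peak_pct = 10,
                                   peak_depth_mm = 0.9, width_mm = 0.4,
                                   grid = grid)
  avg <- amp_l4$values %o% build_design_regressor(stim_paradigm(n_epochs = 1))
  pk <- peak_layer(avg, grid)
  expect_equal(pk$layer, "L4")
  expect_equal(pk$peak_pct, 10)
  amp_surf <- make_amplitude_profile("surface_peak", peak_pct = 30,
                                     width_mm = 0.4, grid = grid)
  pk2 <- peak_layer(amp_surf$values %o% rep(1, 5), grid)
  expect_equal(pk2$layer, "L1")
  # a flat map ties everywhere -> shallowest depth wins
  pk3 <- peak_layer(matrix(1, 40, 5), grid)
  expect_equal(pk3$depth_mm, grid[1])
  # window-mean statistic
  pk4 <- peak_layer(avg, grid, stat = "window_mean", window = 11:70)
  expect_equal(pk4$layer, "L4")
})

test_that("laminar slope interpolates at layer midpoints per layer step", {
  grid <- depth_grid(40, 50)
  flat <- laminar_profile(rep(0.8, 40), grid)
  expect_equal(laminar_slope(flat), 0)
  # linear 1 -> 0 over 0-2 mm: slope = -(midpoint separation) / 2 mm
  lin <- laminar_profile(1 - grid / 2, grid)
  sep <- (0.15 + 0.70) / 2 - 0.15 / 2
  expect_equal(laminar_slope(lin), -sep / 2, tolerance = 1e-12)
  inc <- laminar_profile(grid, grid)
  expect_gt(laminar_slope(inc), 0)
  expect_error(laminar_slope(lin, from = "L9"), "L9")
})

test_that("FWHM interpolates half-maximum crossings around the global peak", {
  # Gaussian: FWHM = 2 sqrt(2 log 2) sigma
  x <- seq(-5, 5, by = 0.05)
  sigma <- 0.6366
  g <- exp(-x^2 / (2 * sigma^2))
  expect_lt(abs(profile_fwhm(g, 0.05) - 2 * sqrt(2 * log(2)) * sigma), 0.05)
  # rectangle of width w -> w
  r <- c(rep(0, 10), rep(1, 15), rep(0, 10))
  expect_equal(profile_fwhm(r, 0.1), 1.5)
  # bimodal: width of the lobe holding the global maximum
  bi <- c(rep(0, 5), rep(0.6, 10), rep(0, 5), rep(1, 4), rep(0, 5))
  expect_equal(profile_fwhm(bi, 1), 4)
})

test_that("background fraction is N_bkg over S_roi and swaps to its reciprocal", {
  img <- simulate_line_image_2d(roi_width_mm = 2, edge_sigma_mm = 0,
                                background_frac = 0.05, noise_sd = 0)
  bm <- background_fraction(img)
  expect_equal(bm$fraction_pct, 5)
  expect_equal(bm$fraction_pct, bm$n_bkg / bm$s_roi * 100)
  # outside all zero -> 0 %
  img0 <- simulate_line_image_2d(roi_width_mm = 2, edge_sigma_mm = 0,
                                 background_frac = 0, noise_sd = 0)
  expect_equal(background_fraction(img0)$fraction_pct, 0)
  # complementing the mask inverts the ratio: f' = 10^4 / f
  swapped <- line_image_2d(img$data, img$fov_mm, !img$roi_mask)
  expect_equal(background_fraction(swapped)$fraction_pct,
               1e4 / bm$fraction_pct, tolerance = 1e-10)
})

test_that("cortical surface detection scans from the shallow end", {
  # step profile 0 -> 100 at bin k
  prof <- c(rep(0, 7), rep(100, 13))
  expect_equal(detect_cortical_surface(prof)$index, 8)
  # everything above threshold -> first bin
  expect_equal(detect_cortical_surface(rep(50, 10))$index, 1)
  # ramp: first bin at or above half of the robust maximum (direct scan oracle)
  ramp <- seq(0, 100, length.out = 21)
  res <- detect_cortical_surface(ramp)
  expect_equal(res$index, which(ramp >= res$threshold)[1])
  expect_equal(res$threshold, 0.5 * quantile(ramp, 0.95, names = FALSE))
})

test_that("metrics are invariant to positive rescaling of the raw series", {
  p <- small_paradigm()
  spec <- laminar_response_spec(n_depth = 10, amplitude_profile = 6,
                                noise_sd_profile = 1, seed = 21)
  s <- simulate_series(spec, p)
  s3 <- s; s3$data <- 2.5 * s$data
  expect_equal(percent_change(s3, p)$data, percent_change(s, p)$data,
               tolerance = 1e-10)
  expect_equal(compute_tsnr(s3)$values, compute_tsnr(s)$values, tolerance = 1e-12)
  expect_equal(normalize_map(s3$data), normalize_map(s$data), tolerance = 1e-12)
})

test_that("percent change and epoch averaging commute on noiseless periodic input", {
  p <- small_paradigm(n_epochs = 8)
  spec <- laminar_response_spec(n_depth = 5, amplitude_profile = 10,
                                noise_sd_profile = 0, drift_coeffs = 0, seed = 1)
  s <- simulate_series(spec, p)
  # drop the non-stationary first epoch so the input is truly periodic
  per <- s$data[, -(1:p$n_per_epoch)]
  p7 <- small_paradigm(n_epochs = 7)
  a <- epoch_average(percent_change(per, p7), p7)
  p1 <- small_paradigm(n_epochs = 1)
  b <- percent_change(epoch_average(per, p7), p1)
  expect_equal(a, b, tolerance = 1e-9)
})
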