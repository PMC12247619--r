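#' Depth grid of a line-scanning acquisition
#'
#' Bin centres in mm, with index 1 at the cortical surface and depth of bin
#' i equal to `(i - 0.5) * depth_res_um / 1000`.
#'
#' @param n_depth Number of depth bins.
#' @param depth_res_um Depth resolution, micrometers.
#' @return Numeric vector of bin-centre depths, mm.
#' @export
depth_grid <- function(n_depth = 40, depth_res_um = 50) {
  assert_number(n_depth, "n_depth", lower = 1)
  assert_number(depth_res_um, "depth_res_um", lower = 0, closed_lower = FALSE)
  (seq_len(n_depth) - 0.5) * depth_res_um / 1000
}

#' Per-depth laminar profile
#'
#' Scalar values (tSNR, percent change, normalized BOLD, ...) on a strictly
#' increasing depth grid.
#'
#' @param values Finite numeric vector.
#' @param depth_mm Depth grid, mm, same length as `values`.
#' @param units Units tag, e.g. `"%"`, `"tSNR"`, `"norm"`.
#' @return Object of class `laminar_profile`.
#' @export
laminar_profile <- function(values, depth_mm, units = "") {
  if (!is.numeric(values) || any(!is.finite(values)))
    stopf("profile values must be finite numeric")
  if (length(values) != length(depth_mm))
    stopf("values and depth grid lengths differ (%d vs %d)",
          length(values), length(depth_mm))
  if (any(diff(depth_mm) <= 0)) stopf("depth grid must be strictly increasing")
  structure(list(values = as.numeric(values), depth_mm = as.numeric(depth_mm),
                 units = units), class = "laminar_profile")
}

#' @export
print.laminar_profile <- function(x, ...) {
  cat(sprintf("<laminar_profile> %d depths (%.3g-%.3g mm)%s; range [%.4g, %.4g]\n",
              length(x$values), min(x$depth_mm), max(x$depth_mm),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Laminar BOLD amplitude profile
#'
#' Gaussian-shaped percent-change amplitude across cortical depth.
#' `"surface_peak"` places the peak at the surface (the macrovessel-weighted,
#' gradient-echo-like pattern); `"l4_peak"` at a chosen depth, by default
#' 0.9 mm in layer 4 (the microvessel-weighted, spin-echo-like pattern);
#' `"custom"` passes an explicit vector through unchanged. The profile is
#' rescaled so its maximum equals `peak_pct` exactly at the grid point
#' nearest `peak_depth_mm`.
#'
#' @param kind `"surface_peak"`, `"l4_peak"` or `"custom"`.
#' @param peak_pct Peak amplitude, percent signal change.
#' @param peak_depth_mm Depth of the peak, mm (ignored for `surface_peak`,
#'   which uses 0).
#' @param width_mm Gaussian falloff scale, mm; `Inf` gives a flat profile.
#' @param grid Depth grid, mm (see [depth_grid()]).
#' @param values Explicit per-depth values for `kind = "custom"`.
#' @return A [laminar_profile()] in percent units.
#' @export
make_amplitude_profile <- function(kind = c("l4_peak", "surface_peak", "custom"),
                                   peak_pct = 10, peak_depth_mm = 0.9,
                                   width_mm = 0.4, grid = depth_grid(),
                                   values = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom") {
    if (is.null(values)) stopf("`values` required for kind = \"custom\"")
    return(laminar_profile(values, grid, units = "%"))
  }
  d0 <- if (kind == "surface_peak") 0 else peak_depth_mm
  if (!is.numeric(width_mm) || length(width_mm) != 1L || is.na(width_mm) ||
      width_mm <= 0)
    stopf("`width_mm` must be a single positive number (Inf allowed)")
  v <- if (is.infinite(width_mm)) rep(1, length(grid))
       else exp(-(grid - d0)^2 / (2 * width_mm^2))
  laminar_profile(peak_pct * v / max(v), grid, units = "%")
}

#' Specification of a synthetic laminar response
#'
#' Ground truth for [simulate_series()]: depth geometry, per-depth response
#' amplitude (percent), baseline intensity, Gaussian noise SD, a slow
#' polynomial drift and optional sinusoidal physiological confounds.
#' Scalars are recycled across depths.
#'
#' @param n_depth,depth_res_um Depth geometry (defaults 40 bins x 50 um,
#'   covering 0-2 mm of cortex).
#' @param amplitude_profile A [laminar_profile()] or numeric vector of
#'   percent-change amplitudes per depth.
#' @param baseline_profile Baseline signal per depth (positive).
#' @param noise_sd_profile Gaussian noise SD per depth (>= 0).
#' @param drift_coeffs Polynomial drift coefficients (constant first), in
#'   signal units, evaluated over normalized time `u` in `[0, 1]`. Order <= 3
#'   keeps the drift exactly removable by the default cubic detrend.
#' @param resp_amp,resp_hz,cardiac_amp,cardiac_hz Optional sinusoidal
#'   confound amplitudes (signal units) and frequencies (Hz); amplitudes
#'   default to 0 (off).
#' @param seed Integer seed; the generated series is a pure function of the
#'   spec (including this seed).
#' @return Object of class `laminar_response_spec`.
#' @export
laminar_response_spec <- function(n_depth = 40, depth_res_um = 50,
                                  amplitude_profile = make_amplitude_profile(
                                    grid = depth_grid(n_depth, depth_res_um)),
                                  baseline_profile = 100,
                                  noise_sd_profile = 2,
                                  drift_coeffs = 0,
                                  resp_amp = 0, resp_hz = 0.3,
                                  cardiac_amp = 0, cardiac_hz = 1,
                                  seed = 1L) {
  assert_number(n_depth, "n_depth", lower = 1)
  assert_number(depth_res_um, "depth_res_um", lower = 0, closed_lower = FALSE)
  n_depth <- as.integer(n_depth)
  amp <- if (inherits(amplitude_profile, "laminar_profile"))
    amplitude_profile$values else as.numeric(amplitude_profile)
  recycle <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, n_depth)
    if (length(x) != n_depth)
      stopf("`%s` length (%d) must be 1 or n_depth (%d)", name, length(x), n_depth)
    x
  }
  amp <- recycle(amp, "amplitude_profile")
  base <- recycle(baseline_profile, "baseline_profile")
  nsd <- recycle(noise_sd_profile, "noise_sd_profile")
  if (any(!is.finite(amp))) stopf("amplitude_profile must be finite")
  if (any(base <= 0)) stopf("baseline_profile must be positive")
  if (any(nsd < 0)) stopf("noise_sd_profile must be non-negative")
  structure(list(n_depth = n_depth, depth_res_um = depth_res_um,
                 amplitude_profile = amp, baseline_profile = base,
                 noise_sd_profile = nsd, drift_coeffs = as.numeric(drift_coeffs),
                 resp_amp = resp_amp, resp_hz = resp_hz,
                 cardiac_amp = cardiac_amp, cardiac_hz = cardiac_hz,
                 seed = as.integer(seed)),
            class = "laminar_response_spec")
}

#' Depth-by-time line-scanning series
#'
#' The central data object of the pipeline: a depth x time signal matrix
#' with its sampling interval and depth resolution. Row 1 is the cortical
#' surface.
#'
#' @param data Depth-by-time numeric matrix, all finite.
#' @param tr_ms Sampling interval, ms.
#' @param depth_res_um Depth resolution, micrometers.
#' @param meta Optional named list of metadata / provenance.
#' @return Object of class `linescan_series`.
#' @export
linescan_series <- function(data, tr_ms, depth_res_um, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (any(!is.finite(data))) stopf("series contains non-finite values")
  assert_number(tr_ms, "tr_ms", lower = 0, closed_lower = FALSE)
  assert_number(depth_res_um, "depth_res_um", lower = 0, closed_lower = FALSE)
  structure(list(data = data, tr_ms = tr_ms, depth_res_um = depth_res_um,
                 meta = meta), class = "linescan_series")
}

#' @export
print.linescan_series <- function(x, ...) {
  cat(sprintf("<linescan_series> %d depths x %d timepoints  TR %g ms  depth res %g um (%g s total)\n",
              nrow(x$data), ncol(x$data), x$tr_ms, x$depth_res_um,
              ncol(x$data) * x$tr_ms / 1000))
  invisible(x)
}

#' @rdname linescan_series
#' @param x Object to query.
#' @export
depths_mm <- function(x) {
  if (inherits(x, "linescan_series"))
    depth_grid(nrow(x$data), x$depth_res_um)
  else if (inherits(x, "laminar_profile")) x$depth_mm
  else stopf("no depth grid for class %s", paste(class(x), collapse = "/"))
}

#' Simulate a laminar line-scanning series
#'
#' Generates `data[d, t] = baseline[d] * (1 + amplitude[d]/100 * r[t]) +
#' drift(t) + confounds(t) + noise[d, t]` where `r` is the peak-normalized
#' block-design regressor of the paradigm, drift is the spec's polynomial
#' over normalized time, and noise is iid Gaussian per sample. Regeneration
#' with the same spec (seed included) is bit-identical; the caller's RNG
#' state is untouched.
#'
#' @param spec A [laminar_response_spec()].
#' @param p A [stim_paradigm()]; its TR becomes the series TR.
#' @param m An [hrf_model()] for the response shape.
#' @return A [linescan_series()] with ground truth recorded in `$meta`.
#' @export
simulate_series <- function(spec, p = stim_paradigm(tr_ms = 100),
                            m = hrf_model(duration_L_s = p$stim_s)) {
  if (!inherits(spec, "laminar_response_spec")) stopf("`spec` must be a laminar_response_spec")
  if (!inherits(p, "stim_paradigm")) stopf("`p` must be a stim_paradigm")
  reg <- build_design_regressor(p, m)
  nt <- p$n_timepoints
  nd <- spec$n_depth
  u <- seq(0, 1, length.out = nt)
  drift <- drop(outer(u, seq_along(spec$drift_coeffs) - 1, `^`) %*% spec$drift_coeffs)
  t_s <- (seq_len(nt) - 1) * p$tr_ms / 1000
  conf <- spec$resp_amp * sin(2 * pi * spec$resp_hz * t_s) +
    spec$cardiac_amp * sin(2 * pi * spec$cardiac_hz * t_s)
  clean <- spec$baseline_profile *
    (1 + outer(spec$amplitude_profile / 100, reg))
  clean <- sweep(clean, 2, drift + conf, `+`)
  noise <- with_seed(spec$seed,
                     matrix(stats::rnorm(nd * nt, sd = spec$noise_sd_profile),
                            nrow = nd, ncol = nt))
  linescan_series(clean + noise, tr_ms = p$tr_ms,
                  depth_res_um = spec$depth_res_um,
                  meta = list(generator = "simulate_series",
                              seed = spec$seed,
                              true_amplitude_pct = spec$amplitude_profile,
                              true_baseline = spec$baseline_profile,
                              noise_sd = spec$noise_sd_profile,
                              paradigm = unclass(p)[c("pre_s", "stim_s", "post_s",
                                                      "n_epochs", "tr_ms")]))
}

#' 2D in-plane line-profile image
#'
#' @param data Readout-by-phase numeric matrix.
#' @param fov_mm Length-2 field of view (readout, phase), mm.
#' @param roi_mask Logical matrix, same shape, marking the nominal ROI strip.
#' @return Object of class `line_image_2d`.
#' @export
line_image_2d <- function(data, fov_mm, roi_mask) {
  if (!is.matrix(data) || !is.numeric(data)) stopf("`data` must be a numeric matrix")
  if (!is.matrix(roi_mask) || !is.logical(roi_mask) ||
      !all(dim(roi_mask) == dim(data)))
    stopf("`roi_mask` must be a logical matrix matching `data`")
  if (!any(roi_mask)) stopf("ROI mask is empty")
  if (length(fov_mm) != 2 || any(fov_mm <= 0)) stopf("`fov_mm` must be two positive lengths")
  structure(list(data = data, fov_mm = as.numeric(fov_mm), roi_mask = roi_mask),
            class = "line_image_2d")
}

#' Simulate a 2D line-profile image
#'
#' Synthetic analogue of the 2D images acquired (phase encoding on) to judge
#' slice selectivity: a strip of unit intensity along the phase direction
#' with Gaussian-blurred edges, residual background signal outside, and
#' optional Gaussian noise. The nominal strip is returned as the ROI mask, so
#' [background_fraction()] on a noise-free image returns
#' `100 * background_frac` and the phase-axis 1D profile has FWHM close to
#' `roi_width_mm`.
#'
#' @param fov_mm Length-2 field of view (readout, phase), mm.
#' @param matrix_size Length-2 matrix size (readout, phase).
#' @param roi_width_mm Width of the selected strip along phase, mm.
#' @param edge_sigma_mm Gaussian edge blur, mm; 0 gives sharp edges.
#' @param background_frac Background intensity as a fraction of the in-ROI
#'   intensity (e.g. 0.05 for 5%).
#' @param noise_sd Gaussian noise SD (signal units); default 0.
#' @param seed Integer seed for the noise.
#' @return A [line_image_2d()].
#' @export
simulate_line_image_2d <- function(fov_mm = c(6.4, 12.8),
                                   matrix_size = c(64, 128),
                                   roi_width_mm = 1.5, edge_sigma_mm = 0.2,
                                   background_frac = 0.05,
                                   noise_sd = 0, seed = 1L) {
  assert_number(roi_width_mm, "roi_width_mm", lower = 0, closed_lower = FALSE)
  assert_number(edge_sigma_mm, "edge_sigma_mm", lower = 0)
  assert_number(background_frac, "background_frac", lower = 0, upper = 1)
  nx <- as.integer(matrix_size[1]); ny <- as.integer(matrix_size[2])
  y <- (seq_len(ny) - 0.5) * fov_mm[2] / ny
  ctr <- fov_mm[2] / 2
  lo <- ctr - roi_width_mm / 2; hi <- ctr + roi_width_mm / 2
  strip <- if (edge_sigma_mm > 0)
    stats::pnorm((y - lo) / edge_sigma_mm) - stats::pnorm((y - hi) / edge_sigma_mm)
  else as.numeric(y >= lo & y < hi)
  prof <- strip + background_frac * (1 - strip)
  img <- matrix(prof, nrow = nx, ncol = ny, byrow = TRUE)
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(nx * ny, sd = noise_sd), nx, ny))
  mask <- matrix(y >= lo & y < hi, nrow = nx, ncol = ny, byrow = TRUE)
  line_image_2d(img, fov_mm, mask)
}
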