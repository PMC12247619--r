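#' Cortical layer scheme
#'
#' Ordered layer labels with contiguous, non-overlapping depth intervals
#' spanning the imaged cortex. The defaults follow standard rat S1 histology
#' ranges over 0-2 mm; they are configuration, not anatomical constants.
#'
#' @param labels Layer labels, shallow to deep.
#' @param from_mm,to_mm Interval bounds, mm; `to_mm[i]` must equal
#'   `from_mm[i+1]`.
#' @return Object of class `layer_scheme` (a data frame with a `mid_mm`
#'   column of interval midpoints).
#' @export
layer_scheme <- function(labels = c("L1", "L2/3", "L4", "L5", "L6"),
                         from_mm = c(0, 0.15, 0.70, 1.10, 1.60),
                         to_mm = c(0.15, 0.70, 1.10, 1.60, 2.00)) {
  if (length(labels) != length(from_mm) || length(labels) != length(to_mm))
    stopf("labels/from_mm/to_mm lengths differ")
  if (any(to_mm <= from_mm)) stopf("each layer interval must have to > from")
  if (length(labels) > 1 && any(abs(from_mm[-1] - to_mm[-length(to_mm)]) > 1e-9))
    stopf("layer intervals must be contiguous")
  structure(data.frame(label = labels, from_mm = from_mm, to_mm = to_mm,
                       mid_mm = (from_mm + to_mm) / 2,
                       stringsAsFactors = FALSE),
            class = c("layer_scheme", "data.frame"))
}

#' @rdname layer_scheme
#' @param depth_mm Depth(s) to classify, mm.
#' @param scheme A `layer_scheme`.
#' @return `layer_of()`: character vector of labels (`NA` outside the scheme).
#' @export
layer_of <- function(depth_mm, scheme = layer_scheme()) {
  idx <- findInterval(depth_mm, c(scheme$from_mm, scheme$to_mm[nrow(scheme)]),
                      rightmost.closed = TRUE)
  out <- rep(NA_character_, length(depth_mm))
  ok <- idx >= 1 & idx <= nrow(scheme)
  out[ok] <- scheme$label[idx[ok]]
  out
}

#' Percent signal change relative to pre-stimulation baseline
#'
#' `(S - S0) / S0 * 100` per depth and timepoint, with `S0` the per-depth
#' mean over the union of every epoch's pre-stimulation window across the
#' whole series. The paradigm must tile the series exactly.
#'
#' @param series A [linescan_series()] or depth-by-time matrix.
#' @param p A [stim_paradigm()] with `pre_s > 0`.
#' @return Depth-by-time matrix of percent changes (a [linescan_series()]
#'   in `%` units when the input was one).
#' @export
percent_change <- function(series, p) {
  if (!inherits(p, "stim_paradigm")) stopf("`p` must be a stim_paradigm")
  dat <- if (inherits(series, "linescan_series")) series$data else series
  if (ncol(dat) != p$n_timepoints)
    stopf("series length (%d) does not tile the paradigm (%d timepoints)",
          ncol(dat), p$n_timepoints)
  if (p$n_pre < 1) stopf("paradigm has no pre-stimulation window")
  pre_idx <- as.vector(outer(seq_len(p$n_pre),
                             (seq_len(p$n_epochs) - 1) * p$n_per_epoch, `+`))
  s0 <- rowMeans(dat[, pre_idx, drop = FALSE])
  if (any(s0 <= 0)) stopf("non-positive baseline S0 at %d depth(s)", sum(s0 <= 0))
  pct <- (dat - s0) / s0 * 100
  if (inherits(series, "linescan_series")) {
    out <- series
    out$data <- pct
    out$meta$units <- "%"
    out
  } else pct
}

#' Average a depth-by-time matrix across epochs
#'
#' @param m Depth-by-time matrix (or [linescan_series()]) whose time axis is
#'   `n_epochs` repeats of one epoch.
#' @param p A [stim_paradigm()].
#' @return Depth-by-`n_per_epoch` matrix (same container as input).
#' @export
epoch_average <- function(m, p) {
  if (!inherits(p, "stim_paradigm")) stopf("`p` must be a stim_paradigm")
  dat <- if (inherits(m, "linescan_series")) m$data else m
  if (ncol(dat) != p$n_timepoints)
    stopf("time length (%d) does not match paradigm (%d)", ncol(dat), p$n_timepoints)
  arr <- array(dat, dim = c(nrow(dat), p$n_per_epoch, p$n_epochs))
  avg <- rowMeans(arr, dims = 2)
  if (inherits(m, "linescan_series")) {
    out <- m
    out$data <- avg
    out$meta$epoch_averaged <- TRUE
    out
  } else avg
}

#' Normalize a map by its maximum intensity
#'
#' @param m Numeric matrix or vector.
#' @return `m / max(m)` (maximum exactly 1).
#' @export
normalize_map <- function(m) {
  if (any(!is.finite(m))) stopf("map contains non-finite values")
  m / max(m)
}

#' Normalize a laminar profile by max(mean + SD)
#'
#' The "maximum mean value plus its standard deviation" convention for
#' normalized laminar BOLD profiles: the mean profile is divided by the
#' maximum over depth of (mean + SD), so trial variability at the peak is
#' folded into the normalizer and the normalized mean stays at or below 1.
#'
#' @param mean_profile,sd_profile Numeric vectors (or [laminar_profile()]s)
#'   of per-depth means and SDs.
#' @return A [laminar_profile()] (dimensionless) when the input carries a
#'   depth grid, else a numeric vector.
#' @export
normalize_profiles_meansd <- function(mean_profile, sd_profile) {
  mv <- if (inherits(mean_profile, "laminar_profile")) mean_profile$values else mean_profile
  sv <- if (inherits(sd_profile, "laminar_profile")) sd_profile$values else sd_profile
  if (length(mv) != length(sv)) stopf("mean and SD profiles differ in length")
  if (any(sv < 0)) stopf("SD profile must be non-negative")
  norm <- mv / max(mv + sv)
  if (inherits(mean_profile, "laminar_profile"))
    laminar_profile(norm, mean_profile$depth_mm, units = "norm")
  else norm
}

#' Peak BOLD layer of an epoch-averaged percent-change map
#'
#' Per depth, takes the temporal maximum of the epoch-averaged percent
#' change (or the mean over a supplied time window), then locates the depth
#' of the maximum — ties broken toward the shallower depth — and maps it to
#' a cortical layer.
#'
#' @param avg_pct Depth-by-epoch-time matrix of epoch-averaged percent
#'   change, or a [linescan_series()] holding one.
#' @param depth_mm Depth grid, mm (taken from the series if omitted).
#' @param scheme A [layer_scheme()].
#' @param stat `"max"` (default) or `"window_mean"`.
#' @param window Integer time indices for `stat = "window_mean"`.
#' @return List: `depth_mm`, `layer`, `peak_pct`, `profile` (the per-depth
#'   statistic as a [laminar_profile()]).
#' @export
peak_layer <- function(avg_pct, depth_mm = NULL, scheme = layer_scheme(),
                       stat = c("max", "window_mean"), window = NULL) {
  stat <- match.arg(stat)
  dat <- if (inherits(avg_pct, "linescan_series")) avg_pct$data else avg_pct
  if (!is.matrix(dat)) dat <- matrix(dat, ncol = 1)
  if (is.null(depth_mm))
    depth_mm <- if (inherits(avg_pct, "linescan_series")) depths_mm(avg_pct)
                else depth_grid(nrow(dat))
  prof <- switch(stat,
                 max = apply(dat, 1, max),
                 window_mean = {
                   if (is.null(window)) stopf("`window` required for stat = \"window_mean\"")
                   rowMeans(dat[, window, drop = FALSE])
                 })
  i <- which.max(prof)  # which.max returns the first (shallowest) maximum
  list(depth_mm = depth_mm[i], layer = layer_of(depth_mm[i], scheme),
       peak_pct = prof[i],
       profile = laminar_profile(prof, depth_mm, units = "%"))
}

#' Laminar slope of a normalized profile between two layers
#'
#' Difference of the profile values at the representative (midpoint) depths
#' of two layers, per one layer step; values are obtained by linear
#' interpolation on the depth grid. Negative slopes indicate a signal drop
#' from the shallower to the deeper layer.
#'
#' @param profile A [laminar_profile()].
#' @param scheme A [layer_scheme()].
#' @param from,to Layer labels (defaults `"L1"` to `"L2/3"`).
#' @return Slope in profile units per layer step.
#' @export
laminar_slope <- function(profile, scheme = layer_scheme(),
                          from = "L1", to = "L2/3") {
  if (!inherits(profile, "laminar_profile")) stopf("`profile` must be a laminar_profile")
  pick <- function(lab) {
    i <- match(lab, scheme$label)
    if (is.na(i)) stopf("layer \"%s\" not in scheme", lab)
    scheme$mid_mm[i]
  }
  v <- stats::approx(profile$depth_mm, profile$values,
                     xout = c(pick(from), pick(to)), rule = 2)$y
  v[2] - v[1]
}

#' Full width at half maximum of a 1D profile
#'
#' Width, at half the global maximum, of the lobe containing the global
#' peak (first peak on ties), with the half-maximum crossings located by
#' linear interpolation between samples. Profiles that never fall below the
#' half maximum on one side return `NA` with a warning.
#'
#' @param values Numeric profile.
#' @param spacing_mm Sample spacing, mm.
#' @return FWHM in mm (or `NA`).
#' @export
profile_fwhm <- function(values, spacing_mm = 1) {
  if (!is.numeric(values) || any(!is.finite(values))) stopf("profile must be finite numeric")
  assert_number(spacing_mm, "spacing_mm", lower = 0, closed_lower = FALSE)
  n <- length(values)
  ipk <- which.max(values)
  half <- values[ipk] / 2
  left <- NA_real_
  if (ipk > 1) for (i in seq(ipk - 1, 1)) if (values[i] < half) {
    # crossing between sample i (below half) and i+1 (above)
    left <- i + (half - values[i]) / (values[i + 1] - values[i])
    break
  }
  right <- NA_real_
  if (ipk < n) for (i in seq(ipk + 1, n)) if (values[i] < half) {
    right <- (i - 1) + (values[i - 1] - half) / (values[i - 1] - values[i])
    break
  }
  if (is.na(left) || is.na(right)) {
    # lobe touches the profile edge: clip to the support (half a sample out)
    if (is.na(left)) left <- 0.5
    if (is.na(right)) right <- n + 0.5
    warnf("half-maximum crossing off the profile edge; FWHM clipped to support")
  }
  (right - left) * spacing_mm
}

#' In-plane background signal fraction
#'
#' Residual signal outside the selected strip of a 2D line-profile image,
#' `N_bkg / S_roi * 100` with `N_bkg` the mean outside-ROI signal and
#' `S_roi` the mean in-ROI signal: a measure of slice-selection quality.
#'
#' @param img A [line_image_2d()].
#' @return List of class `background_metrics`: `s_roi`, `n_bkg`,
#'   `fraction_pct`.
#' @export
background_fraction <- function(img) {
  if (!inherits(img, "line_image_2d")) stopf("`img` must be a line_image_2d")
  if (all(img$roi_mask)) stopf("ROI mask covers the whole image; no background")
  s_roi <- mean(img$data[img$roi_mask])
  n_bkg <- mean(img$data[!img$roi_mask])
  if (s_roi <= 0) stopf("mean in-ROI signal must be positive")
  structure(list(s_roi = s_roi, n_bkg = n_bkg,
                 fraction_pct = n_bkg / s_roi * 100),
            class = "background_metrics")
}

#' @export
print.background_metrics <- function(x, ...) {
  cat(sprintf("<background_metrics> S_roi %.4g, N_bkg %.4g, background %.3g%%\n",
              x$s_roi, x$n_bkg, x$fraction_pct))
  invisible(x)
}

#' Detect the cortical surface from an intensity profile
#'
#' Scanning from the shallow end, returns the first depth index whose
#' intensity reaches `threshold_frac` of the robust maximum (the
#' `robust_q` quantile) of the profile — a documented, configurable
#' stand-in for surface definitions based on line-profile intensity.
#'
#' @param intensity A [laminar_profile()] or numeric vector of per-depth
#'   signal intensities (shallow first).
#' @param threshold_frac Fraction of the robust maximum; default 0.5.
#' @param robust_q Quantile defining the robust maximum; default 0.95.
#' @return List: `index`, `depth_mm` (`NA` for plain vectors without a
#'   grid), `threshold`.
#' @export
detect_cortical_surface <- function(intensity, threshold_frac = 0.5,
                                    robust_q = 0.95) {
  v <- if (inherits(intensity, "laminar_profile")) intensity$values else intensity
  assert_number(threshold_frac, "threshold_frac", lower = 0, upper = 1)
  thr <- threshold_frac * stats::quantile(v, robust_q, names = FALSE)
  idx <- which(v >= thr)[1]
  if (is.na(idx)) stopf("no sample reaches the surface threshold")
  list(index = idx,
       depth_mm = if (inherits(intensity, "laminar_profile"))
         intensity$depth_mm[idx] else NA_real_,
       threshold = thr)
}
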