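#' Bandpass filter specification
#'
#' Passband and FIR order of the zero-phase bandpass applied to each depth's
#' time course. Defaults follow the conventional slow-hemodynamics band
#' (0.01-0.1 Hz) with a 4096-tap linear-phase FIR.
#'
#' @param low_hz,high_hz Passband edges, Hz; `0 < low < high < fs/2`.
#' @param order Number of taps minus one; must be positive and even (so the
#'   group delay `order/2` is an integer number of samples).
#' @param fs_hz Sampling frequency, Hz (`1000 / tr_ms`).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.01, high_hz = 0.1, order = 4096, fs_hz) {
  assert_number(fs_hz, "fs_hz", lower = 0, closed_lower = FALSE)
  assert_number(low_hz, "low_hz", lower = 0, closed_lower = FALSE)
  assert_number(high_hz, "high_hz", lower = low_hz, upper = fs_hz / 2,
                closed_lower = FALSE, closed_upper = FALSE)
  assert_number(order, "order", lower = 2)
  if (order %% 2 != 0) stopf("`order` must be even, got %g", order)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 fs_hz = fs_hz), class = "filter_spec")
}

# apply fn along time: vector in, vector out -> same container out
apply_time <- function(x, fn) {
  if (inherits(x, "linescan_series")) {
    out <- x
    out$data <- t(apply(x$data, 1, fn))
    return(out)
  }
  if (is.matrix(x)) return(t(apply(x, 1, fn)))
  fn(x)
}

#' Remove the temporal mean
#'
#' @param x Numeric vector, depth-by-time matrix, or [linescan_series()];
#'   applied along time.
#' @return Same container with per-trace mean zero.
#' @export
demean <- function(x) apply_time(x, function(v) v - mean(v))

#' Remove a least-squares polynomial trend
#'
#' Fits a polynomial of the given order over time by ordinary least squares
#' and returns the residual; order 0 is equivalent to [demean()], order 3 is
#' the conventional slow-drift detrend.
#'
#' @param x Vector, matrix or [linescan_series()]; applied along time.
#' @param order Polynomial order (>= 0).
#' @return Same container, detrended.
#' @export
detrend_poly <- function(x, order = 3) {
  assert_number(order, "order", lower = 0)
  one <- function(v) {
    n <- length(v)
    if (order == 0) return(v - mean(v))
    basis <- cbind(1, stats::poly(seq_len(n), degree = min(order, n - 1)))
    v - drop(basis %*% qr.coef(qr(basis), v))
  }
  apply_time(x, one)
}

# design the linear-phase FIR bandpass for a spec (Hamming window, as the
# conventional default of windowed-sinc design routines)
design_bandpass <- function(f) {
  w <- c(f$low_hz, f$high_hz) / (f$fs_hz / 2)
  # strip fir1's "Ma" class: plain coefficients dispatch filter() correctly
  as.numeric(signal::fir1(f$order, w, type = "pass"))
}

#' Zero-phase FIR bandpass filtering
#'
#' Designs a linear-phase windowed-sinc (Hamming) bandpass of the given
#' order, filters each time course, and compensates the filter's constant
#' group delay of `order/2` samples by a circular shift. The `order/2`
#' samples at each end of the output are contaminated by the wrap/startup
#' transient; they are flagged `FALSE` in the `"valid"` attribute rather
#' than silently trusted.
#'
#' For signals shorter than the requested order the order is capped at the
#' largest even integer `<= length/3` (with a warning) when
#' `allow_short = TRUE`, otherwise an error is raised.
#'
#' @param x Vector, matrix or [linescan_series()]; applied along time.
#' @param f A [filter_spec()].
#' @param allow_short Cap the order for short signals? Default TRUE.
#' @return Same container, filtered, with logical attribute `"valid"` along
#'   time (stored in `$meta$filter_valid` for series input).
#' @export
bandpass_zero_phase <- function(x, f, allow_short = TRUE) {
  if (!inherits(f, "filter_spec")) stopf("`f` must be a filter_spec object")
  n <- if (inherits(x, "linescan_series")) ncol(x$data)
       else if (is.matrix(x)) ncol(x) else length(x)
  ord <- f$order
  if (ord >= n) {
    if (!allow_short)
      stopf("filter order (%d) must be smaller than signal length (%d)", ord, n)
    ord <- max(2L, 2L * (n %/% 6L))
    warnf("signal length %d < filter order %d; order capped at %d", n, f$order, ord)
    f <- filter_spec(f$low_hz, f$high_hz, ord, f$fs_hz)
  }
  b <- design_bandpass(f)
  d <- ord %/% 2L
  idx <- c((d + 1):n, 1:d)                      # circular shift left by d
  one <- function(v) {
    y <- if (ord > 256) signal::fftfilt(b, v) else
      as.numeric(signal::filter(b, 1, v))
    y[idx]
  }
  valid <- rep(TRUE, n); valid[c(1:d, (n - d + 1):n)] <- FALSE
  out <- apply_time(x, one)
  if (inherits(out, "linescan_series")) out$meta$filter_valid <- valid
  else attr(out, "valid") <- valid
  out
}

#' Z-score a time course
#'
#' `(x - mean) / sd` with the population SD convention (divide by N).
#'
#' @param x Vector, matrix or [linescan_series()]; applied along time.
#' @return Same container, mean 0 and SD 1 per trace.
#' @export
zscore <- function(x) {
  apply_time(x, function(v) {
    s <- sd_pop(v)
    if (s == 0) stopf("cannot z-score a constant time course (SD = 0)")
    (v - mean(v)) / s
  })
}

# population SD (divide by N); the convention used for z-score and tSNR
sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

#' Temporal signal-to-noise ratio across depths
#'
#' Per depth, the temporal mean divided by the standard deviation of the
#' whole time series (not of repeated baseline windows, which are too short
#' under a 4 s on / 16 s off paradigm to count as rest). Computed on the raw
#' series by default; pass a preprocessed series explicitly for the
#' filtered-series variant. Constant traces (SD = 0) are a degenerate input
#' and raise an error.
#'
#' @param series A [linescan_series()] or depth-by-time matrix.
#' @return A [laminar_profile()] of tSNR values (matrix input: plain vector).
#' @export
compute_tsnr <- function(series) {
  dat <- if (inherits(series, "linescan_series")) series$data else series
  if (!is.matrix(dat)) dat <- matrix(dat, nrow = 1)
  mu <- rowMeans(dat)
  sdv <- apply(dat, 1, sd_pop)
  if (any(sdv == 0))
    stopf("tSNR undefined: %d constant depth trace(s) with SD = 0", sum(sdv == 0))
  tsnr <- mu / sdv
  if (inherits(series, "linescan_series"))
    laminar_profile(tsnr, depths_mm(series), units = "tSNR")
  else tsnr
}

#' Standard per-voxel conditioning chain
#'
#' Applies, in the conventional order, demeaning, polynomial detrending and
#' the zero-phase bandpass to every depth of a series. With
#' `keep_baseline = TRUE` (default) the original per-depth temporal mean is
#' added back after filtering so percent-change computation downstream has a
#' well-defined baseline; the conditioning then only removes drift and
#' out-of-band fluctuations.
#'
#' @param series A [linescan_series()].
#' @param f A [filter_spec()]; defaults to 0.01-0.1 Hz, order 4096 at the
#'   series' sampling rate. `NULL` skips filtering.
#' @param detrend_order Polynomial detrend order; `NULL` skips detrending.
#' @param keep_baseline Restore the per-depth mean after conditioning?
#' @return A [linescan_series()]; the stages applied (and the design values
#'   used) are appended to `$meta$provenance`.
#' @export
preprocess_series <- function(series,
                              f = filter_spec(fs_hz = 1000 / series$tr_ms),
                              detrend_order = 3, keep_baseline = TRUE) {
  if (!inherits(series, "linescan_series")) stopf("`series` must be a linescan_series")
  mu <- rowMeans(series$data)
  out <- demean(series)
  prov <- list(list(stage = "demean"))
  if (!is.null(detrend_order)) {
    out <- detrend_poly(out, detrend_order)
    prov <- c(prov, list(list(stage = "detrend_poly", order = detrend_order)))
  }
  if (!is.null(f)) {
    out <- bandpass_zero_phase(out, f)
    prov <- c(prov, list(list(stage = "bandpass_zero_phase",
                              low_hz = f$low_hz, high_hz = f$high_hz,
                              order = f$order, window = "hamming",
                              delay_compensation = "circular shift order/2")))
  }
  if (keep_baseline) {
    out$data <- out$data + mu
    prov <- c(prov, list(list(stage = "restore_baseline_mean")))
  }
  out$meta$provenance <- c(series$meta$provenance %||% list(), prov)
  out
}
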