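#' Block-design stimulation paradigm
#'
#' Timing of a block paradigm: each epoch is `pre_s` seconds of baseline,
#' `stim_s` of stimulation and `post_s` of recovery, repeated `n_epochs`
#' times and sampled every `tr_ms` milliseconds. Every segment must be an
#' integer number of samples. The defaults are the evoked forepaw paradigm
#' used throughout this package: 1 s pre / 4 s stim / 15 s post, 32 epochs
#' (10 min 40 s at TR 100 ms).
#'
#' @param pre_s,stim_s,post_s Segment durations, seconds.
#' @param n_epochs Number of epochs (>= 1).
#' @param tr_ms Sampling interval, ms.
#' @return An object of class `stim_paradigm` with derived counts
#'   `n_pre`, `n_stim`, `n_post`, `n_per_epoch`, `n_timepoints`, `epoch_s`.
#' @export
#' @examples
#' stim_paradigm()  # 6400 timepoints
stim_paradigm <- function(pre_s = 1, stim_s = 4, post_s = 15,
                          n_epochs = 32, tr_ms = 100) {
  assert_number(pre_s, "pre_s", lower = 0)
  assert_number(stim_s, "stim_s", lower = 0, closed_lower = FALSE)
  assert_number(post_s, "post_s", lower = 0)
  assert_number(n_epochs, "n_epochs", lower = 1)
  assert_number(tr_ms, "tr_ms", lower = 0, closed_lower = FALSE)
  tr_s <- tr_ms / 1000
  segs <- c(pre_s, stim_s, post_s) / tr_s
  if (!all(is_whole(segs)))
    stopf("each segment must be an integer multiple of TR = %g ms", tr_ms)
  n <- as.integer(round(segs))
  structure(list(pre_s = pre_s, stim_s = stim_s, post_s = post_s,
                 n_epochs = as.integer(n_epochs), tr_ms = tr_ms,
                 n_pre = n[1], n_stim = n[2], n_post = n[3],
                 n_per_epoch = sum(n), epoch_s = pre_s + stim_s + post_s,
                 n_timepoints = sum(n) * as.integer(n_epochs)),
            class = "stim_paradigm")
}

#' @export
print.stim_paradigm <- function(x, ...) {
  cat(sprintf("<stim_paradigm> %g s pre / %g s stim / %g s post x %d epochs @ TR %g ms (%d timepoints, %g s)\n",
              x$pre_s, x$stim_s, x$post_s, x$n_epochs, x$tr_ms,
              x$n_timepoints, x$n_timepoints * x$tr_ms / 1000))
  invisible(x)
}

#' Stimulus boxcar for a paradigm
#'
#' @param p A [stim_paradigm()].
#' @return Binary vector of length `p$n_timepoints`: 1 during stimulation
#'   samples, 0 elsewhere.
#' @export
build_boxcar <- function(p) {
  if (!inherits(p, "stim_paradigm")) stopf("`p` must be a stim_paradigm object")
  epoch <- c(rep(0, p$n_pre), rep(1, p$n_stim), rep(0, p$n_post))
  rep(epoch, p$n_epochs)
}

#' Hemodynamic response model for block designs
#'
#' Describes the gamma-variate block response used for amplitude
#' estimation: the convolution of a square stimulus of duration
#' `duration_L_s` with the kernel [gamma_kernel()], optionally normalized
#' so the peak of the block response equals 1 (the conventional
#' "peak amplitude of block response = 1" convention, under which each GLM
#' beta is the peak percent change of the fitted response).
#'
#' @param duration_L_s Stimulus duration L, seconds.
#' @param dt_s Sampling step for discrete convolution, seconds.
#' @param normalize_peak Scale the block response to unit peak? Default TRUE.
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(duration_L_s = 4, dt_s = 0.1, normalize_peak = TRUE) {
  assert_number(duration_L_s, "duration_L_s", lower = 0, closed_lower = FALSE)
  assert_number(dt_s, "dt_s", lower = 0, closed_lower = FALSE)
  structure(list(duration_L_s = duration_L_s, dt_s = dt_s,
                 normalize_peak = isTRUE(normalize_peak)),
            class = "hrf_model")
}

#' Gamma-variate impulse kernel
#'
#' \deqn{g(t) = t^4 e^{-t} / (4^4 e^{-4})}
#' normalized to unit peak at t = 4 s; `g(t) = 0` for `t <= 0`.
#'
#' @param t_s Time(s), seconds. Vectorized.
#' @return Dimensionless kernel values.
#' @export
#' @examples
#' gamma_kernel(4)  # 1
gamma_kernel <- function(t_s) {
  if (!is.numeric(t_s) || any(!is.finite(t_s))) stopf("`t_s` must be finite numeric")
  out <- numeric(length(t_s))
  pos <- t_s > 0
  out[pos] <- t_s[pos]^4 * exp(-t_s[pos]) / (4^4 * exp(-4))
  out
}

# closed-form antiderivative of g on [0, x]
gamma_kernel_integral <- function(x) {
  ifelse(x <= 0, 0,
         (24 - exp(-x) * (x^4 + 4 * x^3 + 12 * x^2 + 24 * x + 24)) /
           (4^4 * exp(-4)))
}

#' Block hemodynamic response function
#'
#' \deqn{HRF(t) = \int_0^{\min(t, L)} g(s)\, ds}
#' evaluated in closed form; non-decreasing in t, zero at t = 0 and constant
#' (at its plateau) for `t >= L`. With `normalize_peak = TRUE` the plateau is
#' scaled to exactly 1.
#'
#' @param m An [hrf_model()].
#' @param t_s Time(s) since stimulus onset, seconds (>= 0). Vectorized.
#' @return Dimensionless response values.
#' @export
block_hrf <- function(m, t_s) {
  if (!inherits(m, "hrf_model")) stopf("`m` must be an hrf_model object")
  if (!is.numeric(t_s) || any(!is.finite(t_s))) stopf("`t_s` must be finite numeric")
  if (any(t_s < 0)) stopf("`t_s` must be non-negative")
  raw <- gamma_kernel_integral(pmin(t_s, m$duration_L_s))
  if (m$normalize_peak) raw / gamma_kernel_integral(m$duration_L_s) else raw
}

# kernel support beyond which g is negligible (< 1e-8 of its peak)
KERNEL_SUPPORT_S <- 32

#' Design regressor for a block paradigm
#'
#' Discrete convolution of the paradigm's stimulus boxcar with the
#' gamma-variate kernel sampled at the paradigm TR (kernel truncated at
#' 32 s support, where it has decayed below 1e-8 of its peak). With
#' `normalize_peak` the regressor is divided by its maximum so a GLM beta
#' against it reads as peak response amplitude.
#'
#' @param p A [stim_paradigm()].
#' @param m An [hrf_model()]; its `dt_s` is overridden by the paradigm TR.
#' @return Numeric vector of length `p$n_timepoints`.
#' @export
build_design_regressor <- function(p, m = hrf_model(duration_L_s = p$stim_s)) {
  if (!inherits(p, "stim_paradigm")) stopf("`p` must be a stim_paradigm object")
  if (!inherits(m, "hrf_model")) stopf("`m` must be an hrf_model object")
  dt <- p$tr_ms / 1000
  box <- build_boxcar(p)
  kern <- gamma_kernel(seq(0, KERNEL_SUPPORT_S, by = dt))
  full <- stats::convolve(box, rev(kern), type = "open")
  reg <- full[seq_along(box)] * dt
  if (m$normalize_peak) {
    mx <- max(reg)
    if (mx > 0) reg <- reg / mx
  }
  reg
}

#' Per-depth GLM amplitude estimation
#'
#' Ordinary least squares fit of each depth's time course against a design
#' with an intercept, a linear drift term and the stimulus regressor;
#' returns the regressor coefficient per depth. When the regressor is
#' peak-normalized, the beta is the peak response height in the units of the
#' series (percent change if the series is a percent-change matrix).
#'
#' @param series A `linescan_series` or a depth-by-time numeric matrix.
#' @param regressor Numeric vector matching the series time length.
#' @return Numeric vector of per-depth betas.
#' @export
glm_beta <- function(series, regressor) {
  dat <- if (inherits(series, "linescan_series")) series$data else series
  if (!is.matrix(dat)) dat <- matrix(dat, nrow = 1)
  nt <- ncol(dat)
  if (length(regressor) != nt)
    stopf("regressor length (%d) must equal series time length (%d)",
          length(regressor), nt)
  x <- cbind(intercept = 1,
             drift = seq(-1, 1, length.out = nt),
             stim = regressor)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)])]
    stopf("rank-deficient design: column(s) %s collinear with the rest",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, t(dat))["stim", ]
  unname(beta)
}
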