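# shared fixtures: small protocols, paradigms and specs built in code

se_protocol <- function(...) {
  args <- utils::modifyList(
    list(kind = "SE", tr_ms = 1000, te_ms = 20, exc_fa_deg = 90,
         refocus_fa_deg = 180, t2_ms = 24,
         readout_bw_hz = 5000, readout_fov_mm = 3.2, readout_matrix = 64L),
    list(...))
  do.call(sequence_params, args)
}

gre_protocol <- function(...) {
  args <- utils::modifyList(
    list(kind = "GRE", tr_ms = 100, te_ms = 12.5, exc_fa_deg = 50,
         t2_ms = 20, readout_bw_hz = 9014, readout_fov_mm = 6.4,
         readout_matrix = 128L),
    list(...))
  do.call(sequence_params, args)
}

# short paradigm for cheap tests: 20-s epochs at TR 500 ms
small_paradigm <- function(n_epochs = 4, tr_ms = 500) {
  stim_paradigm(pre_s = 1, stim_s = 4, post_s = 15,
                n_epochs = n_epochs, tr_ms = tr_ms)
}

# independent oracle: iterate the longitudinal Bloch recursion
# (excite alpha -> recover TE/2 -> refocus beta -> recover TR - TE/2)
# to steady state and read out the echo amplitude
bloch_recursion_ss <- function(alpha_deg, beta_deg, tr_ms, te_ms, t1_ms, t2_ms,
                               n_iter = 2000) {
  a <- alpha_deg * pi / 180
  b <- beta_deg * pi / 180
  ea <- exp(-(te_ms / 2) / t1_ms)
  eb <- exp(-(tr_ms - te_ms / 2) / t1_ms)
  mz <- 1
  for (i in seq_len(n_iter)) {
    mz1 <- 1 - (1 - mz * cos(a)) * ea    # recovery to the refocusing pulse
    mz <- 1 - (1 - mz1 * cos(b)) * eb    # refocus inverts Mz, recover to next TR
  }
  sin(a) * mz * exp(-te_ms / t2_ms)
}

# brute-force flip-angle maximization on a 0.1 degree grid
grid_optimal_fa <- function(p) {
  grid <- seq(0.1, 180, by = 0.1)
  s <- if (p$kind == "SE") se_steady_state(p, grid) else gre_steady_state(p, grid)
  grid[which.max(s)]
}
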