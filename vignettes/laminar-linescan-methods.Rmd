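---
title: "Models and methods for laminar line-scanning fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for laminar line-scanning fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linescanr)
```

## The problem

Line-scanning fMRI turns off phase encoding and samples one k-space line per
repetition, trading the second in-plane dimension for very high temporal
(50–1000 ms) and depth (50–100 µm) resolution along a line crossing the
cortical sheet. Two sequence families are in use: a gradient-echo variant
(GRE; T2\*-weighted, sensitive but biased toward large draining veins at the
pial surface) and an alpha–180 spin-echo variant (SE; T2-weighted, less
sensitive but more specific to the microvasculature of deeper layers). This
package implements the computational layer of an SE-versus-GRE comparison in
rat somatosensory cortex: signal models to choose flip angles and predict
temporal SNR (tSNR), a generator of synthetic depth × time series with known
ground truth, and the depth-resolved BOLD analysis chain.

## Steady-state signal models

For the SE line-scanning sequence, iterating the longitudinal Bloch
recursion (excite by $\alpha$, relax $TE/2$, refocus by $\beta$, relax
$TR - TE/2$) to its fixed point gives

$$S_{xy}(\alpha,\beta) =
 \sin\alpha\;\frac{1-\cos\beta\,E_1-(1-\cos\beta)\,E_1'}
                  {1-\cos\alpha\,\cos\beta\,E_1}\;e^{-TE/T_2},
 \qquad E_1 = e^{-TR/T_1},\; E_1' = e^{-(TR-TE/2)/T_1},$$

and for the spoiled GRE sequence the familiar

$$S_{xy}(\theta) = \sin\theta\,\frac{1-E_1}{1-\cos\theta\,E_1}\,e^{-TE/T_2^*}.$$

Setting $\beta = 0$ (no refocusing) reduces the SE form to the GRE form
exactly; the test suite asserts this identity and checks both closed forms
against an independent numerical iteration of the Bloch recursion. Default
relaxation constants are T1 = 2211 ms and T2 = 24 ms (rat somatosensory
cortex at ultra-high field), with T2\* = 20 ms for GRE.

The signal maxima have closed forms — $\alpha^* = \arccos(-E_1)$ for SE with
$\beta = 180^\circ$ and the Ernst angle $\theta^* = \arccos(E_1)$ for GRE —
which `optimal_flip_angle()` uses, falling back to a 0.1° grid search
(ties toward the smaller angle) for intermediate refocusing angles. At
TR 200 ms and T1 2211 ms the SE optimum is ≈156°; acquisitions in
practice round this to the tested grid (e.g. 150°), and both values are
legitimate answers to "what angle should I use".

Relative tSNR between protocols is predicted as

$$\mathrm{tSNR}_{rel} = S_{ss} \times \mathrm{FOV}\,[\mathrm{m}] \,/\, \sqrt{\mathrm{BW}\,[\mathrm{Hz}]},$$

i.e. signal times voxel size over noise bandwidth, assuming tSNR scales
linearly with image SNR and identical noise in the compared acquisitions.
This convention is deliberately minimal — no voxel-count or scan-time
factor — and is recorded in the `"formula"` attribute of the returned value.
It is meaningful only as a ratio between protocols. No decomposition of
noise sources (thermal, physiological, out-of-ROI) is modelled.
`tsnr_efficiency()` divides a measured tSNR by $\sqrt{TR\,[\mathrm{s}]}$ to
compare protocols per unit scan time.

```{r}
se  <- sequence_params("SE", 1000, 20, 90, readout_bw_hz = 5000,
                       readout_fov_mm = 3.2)
gre <- sequence_params("GRE", 100, 12.5, 50, readout_bw_hz = 9014,
                       readout_fov_mm = 6.4)
c(se = as.numeric(predicted_relative_tsnr(se)),
  gre = as.numeric(predicted_relative_tsnr(gre)),
  ratio = tsnr_ratio(se, gre))
```

## Block paradigm and hemodynamic response model

The stimulation paradigm is a block design (default 1 s pre / 4 s stim /
15 s post × 32 epochs). The response model is the gamma-variate block
convention used by standard deconvolution software: an impulse kernel

$$g(t) = t^4 e^{-t} / (4^4 e^{-4})$$

(unit peak at $t = 4$ s), block response
$\mathrm{HRF}(t) = \int_0^{\min(t,L)} g(s)\,ds$ evaluated in closed form,
and a design regressor built by discrete convolution of the stimulus boxcar
with $g$ sampled at the series TR. The convolution kernel is truncated at
32 s, where $g$ has decayed below $10^{-8}$ of its peak, so epochs 2…32 of
the regressor are identical to within $10^{-9}$. The regressor is divided by
its maximum ("peak amplitude of block response = 1"), so a GLM beta against
it reads directly as peak response amplitude. `glm_beta()` fits
`[intercept, linear drift, regressor]` per depth by ordinary least squares;
the heavier cubic detrend lives in the preprocessing stage, mirroring the
conventional processing order, and the baseline model actually used is
recorded in the report settings.

One subtlety the tests document: with 20-s epochs the block response has not
fully returned to baseline when the next epoch's 1-s pre-stimulation window
begins (the tail is ~$10^{-3}$ of peak). The pooled pre-stimulation baseline
$S_0$ is therefore biased by about 0.001 × amplitude, and "noiseless
recovery" of a 10% amplitude is exact to ~0.01 percentage points, not to
machine precision. This is a property of the paradigm, not an
implementation artifact.

## Synthetic series generator

`simulate_series()` builds
`baseline[d] · (1 + amplitude[d]/100 · r[t]) + drift(t) + ε[d,t]` with iid
Gaussian noise, a polynomial drift over normalized time, and optional
sinusoidal "respiration" (0.3 Hz) and "cardiac" (1 Hz) confounds (off by
default, since the emulated acquisitions characterize no noise spectrum).
Design choices:

* **Depth convention.** Bin 1 is the cortical surface; bin $i$ sits at
  $(i-0.5)\,\times$ resolution. Defaults: 40 bins × 50 µm = 0–2 mm.
* **Amplitude profiles.** Gaussian-shaped in depth: `surface_peak` (default
  30% peak — the GRE-like, vein-dominated pattern) and `l4_peak` (default
  10% at 0.9 mm — the SE-like pattern). These defaults are documentation of
  typical shapes, not assertions about biology.
* **Drift of order ≤ 3**, so the cubic detrend can remove it exactly —
  which makes detrending itself testable.
* **Noise levels in the presets** are set as baseline / target-tSNR with
  targets 15.3 (`geline`), 50.8 (`seline`) and 27.0 (`seline_fast`), the
  printed mean tSNRs of the corresponding acquisitions.
* **Determinism.** All randomness flows through the seed stored in the
  spec; the caller's RNG state is saved and restored, so generation is a
  pure function of the spec.

What the generator does **not** emulate: inflow and CSF partial-volume
effects, B1 inhomogeneity, motion, k-space artifacts, or structured
physiological noise. Passing tests on synthetic data therefore validate the
*analysis chain*, not the biology of real laminar responses.

`simulate_line_image_2d()` provides the 2D counterpart for slice-profile
quality metrics: a strip of unit intensity with Gaussian-blurred edges and
a configurable residual background fraction, from which `profile_fwhm()`
and `background_fraction()` recover their ground truth exactly in the
noise-free limit.

## Preprocessing chain

The per-depth conditioning order is demean → cubic detrend → zero-phase
bandpass; tSNR is always computed on the raw series, as mean over the
standard deviation of the *whole* time series (the short 1-s baselines of
this paradigm are not usable as a resting-state SD estimate). The
population-SD convention (divide by N) is used for both z-scoring and tSNR;
at N = 3200 the difference from the sample convention is below 0.02%.

The bandpass is a linear-phase windowed-sinc FIR (Hamming window — the
conventional default of the named design routine; the window used is
recorded in the provenance), default 0.01–0.1 Hz with 4096 taps. Zero phase
is obtained by compensating the constant group delay of order/2 samples
with a circular shift. The order/2 samples at each end are contaminated by
the wrap/startup transient; they are flagged in a validity mask rather than
silently trusted, and amplitude measurements in the tests use only the
valid region. For series shorter than the order (e.g. 3200 samples at TR
200 ms), the order is capped at the largest even integer ≤ N/3 with a
warning; this keeps the design well-posed at the cost of a wider
transition band. Long filters run via FFT (overlap-add) convolution, short
ones directly.

## Percent change, metrics, and an amplitude-calibration caveat

`percent_change()` uses $(S-S_0)/S_0 \times 100$ with $S_0$ the per-depth
mean over the union of all 1-s pre-stimulation windows. Depth-resolved
metrics include epoch averaging, max-normalized maps, the
max(mean + SD)-normalized laminar profile, peak-layer detection (temporal
max of the epoch-averaged percent change by default, window-mean behind a
flag; all argmax ties break toward the shallower depth / earlier time),
laminar slope between layer midpoints per layer step, FWHM by linear
interpolation of half-maximum crossings around the global peak, and
background fraction $N_{bkg}/S_{roi}\times 100$.

**Which series feeds percent change?** A block paradigm with a 20-s epoch
has its fundamental at 0.05 Hz, but the response energy also sits at DC and
at harmonics ≥ 0.1 Hz. The 0.01–0.1 Hz bandpass removes both, and we
measured that percent-change amplitudes computed on the bandpassed series
are attenuated to roughly 60–75% of ground truth on synthetic data. Since
amplitude calibration is a stated requirement of the analysis,
`run_pipeline()` defaults to computing percent change on the demeaned,
cubic-detrended series with the per-depth mean restored
(`pct_basis = "detrended"`), and offers `"filtered"` (for display-style
processing) and `"raw"` behind the flag. The basis actually used is written
into the report settings.

Layer boundaries (`layer_scheme()`: L1 0–0.15, L2/3 0.15–0.70, L4
0.70–1.10, L5 1.10–1.60, L6 1.60–2.00 mm) follow standard rat S1 histology
ranges and are configuration, not constants. The cortical-surface detector
(first depth reaching 50% of the 95th-percentile robust maximum, scanning
from the shallow end) is a documented stand-in for intensity-based surface
definitions and is fully configurable.

## Problem sizes and numerical choices

The test suite and examples run the full-length paradigm (6400 timepoints ×
40 depths) for calibration checks and a 4-epoch variant for structural
tests; the Monte-Carlo ground-truth-recovery check uses 20 seeds at tSNR 30.
These sizes were chosen so that every statistical tolerance in the tests
(5% on tSNR calibration, 10% on amplitude recovery, ≥19/20 peak-layer hits)
is comfortably above the corresponding sampling error at those N. Degenerate
inputs fail loudly: constant traces cannot be z-scored or assigned a tSNR,
rank-deficient GLM designs name the collinear column, non-tiling paradigms
and non-integer segment/TR ratios are configuration errors.

## Known limitations

* The tSNR prediction is relative; absolute values depend on coil, field
  and reconstruction factors outside the model.
* The SE model assumes ideal pulses and full spoiling; slice profiles, B1
  maps and off-resonance are out of scope.
* Only Gaussian noise plus optional sinusoids; no autocorrelated
  physiological noise, so GLM standard errors on real data would be
  optimistic (point estimates, which this package reports, are unaffected).
* No motion correction is implemented (none is emulated).
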