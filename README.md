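# linescanr

Simulation and depth-resolved analysis of laminar line-scanning fMRI.

Line-scanning fMRI samples a single k-space line per repetition time,
giving up one in-plane dimension in exchange for 50–100 µm depth resolution
and 50–1000 ms sampling across the cortical sheet. Gradient-echo (GRE)
line scanning is sensitive but biased toward large draining veins at the
surface; the alpha–180 spin-echo (SE) variant is less sensitive but more
specific to microvasculature in deeper layers. `linescanr` is for
researchers designing or analysing such acquisitions in small animals. It
provides:

* **Steady-state signal models** for both sequences,
  $S_{xy}(\alpha,\beta) = \sin\alpha\,[1-\cos\beta\,E_1-(1-\cos\beta)E_1'] /
  [1-\cos\alpha\cos\beta\,E_1]\cdot e^{-TE/T_2}$ (SE) and
  $S_{xy}(\theta)=\sin\theta\,(1-E_1)/(1-\cos\theta\,E_1)\cdot e^{-TE/T_2^*}$
  (GRE), with analytic flip-angle optimization
  ($\alpha^*=\arccos(-e^{-TR/T_1})$, Ernst angle for GRE) and relative
  tSNR prediction $S\cdot\mathrm{FOV[m]}/\sqrt{\mathrm{BW[Hz]}}$.
* **A block-design hemodynamic response model**: gamma-variate kernel
  $g(t)=t^4e^{-t}/(4^4e^{-4})$, block response
  $\mathrm{HRF}(t)=\int_0^{\min(t,L)}g$, peak-normalized design regressors
  and per-depth GLM amplitude estimation.
* **A seeded synthetic generator** of depth × time line-scan series (block
  responses, baseline gradients, polynomial drift, Gaussian noise) and 2D
  line-profile images with known ground truth.
* **The conditioning chain**: demean, cubic detrend, zero-phase FIR
  bandpass (0.01–0.1 Hz, group-delay compensated), z-score, whole-series
  tSNR.
* **Depth-resolved metrics**: percent change against pooled 1-s
  pre-stimulation baselines, epoch averaging, peak-layer detection,
  normalized laminar profiles, laminar slope, profile FWHM, background
  fraction, cortical-surface detection.
* **NIfTI-1 + JSON-sidecar IO** and an end-to-end `run_pipeline()`.

## Worked example

```r
library(linescanr)

# predict the SE/GRE tSNR advantage from the sequence parameters alone
se  <- sequence_params("SE", 1000, 20, 90, readout_bw_hz = 5000,
                       readout_fov_mm = 3.2)
gre <- sequence_params("GRE", 100, 12.5, 50, readout_bw_hz = 9014,
                       readout_fov_mm = 6.4)
tsnr_ratio(se, gre)
#> [1] 2.221866

optimal_flip_angle(sequence_params("SE", 200, 10, 150, readout_bw_hz = 9014))
#> [1] 155.9955

# simulate a spin-echo-like acquisition and run the full analysis
cfg <- linescan_preset("seline", seed = 7)
rep <- run_pipeline(cfg)
rep
#> <linescan_report> preset seline, seed 7
#>   peak: 10.37% at 0.925 mm (L4); slope L1->L2/3: +0.161
#>   tSNR: mean 39.1 across 40 depths
```

The report says: the strongest evoked BOLD response (10.4% peak percent
change, close to the generator's 10% ground truth) sits 0.925 mm below the
cortical surface, in layer 4 — the microvessel-weighted laminar pattern the
SE preset emulates — and the normalized profile *rises* from L1 to L2/3
(positive slope), i.e. no draining-vein dominance at the surface. The
per-depth tSNR is computed on the raw series as mean over whole-series SD.
`run_pipeline(cfg, out_dir = "out")` additionally writes the series as
NIfTI + JSON sidecar, per-depth TSV tables and a JSON metrics report.

## Documentation

`vignettes/laminar-linescan-methods.Rmd` describes the signal models and
their assumptions, the paradigm/HRF conventions, what the synthetic
generator does and does not emulate, the filtering and normalization
choices, and known limitations.
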