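# nmrvoigt

Untargeted processing of 1D ¹H-NMR spectra for metabolomics by pseudo-Voigt
peak deconvolution.

Conventional untargeted NMR analysis works either on the full-resolution
intensity matrix ("full spectra": tens of thousands of per-point peak
heights) or on equidistant buckets ("binning": trapezoidal AUC per 0.01-ppm
bin). Both drag baseline noise and shift jitter into the statistics.
`nmrvoigt` instead reduces every spectrum to a table of fitted peak
integrals and aligns those across samples into a compact feature matrix:

1. pick all local maxima; score each by its **net intensity** (topographic
   prominence — height above the higher of the two flanking minima);
2. discard candidates below `k_noise × σ`, with σ estimated robustly from
   first differences (or from a signal-free region);
3. split the axis into independent regions and fit each as a **sum of
   pseudo-Voigt lineshapes** by bounded trust-region least squares,

   f(x) = η·L(x; A, μ, w) + (1 − η)·G(x; A, μ, w),

   optimizing per peak the area *A*, center μ, common FWHM *w* and the
   Lorentzian fraction η ∈ [0, 1]; ∫f = A for every η;
4. integrate each fitted peak analytically over μ ± 3·FWHM;
5. align integrals to a reference spectrum's peaks within a shift window
   (default 0.005 ppm) and keep features present in ≥30% of samples with a
   median S/N ≥ 5.

The two conventional methods, probabilistic quotient normalization (PQN),
UV-scaled PCA, a standard-addition error-estimation protocol and a
deterministic urine-like spectrum simulator (with ground truth) are
included, so the whole workflow can be exercised and compared end to end
without any external data.

## Worked example

Simulate six urine-like samples on a 1–2 ppm window (six peaks including an
alanine-like doublet at 1.474/1.486 ppm), run the full pipeline, and look
at the feature matrix:

```r
library(nmrvoigt)

cfg <- sim_config(axis = c(1.0, 2.0, 2.5e-4),
                  peaks = default_urine_peaks()[3:8, ],
                  n_samples = 6L, seed = 11L)
sim <- simulate_dataset(cfg)

res <- cmd_fit(sim$set, "demo_out")   # writes feature_matrix.csv + report
fm  <- res$feature_matrix
fm
#> <feature_matrix: 6 samples x 6 features>

data.frame(center = round(fm$ref_center, 4),
           mean_area = signif(colMeans(fm$values), 3),
           frequency = fm$frequency,
           median_snr = round(fm$median_snr, 1))
#>   center mean_area frequency median_snr
#> 1 1.0496  0.000817         1       85.0
#> 2 1.1997  0.032500         1     1587.9
#> 3 1.3301  0.005770         1      444.3
#> 4 1.4738  0.018800         1     1288.4
#> 5 1.4867  0.018800         1     1289.3
#> 6 1.9197  0.014400         1      902.0
```

All six true peaks come back as features at their simulated centers
(truth: 1.05, 1.20, 1.33, 1.474, 1.486, 1.92 ppm), detected in every
sample. The reported area is the integral over ±3 FWHM, i.e. 79–96% of the
total lineshape area depending on η — e.g. the 1.20-ppm peak was simulated
with total area 0.035 and is reported as 0.0325, and the overlapped doublet
members (0.020 each) as 0.0188 each.

One replicate of the standard-addition comparison (a spiked target two
linewidths from an interferer in a crowded window; mean relative standard
error in % per processing method):

```r
spike_rse_experiment(seed = 1)
#> voigt binned   full
#>  0.10  12.99  41.11
```

The fitted-integral response is an order of magnitude more accurate than
bucket AUCs, which in turn beat on-point peak heights — the motivation for
deconvolution in one line of output.

A shell entry point with the same functionality is installed under
`exec/nmrvoigt` (subcommands `simulate`, `fit`, `bin`, `full`, `evaluate`,
`pca`).

## Documentation

The methods vignette (`vignettes/voigt-fitting-workflow.Rmd`) describes the
model, every tunable parameter with its default and rationale, what the
simulator does and does not emulate, the numerical conventions, and known
limitations.
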