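---
title: "Untargeted pseudo-Voigt peak fitting for 1D NMR metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted pseudo-Voigt peak fitting for 1D NMR metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrvoigt)
```

## The problem

Untargeted ¹H-NMR metabolomics of complex biofluids such as urine usually
analyses either the full-resolution intensity matrix or spectra reduced to
equidistant buckets. Both carry substantial non-informative variance: raised
baselines, residual chemical-shift drift, and measurement noise that is
relatively largest for small intensities. `nmrvoigt` implements a
deconvolution alternative: every spectrum is reduced to a table of fitted
peak integrals, which are then aligned across samples into a feature matrix.
Noise-level points never enter that matrix, so the downstream multivariate
analysis sees far fewer, far cleaner variables.

The package expects spectra that are already phased, baseline-corrected and
peak-aligned (a rigid cross-correlation helper, `global_shift_align()`, is
included as a convenience, but segment-wise alignment is deliberately out of
scope). Its input is a shared ppm axis plus a sample × point intensity
matrix (`spectra_set`), read and written as plain CSV.

## The lineshape model

NMR resonances are Voigt-shaped: a convolution of the Lorentzian lineshape
(natural relaxation) with a Gaussian (field inhomogeneity). We model each
peak with the area-normalized pseudo-Voigt approximation,

$$ f(x; A, \mu, w, \eta) \;=\;
   \eta\, L(x; A, \mu, w) \;+\; (1-\eta)\, G(x; A, \mu, w), $$

where $L$ and $G$ are the Lorentzian and Gaussian of total area $A$ and
common full width at half maximum $w$, and $\eta \in [0,1]$ is the
Lorentzian fraction. $\int f\,dx = A$ for every $\eta$, so the amplitude
parameter *is* the quantity of analytical interest (a peak integral is
proportional to the number of contributing nuclei). The mixing-parameter
formulation directly exposes "the ratio between Gaussian and Lorentzian" as
a fitted quantity; the exact convolution Voigt adds computational cost
without changing the downstream statistics, so it was not made the default.
Note the convention: $\eta$ weights the *Lorentzian*; some instruments'
software weights the Gaussian instead.

Partial integrals over $\mu \pm k\,w$ have closed forms,
$A[\eta\,\tfrac{2}{\pi}\arctan 2k + (1-\eta)\,\mathrm{erf}(2k\sqrt{\ln 2})]$,
used both for the reported peak areas and in the test oracles.

## Per-spectrum processing

`fit_spectrum()` chains five steps.

1. **Peak picking** (`pick_peaks()`): every strict interior local maximum,
   with plateaus reported once at their central point. The *net intensity*
   of a candidate is its height minus the higher of its two flanking
   minima, where each flanking minimum is the lowest point between the
   maximum and the nearest strictly higher point on that side — the
   topographic prominence. Prominence, rather than the distance to the
   immediately adjacent minima, is essential on noisy data: noise jags a
   genuine peak top into several micro-maxima whose adjacent dips are only
   a few noise standard deviations deep, while the top-most jag keeps the
   full peak height as its prominence. It equally discounts raised
   baselines and the shoulders of overlapping neighbors.
2. **Noise filtering** (`estimate_noise()`, `noise_filter()`): candidates
   with net intensity below `k_noise * sigma` are discarded. The default
   noise estimator is the median absolute deviation of first differences
   divided by $\sqrt{2}\cdot 0.67449$, which is robust to peaks; the
   standard deviation over a signal-free window (default 9.5–10 ppm) is
   available as `region_sd`. `k_noise = 5` mirrors the S/N > 5 feature
   threshold; both are configuration-exposed because neither constant is
   canonical.
3. **Segmentation** (`segment_regions()`): the axis is split wherever the
   intensity stays below $3\sigma$ for at least 20 consecutive points;
   regions are padded by 10 points without overlapping, and any region with
   more than 30 candidates is split at its weakest internal minimum to keep
   the joint fit well conditioned. Candidates lying *inside* a long
   sub-threshold run stand on mere baseline (their height is below
   $3\sigma$ even when an extreme noise excursion gave them a passable
   prominence) and are discarded with the run.
4. **Bounded least squares** (`fit_region()`): each region is fitted by a
   Levenberg–Marquardt trust-region scheme (`minpack.lm::nls.lm`) with an
   analytic Jacobian, minimizing the residual sum of squares over per-peak
   $(A, \mu, w, \eta)$. Initialization: picked center, width from the
   half-maximum crossings (fallback four axis steps), $\eta_0 = 0.5$, area
   inverted from the picked height. Bounds: center within one initial width
   of the pick, width between two axis steps and the region span, $\eta$ in
   $[0,1]$, area in $(0, 10\times$ region integral$]$. At most 200
   iterations with gradient tolerance $10^{-10}$; one restart from 10%
   wider initials on non-convergence, keeping the better attempt.
   Standard errors come from the Jacobian at the solution,
   $se = \sqrt{\mathrm{diag}((J^\top J)^{-1})\,rss/(n-p)}$.
5. **Integration and artifact rejection**: every fitted peak is integrated
   analytically over $\mu \pm k_{width} w$ (default $k_{width} = 3$,
   capturing ≈96% of a Gaussian and ≈79% of a Lorentzian). Fitted peaks
   whose height falls below `k_noise * sigma`, that are pinned at the width
   lower bound, or whose width spans fewer than three axis steps (a
   between-grid-point spike is not a sampled lineshape) are dropped as
   noise artifacts; the full diagnostics, including them, remain in the
   per-region fit report.

Determinism is a design requirement: there is no randomness anywhere in the
fitting path, so identical inputs give bit-identical outputs.

## From peak tables to a feature matrix

`align_to_reference()` matches each spectrum's peak table against the peak
table of a reference spectrum (mean or median spectrum, or a QC sample).
Reference peaks are processed in descending area; each claims, per sample,
the nearest unclaimed peak within the shift window (default 0.005 ppm, the
typical residual jitter after alignment; ties go to the larger area). Sample
peaks that match no reference peak seed new features: the largest-area
unclaimed peak opens a feature at its own center and claims all unclaimed
peaks within the window. A single-linkage pooling was considered and
rejected because chaining can place a member further than one window from
the feature center, violating the post-hoc invariant that every matched
peak lies within the window of its feature. Unmatched-peak features keep
the workflow untargeted — truly novel signals survive — but usually die at
the frequency filter.

`frequency_filter()` (default: present in ≥30% of samples, boundary
inclusive) and `snr_filter()` (default: median fitted S/N ≥ 5) then prune
the feature list, and `assemble_feature_matrix()` produces the sample ×
feature integral matrix. Missing entries default to zero-fill — a
non-detected peak is below the noise level, and complete matrices are
required by PCA — with `NA` available for downstream imputation.

## Preprocessing and baselines

- `remove_region()` deletes an interval inclusively on both ends; removing
  the water region 4.70–4.85 ppm from the −1…10 ppm axis at
  $2.5\times10^{-4}$ ppm resolution (44,001 points) leaves 43,400 points —
  only the inclusive convention reproduces that width.
- `pqn_normalize()` implements probabilistic quotient normalization for
  dilution correction: division by the median pointwise quotient against a
  reference (default the median spectrum), computed only where the
  reference exceeds five noise standard deviations, because quotients at
  noise points are unstable. PQN is applied after alignment; its accuracy
  degrades when an additive baseline or residual peak misalignment breaks
  the pure multiplicative-dilution model, which is why its ground-truth
  test runs on aligned, baseline-free simulations.
- `full_matrix()` and `bin_spectra()` are the two conventional comparison
  methods. Binning lays 0.01-ppm buckets over each contiguous axis segment
  from its low edge; a final short bin is kept if it spans at least half a
  width, otherwise merged into its neighbor (1085 bins on the water-removed
  axis above). Each trapezoid panel is assigned to the bin holding its left
  point, so bin areas sum exactly to the segment's trapezoidal integral.
- `pca_uv()` mean-centers and unit-variance-scales every column before the
  SVD, drops constant columns with a warning, and fixes component signs
  (largest-magnitude loading positive) for deterministic output.

## The simulator

`simulate_spectrum()` generates
`dilution * sum(pseudo_voigt) + baseline + noise` on a configurable axis,
with per-sample, per-peak Gaussian jitter of the centers; ground truth is
always returned with the data and no test reads it from anywhere else. All
randomness derives from one root seed through a counter scheme
(`substream = (seed mod 65011) * 33013 + 9973 * sample_index + 1`,
mod $2^{31}-1$), so sample $k$ is invariant to the total sample count.
Peaks are sorted by center before the jitter draws, making the output
invariant to the order of the configured peak list.

The default template holds 31 peaks over 0.8–9.2 ppm with FWHM 0.001–0.004
ppm and $\eta \in [0.3, 0.9]$: an isolated alanine-like doublet at 1.48
ppm, a deliberately overlapped caffeine-like pair near 3.30 ppm at half a
linewidth separation, and isolated peaks spanning three orders of magnitude
in area, several near the detection limit. The default baseline is a gentle
quadratic within a few noise standard deviations — the "baseline above
zero" condition that motivates net-intensity filtering. What the simulator
does **not** emulate: J-coupled multiplet structure, pH-dependent shifts,
correlated (apodized) noise, and solvent artifacts. White per-point noise
is in fact *harsher* on a picking algorithm than real smoothed noise, but
passing tests here still say nothing about, e.g., multiplet
mis-deconvolution on real spectra.

## The standard-addition experiment

`simulate_spike_design()` emulates spiking a target analyte at 5, 10 and
15 µg into four different urine backgrounds (12 spectra), each background
with its own endogenous target level and intensity scale.
`cmd_evaluate()` measures each method's response — intensity at the nearest
axis point (full spectra), trapezoidal AUC of the containing 0.01-ppm bin
(binned), fitted-peak integral of the nearest feature (Voigt) — and builds
one pooled standard curve per method. Because four backgrounds with
different endogenous levels cannot share one raw-response line, responses
are background-corrected first: per background, an OLS line over its three
points extrapolates the amount-0 response, which is subtracted before
pooling. The relative standard error of a point is
$100\,|\hat a_i - a_i| / a_i$ with $\hat a_i$ the back-calculated amount,
and a method's score is the mean over the 12 points. Fig-3-style per-point
"standard errors" could alternatively be read as regression standard
errors; this package documents and uses the back-calculation definition.

`spike_rse_experiment()` packages one replicate of the comparison: a
crowded 2.9–3.7 ppm window, nine background peaks, and an interferer two
linewidths from the target. Two linewidths is a deliberate choice: what a
crowded spectral region with elevated baseline actually presents is tail
overlap between still-distinct maxima. At half-a-linewidth separation the
two resonances merge into a *single* local maximum in a jitter-dependent
subset of spectra, and a deconvolution whose model order follows peak
picking then measures "target" in some samples and "target + interferer"
in others — no method parameter can rescue a calibration from that
discontinuity, which is a genuine limitation of picking-driven
deconvolution worth knowing about. At two linewidths the pair is
consistently resolvable while the interferer still shares the target's bin
(it sits near a bin edge, so bucket AUCs leak with jitter) and contaminates
the target's on-point height. Under those conditions the expected ordering
of mean RSE is Voigt < binned < full spectra; across 25 seeded replicates
the strict ordering holds in well over 80% of runs (the per-replicate
probability is roughly 0.85–0.9 — the binned-versus-full comparison is
between two noisy baselines and occasionally flips at only 12 design
points).

## Problem sizes and numerical choices

The test suite and the acceptance script run on reduced problem sizes
chosen to exercise every code path while keeping a full run in tens of
seconds: 1-ppm windows (4,001 points) for pipeline tests, the full
44,001-point axis only where the printed matrix widths are checked, 25
spike replicates of 12 spectra each, a 27-point noiseless recovery grid and
50 noisy single-peak fits. Axis arithmetic uses `lo + k * step` (never
accumulating sums); interval membership applies a $10^{-9}$ relative guard
so binary floating point cannot move a boundary point across an inclusive
bound. Ties in peak picking resolve to the plateau center; ties in
alignment matching to the larger area; the alignment cross-correlation
takes the most negative shift on exact ties.

## Known limitations

- Model order equals picked-maximum count: peaks closer than roughly one
  linewidth are fitted as one (see above), and their combined integral — not
  their split — is what the feature matrix carries.
- PQN assumes purely multiplicative dilution on aligned spectra; strong
  additive baselines bias the dilution factors by a few percent.
- The rigid `global_shift_align()` corrects only whole-spectrum shifts;
  segment-wise (per-peak) alignment must happen upstream.
- Fitted standard errors are asymptotic (Jacobian-based) and can
  underestimate uncertainty for strongly overlapped peaks whose areas trade
  off.
- White-noise simulations do not certify behavior on real multiplets,
  solvent tails, or macromolecular backgrounds.
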