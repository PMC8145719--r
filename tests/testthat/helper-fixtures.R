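# shared fixtures: small axes and configurations keep the suite fast

tiny_noise <- function(sigma = 1e-9) {
  structure(list(sigma = sigma, method = "diff_mad", region = NULL),
            class = "noise_estimate")
}

# six-peak template on a 1-2 ppm window (4001 points), alanine-like doublet
# at 1.474/1.486 included
small_peaks <- function(jitter_sd = 0.0005) {
  data.frame(
    center = c(1.05, 1.20, 1.33, 1.474, 1.486, 1.92),
    area = c(0.02, 0.035, 0.006, 0.020, 0.020, 0.015),
    fwhm = c(0.0022, 0.0030, 0.0020, 0.0022, 0.0022, 0.0025),
    eta = c(0.5, 0.7, 0.5, 0.6, 0.6, 0.45),
    shift_jitter_sd = jitter_sd)
}

small_cfg <- function(n_samples = 1L, seed = 1L, noise_sd = 0.005,
                      jitter_sd = 0.0005, ...) {
  sim_config(axis = c(1.0, 2.0, 2.5e-4), peaks = small_peaks(jitter_sd),
             noise_sd = noise_sd, n_samples = n_samples, seed = seed, ...)
}

# single noiseless pseudo-Voigt sampled on the conventional axis step
single_peak_spectrum <- function(A = 1, mu = 3.0, w = 0.01, eta = 0.7,
                                 halfspan = 0.1, step = 2.5e-4) {
  x <- ppm_axis(mu - halfspan, mu + halfspan, step)
  spectrum1d(x, pseudo_voigt(x, A, mu, w, eta), id = "single")
}

# fit one isolated peak end to end, returning the fitted parameter row;
# the noise filter removes numerical-rounding ripples in noiseless tails
fit_single <- function(s, sigma = 1e-9) {
  noise <- tiny_noise(sigma)
  cands <- noise_filter(pick_peaks(s), noise, 5)
  regs <- segment_regions(s, cands, noise)
  best <- which.max(vapply(regs, function(r) max(r$cands$height), 1))
  pk <- fit_region(s, regs[[best]], noise)$peaks
  pk[which.max(pk$height), ]
}
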