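#' Default urine-like peak template
#'
#' A fixed table of 31 pseudo-Voigt peaks spanning 0.8-9.2 ppm with widths of
#' 0.001-0.004 ppm and Lorentzian fractions 0.3-0.9, covering the three
#' difficulty regimes a real urine spectrum poses: an isolated doublet at
#' 1.48 ppm (alanine-like, easy to integrate), a strongly overlapped pair
#' near 3.30 ppm separated by half a linewidth (caffeine-like, crowded
#' region), and a range of isolated peaks of widely varying intensity
#' including several near the detection limit.
#'
#' @return Data frame with columns `center` (ppm), `area` (a.u. * ppm),
#'   `fwhm` (ppm), `eta`, `shift_jitter_sd` (ppm).
#' @export
default_urine_peaks <- function() {
  tbl <- data.frame(
    center = c(0.86, 0.95, 1.05, 1.20, 1.33, 1.474, 1.486, 1.92, 2.14, 2.29,
               2.41, 2.54, 2.67, 2.73, 2.90, 3.05, 3.19, 3.2988, 3.3000, 3.42,
               3.56, 3.65, 3.78, 3.90, 4.06, 4.12, 6.54, 7.19, 7.54, 8.46, 9.12),
    area = c(0.012, 0.004, 0.0008, 0.035, 0.006, 0.020, 0.020, 0.015, 0.008,
             0.0006, 0.010, 0.003, 0.060, 0.025, 0.0009, 0.018, 0.007, 0.016,
             0.012, 0.030, 0.009, 0.0007, 0.014, 0.040, 0.011, 0.005, 0.004,
             0.008, 0.003, 0.006, 0.002),
    fwhm = c(0.0022, 0.0018, 0.0015, 0.0030, 0.0020, 0.0022, 0.0022, 0.0025,
             0.0019, 0.0014, 0.0028, 0.0021, 0.0038, 0.0026, 0.0016, 0.0024,
             0.0018, 0.0024, 0.0024, 0.0032, 0.0020, 0.0013, 0.0027, 0.0035,
             0.0023, 0.0017, 0.0020, 0.0026, 0.0018, 0.0022, 0.0015),
    eta = c(0.55, 0.40, 0.35, 0.70, 0.50, 0.60, 0.60, 0.45, 0.80, 0.30, 0.65,
            0.50, 0.75, 0.55, 0.40, 0.60, 0.35, 0.70, 0.70, 0.85, 0.45, 0.30,
            0.55, 0.90, 0.50, 0.40, 0.60, 0.65, 0.50, 0.55, 0.45),
    shift_jitter_sd = 0.0010)
  tbl
}

#' Simulation configuration
#'
#' Describes a synthetic urine-like dataset: the chemical-shift axis, the
#' ground-truth peak list, a slowly varying polynomial baseline, additive
#' Gaussian noise, per-sample multiplicative dilution, and the sample count.
#' Defaults mirror the conventional acquisition grid (-1..10 ppm at 2.5e-4
#' ppm resolution, 44,001 points) and the [default_urine_peaks()] template;
#' the baseline is a gentle quadratic whose amplitude stays within a few
#' noise standard deviations, reproducing the raised-baseline condition that
#' motivates net-intensity (rather than raw-height) noise filtering.
#'
#' @param axis `c(lo, hi, step)` in ppm.
#' @param peaks Peak table as in [default_urine_peaks()].
#' @param baseline Polynomial coefficients, intensity contribution
#'   `sum(baseline[k] * x^(k-1))`.
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.).
#' @param dilution_range `c(lo, hi)` of the uniform multiplicative dilution
#'   factor; `c(1, 1)` disables dilution.
#' @param dilution_factors Optional explicit per-sample dilution factors
#'   (overrides `dilution_range`).
#' @param n_samples Number of samples.
#' @param seed Root seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(axis = c(-1, 10, 2.5e-4),
                       peaks = default_urine_peaks(),
                       baseline = c(0.005, 8e-4, -8e-5),
                       noise_sd = 0.005,
                       dilution_range = c(1, 1),
                       dilution_factors = NULL,
                       n_samples = 1L,
                       seed = 1L) {
  stopifnot(axis[3L] > 0, axis[2L] > axis[1L], noise_sd >= 0,
            all(dilution_range > 0), n_samples >= 1L)
  if (nrow(peaks) > 0L) {
    stopifnot(all(peaks$area > 0), all(peaks$fwhm > 0),
              all(peaks$eta >= 0 & peaks$eta <= 1))
  }
  structure(list(axis = axis, peaks = peaks, baseline = baseline,
                 noise_sd = noise_sd, dilution_range = dilution_range,
                 dilution_factors = dilution_factors,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "sim_config")
}

# per-sample substream: a counter scheme on the root seed, so sample k's
# draws do not depend on how many samples are generated
substream_seed <- function(seed, sample_index) {
  (as.numeric(seed) %% 65011 * 33013 + as.numeric(sample_index) * 9973 + 1) %% 2147483647
}

#' Simulate one spectrum with known ground truth
#'
#' Generates `dilution * sum(pseudo_voigt(x; jittered peaks)) + baseline(x) +
#' noise`. Each peak's center receives a Gaussian jitter (its
#' `shift_jitter_sd`), drawn per sample; the emitted ground-truth table
#' records the jittered (actual) centers, areas, widths, fractions, heights
#' and true S/N. All randomness comes from a substream derived
#' deterministically from `(seed, sample_index)`, and peaks are sorted by
#' center before drawing, so permuting the configured peak list does not
#' change the output.
#'
#' @param cfg A [sim_config()].
#' @param sample_index 0-based sample counter selecting the substream.
#' @return A list: `spectrum` ([spectrum1d()]), `truth` (peak table with
#'   `center`, `area`, `fwhm`, `eta`, `height`, `snr`, `center_nominal`),
#'   `dilution`.
#' @export
simulate_spectrum <- function(cfg, sample_index = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- ppm_axis(cfg$axis[1L], cfg$axis[2L], cfg$axis[3L])
  pk <- cfg$peaks
  if (nrow(pk) > 0L) pk <- pk[order(pk$center, pk$area, pk$fwhm), , drop = FALSE]
  rng <- substream_seed(cfg$seed, sample_index)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng)
  dilution <- if (!is.null(cfg$dilution_factors)) {
    cfg$dilution_factors[sample_index + 1L]
  } else if (cfg$dilution_range[1L] == cfg$dilution_range[2L]) {
    cfg$dilution_range[1L]
  } else {
    stats::runif(1L, cfg$dilution_range[1L], cfg$dilution_range[2L])
  }
  centers <- pk$center
  if (nrow(pk) > 0L) {
    jit <- stats::rnorm(nrow(pk), 0, pk$shift_jitter_sd)
    centers <- pk$center + jit
  }
  y <- numeric(length(x))
  for (i in seq_len(nrow(pk))) {
    y <- y + pseudo_voigt(x, pk$area[i], centers[i], pk$fwhm[i], pk$eta[i])
  }
  y <- dilution * y
  if (length(cfg$baseline)) {
    y <- y + drop(outer(x, seq_along(cfg$baseline) - 1, "^") %*% cfg$baseline)
  }
  if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(x), 0, cfg$noise_sd)
  truth <- if (nrow(pk) > 0L) {
    data.frame(center = centers, area = dilution * pk$area, fwhm = pk$fwhm,
               eta = pk$eta,
               height = pv_height(dilution * pk$area, pk$fwhm, pk$eta),
               snr = if (cfg$noise_sd > 0) {
                 pv_height(dilution * pk$area, pk$fwhm, pk$eta) / cfg$noise_sd
               } else Inf,
               center_nominal = pk$center)
  } else {
    data.frame(center = numeric(), area = numeric(), fwhm = numeric(),
               eta = numeric(), height = numeric(), snr = numeric(),
               center_nominal = numeric())
  }
  list(spectrum = spectrum1d(x, y, id = sprintf("sim_%03d", sample_index)),
       truth = truth, dilution = dilution)
}

#' Simulate a multi-sample dataset
#'
#' `n_samples` independent draws of [simulate_spectrum()] on the shared axis;
#' sample `k` always uses substream `k`, so extending the dataset does not
#' perturb earlier samples.
#'
#' @param cfg A [sim_config()].
#' @return A list: `set` ([spectra_set()]), `truth` (list of per-sample
#'   tables), `dilutions` (named vector).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_samples >= 1L)
  sims <- lapply(seq_len(cfg$n_samples) - 1L, function(k) simulate_spectrum(cfg, k))
  ids <- vapply(sims, function(s) s$spectrum$id, "")
  m <- do.call(rbind, lapply(sims, function(s) s$spectrum$intensity))
  set <- spectra_set(sims[[1L]]$spectrum$ppm, m, ids)
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- ids
  list(set = set,
       truth = truth,
       dilutions = stats::setNames(vapply(sims, `[[`, 1, "dilution"), ids))
}

#' Simulate a standard-addition spike design
#'
#' Emulates spiking an analyte into several biological backgrounds: for each
#' of `n_backgrounds` randomized backgrounds (the background's endogenous
#' target level and an overall intensity factor are drawn once per
#' background) and each spike amount, one spectrum is generated in which the
#' target peak's area is `endogenous + amount * response_per_ug`. The default
#' design — amounts 5, 10, 15 µg over 4 backgrounds — gives 12 spectra.
#'
#' @param base_cfg A [sim_config()] describing the background matrix (its
#'   peak list should include any interfering neighbors of the target).
#' @param target One-row peak table (as in [default_urine_peaks()]) for the
#'   spiked analyte; its `area` field is ignored — the endogenous level is
#'   drawn per background and the spike contributes `amount * response_per_ug`.
#' @param amounts Spike amounts (µg), positive.
#' @param response_per_ug Peak area gained per µg of spike.
#' @param n_backgrounds Number of distinct backgrounds.
#' @param endogenous_range Range of the per-background endogenous target
#'   area, drawn uniformly (in units of area; `c(0, 0)` for none).
#' @return A list: `set` (the spiked [spectra_set()]), `design` (data frame
#'   `sample_id`, `background`, `amount`, `true_area`, `endogenous`),
#'   `truth` (per-sample ground-truth tables).
#' @export
simulate_spike_design <- function(base_cfg, target,
                                  amounts = c(5, 10, 15),
                                  response_per_ug = 0.002,
                                  n_backgrounds = 4L,
                                  endogenous_range = c(0.002, 0.008)) {
  stopifnot(inherits(base_cfg, "sim_config"), length(amounts) >= 1L,
            all(amounts > 0), n_backgrounds >= 1L, response_per_ug > 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(base_cfg$seed, 980001L))
  endo <- stats::runif(n_backgrounds, endogenous_range[1L], endogenous_range[2L])
  bg_scale <- stats::runif(n_backgrounds, 0.85, 1.15)
  design <- expand.grid(amount = amounts, background = seq_len(n_backgrounds))
  design <- design[, c("background", "amount")]
  sims <- vector("list", nrow(design))
  truth <- vector("list", nrow(design))
  ids <- character(nrow(design))
  for (i in seq_len(nrow(design))) {
    b <- design$background[i]
    a <- design$amount[i]
    pk <- base_cfg$peaks
    pk$area <- pk$area * bg_scale[b]
    tgt <- target
    tgt$area <- endo[b] * bg_scale[b] + a * response_per_ug
    cfg_i <- sim_config(axis = base_cfg$axis, peaks = rbind(pk, tgt),
                        baseline = base_cfg$baseline,
                        noise_sd = base_cfg$noise_sd,
                        dilution_range = c(1, 1),
                        n_samples = 1L, seed = base_cfg$seed)
    sims[[i]] <- simulate_spectrum(cfg_i, sample_index = 1000L * b + i)
    ids[i] <- sprintf("bg%d_amt%g", b, a)
    sims[[i]]$spectrum$id <- ids[i]
    truth[[i]] <- sims[[i]]$truth
  }
  m <- do.call(rbind, lapply(sims, function(s) s$spectrum$intensity))
  design$sample_id <- ids
  design$true_area <- vapply(seq_len(nrow(design)), function(i) {
    endo[design$background[i]] * bg_scale[design$background[i]] +
      design$amount[i] * response_per_ug
  }, 1)
  design$endogenous <- endo[design$background] * bg_scale[design$background]
  names(truth) <- ids
  list(set = spectra_set(sims[[1L]]$spectrum$ppm, m, ids),
       design = design[, c("sample_id", "background", "amount",
                           "true_area", "endogenous")],
       truth = truth)
}

#' Simulate a two-class dataset
#'
#' Class B multiplies the areas of selected peaks by a fold-change; labels
#' and the ground-truth effect table are returned with the data.
#'
#' @param cfg A [sim_config()]; `n_samples` is the per-class count here.
#' @param effect_peaks Data frame with columns `peak` (row index into
#'   `cfg$peaks`) and `fold_change` (positive).
#' @param n_per_class `c(nA, nB)`; defaults to `cfg$n_samples` each.
#' @return A list: `set` (labelled [spectra_set()]), `truth`, `effects`.
#' @export
simulate_two_class <- function(cfg, effect_peaks, n_per_class = NULL) {
  stopifnot(inherits(cfg, "sim_config"),
            all(c("peak", "fold_change") %in% names(effect_peaks)),
            all(effect_peaks$fold_change > 0))
  if (is.null(n_per_class)) n_per_class <- rep(cfg$n_samples, 2L)
  cfg_a <- cfg
  cfg_a$n_samples <- as.integer(n_per_class[1L])
  pk_b <- cfg$peaks
  pk_b$area[effect_peaks$peak] <- pk_b$area[effect_peaks$peak] * effect_peaks$fold_change
  cfg_b <- sim_config(axis = cfg$axis, peaks = pk_b, baseline = cfg$baseline,
                      noise_sd = cfg$noise_sd, dilution_range = cfg$dilution_range,
                      dilution_factors = cfg$dilution_factors,
                      n_samples = as.integer(n_per_class[2L]),
                      seed = cfg$seed + 500000L)
  a <- simulate_dataset(cfg_a)
  b <- simulate_dataset(cfg_b)
  ids <- c(paste0("A_", a$set$sample_ids), paste0("B_", b$set$sample_ids))
  set <- spectra_set(a$set$ppm, rbind(a$set$intensities, b$set$intensities),
                     ids, labels = rep(c("A", "B"), n_per_class))
  truth <- c(a$truth, b$truth)
  names(truth) <- ids
  effects <- data.frame(center = cfg$peaks$center[effect_peaks$peak],
                        fold_change = effect_peaks$fold_change)
  list(set = set, truth = truth, effects = effects)
}
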