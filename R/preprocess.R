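#' Remove a chemical-shift region from a spectra set
#'
#' Drops all axis points with `lo <= ppm <= hi` (inclusive on both ends, the
#' convention under which deleting the water region 4.70-4.85 ppm from the
#' 44,001-point -1..10 ppm axis leaves 43,400 points). Remaining points are
#' untouched and keep their order. An interval that misses the axis entirely
#' is a warning no-op.
#'
#' @param s A [spectra_set()].
#' @param lo,hi Removal bounds (ppm), `lo < hi`.
#' @return The trimmed `spectra_set`.
#' @export
remove_region <- function(s, lo = 4.70, hi = 4.85) {
  stopifnot(inherits(s, "spectra_set"), lo < hi)
  eps <- 1e-9 * max(1, abs(lo), abs(hi))
  drop <- s$ppm >= lo - eps & s$ppm <= hi + eps
  if (!any(drop)) {
    warning("removal interval [", lo, ", ", hi, "] does not overlap the axis; no-op")
    return(s)
  }
  if (all(drop)) stop("removal deletes the entire axis", call. = FALSE)
  spectra_set(s$ppm[!drop], s$intensities[, !drop, drop = FALSE],
              s$sample_ids, s$labels)
}

#' Pointwise mean reference spectrum
#'
#' @param s A [spectra_set()].
#' @return A [spectrum1d()] with `id = "mean"`.
#' @export
mean_reference <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  spectrum1d(s$ppm, colMeans(s$intensities), id = "mean")
}

#' Pointwise median reference spectrum
#'
#' Default PQN reference: robust to a few extreme samples.
#'
#' @param s A [spectra_set()].
#' @return A [spectrum1d()] with `id = "median"`.
#' @export
median_reference <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  spectrum1d(s$ppm, apply(s$intensities, 2L, stats::median), id = "median")
}

#' Probabilistic quotient normalization
#'
#' Divides each spectrum by the median of its pointwise quotients against a
#' reference spectrum, correcting multiplicative dilution differences (urine
#' concentration). Quotients are computed only where the reference exceeds
#' `noise_k` times an estimated noise floor, since quotients at noise points
#' are unstable.
#'
#' @param s A [spectra_set()].
#' @param reference A [spectrum1d()] on the same axis; defaults to the median
#'   spectrum of `s`.
#' @param noise_k Reference floor in noise-sigma units (default 5).
#' @return The normalized `spectra_set`, with per-sample dilution factors in
#'   attribute `"dilution_factors"`.
#' @export
pqn_normalize <- function(s, reference = NULL, noise_k = 5) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.null(reference)) reference <- median_reference(s)
  stopifnot(inherits(reference, "spectrum1d"))
  if (length(reference$ppm) != length(s$ppm) ||
      max(abs(reference$ppm - s$ppm)) > 1e-9) {
    stop("reference must share the spectra_set axis", call. = FALSE)
  }
  if (sum(reference$intensity) <= 0) {
    stop("reference has non-positive total intensity", call. = FALSE)
  }
  sigma <- tryCatch(estimate_noise(reference)$sigma, error = function(e) 0)
  use <- reference$intensity > noise_k * sigma
  if (sum(use) < 10L) use <- reference$intensity > 0
  factors <- numeric(nrow(s$intensities))
  out <- s$intensities
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    if (all(row == 0)) {
      stop("sample '", s$sample_ids[i], "' is all zero; cannot normalize", call. = FALSE)
    }
    q <- row[use] / reference$intensity[use]
    f <- stats::median(q)
    if (!is.finite(f) || f <= 0) {
      stop("sample '", s$sample_ids[i], "' has no valid positive quotient", call. = FALSE)
    }
    factors[i] <- f
    out[i, ] <- row / f
  }
  res <- spectra_set(s$ppm, out, s$sample_ids, s$labels)
  attr(res, "dilution_factors") <- stats::setNames(factors, s$sample_ids)
  res
}

#' Rigid cross-correlation alignment to a reference
#'
#' Convenience global alignment: each spectrum is shifted by the integer-point
#' offset (at most `max_shift` ppm in magnitude) that maximizes its
#' cross-correlation with the reference, with edge padding by the edge value.
#' This is a whole-spectrum rigid shift, not a segment-wise alignment; inputs
#' to the workflow are assumed already aligned.
#'
#' @param s A [spectra_set()].
#' @param reference A [spectrum1d()] on the same axis.
#' @param max_shift Maximum allowed shift (ppm), `>= 0`; 0 is the identity.
#' @return The shifted `spectra_set` with applied per-sample shifts (ppm) in
#'   attribute `"shifts_ppm"`.
#' @export
global_shift_align <- function(s, reference = NULL, max_shift = 0.005) {
  stopifnot(inherits(s, "spectra_set"), max_shift >= 0)
  if (is.null(reference)) reference <- mean_reference(s)
  step <- stats::median(diff(s$ppm))
  kmax <- floor(max_shift / step + 1e-9)
  shifts <- numeric(nrow(s$intensities))
  if (kmax == 0L) {
    attr(s, "shifts_ppm") <- stats::setNames(shifts, s$sample_ids)
    return(s)
  }
  ref <- reference$intensity - mean(reference$intensity)
  out <- s$intensities
  for (i in seq_len(nrow(out))) {
    y <- out[i, ]
    yc <- y - mean(y)
    best_k <- 0L
    best_cc <- -Inf
    for (k in -kmax:kmax) {
      cc <- if (k >= 0) {
        sum(yc[seq_len(length(yc) - k)] * ref[seq_len(length(ref) - k) + k])
      } else {
        sum(yc[seq_len(length(yc) + k) - k] * ref[seq_len(length(ref) + k)])
      }
      if (cc > best_cc) {
        best_cc <- cc
        best_k <- k
      }
    }
    out[i, ] <- shift_trace(y, best_k)
    shifts[i] <- best_k * step
  }
  res <- spectra_set(s$ppm, out, s$sample_ids, s$labels)
  attr(res, "shifts_ppm") <- stats::setNames(shifts, s$sample_ids)
  res
}

# index shift with edge-value padding; positive k moves the trace to higher ppm
shift_trace <- function(y, k) {
  n <- length(y)
  if (k == 0L) return(y)
  if (k > 0L) c(rep(y[1L], k), y[seq_len(n - k)])
  else c(y[(1L - k):n], rep(y[n], -k))
}
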