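#' Construct a single 1D NMR spectrum
#'
#' A `spectrum1d` holds one intensity trace on a chemical-shift axis. The axis
#' is always stored ascending; inputs given descending (the usual NMR display
#' order) are reversed together with the intensities.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly monotone.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `ppm`.
#' @param id Sample identifier string.
#' @return An object of class `spectrum1d` with fields `ppm`, `intensity`,
#'   `id`.
#' @export
spectrum1d <- function(ppm, intensity, id = "spectrum") {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have the same length", call. = FALSE)
  }
  if (any(!is.finite(ppm))) stop("ppm axis contains non-finite values", call. = FALSE)
  if (length(ppm) > 1L) {
    d <- diff(ppm)
    if (all(d < 0)) {
      ppm <- rev(ppm)
      intensity <- rev(intensity)
    } else if (any(d <= 0)) {
      stop("ppm axis must be strictly monotone", call. = FALSE)
    }
  }
  structure(list(ppm = ppm, intensity = intensity, id = as.character(id)[1L]),
            class = "spectrum1d")
}

#' Construct a multi-sample spectra set
#'
#' A `spectra_set` is a collection of spectra sharing one chemical-shift axis:
#' an `n_samples x n_points` intensity matrix plus sample identifiers and
#' optional class labels.
#'
#' @param ppm Shared chemical-shift axis (ppm), strictly monotone; stored
#'   ascending.
#' @param intensities Numeric matrix, one row per sample, `length(ppm)`
#'   columns.
#' @param sample_ids Unique sample identifier strings, one per row.
#' @param labels Optional class label per sample (character or factor).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(ppm, intensities, sample_ids = NULL, labels = NULL) {
  ppm <- as.numeric(ppm)
  intensities <- as.matrix(intensities)
  if (any(!is.finite(ppm))) stop("ppm axis contains non-finite values", call. = FALSE)
  if (ncol(intensities) != length(ppm)) {
    stop("intensity matrix must have length(ppm) columns", call. = FALSE)
  }
  if (nrow(intensities) < 1L) stop("spectra_set needs at least one sample", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities)) {
    stop("one sample_id per row required", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (!is.null(labels) && length(labels) != nrow(intensities)) {
    stop("labels must match the number of samples", call. = FALSE)
  }
  if (length(ppm) > 1L) {
    d <- diff(ppm)
    if (all(d < 0)) {
      ppm <- rev(ppm)
      intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
    } else if (any(d <= 0)) {
      stop("ppm axis must be strictly monotone", call. = FALSE)
    }
  }
  dimnames(intensities) <- NULL
  structure(list(ppm = ppm, intensities = intensities,
                 sample_ids = sample_ids, labels = labels),
            class = "spectra_set")
}

#' Extract one sample from a spectra set
#'
#' @param s A `spectra_set`.
#' @param i Sample index or sample id.
#' @return A `spectrum1d`.
#' @export
get_spectrum <- function(s, i) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.character(i)) i <- match(i, s$sample_ids)
  if (is.na(i) || i < 1L || i > nrow(s$intensities)) {
    stop("sample not found in spectra_set", call. = FALSE)
  }
  spectrum1d(s$ppm, s$intensities[i, ], s$sample_ids[i])
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d '%s': %d points, %.4f..%.4f ppm>\n",
              x$id, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set: %d samples x %d points, %.4f..%.4f ppm%s>\n",
              nrow(x$intensities), length(x$ppm), min(x$ppm), max(x$ppm),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Build a regular chemical-shift axis
#'
#' Constructs the axis `lo + k * step` for `k = 0..round((hi - lo)/step)`,
#' e.g. the conventional urine axis -1 to 10 ppm at 2.5e-4 ppm resolution
#' (44,001 points).
#'
#' @param lo,hi Axis endpoints (ppm).
#' @param step Axis resolution (ppm), positive.
#' @return Numeric ascending axis.
#' @export
ppm_axis <- function(lo = -1, hi = 10, step = 2.5e-4) {
  stopifnot(step > 0, hi > lo)
  n <- round((hi - lo) / step)
  lo + (0:n) * step
}
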