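#' Align per-sample peak tables to a reference peak table
#'
#' Builds cross-sample features from per-spectrum fitted peak tables.
#' Reference peaks are processed in descending reference area; for each, every
#' sample contributes at most its nearest unclaimed peak with
#' `|center - ref_center| <= window` (ties on distance go to the larger
#' area). Sample peaks matching no reference peak are pooled into new
#' features: the largest-area unclaimed peak seeds a feature at its center
#' and claims all unclaimed peaks within the window (at most one per sample,
#' the largest), repeating until none remain — so genuinely novel signals
#' survive alignment, though they typically fall to the frequency filter.
#' Every sample peak is used at most once and always lies within `window` of
#' its feature's reference center.
#'
#' @param tables Named list (by sample id) of peak tables as produced by
#'   [fit_spectrum()] (`$peaks`): columns `center`, `area`, `fwhm`, `snr`.
#' @param ref_table Reference peak table (same columns), non-empty.
#' @param window Maximum center distance (ppm) for a match, positive.
#' @return A list of class `peak_features`: `ref_center`, `frequency`,
#'   `median_snr`, `mean_width` (per feature), `areas` (samples x features,
#'   `NA` where undetected), `sample_ids`, `window`.
#' @export
align_to_reference <- function(tables, ref_table, window = 0.005) {
  stopifnot(window > 0, is.list(tables))
  if (is.null(ref_table) || nrow(ref_table) == 0L) {
    stop("reference peak table is empty", call. = FALSE)
  }
  sample_ids <- names(tables)
  if (is.null(sample_ids)) stop("tables must be a named list", call. = FALSE)
  n_s <- length(tables)
  ref_ord <- order(-ref_table$area, ref_table$center)
  claimed <- lapply(tables, function(t) logical(nrow(t)))
  feat_center <- numeric(0)
  feat_rows <- list()  # each: data.frame(sample, row) of claimed peaks

  claim_for_center <- function(center) {
    rows <- data.frame(sample = integer(), row = integer())
    for (si in seq_len(n_s)) {
      t <- tables[[si]]
      if (!nrow(t)) next
      free <- which(!claimed[[si]])
      if (!length(free)) next
      d <- abs(t$center[free] - center)
      ok <- free[d <= window]
      if (!length(ok)) next
      d_ok <- abs(t$center[ok] - center)
      best <- ok[order(d_ok, -t$area[ok])][1L]
      claimed[[si]][best] <<- TRUE
      rows <- rbind(rows, data.frame(sample = si, row = best))
    }
    rows
  }

  for (ri in ref_ord) {
    feat_center <- c(feat_center, ref_table$center[ri])
    feat_rows[[length(feat_rows) + 1L]] <- claim_for_center(ref_table$center[ri])
  }
  # pool leftover sample peaks into new features, largest area first
  repeat {
    best_a <- -Inf; best_c <- NA_real_
    for (si in seq_len(n_s)) {
      t <- tables[[si]]
      free <- which(!claimed[[si]])
      if (!length(free)) next
      j <- free[order(-t$area[free], t$center[free])][1L]
      if (t$area[j] > best_a) {
        best_a <- t$area[j]; best_c <- t$center[j]
      }
    }
    if (!is.finite(best_a)) break
    feat_center <- c(feat_center, best_c)
    feat_rows[[length(feat_rows) + 1L]] <- claim_for_center(best_c)
  }

  areas <- matrix(NA_real_, n_s, length(feat_center))
  snr <- width <- matrix(NA_real_, n_s, length(feat_center))
  for (fi in seq_along(feat_rows)) {
    rows <- feat_rows[[fi]]
    for (k in seq_len(nrow(rows))) {
      t <- tables[[rows$sample[k]]]
      areas[rows$sample[k], fi] <- t$area[rows$row[k]]
      snr[rows$sample[k], fi] <- if ("snr" %in% names(t)) t$snr[rows$row[k]] else NA_real_
      width[rows$sample[k], fi] <- if ("fwhm" %in% names(t)) t$fwhm[rows$row[k]] else NA_real_
    }
  }
  ord <- order(feat_center)
  structure(list(
    ref_center = feat_center[ord],
    frequency = colMeans(!is.na(areas))[ord],
    median_snr = apply(snr, 2L, stats::median, na.rm = TRUE)[ord],
    mean_width = colMeans(width, na.rm = TRUE)[ord],
    areas = areas[, ord, drop = FALSE],
    sample_ids = sample_ids,
    window = window), class = "peak_features")
}

#' Keep features detected in at least a fraction of samples
#'
#' @param features A `peak_features` object.
#' @param min_frac Minimum detection frequency in `[0, 1]`, inclusive
#'   boundary (a feature present in exactly `min_frac` of samples is kept).
#' @return The filtered `peak_features`.
#' @export
frequency_filter <- function(features, min_frac = 0.30) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  subset_features(features, features$frequency >= min_frac)
}

#' Keep features with sufficient median signal-to-noise
#'
#' @param features A `peak_features` object.
#' @param min_snr Minimum median S/N, `>= 0` (inclusive).
#' @return The filtered `peak_features`.
#' @export
snr_filter <- function(features, min_snr = 5) {
  stopifnot(min_snr >= 0)
  keep <- !is.na(features$median_snr) & features$median_snr >= min_snr
  subset_features(features, keep)
}

subset_features <- function(features, keep) {
  structure(list(
    ref_center = features$ref_center[keep],
    frequency = features$frequency[keep],
    median_snr = features$median_snr[keep],
    mean_width = features$mean_width[keep],
    areas = features$areas[, keep, drop = FALSE],
    sample_ids = features$sample_ids,
    window = features$window), class = "peak_features")
}

#' Assemble the final feature matrix
#'
#' Converts aligned, filtered features into the samples x features integral
#' matrix. Missing entries (peak not detected in a sample) are zero-filled by
#' default — a non-detected peak sits below the noise level — or kept `NA`
#' for downstream imputation.
#'
#' @param features A `peak_features` object with at least one feature.
#' @param missing `"zero"` (default) or `"nan"`.
#' @return A list of class `feature_matrix`: `sample_ids`, `ref_center`,
#'   `values` (samples x features), `frequency`, `median_snr`, `mean_width`.
#' @export
assemble_feature_matrix <- function(features, missing = c("zero", "nan")) {
  missing <- match.arg(missing)
  if (length(features$ref_center) == 0L) stop("no features to assemble", call. = FALSE)
  if (anyDuplicated(features$sample_ids)) stop("duplicate sample ids", call. = FALSE)
  ord <- order(features$ref_center)
  values <- features$areas[, ord, drop = FALSE]
  if (missing == "zero") values[is.na(values)] <- 0
  structure(list(sample_ids = features$sample_ids,
                 ref_center = features$ref_center[ord],
                 values = values,
                 frequency = features$frequency[ord],
                 median_snr = features$median_snr[ord],
                 mean_width = features$mean_width[ord]),
            class = "feature_matrix")
}

#' @export
print.peak_features <- function(x, ...) {
  cat(sprintf("<peak_features: %d features x %d samples, window %.4g ppm>\n",
              length(x$ref_center), length(x$sample_ids), x$window))
  invisible(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d samples x %d features>\n",
              length(x$sample_ids), length(x$ref_center)))
  invisible(x)
}
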