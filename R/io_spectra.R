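#' Read a multi-sample spectra CSV
#'
#' Expects a UTF-8 CSV with a mandatory header row: first column `ppm`, one
#' further column per sample. Rows may appear in any axis order; the returned
#' set always stores the axis ascending with rows reordered consistently.
#'
#' @param path Path to the CSV file.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  if (ncol(dt) < 2L) stop("spectra CSV needs a ppm column plus at least one sample column",
                          call. = FALSE)
  if (names(dt)[1L] != "ppm") {
    stop("format error: first column must be named 'ppm', found '",
         names(dt)[1L], "'", call. = FALSE)
  }
  for (j in seq_along(dt)) {
    if (!is.numeric(dt[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[j]]))) & !is.na(dt[[j]]))[1L]
      stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                   names(dt)[j], if (is.na(bad)) NA_integer_ else bad), call. = FALSE)
    }
  }
  ppm <- dt[[1L]]
  if (anyDuplicated(ppm)) stop("format error: duplicate ppm values", call. = FALSE)
  m <- t(as.matrix(dt[, -1L, drop = FALSE]))
  spectra_set(ppm, m, sample_ids = names(dt)[-1L])
}

#' Write a spectra set to CSV
#'
#' Inverse of [read_spectra_csv()]: `ppm` column plus one column per sample,
#' full double precision (round-trip exact to within text representation).
#'
#' @param s A [spectra_set()].
#' @param path Output path.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  if (nrow(s$intensities) < 1L) stop("refusing to write an empty spectra_set", call. = FALSE)
  df <- data.frame(ppm = s$ppm, t(s$intensities), check.names = FALSE)
  names(df) <- c("ppm", s$sample_ids)
  data.table::fwrite(df, path, sep = ",")  # fwrite emits shortest round-trip doubles
  invisible(NULL)
}

#' Read a Bruker processed 1D spectrum (real part)
#'
#' Optional vendor reader. Expects a processed-data directory holding `procs`
#' (JCAMP-style parameter file with `OFFSET`, `SW_p`, `SF`, `SI`, and
#' optionally `NC_proc`, `BYTORDP`) and the real-part file `1r` as 32-bit
#' integers. The axis is reconstructed as `OFFSET - k * (SW_p/SF)/(SI-1)` for
#' `k = 0..SI-1` (left edge at `OFFSET`, spanning `SW_p/SF` ppm) and stored
#' ascending; intensities are scaled by `2^NC_proc`.
#'
#' @param dir Directory containing `procs` and `1r`.
#' @return A [spectrum1d()].
#' @export
read_bruker_processed <- function(dir) {
  procs <- file.path(dir, "procs")
  oned <- file.path(dir, "1r")
  if (!file.exists(procs)) {
    stop("unsupported format: missing parameter file 'procs' in ", dir, call. = FALSE)
  }
  if (!file.exists(oned)) {
    stop("unsupported format: missing processed data file '1r' in ", dir, call. = FALSE)
  }
  par <- read_jcamp_params(procs)
  need <- c("OFFSET", "SW_p", "SF", "SI")
  miss <- setdiff(need, names(par))
  if (length(miss)) {
    stop("unsupported format: 'procs' lacks parameter(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  si <- as.integer(par[["SI"]])
  endian <- if (!is.null(par[["BYTORDP"]]) && par[["BYTORDP"]] == 1) "big" else "little"
  raw <- readBin(oned, what = "integer", n = si, size = 4L, endian = endian)
  if (length(raw) < si) stop("unsupported format: '1r' shorter than SI points", call. = FALSE)
  nc <- if (is.null(par[["NC_proc"]])) 0 else as.numeric(par[["NC_proc"]])
  y <- raw * 2^nc
  offset <- as.numeric(par[["OFFSET"]])
  span <- as.numeric(par[["SW_p"]]) / as.numeric(par[["SF"]])
  ppm <- if (si == 1L) offset else offset - (0:(si - 1L)) * span / (si - 1L)
  spectrum1d(ppm, y, id = basename(dir))
}

read_jcamp_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hits <- regmatches(lines, regexec("^##\\$?([A-Za-z_0-9]+)=\\s*(.*)$", lines))
  out <- list()
  for (h in hits) {
    if (length(h) == 3L) {
      v <- suppressWarnings(as.numeric(h[3L]))
      out[[h[2L]]] <- if (is.na(v)) h[3L] else v
    }
  }
  out
}

#' Write a feature matrix plus its metadata companion
#'
#' Writes two CSVs: `path` with one row per sample (id column `sample_id`,
#' one value column per feature named by the reference center formatted to
#' six decimal places) and `<path minus .csv>_features.csv` with per-feature
#' metadata (reference center, mean fitted width, detection frequency,
#' median S/N).
#'
#' @param fm A `feature_matrix` (see [assemble_feature_matrix()]).
#' @param path Output CSV path.
#' @return Invisibly, the metadata path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  cols <- sprintf("%.6f", fm$ref_center)
  df <- data.frame(sample_id = fm$sample_ids, fm$values, check.names = FALSE)
  names(df) <- c("sample_id", cols)
  data.table::fwrite(df, path, sep = ",")
  meta <- data.frame(ref_center = fm$ref_center,
                     mean_width = fm$mean_width,
                     frequency = fm$frequency,
                     median_snr = fm$median_snr)
  meta_path <- sub("\\.csv$", "", path)
  meta_path <- paste0(meta_path, "_features.csv")
  data.table::fwrite(meta, meta_path, sep = ",")
  invisible(meta_path)
}
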