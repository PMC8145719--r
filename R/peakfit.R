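#' Default fit configuration
#'
#' Collects every tunable of the peak-fitting pipeline with its default:
#' noise estimation (`diff_mad` over first differences, or `region_sd` over a
#' signal-free window, default 9.5-10.0 ppm), the net-intensity noise
#' threshold `k_noise` (default 5, matching the S/N > 5 feature filter), the
#' integration half-range `k_width` in FWHM multiples (default 3), region
#' segmentation (`gap_points` consecutive sub-3-sigma points split regions,
#' `pad_points` padding), the optimizer budget, and the per-region peak cap.
#'
#' @param noise_method `"diff_mad"` or `"region_sd"`.
#' @param noise_region ppm interval used by `region_sd`.
#' @param k_noise Net-intensity threshold in noise-sigma units.
#' @param k_width Integration half-range, multiples of fitted FWHM.
#' @param max_iter Maximum optimizer iterations per region.
#' @param gtol Optimizer gradient tolerance.
#' @param gap_points Minimum run of sub-threshold points that splits regions.
#' @param pad_points Points of padding added to each region side.
#' @param max_peaks_per_region Regions with more candidates are split at
#'   their weakest internal minimum.
#' @return A named list of class `fit_config`.
#' @export
fit_config <- function(noise_method = c("diff_mad", "region_sd"),
                       noise_region = c(9.5, 10.0),
                       k_noise = 5,
                       k_width = 3,
                       max_iter = 200,
                       gtol = 1e-10,
                       gap_points = 20,
                       pad_points = 10,
                       max_peaks_per_region = 30) {
  structure(list(noise_method = match.arg(noise_method),
                 noise_region = noise_region,
                 k_noise = k_noise, k_width = k_width,
                 max_iter = max_iter, gtol = gtol,
                 gap_points = gap_points, pad_points = pad_points,
                 max_peaks_per_region = max_peaks_per_region),
            class = "fit_config")
}

#' Pick all local maxima of a spectrum
#'
#' Returns every strict interior local maximum together with its flanking
#' minima and its net intensity: the height minus the higher of the two
#' flanking minima, where each flanking minimum is the lowest point between
#' the maximum and the nearest strictly higher point on that side (the
#' topographic prominence of the maximum). The net intensity is what the
#' noise filter thresholds: it discounts a raised baseline, the shoulder of
#' an overlapping neighbor, and the point-to-point jitter that noise
#' superimposes on a genuine peak top. Plateau maxima (runs of equal values
#' higher than both sides) are reported once, at the plateau's central point.
#'
#' @param s A [spectrum1d()] with at least 3 points.
#' @return A data frame with one row per candidate: `index`, `center` (ppm),
#'   `height`, `net_intensity`, `left_min_index`, `right_min_index`.
#' @export
pick_peaks <- function(s) {
  stopifnot(inherits(s, "spectrum1d"))
  y <- s$intensity
  n <- length(y)
  if (n < 3L) stop("need at least 3 points to pick peaks", call. = FALSE)
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- logical(k)
  if (k >= 3L) {
    v <- r$values
    is_max[2:(k - 1L)] <- v[2:(k - 1L)] > v[1:(k - 2L)] &
      v[2:(k - 1L)] > v[3:k]
  }
  max_runs <- which(is_max)
  if (!length(max_runs)) {
    return(data.frame(index = integer(), center = numeric(), height = numeric(),
                      net_intensity = numeric(), left_min_index = integer(),
                      right_min_index = integer()))
  }
  idx <- starts[max_runs] + (r$lengths[max_runs] - 1L) %/% 2L
  left <- right <- integer(length(idx))
  lmin <- rmin <- numeric(length(idx))
  for (i in seq_along(idx)) {
    m <- idx[i]
    h <- y[m]
    j <- m - 1L
    bi <- j
    bv <- y[j]
    while (j > 1L && y[j] <= h) {
      if (y[j] < bv) { bv <- y[j]; bi <- j }
      j <- j - 1L
    }
    if (y[j] < bv) { bv <- y[j]; bi <- j }
    left[i] <- bi; lmin[i] <- bv
    j <- m + 1L
    bi <- j
    bv <- y[j]
    while (j < n && y[j] <= h) {
      if (y[j] < bv) { bv <- y[j]; bi <- j }
      j <- j + 1L
    }
    if (y[j] < bv) { bv <- y[j]; bi <- j }
    right[i] <- bi; rmin[i] <- bv
  }
  height <- y[idx]
  net <- height - pmax(lmin, rmin)
  data.frame(index = idx, center = s$ppm[idx], height = height,
             net_intensity = pmax(net, 0), left_min_index = left,
             right_min_index = right)
}

#' Estimate the spectral noise level
#'
#' Two estimators of the additive noise standard deviation: `region_sd`, the
#' standard deviation of intensities in a signal-free window (default
#' 9.5-10.0 ppm), and `diff_mad`, the median absolute deviation of first
#' differences divided by `sqrt(2) * 0.67449` — robust to peaks because
#' differencing removes slowly varying signal. If the requested region is not
#' on the axis, the estimator falls back to `diff_mad` with a warning.
#'
#' @param s A [spectrum1d()].
#' @param method `"diff_mad"` (default) or `"region_sd"`.
#' @param region ppm interval for `region_sd`; needs at least 50 points.
#' @return A list of class `noise_estimate`: `sigma`, `method`, `region`.
#' @export
estimate_noise <- function(s, method = c("diff_mad", "region_sd"),
                           region = c(9.5, 10.0)) {
  stopifnot(inherits(s, "spectrum1d"))
  method <- match.arg(method)
  if (method == "region_sd") {
    in_reg <- s$ppm >= region[1L] & s$ppm <= region[2L]
    if (sum(in_reg) < 50L) {
      warning("noise region has fewer than 50 axis points; falling back to diff_mad")
      method <- "diff_mad"
      region <- NULL
    } else {
      sigma <- stats::sd(s$intensity[in_reg])
      if (!is.finite(sigma) || sigma <= 0) {
        stop("noise estimate must be positive; region is constant", call. = FALSE)
      }
      return(structure(list(sigma = sigma, method = "region_sd", region = region),
                       class = "noise_estimate"))
    }
  }
  sigma <- stats::mad(diff(s$intensity), constant = 1 / 0.67449) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("noise estimate must be positive; trace is (locally) constant", call. = FALSE)
  }
  structure(list(sigma = sigma, method = "diff_mad", region = NULL),
            class = "noise_estimate")
}

#' Discard peak candidates below the noise threshold
#'
#' Retains exactly the candidates whose net intensity is at least
#' `k_noise * sigma`; order is preserved and the output is always a subset of
#' the input.
#'
#' @param cands Candidate table from [pick_peaks()].
#' @param noise A `noise_estimate` from [estimate_noise()].
#' @param k_noise Threshold multiplier, `>= 0`.
#' @return The filtered candidate table.
#' @export
noise_filter <- function(cands, noise, k_noise = 5) {
  stopifnot(k_noise >= 0)
  cands[cands$net_intensity >= k_noise * noise$sigma, , drop = FALSE]
}

#' Split a spectrum into independent fitting regions
#'
#' Contiguous stretches of signal are separated wherever the intensity stays
#' below `3 * sigma` for at least `gap_points` consecutive points. Each region
#' is padded by `pad_points` on each side (without overlapping its
#' neighbors), and every candidate standing on signal (height at least
#' `3 * sigma`) is assigned to exactly one region; regions containing no
#' candidate are dropped, as are candidates lying inside a sub-threshold run
#' (mere baseline). Regions holding more than
#' `max_peaks` candidates are split at the weakest internal minimum between
#' consecutive candidates, which keeps the joint fit well conditioned.
#'
#' @param s A [spectrum1d()].
#' @param cands Candidate table (sorted by center) from [noise_filter()].
#' @param noise A `noise_estimate`.
#' @param gap_points,pad_points,max_peaks See [fit_config()].
#' @return List of regions, each `list(lo_index, hi_index, cands)`.
#' @export
segment_regions <- function(s, cands, noise, gap_points = 20, pad_points = 10,
                            max_peaks = 30) {
  if (nrow(cands) == 0L) return(list())
  cands <- cands[order(cands$center), , drop = FALSE]
  y <- s$intensity
  n <- length(y)
  below <- y < 3 * noise$sigma
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # gaps: long sub-threshold runs; signal blocks are what is between them
  gap <- r$values & r$lengths >= gap_points
  cuts <- cbind(starts[gap], ends[gap])
  block_lo <- c(1L, if (nrow(cuts)) cuts[, 2L] + 1L)
  block_hi <- c(if (nrow(cuts)) cuts[, 1L] - 1L, n)
  keep <- block_lo <= block_hi
  block_lo <- block_lo[keep]; block_hi <- block_hi[keep]
  regions <- list()
  for (b in seq_along(block_lo)) {
    in_b <- cands$index >= block_lo[b] & cands$index <= block_hi[b]
    if (!any(in_b)) next
    regions[[length(regions) + 1L]] <-
      list(lo_index = block_lo[b], hi_index = block_hi[b],
           cands = cands[in_b, , drop = FALSE])
  }
  # candidates inside a long sub-threshold run sit on mere baseline (their
  # height is below 3*sigma even when their prominence passed the net filter)
  # and are discarded with the run
  # enforce the per-region peak cap by splitting at the weakest internal minimum
  regions <- split_large_regions(regions, y, max_peaks)
  # pad without overlapping neighbors
  for (i in seq_along(regions)) {
    lo_lim <- if (i > 1L) regions[[i - 1L]]$hi_index + 1L else 1L
    hi_lim <- if (i < length(regions)) regions[[i + 1L]]$lo_index - 1L else n
    regions[[i]]$lo_index <- max(lo_lim, regions[[i]]$lo_index - pad_points)
    regions[[i]]$hi_index <- min(hi_lim, regions[[i]]$hi_index + pad_points)
  }
  regions
}

split_large_regions <- function(regions, y, max_peaks) {
  out <- list()
  for (reg in regions) {
    queue <- list(reg)
    while (length(queue)) {
      r <- queue[[1L]]
      queue <- queue[-1L]
      m <- nrow(r$cands)
      if (m <= max_peaks) {
        out[[length(out) + 1L]] <- r
        next
      }
      # weakest internal minimum between consecutive candidate maxima
      vals <- vapply(seq_len(m - 1L), function(j) {
        span <- (r$cands$index[j]):(r$cands$index[j + 1L])
        min(y[span])
      }, 1)
      j <- which.min(vals)
      span <- (r$cands$index[j]):(r$cands$index[j + 1L])
      cut <- span[which.min(y[span])]
      left <- list(lo_index = r$lo_index, hi_index = cut,
                   cands = r$cands[seq_len(j), , drop = FALSE])
      right <- list(lo_index = cut, hi_index = r$hi_index,
                    cands = r$cands[(j + 1L):m, , drop = FALSE])
      queue <- c(queue, list(left, right))
    }
  }
  out[order(vapply(out, function(r) r$lo_index, 1L))]
}

# initial parameter vector, lower and upper bounds for one region
region_initials <- function(s, region) {
  step <- stats::median(diff(s$ppm))
  x <- s$ppm[region$lo_index:region$hi_index]
  y <- s$intensity[region$lo_index:region$hi_index]
  span <- max(x) - min(x)
  reg_integral <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  reg_integral <- max(reg_integral, 10 * step * max(abs(y), step))
  cands <- region$cands
  m <- nrow(cands)
  par <- lower <- upper <- numeric(4L * m)
  for (i in seq_len(m)) {
    mu0 <- cands$center[i]
    w0 <- halfmax_width(s, cands$index[i], cands$left_min_index[i],
                        cands$right_min_index[i])
    if (!is.finite(w0) || w0 <= 0) w0 <- 4 * step
    eta0 <- 0.5
    A0 <- pv_area_from_height(max(cands$height[i], .Machine$double.eps), w0, eta0)
    par[(4L * i - 3L):(4L * i)] <- c(A0, mu0, w0, eta0)
    lower[(4L * i - 3L):(4L * i)] <- c(1e-12 * A0, mu0 - w0, 2 * step, 0)
    upper[(4L * i - 3L):(4L * i)] <- c(10 * reg_integral, mu0 + w0,
                                       max(span, 4 * step), 1)
  }
  list(par = par, lower = lower, upper = upper)
}

# FWHM estimate from the half-maximum crossings around a picked candidate
halfmax_width <- function(s, idx, left, right) {
  y <- s$intensity
  half <- y[idx] / 2
  i <- idx
  while (i > left && y[i] > half) i <- i - 1L
  lo <- if (y[i] <= half && i < idx) {
    # linear interpolation between i and i+1
    s$ppm[i] + (half - y[i]) / (y[i + 1L] - y[i]) * (s$ppm[i + 1L] - s$ppm[i])
  } else NA_real_
  j <- idx
  while (j < right && y[j] > half) j <- j + 1L
  hi <- if (y[j] <= half && j > idx) {
    s$ppm[j] + (half - y[j]) / (y[j - 1L] - y[j]) * (s$ppm[j - 1L] - s$ppm[j])
  } else NA_real_
  if (is.na(lo) && is.na(hi)) return(NA_real_)
  if (is.na(lo)) return(2 * (hi - s$ppm[idx]))
  if (is.na(hi)) return(2 * (s$ppm[idx] - lo))
  hi - lo
}

#' Fit pseudo-Voigt peaks to one region
#'
#' Bounded nonlinear least squares of a sum of pseudo-Voigt peaks (one per
#' candidate) against the observed trace, minimizing the residual sum of
#' squares over per-peak `(A, mu, w, eta)` with a Levenberg-Marquardt
#' trust-region scheme and an analytic Jacobian. Initialization: `mu0` at the
#' picked center, `w0` from the half-maximum crossings (fallback 4 axis
#' steps), `eta0 = 0.5`, `A0` inverted from the picked height. Bounds: center
#' within one initial width of the pick, width in `[2 * step, region span]`,
#' `eta` in `[0, 1]`, area in `(0, 10 * region integral]`. On
#' non-convergence one restart is made from 10% wider initial widths and the
#' better attempt kept. Parameter standard errors come from the Jacobian at
#' the solution, `se = sqrt(diag((J'J)^-1) * rss / (n - p))`.
#'
#' @param s A [spectrum1d()].
#' @param region A region from [segment_regions()].
#' @param noise A `noise_estimate` (used for the peaks' S/N).
#' @param cfg A [fit_config()].
#' @return A list of class `fit_region`: `lo_index`, `hi_index`, `peaks`
#'   (data frame: `area`, `center`, `fwhm`, `eta`, `height`, `snr`, `se_area`,
#'   `se_center`, `se_fwhm`, `se_eta`, `at_bound`), `rss`, `n_points`,
#'   `converged`, `n_iter`.
#' @export
fit_region <- function(s, region, noise, cfg = fit_config()) {
  x <- s$ppm[region$lo_index:region$hi_index]
  y <- s$intensity[region$lo_index:region$hi_index]
  m <- nrow(region$cands)
  if (length(x) < 4L * m + 1L) {
    stop("region has too few points for ", m, " peaks", call. = FALSE)
  }
  ini <- region_initials(s, region)

  run <- function(par0) {
    res_fn <- function(p) y - pv_sum_model(x, p, jacobian = FALSE)$y
    jac_fn <- function(p) -pv_sum_model(x, p)$J
    fit <- minpack.lm::nls.lm(par = par0, lower = ini$lower, upper = ini$upper,
                              fn = res_fn, jac = jac_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = cfg$max_iter, gtol = cfg$gtol,
                                ftol = 1e-12, ptol = 1e-12))
    fit
  }
  fit <- run(ini$par)
  converged <- fit$info %in% c(1, 2, 3, 4)
  if (!converged) {
    par2 <- ini$par
    par2[seq(3, length(par2), by = 4)] <- pmin(par2[seq(3, length(par2), by = 4)] * 1.1,
                                               ini$upper[seq(3, length(par2), by = 4)])
    fit2 <- run(par2)
    if (fit2$deviance < fit$deviance) fit <- fit2
    converged <- fit$info %in% c(1, 2, 3, 4)
  }
  par <- fit$par
  rss <- fit$deviance
  n <- length(x)
  p <- length(par)
  J <- pv_sum_model(x, par)$J
  se <- rep(NA_real_, p)
  if (n > p) {
    JtJ <- crossprod(J)
    cov <- tryCatch(solve(JtJ), error = function(e) {
      sv <- svd(JtJ)
      pos <- sv$d > max(sv$d) * 1e-12
      sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    })
    se <- sqrt(pmax(diag(cov) * rss / (n - p), 0))
  }
  step <- stats::median(diff(s$ppm))
  idx4 <- function(k) seq(k, p, by = 4L)
  A <- par[idx4(1L)]; mu <- par[idx4(2L)]; w <- par[idx4(3L)]; eta <- par[idx4(4L)]
  at_bound <- w <= 2 * step * (1 + 1e-6) | A <= ini$lower[idx4(1L)] * (1 + 1e-6)
  peaks <- data.frame(
    area = A, center = mu, fwhm = w, eta = eta,
    height = pv_height(A, w, eta),
    snr = pv_height(A, w, eta) / noise$sigma,
    se_area = se[idx4(1L)], se_center = se[idx4(2L)],
    se_fwhm = se[idx4(3L)], se_eta = se[idx4(4L)],
    at_bound = at_bound)
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(lo_index = region$lo_index, hi_index = region$hi_index,
                 peaks = peaks, rss = rss, n_points = n,
                 converged = converged, n_iter = fit$niter),
            class = "fit_region")
}

#' Fit a whole spectrum
#'
#' The per-spectrum pipeline: pick all local maxima, discard candidates with
#' net intensity below `k_noise * sigma`, segment the axis into independent
#' regions, fit each region by bounded least squares, and integrate each
#' fitted peak over `mu +/- k_width * FWHM`. Fitted peaks whose height falls
#' below `k_noise * sigma` are dropped from the peak table: candidate-stage
#' prominence can exceed the threshold on extreme noise excursions, but a
#' genuine peak must also clear it in fitted S/N (very small peaks below the
#' defined S/N ratio are excluded from further analysis). Region failures are
#' flagged, never fatal. The pipeline is deterministic: identical input and
#' configuration give identical output.
#'
#' @param s A [spectrum1d()].
#' @param cfg A [fit_config()].
#' @param noise Optional precomputed `noise_estimate`; estimated from `s`
#'   otherwise.
#' @return A list of class `spectrum_fit`: `regions` (list of `fit_region`),
#'   `peaks` (per-spectrum peak table with `center`, `area` — the `k_width`
#'   integral — `area_total`, `fwhm`, `eta`, `height`, `snr`, standard errors,
#'   `region`), `noise`, `id`.
#' @export
fit_spectrum <- function(s, cfg = fit_config(), noise = NULL) {
  stopifnot(inherits(s, "spectrum1d"))
  if (is.null(noise)) {
    noise <- estimate_noise(s, method = cfg$noise_method, region = cfg$noise_region)
  }
  cands <- pick_peaks(s)
  cands <- noise_filter(cands, noise, cfg$k_noise)
  regions <- segment_regions(s, cands, noise, gap_points = cfg$gap_points,
                             pad_points = cfg$pad_points,
                             max_peaks = cfg$max_peaks_per_region)
  fitted <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    fitted[[i]] <- tryCatch(fit_region(s, regions[[i]], noise, cfg),
                            error = function(e) {
                              structure(list(lo_index = regions[[i]]$lo_index,
                                             hi_index = regions[[i]]$hi_index,
                                             peaks = NULL, rss = NA_real_,
                                             n_points = regions[[i]]$hi_index -
                                               regions[[i]]$lo_index + 1L,
                                             converged = FALSE, n_iter = 0L,
                                             error = conditionMessage(e)),
                                        class = "fit_region")
                            })
  }
  tabs <- lapply(seq_along(fitted), function(i) {
    pk <- fitted[[i]]$peaks
    if (is.null(pk) || nrow(pk) == 0L) return(NULL)
    # drop noise artifacts: sub-S/N fits, spikes pinned at the width bound,
    # and sub-resolution widths (an FWHM spanning fewer than ~3 axis steps
    # is a between-grid-point spike, not a sampled lineshape)
    step <- stats::median(diff(s$ppm))
    pk <- pk[pk$snr >= cfg$k_noise & !pk$at_bound & pk$fwhm >= 3 * step, ,
             drop = FALSE]
    if (nrow(pk) == 0L) return(NULL)
    pk$area_total <- pk$area
    pk$area <- integrate_peak(data.frame(area = pk$area_total, eta = pk$eta),
                              cfg$k_width)
    pk$region <- i
    pk
  })
  peaks <- do.call(rbind, tabs)
  if (is.null(peaks)) {
    peaks <- data.frame(area = numeric(), center = numeric(), fwhm = numeric(),
                        eta = numeric(), height = numeric(), snr = numeric(),
                        se_area = numeric(), se_center = numeric(),
                        se_fwhm = numeric(), se_eta = numeric(),
                        at_bound = logical(), area_total = numeric(),
                        region = integer())
  } else {
    peaks <- peaks[order(peaks$center), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(regions = fitted, peaks = peaks, noise = noise, id = s$id),
            class = "spectrum_fit")
}

#' Quality report for a set of fitted regions
#'
#' JSON-serializable fit diagnostics: per-region residual sum of squares
#' (absolute and per point), convergence flag, iteration count, and the peak
#' parameters with their standard errors; peaks sitting on a parameter bound
#' are flagged.
#'
#' @param regions List of `fit_region` objects (or a `spectrum_fit`).
#' @return A list ready for [jsonlite::toJSON()].
#' @export
fit_report <- function(regions) {
  if (inherits(regions, "spectrum_fit")) regions <- regions$regions
  list(
    n_regions = length(regions),
    regions = lapply(regions, function(r) {
      list(lo_index = r$lo_index, hi_index = r$hi_index,
           rss = r$rss, rss_per_point = r$rss / r$n_points,
           n_points = r$n_points, converged = r$converged, n_iter = r$n_iter,
           n_peaks = if (is.null(r$peaks)) 0L else nrow(r$peaks),
           peaks = if (is.null(r$peaks)) list() else r$peaks,
           error = r$error)
    })
  )
}

#' Overlay plot of a fitted spectrum
#'
#' Draws the observed trace with each fitted peak's lineshape and the summed
#' model, ppm axis reversed per NMR display convention.
#'
#' @param s The fitted [spectrum1d()].
#' @param fit Its `spectrum_fit`.
#' @param xlim Optional ppm window (plotted reversed).
#' @export
plot_fit_overlay <- function(s, fit, xlim = NULL) {
  if (is.null(xlim)) xlim <- range(s$ppm)
  sel <- s$ppm >= min(xlim) & s$ppm <= max(xlim)
  graphics::plot(s$ppm[sel], s$intensity[sel], type = "l", col = "grey30",
                 xlim = rev(sort(xlim)), xlab = "chemical shift (ppm)",
                 ylab = "intensity (a.u.)", main = s$id)
  pk <- fit$peaks
  if (!is.null(pk) && nrow(pk)) {
    total <- numeric(sum(sel))
    cols <- grDevices::rainbow(nrow(pk), v = 0.8)
    for (i in seq_len(nrow(pk))) {
      yi <- pseudo_voigt(s$ppm[sel], pk$area_total[i], pk$center[i],
                         pk$fwhm[i], pk$eta[i])
      graphics::lines(s$ppm[sel], yi, col = cols[i])
      total <- total + yi
    }
    graphics::lines(s$ppm[sel], total, col = "red", lty = 2)
  }
  invisible(NULL)
}
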