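test_that("peak picking finds interior maxima with flanking minima", {
  x <- seq(0, 1, by = 0.01)
  expect_equal(nrow(pick_peaks(spectrum1d(x, x))), 0L)
  expect_error(pick_peaks(spectrum1d(c(0, 1), c(0, 1))), "3 points")

  g <- single_peak_spectrum(A = 1, mu = 2.0, w = 0.01, eta = 0, halfspan = 0.05)
  cands <- pick_peaks(g)
  expect_equal(nrow(cands), 1L)
  expect_lt(abs(cands$center - 2.0), 2.5e-4)
  expect_true(cands$left_min_index < cands$index &
                cands$index < cands$right_min_index)
  expect_true(cands$height >= cands$net_intensity)

  # plateau reported once at its central point
  y <- c(0, 1, 2, 2, 2, 1, 0)
  p <- pick_peaks(spectrum1d(seq_along(y), y))
  expect_equal(p$index, 4L)
})

test_that("two equal peaks resolve or merge with separation, matching a
           brute-force scan", {
  step <- 2.5e-4
  for (sep in c(0.005, 0.03)) {
    x <- ppm_axis(1.8, 2.2, step)
    y <- pseudo_voigt(x, 1, 2 - sep / 2, 0.01, 0) +
      pseudo_voigt(x, 1, 2 + sep / 2, 0.01, 0)
    found <- nrow(pick_peaks(spectrum1d(x, y)))
    oracle <- sum(diff(sign(diff(y))) == -2)   # strict interior maxima
    expect_equal(found, oracle)
    expect_equal(found, if (sep < 0.01) 1L else 2L)
  }
})

test_that("noise estimators recover a known sigma", {
  set.seed(11)
  s <- spectrum1d(seq_len(10000) * 1e-3, rnorm(10000, 0, 1))
  est <- estimate_noise(s, "diff_mad")
  expect_gt(est$sigma, 0.95)
  expect_lt(est$sigma, 1.05)

  set.seed(12)
  x <- ppm_axis(9, 10.5, 2.5e-4)
  s2 <- spectrum1d(x, rnorm(length(x), 0, 2))
  est2 <- estimate_noise(s2, "region_sd", region = c(9.5, 10.0))
  expect_gt(est2$sigma, 1.9)
  expect_lt(est2$sigma, 2.1)
  expect_equal(est2$method, "region_sd")

  expect_error(estimate_noise(spectrum1d(1:100, rep(0, 100)), "diff_mad"),
               "positive")
  expect_warning(estimate_noise(s, "region_sd", region = c(50, 51)),
                 "fewer than 50")
})

test_that("noise filter keeps exactly the candidates above threshold", {
  noise <- tiny_noise(1)
  cands <- data.frame(index = 1:5, center = 1:5,
                      height = c(10, 6, 4, 5.5, 20),
                      net_intensity = c(10, 6, 4, 5.5, 20),
                      left_min_index = 0:4, right_min_index = 2:6)
  expect_equal(nrow(noise_filter(cands, noise, 0)), 5L)
  expect_equal(noise_filter(cands, noise, 5)$net_intensity, c(10, 6, 5.5, 20))
  expect_equal(nrow(noise_filter(cands[3, ], noise, 5)), 0L)

  # on simulated data the retained set equals a brute-force threshold scan,
  # all strong true peaks survive, and raising k never adds candidates
  sim <- simulate_spectrum(small_cfg(seed = 21L), 0L)
  est <- estimate_noise(sim$spectrum)
  all_c <- pick_peaks(sim$spectrum)
  kept <- noise_filter(all_c, est, 5)
  expect_equal(kept, all_c[all_c$net_intensity >= 5 * est$sigma, ])
  strong <- sim$truth[sim$truth$snr >= 20, ]
  expect_true(all(vapply(strong$center,
                         function(c0) any(abs(kept$center - c0) < 0.002), TRUE)))
  sizes <- vapply(0:10, function(k) nrow(noise_filter(all_c, est, k)), 1L)
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(kept$index %in% all_c$index))
})

test_that("segmentation partitions candidates into disjoint padded regions", {
  sim <- simulate_spectrum(small_cfg(seed = 22L), 0L)
  est <- estimate_noise(sim$spectrum)
  cands <- noise_filter(pick_peaks(sim$spectrum), est, 5)
  regs <- segment_regions(sim$spectrum, cands, est)
  expect_gt(length(regs), 1L)
  assigned <- unlist(lapply(regs, function(r) r$cands$index))
  on_signal <- cands$index[cands$height >= 3 * est$sigma]
  expect_setequal(assigned, on_signal)
  expect_equal(anyDuplicated(assigned), 0L)
  spans <- t(vapply(regs, function(r) c(r$lo_index, r$hi_index), c(1, 1)))
  expect_true(all(spans[, 2] > spans[, 1]))
  if (nrow(spans) > 1L) {
    expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
  }
  for (r in regs) {
    expect_true(all(r$cands$index >= r$lo_index & r$cands$index <= r$hi_index))
  }

  # well-separated doublet with no sub-threshold gap stays in one region
  x <- ppm_axis(1.4, 1.6, 2.5e-4)
  y <- pseudo_voigt(x, 1, 1.49, 0.005, 0.5) + pseudo_voigt(x, 1, 1.51, 0.005, 0.5)
  s <- spectrum1d(x, y)
  n <- tiny_noise(1e-4)
  r1 <- segment_regions(s, pick_peaks(s), n)
  expect_length(r1, 1L)
  expect_equal(nrow(r1[[1L]]$cands), 2L)
})

test_that("noiseless single-peak fits recover all parameters", {
  s <- single_peak_spectrum(A = 1, mu = 3.0, w = 0.01, eta = 0.7)
  pk <- fit_single(s)
  expect_equal(pk$area, 1, tolerance = 1e-6)
  expect_equal(pk$center, 3.0, tolerance = 1e-6)
  expect_equal(pk$fwhm, 0.01, tolerance = 1e-6)
  expect_equal(pk$eta, 0.7, tolerance = 1e-4)
  expect_lt(fit_single(s)$se_area, 1e-6)
})

test_that("noisy single-peak fits recover area and its standard error scale", {
  A <- 1; mu <- 3; w <- 0.01; eta <- 0.7
  height <- pv_height(A, w, eta)
  sigma <- height / 100
  err <- se_area <- numeric(30)
  for (i in seq_len(30)) {
    set.seed(100 + i)
    x <- ppm_axis(2.9, 3.1, 2.5e-4)
    s <- spectrum1d(x, pseudo_voigt(x, A, mu, w, eta) + rnorm(length(x), 0, sigma))
    pk <- fit_single(s, sigma = sigma)
    err[i] <- pk$area - A
    se_area[i] <- pk$se_area
  }
  expect_lt(stats::median(abs(err)) / A, 0.01)
  emp_sd <- stats::sd(err)
  expect_gt(stats::median(se_area), emp_sd / 3)
  expect_lt(stats::median(se_area), emp_sd * 3)
})

test_that("strong overlap conserves the summed fitted area", {
  w <- 0.01
  x <- ppm_axis(2.8, 3.2, 2.5e-4)
  y <- pseudo_voigt(x, 1, 3 - 0.3 * w, w, 0.5) +
    pseudo_voigt(x, 1, 3 + 0.3 * w, w, 0.5)
  s <- spectrum1d(x, y)
  noise <- tiny_noise(1e-8)
  # at 0.6 w separation the maxima merge; supply both true centers as
  # candidates so the joint two-peak fit is exercised
  idx <- vapply(c(3 - 0.3 * w, 3 + 0.3 * w),
                function(m) which.min(abs(x - m)), 1L)
  cands <- data.frame(index = idx, center = x[idx], height = y[idx],
                      net_intensity = y[idx],
                      left_min_index = c(1L, idx[1L]),
                      right_min_index = c(idx[2L], length(x)))
  fr <- fit_region(s, list(lo_index = 1L, hi_index = length(x), cands = cands),
                   noise)
  expect_equal(sum(fr$peaks$area), 2, tolerance = 0.005)
})

test_that("fit_spectrum is deterministic and empty on pure noise", {
  sim <- simulate_spectrum(small_cfg(seed = 23L), 0L)
  f1 <- fit_spectrum(sim$spectrum)
  f2 <- fit_spectrum(sim$spectrum)
  expect_identical(f1$peaks, f2$peaks)
  expect_identical(f1$regions[[1L]]$rss, f2$regions[[1L]]$rss)

  set.seed(31)
  flat <- spectrum1d(ppm_axis(1, 2, 2.5e-4), rnorm(4001, 0, 0.01))
  f0 <- fit_spectrum(flat)
  expect_equal(nrow(f0$peaks), 0L)
})

test_that("fit_spectrum recovers a multi-peak urine-like spectrum", {
  sim <- simulate_spectrum(sim_config(axis = c(0.5, 9.5, 2.5e-4),
                                      n_samples = 1L, seed = 24L), 0L)
  fit <- fit_spectrum(sim$spectrum)
  strong <- sim$truth[sim$truth$snr >= 10, ]
  hit <- vapply(seq_len(nrow(strong)), function(i) {
    j <- which.min(abs(fit$peaks$center - strong$center[i]))
    abs(fit$peaks$center[j] - strong$center[i]) <= 0.002
  }, TRUE)
  expect_gte(mean(hit), 0.95)
  # matched areas: compare the truncated true integral to the fitted one
  err <- vapply(which(hit), function(i) {
    j <- which.min(abs(fit$peaks$center - strong$center[i]))
    truth_int <- integrate_peak(list(area = strong$area[i], eta = strong$eta[i]), 3)
    abs(fit$peaks$area[j] - truth_int) / truth_int
  }, 1)
  expect_lt(stats::median(err), 0.05)
})

test_that("fit report reproduces the residual sum of squares", {
  sim <- simulate_spectrum(small_cfg(seed = 25L), 0L)
  fit <- fit_spectrum(sim$spectrum)
  rep <- fit_report(fit)
  expect_equal(rep$n_regions, length(fit$regions))
  r1 <- fit$regions[[1L]]
  x <- sim$spectrum$ppm[r1$lo_index:r1$hi_index]
  y <- sim$spectrum$intensity[r1$lo_index:r1$hi_index]
  model <- numeric(length(x))
  for (i in seq_len(nrow(r1$peaks))) {
    model <- model + pseudo_voigt(x, r1$peaks$area[i], r1$peaks$center[i],
                                  r1$peaks$fwhm[i], r1$peaks$eta[i])
  }
  expect_equal(rep$regions[[1L]]$rss, sum((y - model)^2), tolerance = 1e-10)
  expect_true(all(vapply(rep$regions, function(r) is.logical(r$converged), TRUE)))
  empty <- fit_report(list())
  expect_equal(empty$n_regions, 0L)
  expect_no_error(jsonlite::toJSON(empty, auto_unbox = TRUE))
})
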