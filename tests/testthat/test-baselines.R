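test_that("full-spectra matrix is the identity view at full axis width", {
  ax <- ppm_axis(-1, 10, 2.5e-4)
  s <- spectra_set(ax, matrix(rnorm(2 * length(ax)), 2), c("a", "b"))
  trimmed <- remove_region(s, 4.70, 4.85)
  m <- full_matrix(trimmed)
  expect_equal(dim(m), c(2L, 43400L))
  expect_identical(unname(m[1, ]), trimmed$intensities[1, ])
})

test_that("0.01-ppm binning of the water-removed axis yields 1085 bins", {
  ax <- ppm_axis(-1, 10, 2.5e-4)
  s <- remove_region(spectra_set(ax, matrix(1, 1, length(ax)), "a"), 4.70, 4.85)
  bm <- bin_spectra(s, 0.01)
  expect_equal(ncol(bm$values), 1085L)
  # a full interior bin of a constant-1.0 spectrum integrates to the width
  expect_equal(unname(bm$values[1, 2]), 0.01, tolerance = 1e-12)
})

test_that("bin count at other widths matches an independent recount oracle", {
  ax <- ppm_axis(-1, 10, 2.5e-4)
  s <- remove_region(spectra_set(ax, matrix(1, 1, length(ax)), "a"), 4.70, 4.85)
  recount <- function(width) {
    segs <- split(s$ppm, cumsum(c(1, diff(s$ppm) > 2 * 2.5e-4)))
    sum(vapply(segs, function(p) {
      span <- max(p) - min(p)
      nf <- floor(span / width + 1e-9)
      if (span - nf * width >= width / 2 - 1e-12) nf + 1 else max(nf, 1)
    }, 1))
  }
  for (width in c(0.01, 0.02, 0.05)) {
    expect_equal(ncol(bin_spectra(s, width)$values), recount(width))
  }
  expect_equal(recount(0.01), 1085L)
  expect_error(bin_spectra(s, 1e-5), "two axis steps")
})

test_that("bin AUCs sum to the whole-segment trapezoidal integral", {
  sim <- simulate_dataset(small_cfg(n_samples = 2L, seed = 31L))
  set <- sim$set
  bm <- bin_spectra(set, 0.01)
  for (i in 1:2) {
    y <- set$intensities[i, ]
    total <- sum(diff(set$ppm) * (head(y, -1) + tail(y, -1)) / 2)
    expect_equal(sum(bm$values[i, ]), total, tolerance = 1e-9)
  }
  # gapped axis: additivity holds per segment
  gapped <- remove_region(set, 1.4, 1.6)
  bm2 <- bin_spectra(gapped, 0.01)
  keepL <- gapped$ppm < 1.4
  yL <- gapped$intensities[1, keepL]
  totL <- sum(diff(gapped$ppm[keepL]) * (head(yL, -1) + tail(yL, -1)) / 2)
  inL <- bm2$bin_hi <= 1.4 + 1e-9
  expect_equal(sum(bm2$values[1, inL]), totL, tolerance = 1e-9)
})

test_that("standard curves back-calculate exactly on linear responses and
           match a closed-form OLS oracle", {
  amounts <- rep(c(5, 10, 15), 2)
  sc <- standard_curve(amounts, 2 * amounts + 1)
  expect_equal(sc$slope, 2)
  expect_equal(sc$intercept, 1)
  expect_equal(sc$rse_per_point, rep(0, 6), tolerance = 1e-10)
  expect_equal(sc$mean_rse, 0, tolerance = 1e-10)

  # perturb one response by +10% at amount 10 and verify against a
  # closed-form least-squares recomputation
  resp <- 2 * amounts + 1
  resp[2] <- resp[2] * 1.1
  sc2 <- standard_curve(amounts, resp)
  xbar <- mean(amounts); ybar <- mean(resp)
  slope <- sum((amounts - xbar) * (resp - ybar)) / sum((amounts - xbar)^2)
  intercept <- ybar - slope * xbar
  back <- (resp - intercept) / slope
  expect_equal(sc2$slope, slope, tolerance = 1e-12)
  expect_equal(sc2$rse_per_point, 100 * abs(back - amounts) / amounts,
               tolerance = 1e-12)
  expect_equal(sc2$mean_rse, mean(100 * abs(back - amounts) / amounts),
               tolerance = 1e-12)

  expect_error(standard_curve(c(5, 5, 10), c(1, 1, 1)), "3 distinct")
  expect_error(standard_curve(c(5, 10, 15), c(2, 2, 2)), "slope")
})

test_that("noisy 12-point design mean RSE matches brute-force recomputation", {
  set.seed(41)
  design <- expand.grid(amount = c(5, 10, 15), background = 1:4)
  design$response <- 0.3 * design$amount + design$background * 2 +
    rnorm(12, 0, 0.1)
  d <- background_correct(design)
  sc <- standard_curve(d$amount, d$response_corrected)
  fit <- lm(response_corrected ~ amount, data = d)
  back <- (d$response_corrected - coef(fit)[1]) / coef(fit)[2]
  expect_equal(sc$mean_rse, mean(100 * abs(back - d$amount) / d$amount),
               tolerance = 1e-12)
})

test_that("method responses extract height, bin AUC and fitted integral", {
  ax <- ppm_axis(1, 2, 2.5e-4)
  s <- spectra_set(ax, matrix(1, 1, length(ax)), "a")
  expect_equal(unname(method_responses(s, 1.25, "full")), 1)
  bm <- bin_spectra(s, 0.01)
  expect_equal(unname(method_responses(bm, 1.255, "binned")), 0.01,
               tolerance = 1e-12)
  fm <- structure(list(sample_ids = "a", ref_center = c(1.25, 1.40),
                       values = matrix(c(7, 9), 1), frequency = c(1, 1),
                       median_snr = c(10, 10), mean_width = c(0.002, 0.002)),
                  class = "feature_matrix")
  expect_equal(unname(method_responses(fm, 1.251, "voigt")), 7)
  expect_warning(r <- method_responses(fm, 1.6, "voigt"), "no feature")
  expect_true(all(is.na(r)))
})

test_that("spiked peak series responds proportionally in voigt mode", {
  a <- 0.01
  tabs <- lapply(1:3, function(k) {
    data.frame(center = 1.5, area = k * a, fwhm = 0.002, snr = 100)
  })
  names(tabs) <- paste0("s", 1:3)
  feats <- align_to_reference(tabs, tabs[[1]], 0.005)
  fm <- assemble_feature_matrix(feats)
  resp <- method_responses(fm, 1.5, "voigt")
  expect_equal(unname(resp / resp[1]), c(1, 2, 3), tolerance = 1e-12)
})

test_that("UV-scaled PCA has the documented algebraic properties", {
  # two samples: PC1 carries all variance
  m2 <- matrix(c(1, 3, 2, 8), 2)
  p2 <- pca_uv(m2)
  expect_equal(p2$explained_fraction[1], 1)

  set.seed(51)
  m <- matrix(rnorm(20 * 8), 20)
  p <- pca_uv(m)
  x <- scale(m)
  attr(x, "scaled:center") <- attr(x, "scaled:scale") <- NULL
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - x)), 1e-10)
  expect_equal(sum(p$explained_variance), sum(apply(x, 2, var)),
               tolerance = 1e-10)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(p$loadings))) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  # block structure recovered up to sign
  blk <- cbind(matrix(rep(rnorm(20), 3), 20) + matrix(rnorm(60, 0, 0.05), 20),
               matrix(rep(rnorm(20), 3), 20) + matrix(rnorm(60, 0, 0.05), 20))
  pb <- pca_uv(blk, n_comp = 2)
  l1 <- pb$loadings[, 1]
  expect_true(all(sign(l1[1:3]) == sign(l1[1])) &&
                all(sign(l1[4:6]) == sign(l1[4])))
  expect_warning(pca_uv(cbind(m, 5)), "constant")
  expect_error(pca_uv(matrix(1, 5, 3)), "non-constant")
})
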