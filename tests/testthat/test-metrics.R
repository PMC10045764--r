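test_that("PSNR follows the peak-over-MSE formula with its two variants", {
  d <- matrix(0, 10, 10); d[1, 1] <- 1
  r <- d; r[] <- d - 0.1  # MSE = 0.01, d_max = 1
  expect_equal(psnr(d, r), 20)
  expect_equal(psnr(d, r, variant = "standard"), 20)  # coincide when d_max = 1

  d2 <- 2 * d; r2 <- d2 - 0.2  # d_max = 2, MSE = 0.04
  expect_equal(psnr(d2, r2), 10 * log10(2 / 0.04))
  expect_equal(psnr(d2, r2, variant = "standard"), 10 * log10(4 / 0.04))

  expect_identical(psnr(d, d), Inf)
  expect_error(psnr(d, matrix(0, 9, 9)), "dimensions")
})

test_that("global SSIM matches its closed-form cases", {
  set.seed(3)
  r <- matrix(runif(400, 0, 1), 20, 20)
  expect_equal(ssim(r, r), 1, tolerance = 1e-9)

  # constant shift: I = 2*mu_d*mu_r / (mu_d^2 + mu_r^2), C = S = 1
  r05 <- r - mean(r) + 0.5   # mu_r = 0.5
  d <- r05 + 0.5             # mu_d = 1.0
  expect_equal(ssim(d, r05), 0.8, tolerance = 1e-9)

  # anti-correlated images have negative structure term
  expect_lt(ssim(1 - r, r), 0)

  # the formula is symmetric
  d2 <- r + matrix(rnorm(400, sd = 0.1), 20, 20)
  expect_equal(ssim(d2, r), ssim(r, d2), tolerance = 1e-12)

  expect_error(ssim(matrix(1, 4, 4), matrix(1, 4, 4), eps = 0), "degenerate")
  expect_lt(abs(ssim(d2, r, variant = "standard") - ssim(d2, r)), 0.05)
})

test_that("ROI metrics are local to the mask", {
  set.seed(4)
  r <- matrix(runif(256), 16, 16)
  d <- r + matrix(rnorm(256, sd = 0.05), 16, 16)
  mask <- matrix(FALSE, 16, 16); mask[5:12, 5:12] <- TRUE

  full <- roi_metrics(d, r, matrix(TRUE, 16, 16))
  expect_equal(full$psnr, psnr(d, r))
  expect_equal(full$ssim, ssim(d, r))

  # identical inside the mask, different outside
  d2 <- d; d2[mask] <- r[mask]
  expect_identical(roi_metrics(d2, r, mask)$psnr, Inf)
  expect_true(is.finite(psnr(d2, r)))

  # changing pixels outside the mask does not alter ROI metrics
  d3 <- d; d3[!mask] <- 99
  expect_equal(roi_metrics(d3, r, mask), roi_metrics(d, r, mask))
  expect_error(roi_metrics(d, r, mask & FALSE), "empty")
})

test_that("ADC maps invert the mono-exponential model", {
  # worked scalar case: s_low = 1, s_high = exp(-0.75), delta-b = 750
  a <- adc_map(matrix(1, 2, 2), matrix(exp(-0.75), 2, 2), 50, 800)
  expect_equal(a$adc[1, 1], 1e-3, tolerance = 1e-12)
  expect_equal(a$delta_b, 750)

  # equal signals give ADC zero; inverted contrast gives negative flagged ADC
  s <- matrix(c(1, 1, 0, 1), 2, 2)
  h <- matrix(c(1, 1.2, 0.5, 0.3), 2, 2)
  a2 <- adc_map(s, h, 50, 800)
  expect_equal(a2$adc[1, 1], 0)
  expect_lt(a2$adc[2, 1], 0)
  expect_true(a2$negative_mask[2, 1])
  expect_false(a2$validity_mask[1, 2])    # zero s_low excluded
  expect_true(is.na(a2$adc[1, 2]))
  expect_error(adc_map(s, h, 800, 800), "b_high")

  # noiseless phantom: pixel-wise recovery of the ground-truth ADC map
  gt <- make_phantom(small_spec())
  low <- simulate_clean(gt, 50); high <- simulate_clean(gt, 800)
  rec <- adc_map(low[, , 1], high[, , 1], 50, 800)
  v <- rec$validity_mask & gt$adc_map[, , 1] > 0
  expect_true(any(v))
  expect_lt(max(abs(rec$adc[v] - gt$adc_map[, , 1][v]) / gt$adc_map[, , 1][v]),
            1e-12)
})

test_that("ROI-mean ADC averages only valid masked pixels", {
  s <- matrix(1, 4, 4); h <- matrix(exp(-0.75), 4, 4)
  h[2, 2] <- exp(-1.5)   # ADC 2e-3 at one pixel
  s[3, 3] <- 0           # invalid pixel
  a <- adc_map(s, h, 50, 800)
  mask <- matrix(TRUE, 4, 4)
  expect_equal(roi_mean_adc(a, mask), mean(a$adc[a$validity_mask]))
  one <- matrix(FALSE, 4, 4); one[2, 2] <- TRUE
  expect_equal(roi_mean_adc(a, one), 2e-3, tolerance = 1e-12)
  uni <- matrix(FALSE, 4, 4); uni[1, ] <- TRUE
  expect_equal(roi_mean_adc(a, uni), 1e-3, tolerance = 1e-12)
  inv <- matrix(FALSE, 4, 4); inv[3, 3] <- TRUE
  expect_error(roi_mean_adc(a, inv), "validity")
})

test_that("series evaluation reports per-slice metrics and ADC summaries", {
  ds <- make_dataset(small_spec(n_slices = 2, noise_sigma = 0.05), 1, seed = 21)
  ser <- normalize_series(ds$subjects[[1]])

  # denoised = reference: SSIM 1 and infinite PSNR in the denoised rows
  rep1 <- evaluate_series(ser, denoised = list("1" = ser$reference), nex = "1")
  den_rows <- rep1$slices[rep1$slices$image == "denoised", ]
  expect_true(all(den_rows$psnr_global == Inf))
  expect_equal(den_rows$ssim_global, rep(1, 2), tolerance = 1e-6)
  expect_equal(nrow(rep1$slices), 2 * 2)   # 2 images x 2 slices for one NEX

  # denoised = noisy: both image rows identical
  rep2 <- evaluate_series(ser, denoised = list("1" = ser$noisy[["1"]]), nex = "1")
  noisy_rows <- rep2$slices[rep2$slices$image == "noisy", -3]
  den_rows2 <- rep2$slices[rep2$slices$image == "denoised", -3]
  rownames(noisy_rows) <- rownames(den_rows2) <- NULL
  expect_equal(noisy_rows, den_rows2)

  # full report: (#NEX x #images x #slices) slice rows and aggregate rows
  rep3 <- evaluate_series(ser, nex = c("1", "2", "4"))
  expect_equal(nrow(rep3$slices), 3 * 1 * 2)
  expect_equal(nrow(rep3$summary), 3)
  expect_equal(nrow(rep3$adc), 3)
  expect_true(all(is.finite(rep3$adc$adc_noisy)))

  dir <- withr::local_tempdir()
  paths <- write_quality_report(rep3, file.path(dir, "report"))
  expect_true(all(file.exists(file.path(dir, c("report_slices.csv",
                                               "report_summary.csv",
                                               "report_adc.csv")))))
})

test_that("PSNR strictly decreases as reference noise grows", {
  set.seed(6)
  r <- matrix(runif(64 * 64, 0, 1), 64, 64)
  sigmas <- c(0.02, 0.05, 0.1)
  mean_psnr <- vapply(sigmas, function(s) {
    mean(vapply(1:20, function(i) {
      psnr(r + matrix(rnorm(64 * 64, sd = s), 64, 64), r)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_psnr) < 0))
})

test_that("signed ROI-mean ADC bias decreases monotonically with NEX", {
  spec <- phantom_spec(n_slices = 2, seed = 2)
  ds <- make_dataset(spec, 2, seed = 31)
  adc_at <- function(ser, nex_img) {
    roi <- dilate_mask(ser$gt$roi_mask, 3)
    roi_mean_adc(adc_map(ser$guide, nex_img, spec$b_low, spec$b_high), roi)
  }
  # average the signed ROI-mean ADC over subjects at NEX 1, 4 and 16
  vals <- vapply(c("1", "4", "16"), function(k) {
    mean(vapply(ds$subjects, function(ser) {
      img <- if (k == "16") ser$reference else ser$noisy[[k]]
      adc_at(ser, img)
    }, numeric(1)))
  }, numeric(1))
  # Jensen's inequality on the log of the averaged magnitude: the upward
  # variance term shrinks as 1/NEX, so the estimate decreases with NEX
  expect_true(all(diff(vals) < 0))
})
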