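#' Peak signal-to-noise ratio
#'
#' The default (`variant = "asprinted"`) evaluates
#' `10 * log10(d_max / MSE)` with `d_max` the peak intensity of `d` and MSE
#' the mean squared difference - the exact form used throughout this
#' package's evaluation tables. Note the numerator is `d_max`, not the
#' conventional `d_max^2`; on unit-normalized images with tiny MSE this
#' yields the characteristic 80+ dB range. `variant = "standard"` computes
#' the textbook `10 * log10(d_max^2 / MSE)` for cross-checks.
#'
#' @param d noisy or denoised image (the image under test).
#' @param r reference image, same shape.
#' @param mask optional logical mask restricting the computation.
#' @param variant `"asprinted"` (default) or `"standard"`.
#' @return PSNR in dB; `Inf` when the images are identical on the mask.
#' @export
psnr <- function(d, r, mask = NULL, variant = c("asprinted", "standard")) {
  variant <- match.arg(variant)
  if (!identical(dim(d), dim(r)))
    abort_validation("d and r must have identical dimensions", "d")
  if (!is.null(mask)) {
    if (!any(mask)) abort_validation("mask is empty", "mask")
    d <- d[mask]; r <- r[mask]
  }
  mse <- mean((d - r)^2)
  if (mse == 0) return(Inf)
  dmax <- max(d)
  if (variant == "standard") dmax <- dmax^2
  10 * log10(dmax / mse)
}

#' Structural similarity (single global window)
#'
#' The default (`variant = "asprinted"`) is the product of three comparison
#' functions computed once over the whole image (or mask):
#' luminance `I = 2*mu_d*mu_r / (mu_d^2 + mu_r^2)`,
#' contrast `C = 2*sd_d*sd_r / (sd_d^2 + sd_r^2)` and
#' structure `S = cov_dr / (sd_d*sd_r)`, each denominator stabilised by a
#' small `eps` (default 1e-12). There is no local windowing and no C1/C2/C3
#' regularisation constants. Standard deviations and the covariance use the
#' n-1 (sample) convention. `variant = "standard"` adds the conventional
#' regularisation constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`,
#' `C3 = C2 / 2` (with `L` the reference dynamic range), still as a single
#' global window, for cross-checks.
#'
#' @param d,r images of identical shape.
#' @param mask optional logical mask.
#' @param eps stabilising constant added to each denominator.
#' @param variant `"asprinted"` (default) or `"standard"`.
#' @return SSIM value (in `[-1, 1]` for nondegenerate inputs).
#' @export
ssim <- function(d, r, mask = NULL, eps = 1e-12,
                 variant = c("asprinted", "standard")) {
  variant <- match.arg(variant)
  if (!identical(dim(d), dim(r)))
    abort_validation("d and r must have identical dimensions", "d")
  if (!is.null(mask)) {
    if (!any(mask)) abort_validation("mask is empty", "mask")
    d <- d[mask]; r <- r[mask]
  }
  d <- as.numeric(d); r <- as.numeric(r)
  mu_d <- mean(d); mu_r <- mean(r)
  sd_d <- sd(d); sd_r <- sd(r)
  cov_dr <- if (length(d) > 1) stats::cov(d, r) else 0
  if (variant == "standard") {
    L <- diff(range(r))
    c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2; c3 <- c2 / 2
    I <- (2 * mu_d * mu_r + c1) / (mu_d^2 + mu_r^2 + c1)
    C <- (2 * sd_d * sd_r + c2) / (sd_d^2 + sd_r^2 + c2)
    S <- (cov_dr + c3) / (sd_d * sd_r + c3)
    return(I * C * S)
  }
  if ((sd_d == 0 || sd_r == 0 || (mu_d == 0 && mu_r == 0)) && eps == 0)
    abort_validation("degenerate input: zero variance or zero means", "d")
  I <- 2 * mu_d * mu_r / (mu_d^2 + mu_r^2 + eps)
  C <- 2 * sd_d * sd_r / (sd_d^2 + sd_r^2 + eps)
  S <- cov_dr / (sd_d * sd_r + eps)
  I * C * S
}

#' ROI-restricted PSNR and SSIM
#'
#' Computes both metrics over masked pixels only; the PSNR peak is taken
#' over the mask. Values are unaffected by pixels outside the mask.
#'
#' @param d,r images of identical shape.
#' @param mask nonempty logical mask.
#' @return list with `psnr` and `ssim`.
#' @export
roi_metrics <- function(d, r, mask) {
  if (!any(mask)) abort_validation("mask is empty", "mask")
  list(psnr = psnr(d, r, mask = mask), ssim = ssim(d, r, mask = mask))
}

#' Pixel-wise ADC map from two diffusion weightings
#'
#' Apparent diffusion coefficient under the mono-exponential decay model:
#' `ADC = -(1/db) * log(s_high / s_low)` with `db = b_high - b_low`.
#' Pixels where either signal is at or below `eps_frac * max(s_low)` are
#' excluded via the validity mask (the log ratio is unstable there).
#' Negative ADC values - possible under noise when the high b-value signal
#' exceeds the low b-value signal - are retained and flagged, not clamped.
#'
#' @param s_low low b-value signal image.
#' @param s_high high b-value signal image, same shape and same units.
#' @param b_low,b_high diffusion weightings in s/mm^2 (`b_high > b_low`).
#' @param eps_frac exclusion threshold as a fraction of `max(s_low)`.
#' @return object of class `adc_map`: list with `adc` (mm^2/s, `NA` outside
#'   the validity mask), `delta_b`, `validity_mask` and `negative_mask`.
#' @export
adc_map <- function(s_low, s_high, b_low, b_high, eps_frac = 1e-6) {
  if (b_high <= b_low) abort_validation("b_high must exceed b_low", "b_high")
  if (!identical(dim(s_low), dim(s_high)))
    abort_validation("s_low and s_high must have identical dimensions", "s_high")
  db <- b_high - b_low
  eps <- eps_frac * max(s_low)
  valid <- s_low > eps & s_high > eps
  adc <- array(NA_real_, dim(s_low) %||% length(s_low))
  adc[valid] <- -log(s_high[valid] / s_low[valid]) / db
  structure(list(adc = adc, delta_b = db, validity_mask = valid,
                 negative_mask = valid & !is.na(adc) & adc < 0),
            class = "adc_map")
}

#' Mean ADC over a region of interest
#'
#' Arithmetic mean of the ADC over the intersection of the ROI with the
#' map's validity mask; invalid pixels inside the ROI are excluded.
#'
#' @param adc an `adc_map`.
#' @param mask logical ROI mask.
#' @return mean ADC in mm^2/s.
#' @export
roi_mean_adc <- function(adc, mask) {
  sel <- mask & adc$validity_mask
  if (!any(sel)) abort_validation("ROI does not intersect the validity mask", "mask")
  mean(adc$adc[sel])
}

#' Quality report for a series and its denoised volumes
#'
#' Per-NEX, per-slice PSNR and SSIM (global and ROI-restricted) of the noisy
#' and the denoised volume against the reference, plus ROI-mean ADC per NEX.
#' Metrics are computed per slice and then aggregated as mean and sd across
#' slices. ADC uses de-normalized intensities (the stored normalization
#' scales are undone) so the signal ratio between b-values is physical.
#'
#' @param series a `dwi_series`.
#' @param denoised named list (by NEX, e.g. `"1"`) of denoised volumes in the
#'   same normalized units as `series$noisy`; may be `NULL` to report the
#'   noisy series only.
#' @param roi_mask logical mask (slice-matched array); default: the series'
#'   ground-truth rectum mask dilated by `roi_dilate` pixels.
#' @param nex NEX values to report (default: those present).
#' @param roi_dilate dilation radius in pixels for the default ROI.
#' @return list of class `quality_report` with `slices` (per-slice
#'   data.frame), `summary` (mean/sd aggregate) and `adc` (per-NEX ROI-mean
#'   ADC data.frame, in 1e-3 mm^2/s as conventionally tabulated).
#' @export
evaluate_series <- function(series, denoised = NULL, roi_mask = NULL,
                            nex = names(series$noisy), roi_dilate = 3) {
  if (is.null(roi_mask)) {
    if (is.null(series$gt))
      abort_validation("no roi_mask given and series carries no ground truth",
                       "roi_mask")
    roi_mask <- dilate_mask(series$gt$roi_mask, roi_dilate)
  }
  d <- dim(series$reference)
  rows <- list(); i <- 0L
  for (k in as.character(nex)) {
    vols <- list(noisy = series$noisy[[k]])
    if (!is.null(denoised[[k]])) vols$denoised <- denoised[[k]]
    for (nm in names(vols)) {
      for (s in seq_len(d[3])) {
        x <- vols[[nm]][, , s]; r <- series$reference[, , s]; m <- roi_mask[, , s]
        i <- i + 1L
        rows[[i]] <- data.frame(
          subject = series$subject_id, nex = as.integer(k), image = nm,
          slice = s,
          psnr_global = psnr(x, r), psnr_roi = psnr(x, r, mask = m),
          ssim_global = ssim(x, r), ssim_roi = ssim(x, r, mask = m),
          stringsAsFactors = FALSE)
      }
    }
  }
  slices <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(slices, list(slices$nex, slices$image),
                                     drop = TRUE), function(g) {
    data.frame(subject = g$subject[1], nex = g$nex[1], image = g$image[1],
               psnr_global_mean = mean(g$psnr_global), psnr_global_sd = sd(g$psnr_global),
               psnr_roi_mean = mean(g$psnr_roi), psnr_roi_sd = sd(g$psnr_roi),
               ssim_global_mean = mean(g$ssim_global), ssim_global_sd = sd(g$ssim_global),
               ssim_roi_mean = mean(g$ssim_roi), ssim_roi_sd = sd(g$ssim_roi),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL

  # ADC in raw units: undo normalization scales
  guide_raw <- series$guide * series$norm_scale_guide
  adc_rows <- list(); j <- 0L
  ref_raw <- series$reference * series$norm_scale_highb
  adc_ref <- adc_map(guide_raw, ref_raw, series$b_low, series$b_high)
  adc_true <- if (!is.null(series$gt)) {
    mean(series$gt$adc_map[roi_mask & series$gt$adc_map > 0])
  } else NA_real_
  for (k in as.character(nex)) {
    j <- j + 1L
    noisy_raw <- series$noisy[[k]] * series$norm_scale_highb
    a_noisy <- roi_mean_adc(adc_map(guide_raw, noisy_raw,
                                    series$b_low, series$b_high), roi_mask)
    a_den <- if (!is.null(denoised[[k]])) {
      den_raw <- denoised[[k]] * series$norm_scale_highb
      roi_mean_adc(adc_map(guide_raw, den_raw, series$b_low, series$b_high),
                   roi_mask)
    } else NA_real_
    adc_rows[[j]] <- data.frame(
      subject = series$subject_id, nex = as.integer(k),
      adc_noisy = a_noisy * 1e3, adc_denoised = a_den * 1e3,
      adc_reference = roi_mean_adc(adc_ref, roi_mask) * 1e3,
      adc_truth = adc_true * 1e3, stringsAsFactors = FALSE)
  }
  structure(list(slices = slices, summary = agg,
                 adc = do.call(rbind, adc_rows)),
            class = "quality_report")
}

#' Serialize a quality report to CSV
#'
#' Writes the per-slice table, the aggregate table and the ADC table as
#' three CSV files sharing a common prefix.
#'
#' @param report a `quality_report`.
#' @param prefix file-path prefix; `<prefix>_slices.csv`,
#'   `<prefix>_summary.csv` and `<prefix>_adc.csv` are written.
#' @return the three paths, invisibly.
#' @export
write_quality_report <- function(report, prefix) {
  paths <- paste0(prefix, c("_slices.csv", "_summary.csv", "_adc.csv"))
  tables <- list(report$slices, report$summary, report$adc)
  for (i in 1:3) {
    write_atomic(paths[i], function(tmp) write.csv(tables[[i]], tmp, row.names = FALSE))
  }
  invisible(paths)
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  print(x$summary, digits = 4)
  cat("\nROI mean ADC (1e-3 mm^2/s):\n")
  print(x$adc, digits = 4)
  invisible(x)
}
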