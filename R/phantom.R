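#' Default tissue set for the rectal DWI phantom
#'
#' A pelvis-like disk containing an off-centre rectum modelled as a
#' fluid-filled lumen surrounded by two concentric wall layers with distinct
#' proton-density signal (S0) and diffusivity (ADC), so that wall-layer
#' delineation is a measurable feature of a denoised image. Later entries
#' overwrite earlier ones where shapes overlap. ADC values are typical
#' body-tissue diffusivities in mm^2/s; S0 is in arbitrary units with the
#' brightest tissue (inner wall) at 1.
#'
#' @param matrix_size in-plane matrix size used to scale the body outline.
#' @return list of tissue definitions (`label`, `shape`, `s0`, `adc`).
#' @export
default_tissues <- function(matrix_size = 140) {
  r_body <- 0.44 * matrix_size
  off <- c(0.11 * matrix_size, 0)  # rectum sits below the image centre
  list(
    list(label = "body", shape = list(type = "disk", center = c(0, 0), r = r_body),
         s0 = 0.55, adc = 1.5e-3),
    list(label = "lumen", shape = list(type = "disk", center = off, r = 8),
         s0 = 0.85, adc = 2.6e-3),
    list(label = "wall_inner", shape = list(type = "annulus", center = off,
                                            r_inner = 8, r_outer = 12),
         s0 = 1.0, adc = 1.1e-3),
    list(label = "wall_outer", shape = list(type = "annulus", center = off,
                                            r_inner = 12, r_outer = 16),
         s0 = 0.7, adc = 1.6e-3)
  )
}

#' Phantom specification
#'
#' Describes a synthetic multi-NEX rectal DWI acquisition: in-plane geometry,
#' per-tissue signal model, the two diffusion weightings, per-excitation noise
#' level and repetition counts. The defaults mirror a clinical rectal DWI
#' protocol: 140 x 140 in-plane matrix, b = 50 / 800 s/mm^2, a low b-value
#' guide averaged over 4 excitations and a high b-value reference averaged
#' over 16. `noise_sigma` is the standard deviation of each complex channel
#' of the per-excitation noise, in the same arbitrary units as S0; the default
#' puts the single-excitation SNR of the rectal wall at high b-value in the
#' 5-10 range, i.e. visibly noisy.
#'
#' @param matrix_size pixels per in-plane axis (>= 64).
#' @param n_slices number of slices.
#' @param tissues list of tissue definitions, see [default_tissues()].
#' @param rectum_roi character vector of tissue labels that form the
#'   rectum ROI (by default the two wall layers, i.e. the wall annulus).
#' @param noise_sigma per-excitation complex-channel noise sd.
#' @param b_low,b_high diffusion weightings in s/mm^2 (`b_high > b_low`).
#' @param nex_low repetitions averaged into the guide.
#' @param nex_high_reference repetitions averaged into the reference.
#' @param nex_noisy accelerated repetition counts for the noisy series.
#' @param noise_model `"rician"` (magnitude of complex Gaussian, the physical
#'   model for magnitude MRI) or `"gaussian"` (additive, for analytic tests).
#' @param slice_thickness,slice_gap slice geometry metadata in mm (recorded in
#'   output headers only; the simulation is 2-D slice-wise).
#' @param gas_warp_amplitude optional per-repetition smooth geometric warp of
#'   the rectal region, in pixels of peak displacement; `0` (default) disables
#'   it. Emulates gas-induced distortion for qualitative robustness demos.
#' @param seed integer seed controlling geometry jitter and noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 140, n_slices = 3,
                         tissues = default_tissues(matrix_size),
                         rectum_roi = c("wall_inner", "wall_outer"),
                         noise_sigma = 0.05,
                         b_low = 50, b_high = 800,
                         nex_low = 4, nex_high_reference = 16,
                         nex_noisy = c(1L, 2L, 4L),
                         noise_model = c("rician", "gaussian"),
                         slice_thickness = 5, slice_gap = 1,
                         gas_warp_amplitude = 0,
                         seed = 1L) {
  spec <- list(
    matrix_size = as.integer(matrix_size), n_slices = as.integer(n_slices),
    tissues = tissues, rectum_roi = rectum_roi,
    noise_sigma = noise_sigma, b_low = b_low, b_high = b_high,
    nex_low = as.integer(nex_low),
    nex_high_reference = as.integer(nex_high_reference),
    nex_noisy = as.integer(nex_noisy),
    noise_model = match.arg(noise_model),
    slice_thickness = slice_thickness, slice_gap = slice_gap,
    gas_warp_amplitude = gas_warp_amplitude,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$matrix_size < 64)
    abort_validation("matrix_size must be >= 64", "matrix_size")
  if (spec$n_slices < 1)
    abort_validation("n_slices must be >= 1", "n_slices")
  if (spec$noise_sigma < 0)
    abort_validation("noise_sigma must be >= 0", "noise_sigma")
  if (spec$b_high <= spec$b_low)
    abort_validation("b_high must exceed b_low", "b_high")
  labels <- vapply(spec$tissues, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    abort_validation("tissue labels must be distinct", "tissues")
  adcs <- vapply(spec$tissues, `[[`, numeric(1), "adc")
  if (any(adcs < 0))
    abort_validation("all tissue ADC values must be >= 0", "tissues")
  if (!all(spec$rectum_roi %in% labels))
    abort_validation("rectum_roi labels not present among tissues", "rectum_roi")
  if (spec$nex_high_reference < max(spec$nex_noisy))
    abort_validation("nex_high_reference must cover the largest noisy NEX",
                     "nex_high_reference")
  invisible(spec)
}

# Rasterise one shape on the pixel grid; pixel centres at integer coordinates,
# image centre at (size+1)/2. `jitter` shifts the shape centre and scales radii.
shape_mask <- function(shape, size, jitter = NULL) {
  ctr <- (size + 1) / 2
  offs <- shape$center + (jitter$center_offset %||% c(0, 0))
  scl <- jitter$radius_scale %||% 1
  rr <- matrix(seq_len(size), size, size) - ctr - offs[1]
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr - offs[2]
  d2 <- rr^2 + cc^2
  switch(shape$type,
    disk = d2 < (shape$r * scl)^2,
    annulus = d2 >= (shape$r_inner * scl)^2 & d2 < (shape$r_outer * scl)^2,
    abort_validation(paste("unknown shape type:", shape$type), "tissues")
  )
}

#' Build ground-truth maps from a phantom specification
#'
#' Paints the tissue shapes onto per-slice S0 and ADC maps, together with the
#' label map and the rectum ROI mask (union of the `rectum_roi` tissue
#' labels). The output is deterministic given the spec; subject-level geometry
#' jitter (used by [make_dataset()]) enters through `jitter`. Slices differ by
#' a mild deterministic taper of the rectum radii to mimic anatomy changing
#' along the organ.
#'
#' @param spec a [phantom_spec()].
#' @param jitter optional list with `center_offset` (length-2, pixels) and
#'   `radius_scale` (scalar) applied to the rectum shapes.
#' @return object of class `phantom_gt` with fields `s0_map`, `adc_map`,
#'   `roi_mask`, `label_map` (arrays `matrix_size x matrix_size x n_slices`)
#'   and `spec`.
#' @export
make_phantom <- function(spec, jitter = NULL) {
  validate_phantom_spec(spec)
  n <- spec$matrix_size; S <- spec$n_slices
  s0 <- array(0, c(n, n, S)); adc <- array(0, c(n, n, S))
  lab <- array(0L, c(n, n, S)); roi <- array(FALSE, c(n, n, S))
  labels <- vapply(spec$tissues, `[[`, character(1), "label")
  rectal <- labels %in% c("lumen", spec$rectum_roi)
  mid <- (S + 1) / 2
  for (s in seq_len(S)) {
    # rectum radii taper by up to 5% away from the central slice
    taper <- 1 - 0.05 * abs(s - mid) / max(1, mid - 1)
    for (t in seq_along(spec$tissues)) {
      tis <- spec$tissues[[t]]
      jit <- if (rectal[t]) {
        list(center_offset = jitter$center_offset %||% c(0, 0),
             radius_scale = (jitter$radius_scale %||% 1) * taper)
      } else NULL
      m <- shape_mask(tis$shape, n, jit)
      s0[, , s][m] <- tis$s0
      adc[, , s][m] <- tis$adc
      lab[, , s][m] <- t
      if (tis$label %in% spec$rectum_roi) roi[, , s][m] <- TRUE
    }
    # overwriting by later tissues removes earlier ROI membership
    roi[, , s] <- roi[, , s] & (matrix(labels[pmax(lab[, , s], 1)], n, n) %in%
                                  spec$rectum_roi) & lab[, , s] > 0
  }
  if (!any(roi)) abort_validation("rectum ROI mask is empty", "rectum_roi")
  structure(list(s0_map = s0, adc_map = adc, roi_mask = roi,
                 label_map = lab, spec = spec),
            class = "phantom_gt")
}

#' Noise-free diffusion-weighted signal
#'
#' Evaluates the mono-exponential diffusion decay `S0 * exp(-b * ADC)`
#' pixel-wise for one diffusion weighting.
#'
#' @param gt a `phantom_gt`.
#' @param b diffusion weighting in s/mm^2 (>= 0).
#' @param slice optional slice index; default returns all slices.
#' @return matrix (one slice) or array of clean signal.
#' @export
simulate_clean <- function(gt, b, slice = NULL) {
  if (b < 0) abort_validation("b must be >= 0", "b")
  out <- gt$s0_map * exp(-b * gt$adc_map)
  if (!is.null(slice)) out[, , slice] else out
}

#' Simulate per-excitation magnitude images
#'
#' Each repetition is an independent noisy realisation of the clean image.
#' Under the Rician model (default) a repetition is
#' `sqrt((clean + g1)^2 + g2^2)` with `g1`, `g2` independent zero-mean
#' Gaussian fields of standard deviation `sigma` - the magnitude of a complex
#' Gaussian, the physical noise model of magnitude MRI. The Gaussian option
#' (`clean + g1`) is provided for analytic tests. Fully reproducible from
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param clean clean slice image (matrix) or slice volume.
#' @param sigma per-excitation complex-channel noise sd (>= 0).
#' @param nex number of repetitions to draw (>= 1).
#' @param seed integer seed.
#' @param b_value diffusion weighting recorded in the stack, if known.
#' @param noise_model `"rician"` or `"gaussian"`.
#' @param warp_amplitude optional rectal warp amplitude in pixels; needs
#'   `warp_roi` (logical mask) when positive.
#' @param warp_roi logical mask of the region to warp.
#' @return object of class `repetition_stack`: list with `b_value`,
#'   `repetitions` (list of magnitude images) and `seed_used`.
#' @export
simulate_repetitions <- function(clean, sigma, nex, seed, b_value = NA_real_,
                                 noise_model = c("rician", "gaussian"),
                                 warp_amplitude = 0, warp_roi = NULL) {
  if (sigma < 0) abort_validation("sigma must be >= 0", "sigma")
  if (nex < 1) abort_validation("nex must be >= 1", "nex")
  noise_model <- match.arg(noise_model)
  reps <- with_seed(seed, {
    lapply(seq_len(nex), function(r) {
      src <- clean
      if (warp_amplitude > 0 && !is.null(warp_roi)) {
        src <- warp_image(src, warp_roi, warp_amplitude,
                          phase = stats::runif(1, 0, 2 * pi))
      }
      if (sigma == 0) return(src)
      g1 <- array(rnorm(length(src), sd = sigma), dim = dim(src) %||% length(src))
      if (noise_model == "gaussian") {
        src + g1
      } else {
        g2 <- array(rnorm(length(src), sd = sigma), dim = dim(src) %||% length(src))
        sqrt((src + g1)^2 + g2^2)
      }
    })
  })
  structure(list(b_value = b_value, repetitions = reps, seed_used = as.integer(seed)),
            class = "repetition_stack")
}

# Smooth horizontal displacement of a masked region, bilinear resampling.
# Used only by the optional gas-distortion scenario.
warp_image <- function(img, roi, amplitude, phase = 0) {
  H <- nrow(img); W <- ncol(img)
  idx <- which(roi, arr.ind = TRUE)
  if (nrow(idx) == 0) return(img)
  ctr <- colMeans(idx)
  out <- img
  d <- amplitude * sin(2 * pi * (idx[, 1] - ctr[1]) / max(8, diff(range(idx[, 1]))) + phase)
  sj <- pmin(pmax(idx[, 2] + d, 1), W)
  j0 <- floor(sj); j1 <- pmin(j0 + 1, W); f <- sj - j0
  out[idx] <- (1 - f) * img[cbind(idx[, 1], j0)] + f * img[cbind(idx[, 1], j1)]
  out
}

#' Generate a multi-subject synthetic DWI dataset
#'
#' For each subject the rectum geometry is jittered (seeded per subject), a
#' 16-repetition high b-value stack and an `nex_low`-repetition low b-value
#' stack are simulated per slice, and the series are assembled: the guide is
#' the low-b average, the noisy series at NEX in `spec$nex_noisy` are prefix
#' averages of the *same* 16-repetition stack, and the reference is the full
#' 16-repetition average. Prefix averaging mirrors a single acquisition from
#' which all accelerated images are retrospectively formed, so comparisons
#' across NEX isolate the effect of averaging.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; subject-level streams are derived from it.
#' @return object of class `dwi_dataset`: list with `subjects` (list of
#'   `dwi_series`), `spec` and `seed`.
#' @export
make_dataset <- function(spec, n_subjects, seed = spec$seed) {
  validate_phantom_spec(spec)
  if (n_subjects < 1) abort_validation("n_subjects must be >= 1", "n_subjects")
  subjects <- lapply(seq_len(n_subjects), function(sub) {
    sseed <- derive_seed(seed, sub)
    jit <- with_seed(sseed, list(
      center_offset = round(stats::runif(2, -4, 4)),
      radius_scale = stats::runif(1, 0.92, 1.08)
    ))
    gt <- make_phantom(spec, jitter = jit)
    n <- spec$matrix_size; S <- spec$n_slices
    guide <- array(0, c(n, n, S)); reference <- array(0, c(n, n, S))
    noisy <- lapply(spec$nex_noisy, function(k) array(0, c(n, n, S)))
    names(noisy) <- as.character(spec$nex_noisy)
    for (s in seq_len(S)) {
      clean_low <- simulate_clean(gt, spec$b_low, slice = s)
      clean_high <- simulate_clean(gt, spec$b_high, slice = s)
      warp_roi <- if (spec$gas_warp_amplitude > 0) {
        gt$roi_mask[, , s] | gt$label_map[, , s] %in%
          which(vapply(spec$tissues, `[[`, character(1), "label") == "lumen")
      } else NULL
      low_stack <- simulate_repetitions(
        clean_low, spec$noise_sigma, spec$nex_low, derive_seed(sseed, s, 1),
        b_value = spec$b_low, noise_model = spec$noise_model)
      high_stack <- simulate_repetitions(
        clean_high, spec$noise_sigma, spec$nex_high_reference,
        derive_seed(sseed, s, 2), b_value = spec$b_high,
        noise_model = spec$noise_model,
        warp_amplitude = spec$gas_warp_amplitude, warp_roi = warp_roi)
      guide[, , s] <- average_nex(low_stack, spec$nex_low)
      reference[, , s] <- average_nex(high_stack, spec$nex_high_reference)
      for (k in spec$nex_noisy) {
        noisy[[as.character(k)]][, , s] <- average_nex(high_stack, k)
      }
    }
    structure(list(
      subject_id = sprintf("sub-%03d", sub),
      guide = guide, noisy = noisy, reference = reference,
      b_low = spec$b_low, b_high = spec$b_high,
      nex_low = spec$nex_low, nex_reference = spec$nex_high_reference,
      norm_scale_highb = 1, norm_scale_guide = 1, normalized = FALSE,
      gt = gt, seed_used = sseed
    ), class = "dwi_series")
  })
  structure(list(subjects = subjects, spec = spec, seed = as.integer(seed)),
            class = "dwi_dataset")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d, %d slices, b = %g/%g s/mm^2, sigma = %g (%s), NEX guide %d / ref %d\n",
              x$matrix_size, x$matrix_size, x$n_slices, x$b_low, x$b_high,
              x$noise_sigma, x$noise_model, x$nex_low, x$nex_high_reference))
  invisible(x)
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$reference)
  cat(sprintf("<dwi_series> %s: %dx%dx%d, noisy NEX {%s}, normalized = %s\n",
              x$subject_id, d[1], d[2], d[3],
              paste(names(x$noisy), collapse = ","), x$normalized))
  invisible(x)
}
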