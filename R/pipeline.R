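#' Average the first n repetitions of a stack
#'
#' Pixel-wise arithmetic mean of the first `n` magnitude images of a
#' repetition stack. Averaging the common prefix is how the accelerated
#' (NEX = 1, 2, 4) and reference (NEX = 16) images are all formed from a
#' single simulated acquisition.
#'
#' @param stack a `repetition_stack` from [simulate_repetitions()].
#' @param n number of leading repetitions to average.
#' @return slice image (same shape as one repetition).
#' @export
average_nex <- function(stack, n) {
  if (n < 1 || n > length(stack$repetitions))
    abort_validation(sprintf("n = %d outside 1..%d repetitions", n,
                             length(stack$repetitions)), "n")
  out <- stack$repetitions[[1]]
  if (n > 1) for (r in 2:n) out <- out + stack$repetitions[[r]]
  out / n
}

#' Training-time series normalization
#'
#' Divides the noisy and reference volumes by the global maximum of the
#' reference (over all slices), and the guide by its own global maximum, so
#' that after normalization the reference and guide both peak at 1. The
#' noisy volumes may exceed 1 where their maxima exceed the reference maximum;
#' no clipping is applied. The applied divisors accumulate in
#' `norm_scale_highb` / `norm_scale_guide` so intensities can be restored;
#' applying the function twice is therefore the identity.
#'
#' @param series a `dwi_series`.
#' @return the normalized `dwi_series`.
#' @export
normalize_series <- function(series) {
  ref_max <- max(series$reference)
  guide_max <- max(series$guide)
  if (ref_max <= 0) abort_validation("reference volume is all zero", "reference")
  if (guide_max <= 0) abort_validation("guide volume is all zero", "guide")
  series$reference <- series$reference / ref_max
  series$noisy <- lapply(series$noisy, function(v) v / ref_max)
  series$guide <- series$guide / guide_max
  series$norm_scale_highb <- series$norm_scale_highb * ref_max
  series$norm_scale_guide <- series$norm_scale_guide * guide_max
  series$normalized <- TRUE
  series
}

#' Inference-time normalization
#'
#' At deployment there is no reference acquisition, so the noisy volume is
#' divided by its own global maximum (and the guide by its own), returning
#' the scales needed to restore the denoised output to input units.
#'
#' @param noisy,guide volumes with positive maxima.
#' @return list with `noisy`, `guide`, `scale_noisy`, `scale_guide`.
#' @export
normalize_for_inference <- function(noisy, guide) {
  mn <- max(noisy); mg <- max(guide)
  if (mn <= 0) abort_validation("noisy volume is all zero", "noisy")
  if (mg <= 0) abort_validation("guide volume is all zero", "guide")
  list(noisy = noisy / mn, guide = guide / mg,
       scale_noisy = mn, scale_guide = mg)
}

# Patch grid positions along one axis: regular stride, with the final
# position clamped to the border so the full extent is always covered.
patch_positions <- function(extent, size, stride) {
  last <- extent - size + 1
  pos <- seq(1, last, by = stride)
  if (pos[length(pos)] != last) pos <- c(pos, last)
  pos
}

#' Extract co-located guide/noisy/reference patch triples
#'
#' Cuts a regular grid of square patches from every slice of a series, with
#' identical coordinates in the guide, the selected noisy volume and the
#' reference. The last row/column of the grid is clamped to the image border
#' so every pixel is covered for any stride.
#'
#' @param series a (typically normalized) `dwi_series`.
#' @param nex which noisy series to cut from (must be a name of
#'   `series$noisy`).
#' @param size patch side in pixels (default 60).
#' @param stride grid step in pixels (default 20, overlapping).
#' @return list of `patch_triple` objects, each with `guide_patch`,
#'   `noisy_patch`, `reference_patch`, `origin = c(slice, row, col)`
#'   (1-based top-left corner) and `augmentation_id = 0`.
#' @export
extract_patches <- function(series, nex, size = 60, stride = 20) {
  noisy <- series$noisy[[as.character(nex)]]
  if (is.null(noisy))
    abort_validation(sprintf("no noisy series at NEX = %s", nex), "nex")
  d <- dim(series$reference)
  if (size > d[1] || size > d[2])
    abort_validation("patch size exceeds image size", "size")
  if (stride < 1) abort_validation("stride must be >= 1", "stride")
  rows <- patch_positions(d[1], size, stride)
  cols <- patch_positions(d[2], size, stride)
  out <- vector("list", d[3] * length(rows) * length(cols))
  i <- 0L
  for (s in seq_len(d[3])) {
    for (r in rows) {
      for (cc in cols) {
        i <- i + 1L
        ri <- r:(r + size - 1); ci <- cc:(cc + size - 1)
        out[[i]] <- structure(list(
          guide_patch = series$guide[ri, ci, s],
          noisy_patch = noisy[ri, ci, s],
          reference_patch = series$reference[ri, ci, s],
          origin = c(slice = s, row = r, col = cc),
          augmentation_id = 0L
        ), class = "patch_triple")
      }
    }
  }
  out
}

#' Apply one of the eight square symmetries to a matrix
#'
#' `op_id` enumerates the dihedral group of the square: `op_id %% 4`
#' counter-clockwise quarter-turns, preceded by a horizontal (left-right)
#' flip when `op_id >= 4`.
#'
#' @param m matrix.
#' @param op_id integer in 0..7.
#' @return transformed matrix.
#' @export
dihedral_op <- function(m, op_id) {
  if (op_id < 0 || op_id > 7) abort_validation("op_id must be in 0..7", "op_id")
  if (op_id >= 4) m <- m[, ncol(m):1, drop = FALSE]
  r <- op_id %% 4
  for (k in seq_len(r)) m <- t(m)[nrow(t(m)):1, , drop = FALSE]
  m
}

#' Augment a patch triple
#'
#' Applies the same dihedral symmetry to the guide, noisy and reference
#' patches, preserving their co-location; training draws `op_id` uniformly
#' per patch per epoch.
#'
#' @param triple a `patch_triple`.
#' @param op_id integer in 0..7 ([dihedral_op()] numbering).
#' @return the augmented `patch_triple` (with `augmentation_id` set).
#' @export
augment <- function(triple, op_id) {
  if (op_id < 0 || op_id > 7) abort_validation("op_id must be in 0..7", "op_id")
  triple$guide_patch <- dihedral_op(triple$guide_patch, op_id)
  triple$noisy_patch <- dihedral_op(triple$noisy_patch, op_id)
  triple$reference_patch <- dihedral_op(triple$reference_patch, op_id)
  triple$augmentation_id <- as.integer(op_id)
  triple
}

#' Read a 3-D NIfTI volume
#'
#' @param path file path.
#' @param expect_3d raise a shape error unless the volume is 3-D (a 2-D slice
#'   is promoted to a single-slice volume).
#' @return numeric array with attribute `pixdim` (voxel sizes in mm).
#' @export
read_dwi_nifti <- function(path, expect_3d = TRUE) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (expect_3d) {
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
    if (length(dim(arr)) != 3)
      stop(sprintf("expected a 3-D volume in %s but found %d dimensions",
                   path, length(dim(arr))))
  }
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' Write a volume as 32-bit float NIfTI
#'
#' Slices are stacked on the third axis. Written atomically (temporary file
#' plus rename).
#'
#' @param volume 2-D or 3-D numeric array.
#' @param path destination (`.nii` or `.nii.gz`).
#' @param pixdim voxel sizes in mm; defaults to in-plane 1 mm with the slice
#'   pitch (thickness + gap) on the third axis.
#' @return the path, invisibly.
#' @export
write_dwi_nifti <- function(volume, path, pixdim = c(1, 1, 6)) {
  arr <- volume
  if (length(dim(arr) %||% 0) == 2) dim(arr) <- c(dim(arr), 1)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdim[seq_along(dim(arr))]
  # temp name keeps the extension so writeNifti picks the right compression
  tmpfile <- file.path(dirname(path),
                       paste0(".tmp", Sys.getpid(), "-", basename(path)))
  on.exit(if (file.exists(tmpfile)) unlink(tmpfile), add = TRUE)
  RNifti::writeNifti(img, tmpfile, datatype = "float")
  if (!file.rename(tmpfile, path)) stop("could not write NIfTI file: ", path)
  invisible(path)
}

#' Write / read a JSON sidecar manifest
#'
#' Records the provenance of a dataset directory: spec fields, seeds and
#' normalization scales.
#'
#' @param manifest named list.
#' @param path JSON file path.
#' @return `read_manifest` returns the parsed list.
#' @export
write_manifest <- function(manifest, path) {
  write_atomic(path, function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
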