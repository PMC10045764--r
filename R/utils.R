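`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a validation error
#'
#' Validation failures (bad field values, inconsistent shapes) are raised with
#' the condition class `dwidcnn_validation_error` so callers - in particular
#' the command-line interface - can distinguish them from runtime failures.
#'
#' @param msg message text.
#' @param field name of the offending field, if any.
#' @keywords internal
abort_validation <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("[%s] %s", field, msg)
  stop(structure(
    class = c("dwidcnn_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a reproducible child seed
#'
#' Mixes a base seed with up to three stream indices into a 31-bit integer so
#' that every stochastic sub-task (subject, slice, stack) draws from its own
#' deterministic stream.
#'
#' @param seed base integer seed.
#' @param a,b,c stream indices.
#' @return an integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, a = 0L, b = 0L, c = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + 7919 * as.numeric(a)) %% m
  s <- (s * 48271 + 104729 * as.numeric(b)) %% m
  s <- (s * 48271 + 131071 * as.numeric(c)) %% m
  as.integer(s %% (m - 1) + 1)
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Write a file atomically
#'
#' Writes to a temporary sibling path and renames it into place, so an
#' interrupted run never leaves a truncated file in an output directory.
#'
#' @param path final destination.
#' @param writer function of one argument (the temporary path) that performs
#'   the actual write.
#' @keywords internal
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Binary dilation of a mask with a disk structuring element
#'
#' @param mask logical matrix (or 3-D array, dilated slice-wise).
#' @param radius disk radius in pixels; `0` returns the mask unchanged.
#' @return logical object of the same shape.
#' @export
dilate_mask <- function(mask, radius = 3) {
  if (radius <= 0) return(mask)
  if (length(dim(mask)) == 3) {
    out <- mask
    for (s in seq_len(dim(mask)[3])) out[, , s] <- dilate_mask(mask[, , s], radius)
    return(out)
  }
  m <- as.matrix(mask)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  r <- as.integer(ceiling(radius))
  for (di in -r:r) {
    for (dj in -r:r) {
      if (di * di + dj * dj > radius * radius) next
      si <- max(1, 1 - di):min(H, H - di)
      sj <- max(1, 1 - dj):min(W, W - dj)
      out[si + di, sj + dj] <- out[si + di, sj + dj] | m[si, sj]
    }
  }
  out
}
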