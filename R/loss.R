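#' Loss configuration
#'
#' The training objective is a linear combination of an L2 term (half the
#' sum of squared differences between denoised and reference) and an L1 term
#' (sum of absolute differences) weighted by `lambda_l1`:
#' `L = sum(0.5 * (d - r)^2) + lambda * sum(|d - r|)`.
#' The L1 term counteracts the over-smoothing tendency of a pure L2
#' objective while the L2 term suppresses residual noise; the weight
#' balances the two.
#'
#' @param mode `"joint"` (both terms), `"l2_only"` (L2 term alone,
#'   equivalent to `lambda_l1 = 0`) or `"l1_only"` (the pure L1 sum, with
#'   the weight absorbed).
#' @param lambda_l1 nonnegative L1 weight (default 4, the weight favoured
#'   for the best denoising/smoothing balance).
#' @return object of class `loss_config`.
#' @export
loss_config <- function(mode = c("joint", "l2_only", "l1_only"), lambda_l1 = 4) {
  mode <- match.arg(mode)
  if (lambda_l1 < 0) abort_validation("lambda_l1 must be >= 0", "lambda_l1")
  if (mode == "l2_only") lambda_l1 <- 0
  structure(list(mode = mode, lambda_l1 = lambda_l1), class = "loss_config")
}

#' Joint L1-L2 loss
#'
#' Evaluates the configured objective summed over all pixels of all batch
#' items: `sum(0.5 * e^2) + lambda * sum(|e|)` with `e = d - r` in joint
#' mode; the L2 term alone in `l2_only` mode; the plain `sum(|e|)` in
#' `l1_only` mode. No averaging is applied here - the training loop divides
#' by the batch size so the meaning of `lambda_l1` does not depend on batch
#' size.
#'
#' @param d denoised batch (any numeric array).
#' @param r reference batch of identical shape.
#' @param config a [loss_config()].
#' @return scalar loss.
#' @export
joint_l1_l2_loss <- function(d, r, config = loss_config()) {
  if (!identical(dim(d), dim(r)) || length(d) != length(r))
    abort_validation("d and r must have identical shape", "d")
  e <- d - r
  switch(config$mode,
    joint = sum(0.5 * e^2) + config$lambda_l1 * sum(abs(e)),
    l2_only = sum(0.5 * e^2),
    l1_only = sum(abs(e))
  )
}

# Gradient of the loss with respect to d (same summation convention).
loss_gradient <- function(d, r, config) {
  e <- d - r
  switch(config$mode,
    joint = e + config$lambda_l1 * sign(e),
    l2_only = e,
    l1_only = sign(e)
  )
}
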