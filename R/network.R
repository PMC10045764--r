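#' Network configuration
#'
#' Architecture of the residual denoising network: a first convolution + ReLU
#' layer mapping the two input channels (noisy high b-value image and low
#' b-value guide) to `width` feature maps, `depth - 2` hidden
#' convolution + batch-norm + ReLU layers of `width` maps, and a final linear
#' convolution producing the single-channel residual (the predicted noise).
#' All convolutions are `kernel x kernel` with zero "same" padding, so the
#' network is fully convolutional: any input size at or above the kernel is
#' accepted and preserved. The full-size preset (`preset = "paper"`) is
#' 64 layers of 64 maps; the default is a desk-scale 8-layer, 32-map network
#' suitable for CPU training.
#'
#' @param depth total layer count (>= 3).
#' @param width feature maps per hidden layer (>= 1).
#' @param kernel spatial kernel size (odd).
#' @param in_channels input channels (2: noisy + guide).
#' @param out_channels output channels (1: residual).
#' @param bn_eps batch-norm variance stabiliser.
#' @param bn_momentum retention factor of the running statistics
#'   (`running <- momentum * running + (1 - momentum) * batch`).
#' @param seed seed for weight initialisation.
#' @param preset `"paper"` selects depth 64 / width 64.
#' @return object of class `net_config`.
#' @export
net_config <- function(depth = 8, width = 32, kernel = 3,
                       in_channels = 2, out_channels = 1,
                       bn_eps = 1e-5, bn_momentum = 0.9,
                       seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    if (preset != "paper") abort_validation("unknown preset", "preset")
    depth <- 64; width <- 64; kernel <- 3
  }
  cfg <- list(depth = as.integer(depth), width = as.integer(width),
              kernel = as.integer(kernel),
              in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              bn_eps = bn_eps, bn_momentum = bn_momentum,
              seed = as.integer(seed))
  class(cfg) <- "net_config"
  validate_net_config(cfg)
  cfg
}

validate_net_config <- function(cfg) {
  if (cfg$depth < 3) abort_validation("depth must be >= 3", "depth")
  if (cfg$width < 1) abort_validation("width must be >= 1", "width")
  if (cfg$kernel %% 2 != 1) abort_validation("kernel must be odd", "kernel")
  if (cfg$in_channels < 1) abort_validation("in_channels must be >= 1", "in_channels")
  if (cfg$out_channels < 1) abort_validation("out_channels must be >= 1", "out_channels")
  invisible(cfg)
}

# Per-layer shapes: first and last layers carry a bias and no batch norm
# (a bias preceding batch norm would be absorbed by it); hidden layers use
# batch norm and drop the bias.
layer_plan <- function(cfg) {
  lapply(seq_len(cfg$depth), function(l) {
    first <- l == 1L; last <- l == cfg$depth
    list(cin = if (first) cfg$in_channels else cfg$width,
         cout = if (last) cfg$out_channels else cfg$width,
         bias = first || last, bn = !first && !last, act = !last)
  })
}

#' Build a residual denoising network
#'
#' Allocates and initialises all layer parameters. Convolution weights use
#' Kaiming fan-in scaling (`sd = sqrt(2 / (kernel^2 * cin))`), drawn from a
#' seeded normal stream; biases start at zero, batch-norm scale at one and
#' shift at zero.
#'
#' @param config a [net_config()].
#' @return object of class `dcnn_net`.
#' @export
build_network <- function(config) {
  validate_net_config(config)
  k <- config$kernel
  layers <- with_seed(config$seed, {
    lapply(layer_plan(config), function(p) {
      fan_in <- k * k * p$cin
      l <- list(
        W = matrix(rnorm(fan_in * p$cout, sd = sqrt(2 / fan_in)), fan_in, p$cout),
        cin = p$cin, cout = p$cout, bias = p$bias, bn = p$bn, act = p$act
      )
      if (p$bias) l$b <- numeric(p$cout)
      if (p$bn) {
        l$gamma <- rep(1, p$cout); l$beta <- numeric(p$cout)
        l$running_mean <- numeric(p$cout); l$running_var <- rep(1, p$cout)
      }
      l
    })
  })
  structure(list(config = config, layers = layers), class = "dcnn_net")
}

#' Count convolution weights of a network
#'
#' Sums the sizes of the convolution kernels actually allocated (biases and
#' batch-norm parameters are not included).
#'
#' @param net a `dcnn_net` or a [net_config()].
#' @return integer weight count.
#' @export
count_conv_weights <- function(net) {
  if (inherits(net, "net_config")) net <- build_network(net)
  sum(vapply(net$layers, function(l) length(l$W), numeric(1)))
}

# ---- forward / backward ---------------------------------------------------

# Forward pass. x: H x W x Cin x N array. Returns list(out, cache) where
# cache holds what the backward pass needs; in training mode the running
# batch-norm statistics of `net` are updated (returned as net).
net_forward <- function(net, x, training = FALSE, keep_cache = FALSE) {
  k <- net$config$kernel
  eps <- net$config$bn_eps
  mom <- net$config$bn_momentum
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    z <- .conv2d_forward(x, l$W, if (l$bias) l$b else NULL, k)
    cache <- if (keep_cache) list(x_in = x) else NULL
    if (l$bn) {
      if (training) {
        st <- .bn_stats(z)
        mu <- st$mean; v2 <- st$var
        net$layers[[li]]$running_mean <- mom * l$running_mean + (1 - mom) * mu
        net$layers[[li]]$running_var <- mom * l$running_var + (1 - mom) * v2
      } else {
        mu <- l$running_mean
        v2 <- l$running_var
      }
      inv_sd <- 1 / sqrt(v2 + eps)
      ap <- .bn_apply(z, mu, inv_sd, l$gamma, l$beta, keep_cache)
      z <- ap$y
      if (keep_cache) { cache$xhat <- ap$xhat; cache$inv_sd <- inv_sd }
    }
    if (l$act) {
      if (keep_cache) cache$pre_act <- z
      z <- pmax(z, 0)
    }
    if (keep_cache) caches[[li]] <- cache
    x <- z
  }
  list(out = x, net = net, caches = caches)
}

# Backward pass through the cached forward. g: gradient wrt the output.
# Returns list(grads) parallel to net$layers.
net_backward <- function(net, caches, g) {
  k <- net$config$kernel
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    cache <- caches[[li]]
    if (l$act) g <- g * (cache$pre_act > 0)
    gr <- list()
    if (l$bn) {
      bn <- .bn_backward(g, cache$xhat, l$gamma, cache$inv_sd)
      gr$gamma <- bn$ggamma
      gr$beta <- bn$gbeta
      g <- bn$gz
    }
    bw <- .conv2d_backward(cache$x_in, l$W, g, k, li > 1L, l$bias)
    gr$W <- bw$gw
    if (l$bias) gr$b <- bw$gb
    grads[[li]] <- gr
    g <- bw$gx
  }
  grads
}

#' Predict the noise residual for one slice
#'
#' Runs the network in evaluation mode (batch norm uses its stored running
#' statistics, so repeated calls are deterministic) on the two-channel input
#' formed by the noisy high b-value slice and the low b-value guide. The
#' network is fully convolutional: any spatial size at or above the kernel
#' is accepted, e.g. full slices after patch-based training.
#'
#' @param net a `dcnn_net`.
#' @param noisy,guide matrices of identical shape, in normalized units.
#' @return residual matrix of the same shape.
#' @export
predict_residual <- function(net, noisy, guide) {
  if (!identical(dim(noisy), dim(guide)))
    abort_validation("noisy and guide must have identical dimensions", "guide")
  x <- array(0, c(nrow(noisy), ncol(noisy), 2, 1))
  x[, , 1, 1] <- noisy; x[, , 2, 1] <- guide
  out <- net_forward(net, x, training = FALSE)$out
  out[, , 1, 1]
}

# Batched residual prediction over the slices of a volume.
predict_residual_volume <- function(net, noisy, guide) {
  d <- dim(noisy)
  x <- array(0, c(d[1], d[2], 2, d[3]))
  x[, , 1, ] <- noisy; x[, , 2, ] <- guide
  out <- net_forward(net, x, training = FALSE)$out
  array(out[, , 1, ], d)
}

#' Denoise a volume
#'
#' Subtracts the predicted residual from the noisy volume slice-wise.
#' Negative output pixels are clamped to zero (the images are magnitudes);
#' before clamping the residual identity `denoised + residual = noisy` holds
#' exactly, and the returned `residual` allows its reconstruction.
#'
#' @param net a `dcnn_net`.
#' @param noisy,guide aligned slice volumes in normalized units.
#' @param scale factor that restores input units
#'   (`denoised * scale` is in raw units), recorded in the result.
#' @return object of class `denoised_result` with `denoised` (clamped),
#'   `residual` and `scale`.
#' @export
denoise <- function(net, noisy, guide, scale = 1) {
  if (!identical(dim(noisy), dim(guide)))
    abort_validation("noisy and guide must have identical dimensions", "guide")
  if (length(dim(noisy)) == 2) {
    res <- predict_residual(net, noisy, guide)
  } else {
    res <- predict_residual_volume(net, noisy, guide)
  }
  structure(list(denoised = pmax(noisy - res, 0), residual = res, scale = scale),
            class = "denoised_result")
}

# Denoise every noisy NEX series of a (normalized) dwi_series; returns a
# named list of denoised volumes in normalized units.
denoise_series <- function(net, series) {
  lapply(series$noisy, function(v) denoise(net, v, series$guide)$denoised)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores a format version, the architecture configuration,
#' all layer parameters (including batch-norm running statistics), the
#' normalization convention tag and any extra metadata (e.g. training
#' history), so a saved model can be reloaded and applied reproducibly.
#'
#' @param net a `dcnn_net`.
#' @param path checkpoint file path.
#' @param norm_convention tag describing the intensity convention the model
#'   was trained under.
#' @param extra named list of additional metadata.
#' @return `load_checkpoint` returns a list with `net` and the stored
#'   metadata.
#' @export
save_checkpoint <- function(net, path, norm_convention = "reference_max",
                            extra = list()) {
  obj <- list(format_version = 1L, config = unclass(net$config),
              layers = net$layers, norm_convention = norm_convention,
              extra = extra)
  write_atomic(path, function(tmp) saveRDS(obj, tmp))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L))
    stop("unsupported checkpoint format version: ", obj$format_version)
  cfg <- obj$config; class(cfg) <- "net_config"
  net <- structure(list(config = cfg, layers = obj$layers), class = "dcnn_net")
  list(net = net, norm_convention = obj$norm_convention, extra = obj$extra)
}

#' @export
print.dcnn_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dcnn_net> depth %d, width %d, %dx%d kernels, %d-in/%d-out, %s conv weights\n",
              cfg$depth, cfg$width, cfg$kernel, cfg$kernel,
              cfg$in_channels, cfg$out_channels,
              format(count_conv_weights(x), big.mark = ",")))
  invisible(x)
}
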