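#' Training configuration
#'
#' Schedule and optimisation settings for [train_dcnn()]. The full-scale
#' schedule is 18 epochs with the validation loss evaluated every third
#' epoch; both are configurable for desk-scale runs. The optimiser is Adam
#' (the loss, not the optimiser, is the contract); per-batch losses are sums
#' over pixels divided by the batch size, so `lambda_l1` keeps its meaning
#' across batch sizes.
#'
#' @param epochs training epochs (>= 1; full-scale preset 18).
#' @param batch_size patches per optimisation step.
#' @param learning_rate Adam step size.
#' @param optimizer optimiser name (only `"adam"` is implemented).
#' @param validation_period epochs between validation-loss evaluations
#'   (full-scale preset 3).
#' @param patch_size,patch_stride patch grid passed to [extract_patches()].
#' @param nex_train noisy NEX levels whose patches enter training; mixing
#'   levels trains a single network usable at any of them.
#' @param patches_per_series optional cap on patches kept per (series, NEX),
#'   sampled reproducibly; `NULL` keeps the full grid.
#' @param seed master seed (initialisation stream is taken from the network
#'   config; data order and augmentation from this one).
#' @param checkpoint_dir if set, `last.ckpt` is rewritten after every epoch
#'   so an interrupted run leaves a resumable checkpoint.
#' @param verbose emit one structured log line per epoch to stderr.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 18, batch_size = 32, learning_rate = 1e-3,
                         optimizer = "adam", validation_period = 3,
                         patch_size = 60, patch_stride = 20,
                         nex_train = c(1, 2, 4), patches_per_series = NULL,
                         seed = 1L, checkpoint_dir = NULL, verbose = FALSE) {
  if (epochs < 1) abort_validation("epochs must be >= 1", "epochs")
  if (validation_period < 1)
    abort_validation("validation_period must be >= 1", "validation_period")
  if (optimizer != "adam") abort_validation("unknown optimizer", "optimizer")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 validation_period = as.integer(validation_period),
                 patch_size = as.integer(patch_size),
                 patch_stride = as.integer(patch_stride),
                 nex_train = as.integer(nex_train),
                 patches_per_series = patches_per_series,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Split a dataset into training / validation / test subjects
#'
#' @param dataset a `dwi_dataset` from [make_dataset()].
#' @param n_train,n_val,n_test subject counts (in subject order).
#' @return list with `train`, `val`, `test` lists of `dwi_series`.
#' @export
split_dataset <- function(dataset, n_train, n_val, n_test = 0) {
  subs <- dataset$subjects
  if (n_train + n_val + n_test > length(subs))
    abort_validation("split exceeds the number of subjects", "n_train")
  list(train = subs[seq_len(n_train)],
       val = subs[n_train + seq_len(n_val)],
       test = if (n_test > 0) subs[n_train + n_val + seq_len(n_test)] else list())
}

# Collect training patch triples from a list of (normalized) series.
collect_patches <- function(series_list, tc) {
  out <- list()
  for (series in series_list) {
    if (!isTRUE(series$normalized)) series <- normalize_series(series)
    for (k in tc$nex_train) {
      p <- extract_patches(series, k, size = tc$patch_size,
                           stride = tc$patch_stride)
      if (!is.null(tc$patches_per_series) &&
          length(p) > tc$patches_per_series) {
        p <- p[sample.int(length(p), tc$patches_per_series)]
      }
      out <- c(out, p)
    }
  }
  out
}

# Assemble a batch: x (sz, sz, 2, B) with noisy in channel 1 and guide in
# channel 2; ref and noisy (sz, sz, 1, B). Augmentation ops applied jointly.
assemble_batch <- function(patches, idx, ops = NULL) {
  sz <- nrow(patches[[idx[1]]]$noisy_patch)
  B <- length(idx)
  x <- array(0, c(sz, sz, 2, B))
  ref <- array(0, c(sz, sz, 1, B))
  for (b in seq_len(B)) {
    p <- patches[[idx[b]]]
    if (!is.null(ops) && ops[b] > 0) p <- augment(p, ops[b])
    x[, , 1, b] <- p$noisy_patch
    x[, , 2, b] <- p$guide_patch
    ref[, , 1, b] <- p$reference_patch
  }
  list(x = x, ref = ref)
}

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    st <- list(W = list(m = l$W * 0, v = l$W * 0))
    if (l$bias) st$b <- list(m = l$b * 0, v = l$b * 0)
    if (l$bn) {
      st$gamma <- list(m = l$gamma * 0, v = l$gamma * 0)
      st$beta <- list(m = l$beta * 0, v = l$beta * 0)
    }
    st
  })
}

adam_step <- function(net, state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
  for (li in seq_along(net$layers)) {
    for (par in names(state[[li]])) {
      g <- grads[[li]][[par]]
      st <- state[[li]][[par]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[li]][[par]] <- st
      net$layers[[li]][[par]] <- net$layers[[li]][[par]] -
        lr * (st$m / corr1) / (sqrt(st$v / corr2) + eps)
    }
  }
  list(net = net, state = state)
}

# Recalibrate batch-norm running statistics after training ("precise BN"):
# one forward sweep over training batches in training mode, replacing the
# momentum-weighted running moments by the plain average of batch moments.
# Removes the train/eval mismatch floor left by the exponential average.
bn_recalibrate <- function(net, patches, batch_size, max_batches = 50L) {
  n <- length(patches)
  n_batches <- min(max_batches, n %/% batch_size)
  if (n_batches < 1) return(net)
  for (li in seq_along(net$layers)) {
    if (net$layers[[li]]$bn) {
      net$layers[[li]]$running_mean[] <- 0
      net$layers[[li]]$running_var[] <- 0
    }
  }
  mom0 <- net$config$bn_momentum
  for (k in seq_len(n_batches)) {
    idx <- ((k - 1) * batch_size + 1):(k * batch_size)
    ba <- assemble_batch(patches, idx)
    net$config$bn_momentum <- 1 - 1 / k   # running = cumulative batch mean
    net <- net_forward(net, ba$x, training = TRUE)$net
  }
  net$config$bn_momentum <- mom0
  net
}

# Mean per-patch validation loss in evaluation mode.
validation_loss <- function(net, patches, lc, batch_size) {
  n <- length(patches)
  total <- 0
  i <- 1L
  while (i <= n) {
    idx <- i:min(n, i + batch_size - 1L)
    ba <- assemble_batch(patches, idx)
    res <- net_forward(net, ba$x, training = FALSE)$out
    d <- ba$x[, , 1, , drop = FALSE] - res
    total <- total + joint_l1_l2_loss(d, ba$ref, lc)
    i <- i + batch_size
  }
  total / n
}

#' Train the residual denoising network
#'
#' Mini-batch optimisation of the configured loss on guide/noisy/reference
#' patch triples, with a fresh uniform dihedral augmentation drawn per patch
#' per epoch. The network predicts the noise residual of the noisy channel;
#' the loss compares `noisy - residual` against the reference. The
#' validation loss (mean per-patch, evaluation mode) is recorded every
#' `validation_period` epochs. Fully deterministic given the seeds: data
#' order, augmentation and weight initialisation are all seeded.
#'
#' @param dataset list with `train` and `val` lists of `dwi_series`
#'   (see [split_dataset()]).
#' @param net_config a [net_config()].
#' @param loss_config a [loss_config()].
#' @param train_config a [train_config()].
#' @param init_net optional `dcnn_net` to warm-start from (e.g. a loaded
#'   checkpoint to resume, or a previous stage of a learning-rate schedule);
#'   its architecture must match `net_config`.
#' @return list of class `train_result` with `net`, `history` (data.frame
#'   `epoch`, `train_loss`, `val_loss`), and the three configs.
#' @export
train_dcnn <- function(dataset, net_config, loss_config = loss_config(),
                       train_config = train_config(), init_net = NULL) {
  tc <- train_config; lc <- loss_config
  if (length(dataset$train) < 1 || length(dataset$val) < 1)
    abort_validation("dataset needs >= 1 training and >= 1 validation subject",
                     "dataset")
  net <- if (is.null(init_net)) build_network(net_config) else {
    if (!identical(unclass(init_net$config)[c("depth", "width", "kernel",
                                              "in_channels", "out_channels")],
                   unclass(net_config)[c("depth", "width", "kernel",
                                         "in_channels", "out_channels")]))
      abort_validation("init_net architecture does not match net_config",
                       "init_net")
    init_net
  }
  state <- adam_init(net)
  history <- data.frame(epoch = seq_len(tc$epochs),
                        train_loss = NA_real_, val_loss = NA_real_)
  with_seed(tc$seed, {
    train_patches <- collect_patches(dataset$train, tc)
    val_patches <- collect_patches(dataset$val, tc)
    n <- length(train_patches)
    if (n < tc$batch_size)
      abort_validation("fewer training patches than one batch", "batch_size")
    steps <- n %/% tc$batch_size
    t <- 0L
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ops <- sample.int(8, n, replace = TRUE) - 1L
      ep_loss <- 0
      for (s in seq_len(steps)) {
        idx <- ord[((s - 1) * tc$batch_size + 1):(s * tc$batch_size)]
        ba <- assemble_batch(train_patches, idx, ops[idx])
        fw <- net_forward(net, ba$x, training = TRUE, keep_cache = TRUE)
        net <- fw$net
        d <- ba$x[, , 1, , drop = FALSE] - fw$out
        loss <- joint_l1_l2_loss(d, ba$ref, lc) / tc$batch_size
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d step %d; lower the learning rate",
                       epoch, s))
        ep_loss <- ep_loss + loss
        # d = noisy - residual, so d(loss)/d(residual) = -d(loss)/d(d)
        g <- -loss_gradient(d, ba$ref, lc) / tc$batch_size
        grads <- net_backward(net, fw$caches, g)
        t <- t + 1L
        up <- adam_step(net, state, grads, tc$learning_rate, t)
        net <- up$net; state <- up$state
      }
      history$train_loss[epoch] <- ep_loss / steps
      if (epoch %% tc$validation_period == 0) {
        history$val_loss[epoch] <- validation_loss(net, val_patches, lc,
                                                   tc$batch_size)
      }
      if (tc$verbose) {
        message(sprintf("epoch=%d train_loss=%.6g val_loss=%s lambda=%g",
                        epoch, history$train_loss[epoch],
                        ifelse(is.na(history$val_loss[epoch]), "NA",
                               sprintf("%.6g", history$val_loss[epoch])),
                        lc$lambda_l1))
      }
      if (!is.null(tc$checkpoint_dir)) {
        save_checkpoint(net, file.path(tc$checkpoint_dir, "last.ckpt"),
                        extra = list(epoch = epoch, history = history,
                                     loss_config = unclass(lc),
                                     train_config = unclass(tc)))
      }
    }
    net <- bn_recalibrate(net, train_patches, tc$batch_size)
  })
  structure(list(net = net, history = history, net_config = net_config,
                 loss_config = lc, train_config = tc),
            class = "train_result")
}

#' Train one network per L1 weight and tabulate image quality
#'
#' Trains identically seeded networks over a list of L1 weights (the
#' canonical sweep is `c(2, 4, 5, 6, 10)`) and evaluates each on held-out
#' subjects, returning the quality table; the choice among weights is left
#' to the user.
#'
#' @param dataset list with `train`, `val` and nonempty `test` series lists.
#' @param net_config a [net_config()].
#' @param train_config a [train_config()].
#' @param lambdas numeric vector of L1 weights (>= 1 value).
#' @param eval_nex NEX level evaluated in the table (default 1).
#' @return data.frame with one row per lambda: mean global PSNR/SSIM of the
#'   noisy and denoised test images against the reference.
#' @export
lambda_sweep <- function(dataset, net_config, train_config,
                         lambdas = c(2, 4, 5, 6, 10), eval_nex = 1) {
  if (length(lambdas) < 1) abort_validation("need >= 1 lambda", "lambdas")
  test <- if (length(dataset$test) > 0) dataset$test else dataset$val
  rows <- lapply(lambdas, function(lam) {
    fit <- train_dcnn(dataset, net_config, loss_config("joint", lam),
                      train_config)
    ev <- evaluate_model(fit$net, test, nex = eval_nex)
    cbind(data.frame(lambda = lam), ev)
  })
  do.call(rbind, rows)
}

#' Evaluate a trained network on held-out subjects
#'
#' Denoises every requested NEX series of every subject and aggregates the
#' per-slice global metrics across all subjects and slices.
#'
#' @param net a `dcnn_net`.
#' @param series_list list of `dwi_series`.
#' @param nex NEX levels to evaluate.
#' @return data.frame with one row per (nex): mean PSNR/SSIM for noisy and
#'   denoised images, plus ROI-mean ADC columns (1e-3 mm^2/s).
#' @export
evaluate_model <- function(net, series_list, nex = c(1, 2, 4)) {
  reports <- lapply(series_list, function(series) {
    if (!isTRUE(series$normalized)) series <- normalize_series(series)
    den <- denoise_series(net, series)
    evaluate_series(series, den, nex = as.character(nex))
  })
  slices <- do.call(rbind, lapply(reports, `[[`, "slices"))
  adc <- do.call(rbind, lapply(reports, `[[`, "adc"))
  out <- do.call(rbind, lapply(split(slices, slices$nex), function(g) {
    data.frame(
      nex = g$nex[1],
      psnr_noisy = mean(g$psnr_global[g$image == "noisy"]),
      psnr_denoised = mean(g$psnr_global[g$image == "denoised"]),
      ssim_noisy = mean(g$ssim_global[g$image == "noisy"]),
      ssim_denoised = mean(g$ssim_global[g$image == "denoised"]),
      psnr_roi_noisy = mean(g$psnr_roi[g$image == "noisy"]),
      psnr_roi_denoised = mean(g$psnr_roi[g$image == "denoised"]),
      ssim_roi_noisy = mean(g$ssim_roi[g$image == "noisy"]),
      ssim_roi_denoised = mean(g$ssim_roi[g$image == "denoised"]))
  }))
  adc_agg <- do.call(rbind, lapply(split(adc, adc$nex), function(g) {
    data.frame(nex = g$nex[1], adc_noisy = mean(g$adc_noisy),
               adc_denoised = mean(g$adc_denoised),
               adc_reference = mean(g$adc_reference),
               adc_truth = mean(g$adc_truth))
  }))
  out <- merge(out, adc_agg, by = "nex")
  rownames(out) <- NULL
  out
}
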