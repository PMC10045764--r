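test_that("training is bit-reproducible under identical seeds", {
  sp <- tiny_split()
  fit1 <- train_dcnn(sp, tiny_net(), loss_config("joint", 4), tiny_train())
  fit2 <- train_dcnn(sp, tiny_net(), loss_config("joint", 4), tiny_train())
  expect_identical(fit1$net$layers, fit2$net$layers)
  expect_identical(fit1$history, fit2$history)

  fit3 <- train_dcnn(sp, tiny_net(), loss_config("joint", 4), tiny_train(seed = 5))
  expect_false(identical(fit1$net$layers, fit3$net$layers))
})

test_that("validation losses appear exactly at multiples of the validation period", {
  sp <- tiny_split()
  fit <- train_dcnn(sp, tiny_net(), loss_config("joint", 4),
                    tiny_train(epochs = 5) |> (\(tc) { tc$validation_period <- 2L; tc })())
  logged <- which(!is.na(fit$history$val_loss))
  expect_identical(logged, c(2L, 4L))
})

test_that("training on noiseless data learns the identity map", {
  sp <- tiny_split(sigma = 0)
  nc <- tiny_net(depth = 4, width = 8)
  mk <- function(ep, lr, seed) {
    train_config(epochs = ep, batch_size = 12, validation_period = ep,
                 learning_rate = lr, patch_size = 32, patch_stride = 32,
                 seed = seed)
  }
  # staged learning-rate descent on the degenerate target (residual = 0)
  fit <- train_dcnn(sp, nc, loss_config("joint", 4), mk(150, 3e-3, 4))
  first_val <- fit$history$val_loss[150]
  fit <- train_dcnn(sp, nc, loss_config("l2_only"), mk(300, 1e-3, 5),
                    init_net = fit$net)
  fit <- train_dcnn(sp, nc, loss_config("l2_only"), mk(300, 3e-4, 6),
                    init_net = fit$net)
  last_val <- fit$history$val_loss[300]
  expect_lt(last_val, 0.05 * first_val)

  ser <- normalize_series(sp$val[[1]])
  den <- denoise(fit$net, ser$noisy[["1"]], ser$guide)$denoised
  expect_gt(psnr(den, ser$noisy[["1"]]), 40)  # denoise ~ identity
})

test_that("a short desk-scale run reduces the validation loss", {
  sp <- tiny_split(n_train = 2, sigma = 0.05)
  fit <- train_dcnn(sp, tiny_net(depth = 4, width = 8),
                    loss_config("joint", 4),
                    tiny_train(epochs = 6, seed = 8))
  vals <- fit$history$val_loss[!is.na(fit$history$val_loss)]
  expect_lt(vals[length(vals)], vals[1])
})

test_that("non-finite losses abort with a diagnostic", {
  sp <- tiny_split()
  sp$train[[1]]$noisy[["1"]][1, 1, 1] <- NaN
  expect_error(
    train_dcnn(sp, tiny_net(), loss_config("joint", 4), tiny_train()),
    "non-finite")
})

test_that("the lambda sweep shares seeds so duplicated entries coincide", {
  sp <- tiny_split(n_train = 1, n_val = 1, n_test = 1)
  tab <- lambda_sweep(sp, tiny_net(), tiny_train(epochs = 1),
                      lambdas = c(3, 3), eval_nex = 1)
  expect_equal(tab[1, ], tab[2, ], ignore_attr = TRUE)

  # lambda = 0 is exactly an L2-only run under the same seeds
  tab0 <- lambda_sweep(sp, tiny_net(), tiny_train(epochs = 1),
                       lambdas = 0, eval_nex = 1)
  fit_l2 <- train_dcnn(sp, tiny_net(), loss_config("l2_only"),
                       tiny_train(epochs = 1))
  ev_l2 <- evaluate_model(fit_l2$net, sp$test, nex = 1)
  expect_equal(tab0[, -1], ev_l2, ignore_attr = TRUE)
})

test_that("checkpoints allow resuming and record the training history", {
  dir <- withr::local_tempdir()
  sp <- tiny_split()
  tc <- tiny_train(epochs = 2)
  tc$checkpoint_dir <- dir
  fit <- train_dcnn(sp, tiny_net(), loss_config("joint", 4), tc)
  expect_true(file.exists(file.path(dir, "last.ckpt")))
  ck <- load_checkpoint(file.path(dir, "last.ckpt"))
  expect_equal(ck$extra$epoch, 2)
  resumed <- train_dcnn(sp, tiny_net(), loss_config("joint", 4),
                        tiny_train(epochs = 1, seed = 9), init_net = ck$net)
  expect_s3_class(resumed, "train_result")
  expect_error(
    train_dcnn(sp, tiny_net(depth = 5), loss_config(), tiny_train(epochs = 1),
               init_net = ck$net),
    "architecture")
})
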