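# Independent layer-shape walk: first layer maps in_channels -> width,
# hidden layers width -> width, last layer width -> out_channels.
shape_walk_weights <- function(depth, width, kernel, cin, cout) {
  total <- 0
  for (l in seq_len(depth)) {
    ci <- if (l == 1) cin else width
    co <- if (l == depth) cout else width
    total <- total + kernel * kernel * ci * co
  }
  total
}

test_that("convolution weight counts match an independent shape walk", {
  paper <- net_config(preset = "paper")
  expect_identical(count_conv_weights(paper),
                   shape_walk_weights(64, 64, 3, 2, 1))
  expect_identical(count_conv_weights(paper), 2287296)

  for (cfg in list(c(3, 1), c(3, 5), c(8, 32), c(5, 2))) {
    nc <- net_config(depth = cfg[1], width = cfg[2])
    expect_identical(count_conv_weights(nc),
                     shape_walk_weights(cfg[1], cfg[2], 3, 2, 1))
  }
})

test_that("network configuration is validated", {
  expect_error(net_config(depth = 2), "depth")
  expect_error(net_config(width = 0), "width")
  expect_error(net_config(kernel = 4), "kernel")
  expect_error(net_config(preset = "huge"), "preset")
})

test_that("the network is fully convolutional with same-size output", {
  net <- build_network(net_config(depth = 4, width = 3, seed = 1))
  for (d in list(c(7, 9), c(60, 60), c(140, 140))) {
    noisy <- matrix(runif(prod(d)), d[1], d[2])
    guide <- matrix(runif(prod(d)), d[1], d[2])
    res <- predict_residual(net, noisy, guide)
    expect_identical(dim(res), dim(noisy))
  }
  expect_error(predict_residual(net, matrix(0, 4, 4), matrix(0, 5, 5)), "dimensions")
})

test_that("inference is deterministic and the residual identity holds", {
  net <- build_network(net_config(depth = 5, width = 4, seed = 3))
  noisy <- array(runif(32 * 32 * 2), c(32, 32, 2))
  guide <- array(runif(32 * 32 * 2), c(32, 32, 2))
  r1 <- denoise(net, noisy, guide)
  r2 <- denoise(net, noisy, guide)
  expect_identical(r1, r2)
  # denoised is exactly the clamped difference of input and residual
  expect_identical(r1$denoised, pmax(noisy - r1$residual, 0))
  expect_true(all(r1$denoised >= 0))
})

test_that("a zero final layer forces a zero residual, and clamping applies", {
  net <- build_network(net_config(depth = 4, width = 3, seed = 2))
  last <- length(net$layers)
  net$layers[[last]]$W[] <- 0
  net$layers[[last]]$b[] <- 0
  noisy <- matrix(runif(100), 10, 10)
  guide <- matrix(runif(100), 10, 10)
  expect_true(all(predict_residual(net, noisy, guide) == 0))
  expect_identical(denoise(net, noisy, guide)$denoised, noisy)

  # constant positive bias makes the residual exceed small pixels -> clamp to 0
  net$layers[[last]]$b[] <- 0.5
  den <- denoise(net, noisy, guide)
  expect_true(all(den$residual == 0.5))
  expect_identical(den$denoised, pmax(noisy - 0.5, 0))
  expect_true(any(den$denoised == 0))
})

test_that("backpropagation matches finite-difference gradients", {
  nc <- net_config(depth = 3, width = 2, seed = 6)
  net <- build_network(nc)
  set.seed(9)
  x <- array(rnorm(6 * 7 * 2 * 2), c(6, 7, 2, 2))
  gy <- array(rnorm(6 * 7 * 1 * 2), c(6, 7, 1, 2))
  fw <- dwidcnn:::net_forward(net, x, training = TRUE, keep_cache = TRUE)
  grads <- dwidcnn:::net_backward(net, fw$caches, gy)

  objective <- function(net) sum(dwidcnn:::net_forward(net, x, training = TRUE)$out * gy)
  h <- 1e-6
  check <- function(li, par, idx) {
    np <- net; np$layers[[li]][[par]][idx] <- np$layers[[li]][[par]][idx] + h
    nm <- net; nm$layers[[li]][[par]][idx] <- nm$layers[[li]][[par]][idx] - h
    num <- (objective(np) - objective(nm)) / (2 * h)
    expect_equal(grads[[li]][[par]][idx], num, tolerance = 1e-5)
  }
  check(1, "W", 5); check(1, "b", 1)
  check(2, "W", 11); check(2, "gamma", 2); check(2, "beta", 1)
  check(3, "W", 3); check(3, "b", 1)
})

test_that("checkpoints round-trip weights, config and metadata", {
  dir <- withr::local_tempdir()
  net <- build_network(net_config(depth = 4, width = 3, seed = 8))
  p <- file.path(dir, "model.ckpt")
  save_checkpoint(net, p, extra = list(note = "fixture"))
  back <- load_checkpoint(p)
  expect_equal(back$net$layers, net$layers)
  expect_equal(back$extra$note, "fixture")
  expect_equal(back$norm_convention, "reference_max")
  noisy <- matrix(runif(64), 8, 8); guide <- matrix(runif(64), 8, 8)
  expect_identical(predict_residual(back$net, noisy, guide),
                   predict_residual(net, noisy, guide))
  expect_error(load_checkpoint(file.path(dir, "none.ckpt")), "not found")
})
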