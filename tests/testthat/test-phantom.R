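test_that("uniform and zero-background phantoms produce the stated maps", {
  gt <- make_phantom(uniform_spec())
  expect_true(all(gt$s0_map == 1))
  expect_true(all(gt$adc_map == 1e-3))

  gt2 <- make_phantom(small_spec())
  for (b in c(0, 50, 800)) {
    clean <- simulate_clean(gt2, b)
    expect_true(all(clean[gt2$label_map == 0] == 0))
  }
})

test_that("rectum ROI pixel count matches the analytic annulus area", {
  spec <- phantom_spec()  # defaults: 140 x 140, wall annulus radii 8..16
  gt <- make_phantom(spec)
  central <- (spec$n_slices + 1) %/% 2
  count <- sum(gt$roi_mask[, , central])
  analytic <- pi * (16^2 - 8^2)
  expect_lt(abs(count - analytic) / analytic, 0.05)
})

test_that("clean signal follows mono-exponential decay", {
  gt <- make_phantom(uniform_spec(s0 = 1, adc = 1e-3))
  expect_identical(simulate_clean(gt, 0), gt$s0_map)
  expect_equal(simulate_clean(gt, 800)[1, 1, 1], exp(-0.8), tolerance = 1e-12)
  expect_equal(simulate_clean(gt, 800)[1, 1, 1], 0.44933, tolerance = 1e-5)

  gt0 <- make_phantom(uniform_spec(s0 = 0.7, adc = 0))
  expect_true(all(simulate_clean(gt0, 1500) == 0.7))

  expect_error(simulate_clean(gt, -10), "b must be")
})

test_that("repetition noise model is Rician, seeded, and exact when sigma = 0", {
  clean <- matrix(0.5, 40, 40)
  st0 <- simulate_repetitions(clean, 0, 3, seed = 1)
  for (r in st0$repetitions) expect_identical(r, clean)

  # Rayleigh mean at zero signal: sigma * sqrt(pi / 2)
  z <- matrix(0, 140, 140)
  st <- simulate_repetitions(z, 0.1, 1, seed = 7)
  expect_equal(mean(st$repetitions[[1]]), 0.1 * sqrt(pi / 2), tolerance = 0.02)
  expect_true(all(st$repetitions[[1]] >= 0))

  st_a <- simulate_repetitions(clean, 0.05, 4, seed = 11)
  st_b <- simulate_repetitions(clean, 0.05, 4, seed = 11)
  expect_identical(st_a, st_b)
  st_c <- simulate_repetitions(clean, 0.05, 4, seed = 12)
  expect_false(identical(st_a$repetitions[[1]], st_c$repetitions[[1]]))

  # gaussian option has (approximately) zero mean at zero signal
  stg <- simulate_repetitions(z, 0.1, 1, seed = 7, noise_model = "gaussian")
  expect_lt(abs(mean(stg$repetitions[[1]])), 0.01)

  expect_error(simulate_repetitions(clean, -1, 1, seed = 1), "sigma")
  expect_error(simulate_repetitions(clean, 0.1, 0, seed = 1), "nex")
})

test_that("datasets are reproducible and the noisy series are prefixes of the reference stack", {
  spec <- small_spec(noise_sigma = 0)
  ds <- make_dataset(spec, 1, seed = 5)
  s <- ds$subjects[[1]]
  # noiseless degenerate: all averages equal the clean image (up to the
  # last-ulp rounding of the 16-term accumulation)
  expect_equal(s$noisy[["1"]], s$reference, tolerance = 1e-15)

  # NEX = 16 prefix of the 16-repetition stack is the reference itself
  spec2 <- small_spec(nex_noisy = c(1L, 2L, 4L, 16L))
  ds2 <- make_dataset(spec2, 1, seed = 9)
  expect_identical(ds2$subjects[[1]]$noisy[["16"]], ds2$subjects[[1]]$reference)

  ds_a <- make_dataset(small_spec(), 2, seed = 13)
  ds_b <- make_dataset(small_spec(), 2, seed = 13)
  expect_identical(ds_a, ds_b)
  # subject geometry jitter makes subjects distinct
  expect_false(identical(ds_a$subjects[[1]]$gt$roi_mask,
                         ds_a$subjects[[2]]$gt$roi_mask))
})

test_that("spec validation names the offending field", {
  expect_error(phantom_spec(matrix_size = 32), "matrix_size")
  expect_error(phantom_spec(noise_sigma = -0.1), "noise_sigma")
  expect_error(phantom_spec(b_low = 800, b_high = 50), "b_high")
  tiss <- default_tissues(140)
  tiss[[2]]$label <- tiss[[1]]$label
  expect_error(phantom_spec(tissues = tiss), "distinct")
  tiss2 <- default_tissues(140)
  tiss2[[3]]$adc <- -1e-3
  expect_error(phantom_spec(tissues = tiss2), "ADC")
  expect_error(make_dataset(small_spec(), 0), "n_subjects")
})
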