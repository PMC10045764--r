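# Small phantoms and datasets used across test files.

# 64 x 64 single-slice spec with the default anatomy scaled down.
small_spec <- function(n_slices = 1, ...) {
  phantom_spec(matrix_size = 64, n_slices = n_slices,
               tissues = default_tissues(64), ...)
}

# One uniform tissue covering the whole field of view.
uniform_spec <- function(s0 = 1, adc = 1e-3, ...) {
  phantom_spec(
    matrix_size = 64, n_slices = 1,
    tissues = list(list(label = "t",
                        shape = list(type = "disk", center = c(0, 0), r = 200),
                        s0 = s0, adc = adc)),
    rectum_roi = "t", ...)
}

# Hand-built series with known contents (bypasses the simulator).
manual_series <- function(guide, noisy1, reference) {
  structure(list(
    subject_id = "manual", guide = guide,
    noisy = list("1" = noisy1), reference = reference,
    b_low = 50, b_high = 800, nex_low = 4, nex_reference = 16,
    norm_scale_highb = 1, norm_scale_guide = 1, normalized = FALSE,
    gt = NULL, seed_used = 0L), class = "dwi_series")
}

# Tiny noisy dataset for training smoke tests.
tiny_split <- function(n_train = 1, n_val = 1, n_test = 0, sigma = 0.05,
                       seed = 3) {
  ds <- make_dataset(small_spec(noise_sigma = sigma, seed = seed),
                     n_train + n_val + n_test, seed = seed)
  split_dataset(ds, n_train, n_val, n_test)
}

tiny_net <- function(depth = 3, width = 4, seed = 2) {
  net_config(depth = depth, width = width, seed = seed)
}

tiny_train <- function(epochs = 2, seed = 4, ...) {
  train_config(epochs = epochs, batch_size = 8, validation_period = 1,
               patch_size = 32, patch_stride = 32, seed = seed, ...)
}
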