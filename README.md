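# dwidcnn — guided residual denoising of high b-value diffusion-weighted MRI

High b-value diffusion-weighted MRI (DWI) has intrinsically low SNR, so
clinical rectal protocols average 16 repeated excitations (NEX = 16) — a
~6-minute scan. `dwidcnn` implements the alternative: acquire only 1, 2 or 4
excitations (16-, 8- or 4-fold acceleration) and restore image quality with
a residual denoising convolutional network that takes the noisy high-b image
*and* the high-SNR low-b image (an anatomical guide) as a two-channel input
and predicts the noise to subtract:

    denoised = noisy − f(noisy, guide)

The network is a stack of 3×3 same-padded convolutions (first layer + ReLU,
hidden layers + batch norm + ReLU, linear final layer; full-size preset:
64 layers × 64 feature maps, 2,287,296 convolution weights). Training
minimises a joint L1–L2 loss

    L = Σ ½‖d − r‖² + λ Σ‖d − r‖₁,   λ = 4 by default,

whose L1 weight trades residual noise (L2-only over-smooths) against noise
retention (L1-only under-smooths). Evaluation uses the tabulated PSNR
(`10·log10(d_max/MSE)`), single-window SSIM (luminance × contrast ×
structure), ROI-restricted variants around the rectum, and pixel-wise ADC
mapping `−ln(s_high/s_low)/Δb` in mm²/s.

The package is aimed at MR-physics and image-analysis researchers who want a
fully seeded, CPU-scale, end-to-end testbed for guided DWI denoising: a
rectum-like multi-NEX Rician phantom generator stands in for patient data,
and everything — simulation, patch pipeline, network, training, metrics — is
exercised by the test suite. The convolution layers and backpropagation are
implemented in the package itself (RcppArmadillo im2col + GEMM), so there is
no deep-learning-framework dependency.

See `vignettes/guided-dwi-denoising.Rmd` for the model, the phantom's
assumptions, and all numerical conventions.

## Worked example

Simulate 17 synthetic subjects, train the desk-scale network (depth 8,
width 32) with the joint loss, and evaluate on 5 held-out subjects:

```r
library(dwidcnn)

spec <- phantom_spec(n_slices = 2, seed = 1)      # 140x140, b = 50/800 s/mm2
ds   <- make_dataset(spec, 17, seed = 1)
sp   <- split_dataset(ds, n_train = 10, n_val = 2, n_test = 5)

fit <- train_dcnn(sp,
                  net_config(depth = 8, width = 32, seed = 2),
                  loss_config("joint", lambda_l1 = 4),
                  train_config(epochs = 5, batch_size = 16,
                               validation_period = 2, patch_stride = 40,
                               seed = 3))

evaluate_model(fit$net, sp$test, nex = c(1, 2, 4))
```

which prints, among further ROI and ADC columns (~10 min on one CPU):

```
  nex psnr_noisy psnr_denoised ssim_noisy ssim_denoised
1   1      21.62         27.33      0.825         0.947
2   2      24.52         29.24      0.909         0.967
3   4      27.97         30.42      0.959         0.976
```

Reading the table: the denoised NEX = 1 image gains **+5.7 dB PSNR** and
**+0.12 SSIM** over the raw single-excitation input. The ROI-mean ADC
columns for NEX = 1 (in 10⁻³ mm²/s) read 1.568 noisy, 1.506 denoised,
1.515 reference against a simulation truth of 1.563 — the denoised estimate
sits within ~4% of truth, close to the NEX = 16 reference's own value (the
vignette explains why the raw NEX = 1 estimate can appear even less biased).
PSNR/SSIM here use the
package's literal metric variants — see the vignette before comparing with
other software.

The same workflow is available from the shell via the installed launcher
(`inst/exec/dwidcnn`): `simulate`, `train`, `denoise`, `evaluate` and
`sweep-lambda` subcommands, YAML configs with flag overrides, seeded and
atomically written outputs.

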