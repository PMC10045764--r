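---
title: "Guided residual denoising of high b-value DWI: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided residual denoising of high b-value DWI: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diffusion-weighted MRI (DWI) of the rectum is acquired with single-shot EPI
at two diffusion weightings, a low b-value (50 s/mm²) and a high b-value
(800 s/mm²). The diffusion gradients attenuate the signal, so the high
b-value image has very low SNR and is conventionally acquired 16 times
(NEX = 16) and averaged — a ~6-minute scan. The goal of this package is the
opposite trade: acquire only 1, 2 or 4 excitations (16-, 8- and 4-fold
acceleration) and recover the image quality of the 16-average reference with
a learned denoiser. Because the low b-value image is fast and high-SNR, it is
supplied to the denoiser as a second input channel — an anatomical guide.

## The model

The denoiser is a residual convolutional network. Its input is the pair
(noisy high-b image, low-b guide) stacked as two channels; its output is the
predicted *noise* of the high-b channel, which is subtracted from the input:

    denoised = noisy − f(noisy, guide)

Residual learning makes the target (the noise field) approximately
stationary and zero-mean, which is easier to fit than the image itself.
Layer 1 is a 3×3 convolution (2 → width channels) with ReLU; layers
2 … depth−1 are 3×3 convolutions (width → width) with batch normalisation
between the convolution and the ReLU; the final layer is a linear 3×3
convolution producing one channel. All layers use zero "same" padding, so
the network is fully convolutional: it is trained on 60×60 patches and
applied to whole 140×140 slices. The full-size preset (`preset = "paper"`,
depth 64, width 64) has 2,287,296 convolution weights; the desk-scale
default used throughout the tests is depth 8, width 32, which trains in
minutes on one CPU while exercising exactly the same architecture contract.

Design choices not forced by the architecture: biases are present only on
the first and last layers (a bias before batch norm is absorbed by it);
batch-norm uses ε = 1e-5 and a running-statistics retention of 0.9, with a
"precise BN" pass after training that replaces the exponential running
moments by a plain average over up to 50 training batches; weights are
initialised with seeded Kaiming fan-in scaling.

## The loss

Training minimises a joint L1–L2 objective over denoised/reference pairs:

    L = Σ ½‖d − r‖² + λ Σ ‖d − r‖₁

The L2 term suppresses residual noise but over-smooths; the L1 term
preserves edges (rectal wall layers) but retains noise; λ balances the two,
with λ = 4 the default. `l2_only` and `l1_only` modes implement the two
degenerate comparisons. Per batch the loss is the pixel sum divided by the
batch size, so λ has the same meaning at any batch size; this convention is
recorded in checkpoints. The optimiser is Adam (lr 1e-3 by default) — the
loss, not the optimiser, is the contract. No early stopping is used; the
full-size schedule is 18 epochs with validation loss evaluated every third
epoch, both configurable.

## The phantom

No patient data ships with the package; the `phantom_sim` module generates
synthetic series with the statistical structure the denoiser assumes:

* **Geometry** — a 140×140 pelvis-like disk containing an off-centre rectum:
  a fluid lumen (ADC 2.6e-3 mm²/s), a bright inner wall (S0 = 1,
  ADC 1.1e-3) and a darker outer wall (S0 = 0.7, ADC 1.6e-3) as two
  concentric annuli (radii 8/12/16 px), so wall-layer delineation is a
  measurable feature. Subject-level jitter (centre ±4 px, radii ±8%) and a
  mild radius taper across slices emulate anatomical variability.
* **Signal** — mono-exponential decay `S0 · exp(−b · ADC)` at b = 50 and
  800 s/mm².
* **Noise** — each excitation is a Rician magnitude image,
  `|clean + ε₁ + iε₂|` with ε ~ N(0, σ²): the physical model for magnitude
  MRI. σ = 0.05 (relative to the brightest tissue) puts the
  single-excitation SNR of the rectal wall at high b-value around 4–8,
  i.e. visibly noisy; a pure-Gaussian option exists for analytic tests.
* **Averaging** — the NEX 1/2/4 noisy series are prefix averages of the
  *same* 16-repetition stack whose full average is the reference, so
  comparisons across NEX isolate averaging. Noise sd falls as 1/√N.
* **Not modelled** — k-space/EPI effects (partial Fourier, coil
  sensitivities, susceptibility distortion), T2 shine-through, perfusion,
  and non-mono-exponential diffusion. An optional seeded geometric warp of
  the rectal region emulates gas-induced distortion for qualitative demos
  only. Passing tests therefore demonstrate the pipeline and the denoising
  mechanism, not clinical performance on patient data.

## Data pipeline conventions

Training-time normalisation divides the noisy and reference volumes by the
global maximum of the reference and the guide by its own maximum (so both
reference and guide peak at 1; the noisy may exceed 1, unclipped). At
inference no reference exists, so the noisy volume is normalised by its own
maximum and the scale is returned for unit restoration. Patches are cut on a
regular grid (default stride 20; the tests use 40) with the last grid
position clamped to the border so the whole image is covered at any stride.
Augmentation draws uniformly from the 8 dihedral symmetries of the square,
applied identically to guide, noisy and reference patches. Volumes are
exchanged as 32-bit float NIfTI with JSON sidecar manifests; coordinates are
(slice, row, column), 1-based in R.

## Metrics

`psnr()` and `ssim()` implement the package's tabulated variants exactly:
PSNR is `10·log10(d_max / MSE)` with `d_max` the peak of the image under
test (note: not `d_max²`; on unit-normalised images this yields the 80+ dB
range reported for patient data), and SSIM is the single-window product of
luminance, contrast and structure terms with ε-stabilised (1e-12)
denominators and no C1/C2 constants. Textbook variants are available behind
`variant = "standard"` for cross-checks and are used nowhere by default.
ROI-restricted metrics take the peak and moments over the mask only; the
default ROI is the phantom's wall annulus dilated by 3 px ("surrounding the
rectum"). ADC is the pixel-wise log-ratio `−ln(s_high/s_low)/Δb`, with
pixels below 1e-6 of the low-b peak excluded and negative values flagged but
not clamped; tables report 1e-3 mm²/s. Per-slice metrics are aggregated as
mean ± sd across slices (whether to pool pixels instead is a free choice;
per-slice aggregation is this package's convention, stated here).

## ADC bias of averaged magnitude data

A point worth making explicit because it shapes what denoising can and
cannot improve. Writing `A_n` for the n-average of Rician magnitudes with
clean signal `s`, `E[ln A_n] ≈ ln E[M] − Var(M)/(2 n E[M]²)`. The first term
(the Rician noise floor, `E[M] > s`) biases ADC down and is independent of
n; the second (Jensen's inequality on the log) biases ADC up and shrinks as
1/n. The signed ROI-mean ADC therefore *decreases monotonically with NEX* —
a property the test suite checks — and at moderate SNR the two terms nearly
cancel at NEX = 1, so the raw single-excitation ADC can be *less* biased
with respect to the noise-free truth than the 16-average reference. A
denoiser trained toward the reference inherits the reference's floor bias;
consequently its ROI-mean ADC lands close to truth (within a few percent at
the phantom's SNR) but not necessarily closer than the noisy NEX = 1
estimate, whose two bias terms cancel. The evaluation reports all four
quantities (noisy, denoised, reference, truth) so this can be seen directly.

## Desk-scale study conditions

All quantitative checks and the acceptance script run at a scale chosen for
a single CPU: 17 subjects (10 train / 2 validation / 5 held-out), 2 slices
per subject, depth-8/width-32 network, mixed-NEX (1, 2, 4) patch pool with
stride 40 (9 patches per slice per NEX), batch 16, 5 epochs of Adam at
lr 1e-3 with validation every 2 epochs. One network is trained on the mixed
pool and applied at every NEX (training one network per NEX is the
full-scale alternative). Under these conditions the denoiser improves the
held-out NEX = 1 images by roughly +5–7 dB PSNR and +0.12 SSIM over the
noisy input, and the three-way loss comparison (L1-only, L2-only, joint)
reproduces the expected ordering with the joint loss at or near the top.
The λ sweep utility trains one network per λ over {2, 4, 5, 6, 10} with
shared seeds and tabulates the metrics; selection among them is left to the
user.

## Numerical and degenerate-input conventions

* All randomness (geometry jitter, noise draws, data order, augmentation,
  initialisation) flows from explicit integer seeds; runs are
  bit-reproducible on a fixed BLAS single-threaded.
* Identical images yield `Inf` PSNR (a distinct signal, not an error);
  zero-variance images error in `ssim()` only when the ε override is 0.
* Negative denoised pixels are clamped to zero (magnitudes); the residual
  identity `denoised = clamp(noisy − residual)` holds exactly.
* A non-finite training loss aborts with a diagnostic rather than
  continuing.
* `adc_map()` keeps negative ADC values (possible under noise) and flags
  them; ROI means use only valid pixels.

## Known limitations

The phantom is piecewise-smooth and far simpler than patient anatomy, so
desk-scale PSNR/SSIM levels are not comparable to values measured on
clinical cohorts (the metric *formulas* are, however, identical). The
desk-scale network is intentionally small; the full-size 64/64 preset is
constructed and shape-checked but not trained in the tests. On clean
(noise-free) data the small network learns the identity map to ~50 dB, an
optimisation floor of short CPU schedules rather than a model limitation.
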