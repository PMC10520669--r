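---
title: "Models and methods behind msimsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msimsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`msimsr` implements a complete multifocal structured illumination
microscopy (MSIM) tool chain: a physical forward simulator, the
conventional four-step reconstruction, a learned per-frame
super-resolution network with its composite loss and training schemes,
and a quantitative evaluation suite. This vignette records the models,
the tunable parameters, and the design decisions a maintainer should
know about — including the places where the underlying procedure is
under-determined and the package had to commit to a choice.

## The forward model

A `SampleMap` is a nonnegative fluorophore density $s(u)$ on a pixel
grid (default pixel size 130 nm). The built-in phantoms are the spoke
(Siemens-star) target $\rho(r,\theta) \propto 1 + \cos(n\,\theta)$ with
$n = 48$ lobes by default (peak normalised to 1; the lobe count sets the
spoke width, and the spacing between spokes shrinks toward the center so
a single phantom probes resolution continuously), plus seeded random
filament and blob structures that diversify training data.

Illumination is a square lattice of foci with period `spacingPx`
(default 16 px) raster-scanned with step `stepPx`; the pattern of frame
$i$ is $p_i(u) = \sum_j \delta(r - b_{ij}) \otimes h_{ex}(u)$. With step
1 the scan visits each offset of the unit cell exactly once, so a
256×256 field yields 256 frames; step 2 visits every second offset in
both axes (the fourfold fewer-frames mode). Image formation is
$I_i(x) = \int p_i(u)\, s(u)\, h_{em}(x-u)\,du$, evaluated as a
pointwise product followed by an FFT convolution with zero padding. The
test suite holds this path to a brute-force direct summation at
$10^{-6}$ relative error, and checks linearity and flux bookkeeping.

One analytic subtlety: under unit-step scanning the *summed* excitation
$\sum_i p_i$ is flat in the interior (each pixel hosts a focus exactly
once), so the wide-field image — the pixelwise sum of all raw frames —
equals $s \otimes h_{em}$ away from the border, with no excitation blur.
The property test asserts exactly this invariant.

PSFs are isotropic Gaussians with $\sigma = 0.21\,\lambda/\mathrm{NA}$
(the Gaussian fit to the Airy core), truncated at $\pm 4\sigma$ on an
odd-sided grid and renormalised to unit sum. Defaults are
$\lambda = 560$ nm emission and NA 1.1, giving $\sigma \approx 0.82$ px
at 130 nm sampling. Defocus follows the geometric-optics growth
$\sigma(\Delta z) = \sqrt{\sigma_0^2 + (0.5\,\mathrm{NA}\,\Delta z/n)^2}$
with immersion index $n = 1.33$ — monotone and configurable, chosen
because only the defocus *distance* (3 µm for thick-sample training) is
physically prescribed. The excitation wavelength used in simulation and
whether two-photon excitation squares $h_{ex}$ are not prescribed
either; the package defaults to $h_{ex} = h_{em}$'s geometry at the same
width, with an optional `twoPhoton` mode that sharpens the excitation
profile by $\sqrt 2$. A kernel whose $\sigma$ falls below 0.2 px is
rejected as unresolvable at the requested sampling.

Noise is a Poisson draw on `photonScale` × frame divided back by
`photonScale`, then additive Gaussian read noise, then a clip at zero
(detector counts are nonnegative, and downstream ratios need it). The
training-pair generators choose `photonScale` per sample so the
brightest pixel collects ≈200 photons (≈50 in the low-SNR defocus
scheme) and set read noise to 1% of the peak — a mid-range SNR chosen
once as a realistic camera regime, since the exact noise magnitudes of
the original acquisitions are not stated. Every stochastic step takes an
explicit seed; frame $i$ of a stack is corrupted with `seed + i`.

## Conventional reconstruction

1. **Focus positions.** Either the simulation schedule (`"oracle"`) or
   detection (`"detected"`): Gaussian denoising (σ = 1 px, *replicated*
   boundaries so border foci are not displaced), strict local maxima
   with an exclusion radius of half the expected spacing, a threshold at
   0.3 of the global maximum, and finally a snap to the best-fitting
   periodic lattice (modal row/column phase). The snap exists because
   the recorded frame truncates the optical field: a focus sitting on
   the image border can shift its raw maximum by one pixel under any
   boundary convention, while the scan geometry guarantees periodicity.
   `snapToLattice = FALSE` exposes the raw maxima (that is what the
   acceptance measurement of the modal 16 px spacing uses, so the
   spacing is genuinely measured rather than assumed). With oracle foci
   and no noise, detected-mode and oracle-mode reconstructions agree to
   $10^{-6}$.
2. **Pinholing.** Each pixel is multiplied by a Gaussian mask of width
   `pinholeSigmaPx` centered on its *nearest* focus — a global Voronoi
   partition rather than fixed square crops, which is equivalent at the
   lattice spacings used and avoids overlap bookkeeping. The default
   width equals the emission PSF σ (the ~1-resel digital pinhole of the
   image-scanning convention); the width is not physically prescribed.
   Distance ties go to the focus with the smaller (row, col) — a purely
   deterministic tie-break.
3. **Local scaling / pixel reassignment.** On a doubled canvas, pixel
   $x$ assigned to focus $b$ deposits its value at integer position
   $x + b$, i.e. at $(x+b)/2$ in original units — half the distance
   toward the focus, the geometry that doubles resolution. Integer
   deposition conserves flux exactly, and the implementation is held to
   a brute-force oracle bit-for-bit.
4. **Summing and deconvolution.** Frames are summed pixelwise and
   deconvolved with multiplicative Richardson–Lucy updates using the
   emission PSF resampled at half the pixel size (σ doubles in pixel
   units on the doubled grid). The iteration count is not prescribed
   (the original pipeline delegates to an external plugin); the default
   is 20, configurable, with `nIter = 0` an exact identity. A ratio
   floor of $10^{-12}$ guards empty divisions.

For network training targets the reconstruction runs *per frame*
(pinhole + reassign + per-frame deconvolution by default), because the
network maps single frames; the baseline stack reconstruction
deconvolves once after summation. Both placements are supported by an
options flag.

## The network

A four-stage encoder (two 3×3 conv + BatchNorm + ReLU blocks per stage,
2×2 max-pool between stages; the fourth stage is the bottleneck, so
there are three pools and three skips — the stage indexing runs to four
while the text convention speaks of "three downsampling blocks") and a
symmetric three-stage decoder. Decoder stages upsample by
nearest-neighbor interpolation followed by a 1×1 convolution that halves
the channels (transposed convolution is available as an ablation),
concatenate with the dense-connection transform of the matching encoder
feature, and apply two conv-BN-ReLU blocks. Dropout (p = 0.5) sits
between successive upsampling stages. The output block upsamples once
more and maps the final features to one nonnegative channel through a
3×3 and then a 1×1 convolution ("two convolutional blocks with different
kernel sizes" — the minimal consistent pair) with a final ReLU, so a
W×H input yields a 2W×2H image.

Dense connections follow the DenseNet pattern: an initial 3×3
convolution at the input width, then $L$ bottleneck layers
(BN-ReLU-conv1×1 to $4k$ channels, BN-ReLU-conv3×3 to $k$), each
concatenated with all predecessors, and a transition
(BN-ReLU-conv1×1-BN-ReLU) restoring the input channel count. $L = 0$ is
an exact pass-through. The three skip configurations default to
$\{L=0\}$ on the deepest skip, $\{L=3, k=32\}$ in the middle and
$\{L=5, k=8\}$ on the shallowest — the assignment of configuration to
depth is not prescribed, so it is a documented, configurable default.
Encoder widths default to 32–64–128–256 (doubling convention; only the
32 channels entering the output block are pinned). Weights use seeded
He-normal initialisation; biases start at zero.

Because no deep-learning framework exists for R in this environment,
the package authors its own engine: a reverse-mode tape autodiff over
`[H, W, C, N]` arrays with Rcpp/Armadillo kernels — im2col+GEMM
convolution with direct-stencil (3×3, small channel counts) and
pointwise-GEMM (1×1) fast paths, fused BatchNorm+ReLU forward/backward,
max/average pooling, nearest and zero-insertion upsampling, and
separable Gaussian window convolutions for the loss. Gradients of every
layer type are verified against central finite differences (relative
error ~$10^{-9}$) in the test suite. BatchNorm running statistics are
warm-started from the first batch instead of the conventional
mean 0 / variance 1, then tracked with momentum 0.1: after very short
training runs the evaluation-mode network is then faithful to the
training-mode network, which matters for the minutes-long CPU studies
the package runs routinely.

## Loss and training

$L = \alpha\,(1-\mathrm{MS\text{-}SSIM}(Y,\bar Y)) + (1-\alpha)\,
\overline{G \otimes |Y-\bar Y|}$ with $\alpha = 0.75$ and a 9×9,
σ = 1.5 Gaussian $G$. Two interpretation points:

* The "point-wise multiplication" of the L1 error with $G$ is realised
  as convolution with the unit-sum kernel before averaging (a literal
  9×9 pointwise product with a full-size image is dimensionally
  impossible); a constant error $e$ therefore contributes exactly
  $(1-\alpha)e$.
* MS-SSIM multiplies the mean contrast–structure terms of scales
  $1..M-1$ with the mean full SSIM (luminance × contrast–structure) at
  the coarsest scale, all under the β exponents — the composition used
  by the standard implementations, with the property that $M = 1$,
  $\beta = 1$ reduces *exactly* to single-scale SSIM (the suite checks
  this against an independently coded sliding-window oracle). Windows
  are 11×11 σ = 1.5 Gaussians on the valid region; scales are linked by
  2×2 mean pooling; $C_1 = (0.01)^2$, $C_2 = (0.03)^2$ on the
  normalised unit range. $M = 5$ needs ≥ 176 px; smaller patches reduce
  $M$ automatically with β renormalised to the same total. Fractional
  exponents clamp their base at $10^{-6}$; an exponent of exactly 1 is
  applied verbatim so negative SSIM values survive the reduction case.

Training pairs couple a noisy raw frame with the conventional
single-frame reconstruction of the same noiseless frame; spoke lobe
counts are randomised per sample (12–64) and mixed with filament/blob
phantoms. The fewer-frames scheme renders, for every step-2 scan
position, four frames at lattice offsets (0,0), (0,1), (1,0), (1,1);
the input is the noisy (0,0) frame and the target the sum of the four
single-frame reconstructions. The defocus scheme adds an out-of-focus
emission path (3 µm) to the input only and raises the Poisson noise.
All pairs are normalised by the dataset maximum (stored in the model and
reapplied at inference — test-time handling is otherwise unspecified),
split 70/30 by a seeded shuffle, and optimised with Adam (lr $10^{-3}$,
batch 8 by default); the best-validation parameter set and BatchNorm
statistics are retained. Stack inference feeds each frame through the
network in evaluation mode and sums the outputs, mirroring the
frame-wise definition of the training targets.

## Evaluation

PSNR, NRMSE, MSE and SSIM quantize each image pair to a shared 0–255
range first (round-half-even), because that 8-bit convention is what
makes reported values comparable: PSNR uses MAX = 255 (the printed
PSNR/MSE pairs of the original tables are mutually consistent only with
the MAX term — the suite checks $20\log_{10}(255/\sqrt{188.920})$
against the printed 25.437 dB within 0.1 dB), NRMSE divides by the
range of the first image, SSIM uses 11×11 σ = 1.5 windows with
$c_1 = (0.01 \cdot 255)^2$, $c_2 = (0.03 \cdot 255)^2$. The
resolution-scaled error map downsamples the 2W×2H image by 2×2 block
mean and fits a Gaussian blur σ ∈ [0, 10] px (golden-section, 40
shrinks, with the σ = 0 endpoint compared explicitly) with a
closed-form affine intensity map against the reference; RSE is the RMS
mismatch and RSP the Pearson coefficient. The exact resolution-scaling
function of the reference plugin is unpublished; this Gaussian + affine
surrogate is the documented stand-in, validated by construct-and-recover
tests. FWHM interpolates the half-maximum crossings linearly and
refuses profiles without both crossings.

## Scaled-down studies and what they show

The training studies in the test suite run at desk scale: 200 pairs on
64×64 frames (targets 128×128), 10 epochs, batch 8, Adam $10^{-3}$, ten
training seeds against a fixed dataset; the fewer-frames study
fine-tunes the recovered model on 96 shifted-lattice pairs for 6 epochs
and compares against the step-2 conventional reconstruction of a
held-out phantom, with the full step-1 conventional reconstruction as
reference. At this scale the full-width architecture is unnecessarily
expensive, so the studies use `compactNetworkConfig()`: the same
topology with encoder widths 4–32, shallow dense skips (one and two
bottleneck layers at growth rates 8 and 4), and no dropout (short
schedules leave no room for heavy regularisation). These
sizes were fixed from throughput measurements of the engine before the
studies were run, and are stated here as the package's own choice of
study size.

The generator emulates thin, static, single-channel samples under an
ideal scan: Gaussian PSFs, perfectly periodic lattices, shot + read
noise. It does not emulate aberrations, sample motion, photobleaching,
background autofluorescence, camera fixed-pattern noise, or 3D
structure beyond the two-plane defocus mixture — so passing studies
demonstrate that the pipeline and optimiser behave correctly under the
stated model, not that a trained model transfers to any particular
microscope's data.

## Known limitations

* Double-precision throughout; the engine is single-threaded and sized
  for desk-scale studies, not for training the full-width network on
  thousands of pairs.
* 2D only; the defocus mixture is a two-plane surrogate for thick
  samples, not an axial model.
* Richardson–Lucy is the plain multiplicative scheme without
  regularisation or acceleration.
* Lattice detection assumes the nominal spacing is known (it is, for a
  calibrated scan); it estimates only the lattice phase.
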