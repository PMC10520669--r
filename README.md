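# msimsr

Simulation, reconstruction and learned super-resolution for multifocal
structured illumination microscopy (MSIM), in R.

MSIM parallelises point-scanning microscopy: a sparse square lattice of
excitation foci (period 16 px by default) is raster-scanned across the
sample and a camera records one raw frame per lattice position — 256
frames for a full unit-step scan. The classical reconstruction recovers a
twofold resolution gain in four steps: **pinholing** (a digital Gaussian
mask around each focus rejects out-of-focus light), **local scaling**
(pixel reassignment: each pixel's signal is moved half the distance
toward its nearest focus, realised on a 2W×2H grid), **summing** over
frames, and **Richardson–Lucy deconvolution**. `msimsr` implements this
pipeline end to end, together with a dense-skip encoder–decoder network
that learns the direct mapping from a raw multifocal frame to its
super-resolution counterpart, so that a full stack is reconstructed by
per-frame inference and summation — and, in a fewer-frames mode, from a
quarter of the raw data (scan step 2, with training targets assembled
from four shifted-lattice reconstructions).

The forward model is

- sample: ρ(r, θ) ∝ 1 + cos(48 θ) (spoke phantom; the lobe count is the
  spoke-width control), plus random filament/blob phantoms,
- illumination: p_i(u) = Σ_j δ(r − b_ij) ⊗ h_ex(u) over the scanned
  lattice positions b_ij,
- image formation: I_i(x) = ∫ p_i(u) s(u) h_em(x − u) du with Gaussian
  PSFs (σ = 0.21 λ/NA; defaults λ = 560 nm, NA = 1.1, 130 nm pixels),
  corrupted by Poisson shot noise and additive Gaussian read noise.

Training minimises L = α (1 − MS-SSIM(Y, Ȳ)) + (1 − α) ‖G ⊗ |Y − Ȳ|‖₁
with α = 0.75 and a 9×9, σ = 1.5 Gaussian G, using Adam. Because no deep
learning framework is available in R, the package ships its own compact
reverse-mode autodiff engine (Rcpp/Armadillo kernels for convolution,
pooling, fused BatchNorm+ReLU); gradients are verified against finite
differences in the test suite. Evaluation utilities cover PSNR, NRMSE,
MSE and SSIM on the field-standard 8-bit convention, SQUIRREL-style
resolution-scaled error maps (RSE/RSP), and FWHM profiling.

## Worked example

```r
library(msimsr)

spoke <- makeSpokeSample(64, nLobes = 16)       # ground truth, peak 1
ex <- makeGaussianPsf(560, 1.1, 130, role = "excitation")
em <- makeGaussianPsf(560, 1.1, 130, role = "emission")
sched <- buildSchedule(c(64, 64), spacingPx = 16, stepPx = 1)
sched
#> IlluminationSchedule 64x64 px, spacing=16 step=1 -> 256 frames (16 foci/frame)

stack <- simulateStack(spoke, sched, ex, em,
                       noise = list(gaussSigma = 0.002, photonScale = 500),
                       seed = 7)
wf <- widefield(stack)                          # diffraction-limited sum
sr <- reconstructConventional(stack, em)
sr
#> SRImage 128x128 px (65.0 nm/px), provenance=conventional, 256 frames used

# resolution gain on a sub-resolution bead
bead <- simulateStack(msimsr:::beadSample(64), sched, ex, em)
wfB <- widefield(bead)
srB <- srMatrix(reconstructConventional(bead, em))
pk <- which(wfB == max(wfB), arr.ind = TRUE)[1, ]
fwhm(wfB[pk[1], ], 130)                         # wide-field FWHM, nm
#> [1] 248.7765
pk2 <- which(srB == max(srB), arr.ind = TRUE)[1, ]
fwhm(srB[pk2[1], ], 65)                         # reconstructed FWHM, nm
#> [1] 69.33399
```

The wide-field bead profile measures ≈249 nm FWHM — the emission PSF
itself (2.355 σ with σ = 0.21 λ/NA ≈ 107 nm). Pinholing plus pixel
reassignment narrows it by the geometric √2, and the 20 Richardson–Lucy
iterations sharpen the isolated point emitter well beyond the nominal
twofold gain (deconvolution of an isolated bead converges toward a
point); structured samples settle near the twofold figure.

Training and inference follow the same surface:

```r
ds <- makeTrainingPairs(sched, ex, em, nPairs = 200, seed = 101)
model <- msimNetwork(compactNetworkConfig(), seed = 1)
fit <- trainNetwork(model, ds, trainConfig(epochs = 10, seed = 1))
deep <- inferStack(fit$model, stack)            # provenance "deep"
```

A command-line launcher (`inst/cli/msimsr`) exposes `simulate`,
`reconstruct`, `make-dataset`, `train`, `infer`, `evaluate` and
`fixtures` subcommands over the same functions.

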