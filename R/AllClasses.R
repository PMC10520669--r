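#' @useDynLib msimsr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' SampleMap: ground-truth fluorophore density on a pixel grid
#'
#' A `SampleMap` holds a two-dimensional, nonnegative fluorescence density
#' \eqn{s(u)} sampled at pixel centers, together with the physical pixel size.
#' It is the ground truth from which raw multifocal frames are simulated.
#'
#' @slot density numeric matrix, finite and nonnegative.
#' @slot pixelSizeNm positive scalar, physical size of one pixel in nanometres.
#' @slot descriptor free-text provenance string (e.g. `"spoke n_lobes=48"`).
#' @export
setClass("SampleMap",
  representation(density = "matrix", pixelSizeNm = "numeric",
                 descriptor = "character"),
  prototype(pixelSizeNm = 130, descriptor = ""))

setValidity("SampleMap", function(object) {
  d <- object@density
  if (!is.numeric(d)) return("density must be numeric")
  if (any(!is.finite(d))) return("density must be finite")
  if (any(d < 0)) return("density must be nonnegative")
  if (nrow(d) < 16 || ncol(d) < 16) return("density grid must be at least 16x16")
  if (length(object@pixelSizeNm) != 1 || object@pixelSizeNm <= 0)
    return("pixelSizeNm must be a positive scalar")
  TRUE
})

#' PsfKernel: discretised Gaussian point spread function
#'
#' A normalised, centrosymmetric 2D Gaussian kernel standing for the
#' excitation PSF \eqn{h_{ex}} or the emission PSF \eqn{h_{em}}, with an
#' optional defocus that widens the in-focus width monotonically.
#'
#' @slot kernel odd-sided numeric matrix summing to 1.
#' @slot sigmaPx Gaussian width in pixels.
#' @slot wavelengthNm,na,defocusUm physical parameters the kernel was built from.
#' @slot role `"excitation"` or `"emission"`.
#' @export
setClass("PsfKernel",
  representation(kernel = "matrix", sigmaPx = "numeric",
                 wavelengthNm = "numeric", na = "numeric",
                 defocusUm = "numeric", role = "character"))

setValidity("PsfKernel", function(object) {
  k <- object@kernel
  if (nrow(k) != ncol(k) || nrow(k) %% 2 != 1)
    return("kernel must be square with odd side length")
  if (any(k < 0)) return("kernel must be nonnegative")
  if (abs(sum(k) - 1) > 1e-9) return("kernel must sum to 1 within 1e-9")
  if (max(abs(k - k[nrow(k):1, ncol(k):1])) > 1e-12)
    return("kernel must be centrosymmetric")
  if (!object@role %in% c("excitation", "emission"))
    return("role must be 'excitation' or 'emission'")
  TRUE
})

#' IlluminationSchedule: scanned lattice of excitation foci
#'
#' Describes the square lattice of laser foci (period `spacingPx`) and the
#' raster scan that shifts the lattice by `stepPx` between frames. With a
#' scan step of 1 the offsets tile the full unit cell, so
#' `nFrames == spacingPx^2`; a step of `q` gives `(spacingPx/q)^2` frames.
#'
#' Coordinates are 1-based `(row, col)` pixel centers.
#'
#' @slot frameShape integer `(H, W)`.
#' @slot spacingPx,stepPx lattice period and scan step, pixels.
#' @slot nFrames number of frames `m`.
#' @slot scanOffsets `nFrames x 2` matrix of per-frame `(dy, dx)` offsets
#'   (0-based shifts of the lattice origin, in pixels).
#' @slot foci list of `n x 2` matrices of focus `(row, col)` positions.
#' @export
setClass("IlluminationSchedule",
  representation(frameShape = "integer", spacingPx = "integer",
                 stepPx = "integer", nFrames = "integer",
                 scanOffsets = "matrix", foci = "list"))

setValidity("IlluminationSchedule", function(object) {
  if (length(object@frameShape) != 2) return("frameShape must be length 2")
  if (object@nFrames != length(object@foci))
    return("foci list length must equal nFrames")
  if (nrow(object@scanOffsets) != object@nFrames)
    return("scanOffsets must have one row per frame")
  for (f in object@foci) {
    if (any(f[, 1] < 1 | f[, 1] > object@frameShape[1] |
            f[, 2] < 1 | f[, 2] > object@frameShape[2]))
      return("all foci must lie inside frameShape")
  }
  TRUE
})

#' RawStack: simulated or acquired raw multifocal frames
#'
#' The stack of `m` raw camera frames \eqn{I_i(x)}, one per illumination
#' pattern, with acquisition metadata and noise provenance.
#'
#' @slot frames numeric array `H x W x m`, finite and nonnegative.
#' @slot schedule the [IlluminationSchedule-class] the stack was scanned with.
#' @slot pixelSizeNm physical pixel size, nanometres.
#' @slot noise list with `gaussSigma` (additive read noise, >= 0) and
#'   `photonScale` (photons per intensity unit, or `NA` for no shot noise).
#' @slot seed integer seed the corruption was drawn with, or `NA`.
#' @export
setClass("RawStack",
  representation(frames = "array", schedule = "IlluminationSchedule",
                 pixelSizeNm = "numeric", noise = "list", seed = "numeric"))

setValidity("RawStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3) return("frames must be a 3D array (H x W x m)")
  if (d[3] != object@schedule@nFrames)
    return("frame count must equal schedule nFrames")
  if (any(d[1:2] != object@schedule@frameShape))
    return("frame shape must match schedule frameShape")
  if (any(!is.finite(object@frames))) return("frames must be finite")
  if (any(object@frames < 0)) return("frames must be nonnegative")
  TRUE
})

#' FociSet: per-frame illumination focus positions
#'
#' Focus coordinates used by the conventional reconstruction, either taken
#' from the simulation schedule (`"oracle"`) or found by lattice detection
#' on the raw frames (`"detected"`).
#'
#' @slot foci list of `n x 2` matrices of `(row, col)` positions (may be
#'   fractional for detected maxima).
#' @slot detectionMode `"oracle"` or `"detected"`.
#' @export
setClass("FociSet",
  representation(foci = "list", detectionMode = "character"))

setValidity("FociSet", function(object) {
  if (!object@detectionMode %in% c("oracle", "detected"))
    return("detectionMode must be 'oracle' or 'detected'")
  TRUE
})

#' SRImage: a super-resolution reconstruction on the doubled grid
#'
#' Holds a `2H x 2W` nonnegative image whose pixel size is half the raw
#' pixel size, with provenance recording how it was produced.
#'
#' @slot image numeric matrix, `2H x 2W`.
#' @slot pixelSizeNm pixel size of the doubled grid (half the raw size).
#' @slot provenance one of `"conventional"`, `"deep"`, `"partial-frame sum"`.
#' @slot nFramesUsed number of raw frames that contributed.
#' @export
setClass("SRImage",
  representation(image = "matrix", pixelSizeNm = "numeric",
                 provenance = "character", nFramesUsed = "integer"))

setValidity("SRImage", function(object) {
  if (any(!is.finite(object@image))) return("image must be finite")
  if (any(object@image < 0)) return("image must be nonnegative")
  if (!object@provenance %in% c("conventional", "deep", "partial-frame sum"))
    return("unknown provenance")
  TRUE
})
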