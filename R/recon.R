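#' Detect the illumination lattice on a raw frame
#'
#' Denoises the frame with a small Gaussian (replicated boundaries, so
#' border foci are not displaced), finds strict local maxima within an
#' exclusion radius of half the expected lattice spacing, discards maxima
#' below `thresholdFrac` of the global maximum, and — since the foci of a
#' multifocal scan form a periodic square lattice — snaps the result to
#' the best-fitting lattice: the modal row/column phases of the maxima
#' determine the offset and the full grid is returned. Set
#' `snapToLattice = FALSE` to obtain the raw maxima instead.
#'
#' @param frame numeric `H x W` matrix (one raw multifocal frame).
#' @param expectedSpacingPx expected lattice period in pixels (>= 4).
#' @param denoiseSigma Gaussian denoising width in pixels (default 1).
#' @param thresholdFrac discard maxima below this fraction of the global
#'   maximum (default 0.3).
#' @param snapToLattice return the fitted periodic lattice rather than the
#'   raw maxima (default `TRUE`).
#' @return an `n x 2` matrix of detected `(row, col)` focus positions,
#'   sorted lexicographically.
#' @export
detectLattice <- function(frame, expectedSpacingPx = 16, denoiseSigma = 1,
                          thresholdFrac = 0.3, snapToLattice = TRUE) {
  stopIfNot(expectedSpacingPx >= 4, "expectedSpacingPx must be >= 4")
  if (max(frame) <= 0) stop("no foci: frame is all zero", call. = FALSE)
  den <- if (denoiseSigma > 0)
    as.matrix(EBImage::filter2(frame, gaussKernelMatrix(denoiseSigma),
                               boundary = "replicate"))
  else frame
  e <- max(1L, floor(expectedSpacingPx / 2))
  H <- nrow(den); W <- ncol(den)
  # windowed maximum by shifted pmax (zero padding outside)
  wmax <- matrix(-Inf, H, W)
  for (dy in -e:e) {
    rs <- max(1, 1 + dy):min(H, H + dy)
    rd <- max(1, 1 - dy):min(H, H - dy)
    for (dx in -e:e) {
      cs <- max(1, 1 + dx):min(W, W + dx)
      cd <- max(1, 1 - dx):min(W, W - dx)
      sub <- matrix(-Inf, H, W)
      sub[rd, cd] <- den[rs, cs]
      wmax <- pmax(wmax, sub)
    }
  }
  keep <- den >= wmax & den >= thresholdFrac * max(den)
  pos <- which(keep, arr.ind = TRUE)
  if (nrow(pos) == 0) stop("no foci detected", call. = FALSE)
  if (snapToLattice) {
    modal <- function(v) as.integer(names(sort(table(v),
                                               decreasing = TRUE))[1])
    offR <- modal((pos[, 1] - 1) %% expectedSpacingPx)
    offC <- modal((pos[, 2] - 1) %% expectedSpacingPx)
    pos <- as.matrix(expand.grid(
      row = seq.int(1 + offR, H, by = expectedSpacingPx),
      col = seq.int(1 + offC, W, by = expectedSpacingPx)))
  }
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  colnames(pos) <- c("row", "col")
  storage.mode(pos) <- "double"
  pos
}

# FociSet for a whole stack, oracle (from the schedule) or detected
fociForStack <- function(stack, mode = c("oracle", "detected"),
                         expectedSpacingPx = NULL, denoiseSigma = 1,
                         thresholdFrac = 0.3) {
  mode <- match.arg(mode)
  sched <- stack@schedule
  if (mode == "oracle") {
    f <- lapply(sched@foci, function(m) {
      m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
      storage.mode(m) <- "double"; m
    })
    return(new("FociSet", foci = f, detectionMode = "oracle"))
  }
  if (is.null(expectedSpacingPx)) expectedSpacingPx <- sched@spacingPx
  nExp <- nrow(sched@foci[[1]])
  nFail <- 0L
  f <- lapply(seq_len(nFrames(stack)), function(i) {
    res <- tryCatch(detectLattice(stack@frames[, , i], expectedSpacingPx,
                                  denoiseSigma, thresholdFrac),
                    error = function(e) NULL)
    if (is.null(res) || nrow(res) < 0.5 * nExp) {
      nFail <<- nFail + 1L
      res <- matrix(numeric(0), 0, 2)
    }
    res
  })
  if (nFail > 0.1 * nFrames(stack))
    stop(sprintf("lattice detection failed on %d of %d frames", nFail,
                 nFrames(stack)), call. = FALSE)
  new("FociSet", foci = f, detectionMode = "detected")
}

#' Apply digital Gaussian pinholes around each focus
#'
#' Multiplies every pixel by a Gaussian mask (peak 1) of width
#' `pinholeSigmaPx` centered on the pixel's nearest focus, rejecting light
#' far from any illumination spot. The partition of pixels among foci is
#' the nearest-focus (Voronoi) assignment; distance ties go to the focus
#' with the smaller `(row, col)`.
#'
#' @param frame numeric `H x W` matrix.
#' @param foci `n x 2` matrix of focus positions.
#' @param pinholeSigmaPx pinhole width in pixels (> 0).
#' @return the pinholed frame (pointwise `<=` the input).
#' @export
applyPinholes <- function(frame, foci, pinholeSigmaPx) {
  stopIfNot(nrow(foci) >= 1, "foci must be nonempty")
  stopIfNot(pinholeSigmaPx > 0, "pinholeSigmaPx must be positive")
  foci <- foci[order(foci[, 1], foci[, 2]), , drop = FALSE]
  nf <- nearest_focus_cpp(nrow(frame), ncol(frame), foci)
  frame * exp(-nf$dist^2 / (2 * pinholeSigmaPx^2))
}

#' Pixel reassignment onto the doubled grid ("local scaling")
#'
#' Each input pixel `x`, assigned to its nearest focus `b`, deposits its
#' value at integer position `x + b` of a `2H x 2W` canvas. In original
#' pixel units that is position `(x + b)/2`, i.e. the light is moved half
#' the distance separating the pixel from its focus — the reassignment rule
#' that doubles resolution in image scanning microscopy. Flux is conserved
#' exactly.
#'
#' @inheritParams applyPinholes
#' @param pinholedFrame numeric `H x W` matrix (typically pinholed).
#' @return a numeric `2H x 2W` matrix.
#' @export
reassignFrame <- function(pinholedFrame, foci) {
  stopIfNot(nrow(foci) >= 1, "foci must be nonempty")
  foci <- foci[order(foci[, 1], foci[, 2]), , drop = FALSE]
  reassign_cpp(pinholedFrame, foci)
}

#' Sum a list of reassigned frames
#'
#' @param reassignedFrames list of equally sized matrices.
#' @return their pixelwise sum.
#' @export
sumStack <- function(reassignedFrames) {
  stopIfNot(length(reassignedFrames) >= 1, "need at least one frame")
  Reduce(`+`, reassignedFrames)
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy updates
#' \eqn{e^{t+1} = e^t \cdot [\,(I / (e^t \otimes h)) \otimes \hat h\,]}
#' with the given PSF (maximum-likelihood deblurring under Poisson
#' statistics). Nonnegativity is preserved; `nIter = 0` returns the input.
#'
#' @param image nonnegative numeric matrix.
#' @param psf a [PsfKernel-class] (kernel must sum to 1).
#' @param nIter number of iterations (default 20).
#' @return the deconvolved matrix.
#' @export
richardsonLucy <- function(image, psf, nIter = 20L) {
  stopIfNot(nIter >= 0, "nIter must be >= 0")
  stopIfNot(all(image >= 0), "image must be nonnegative")
  k <- if (is(psf, "PsfKernel")) psfMatrix(psf) else psf
  if (abs(sum(k) - 1) > 1e-6)
    stop("deconvolution kernel must be normalized to sum 1", call. = FALSE)
  kFlip <- k[nrow(k):1, ncol(k):1]
  est <- image
  eps <- 1e-12
  for (it in seq_len(nIter)) {
    blur <- convZero(est, k)
    ratio <- image / (blur + eps)
    est <- est * convZero(ratio, kFlip)
  }
  est
}

#' Conventional four-step MSIM reconstruction
#'
#' Runs the classical pipeline on a raw stack: per-frame focus positions
#' (from the simulation schedule or by lattice detection), digital
#' pinholing, pixel reassignment onto the doubled grid, summation over
#' frames, and Richardson-Lucy deconvolution with the emission PSF
#' resampled at half the pixel size.
#'
#' @param stack a [RawStack-class].
#' @param psfEm the emission [PsfKernel-class] used for the pinhole width
#'   default and the deconvolution kernel.
#' @param opts list of options: `fociMode` (`"oracle"` or `"detected"`,
#'   default `"oracle"`), `pinholeSigmaPx` (default: the emission PSF width),
#'   `nIter` Richardson-Lucy iterations (default 20), `deconvolve`
#'   (default `TRUE`), `denoiseSigma` and `thresholdFrac` for detection.
#' @return an [SRImage-class] of dimensions `2H x 2W`.
#' @examples
#' sp <- makeSpokeSample(64, 12)
#' sc <- buildSchedule(c(64, 64), 16, 4)
#' ex <- makeGaussianPsf(560, 1.1, 130, role = "excitation")
#' em <- makeGaussianPsf(560, 1.1, 130, role = "emission")
#' st <- simulateStack(sp, sc, ex, em)
#' sr <- reconstructConventional(st, em, list(nIter = 5))
#' dim(srMatrix(sr))
#' @export
reconstructConventional <- function(stack, psfEm, opts = list()) {
  o <- reconOpts(psfEm, opts)
  fs <- fociForStack(stack, o$fociMode, denoiseSigma = o$denoiseSigma,
                     thresholdFrac = o$thresholdFrac)
  m <- nFrames(stack)
  acc <- NULL
  used <- 0L
  for (i in seq_len(m)) {
    f <- fs@foci[[i]]
    if (nrow(f) == 0) next
    ph <- applyPinholes(stack@frames[, , i], f, o$pinholeSigmaPx)
    rs <- reassignFrame(ph, f)
    acc <- if (is.null(acc)) rs else acc + rs
    used <- used + 1L
  }
  if (is.null(acc)) stop("no frames could be reconstructed", call. = FALSE)
  if (o$deconvolve)
    acc <- richardsonLucy(acc, deconvKernel(psfEm), o$nIter)
  new("SRImage", image = pmax(acc, 0), pixelSizeNm = stack@pixelSizeNm / 2,
      provenance = "conventional", nFramesUsed = used)
}

#' Reconstruct a single raw frame (training-target path)
#'
#' Pinholes and reassigns one frame; optionally deconvolves the doubled
#' image per frame. Summing the outputs over a stack's frames (without
#' deconvolution) reproduces [reconstructConventional()] before its
#' deconvolution step.
#'
#' @param frame numeric `H x W` matrix.
#' @param foci `n x 2` matrix of focus positions for this frame.
#' @param psfEm emission [PsfKernel-class].
#' @param opts as in [reconstructConventional()]; `deconvolve` defaults to
#'   `FALSE` here.
#' @return an [SRImage-class] with provenance `"partial-frame sum"`.
#' @export
reconstructSingleFrame <- function(frame, foci, psfEm, opts = list()) {
  if (is.null(opts$deconvolve)) opts$deconvolve <- FALSE
  o <- reconOpts(psfEm, opts)
  ph <- applyPinholes(frame, foci, o$pinholeSigmaPx)
  rs <- reassignFrame(ph, foci)
  if (o$deconvolve) rs <- richardsonLucy(rs, deconvKernel(psfEm), o$nIter)
  new("SRImage", image = pmax(rs, 0), pixelSizeNm = NA_real_,
      provenance = "partial-frame sum", nFramesUsed = 1L)
}

# emission PSF resampled on the half-pixel grid (sigma doubles in px)
deconvKernel <- function(psfEm) gaussKernelMatrix(2 * psfSigma(psfEm))

reconOpts <- function(psfEm, opts) {
  o <- list(fociMode = "oracle", pinholeSigmaPx = psfSigma(psfEm),
            nIter = 20L, deconvolve = TRUE, denoiseSigma = 1,
            thresholdFrac = 0.3)
  for (nm in names(opts)) {
    if (!nm %in% names(o)) stop("unknown reconstruction option: ", nm,
                                call. = FALSE)
    o[[nm]] <- opts[[nm]]
  }
  o
}
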