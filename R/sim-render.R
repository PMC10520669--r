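#' Image formation for one raw multifocal frame
#'
#' Implements the incoherent imaging model
#' \eqn{I_i(x) = \int p_i(u)\, s(u)\, h_{em}(x-u)\, du}: the illumination
#' pattern is multiplied pointwise with the fluorophore density and the
#' product is convolved with the emission PSF (zero-padded boundaries,
#' FFT path).
#'
#' @param sample a [SampleMap-class].
#' @param pattern `H x W` illumination pattern from [renderPattern()].
#' @param psfEm emission [PsfKernel-class].
#' @return a numeric `H x W` matrix (noiseless frame).
#' @export
renderRawFrame <- function(sample, pattern, psfEm) {
  d <- sampleDensity(sample)
  stopIfNot(all(dim(d) == dim(pattern)), "sample and pattern shapes differ")
  convZero(pattern * d, psfMatrix(psfEm))
}

#' Focused + defocused mixture frame for thick-sample training
#'
#' Renders the same excited sample through an in-focus emission PSF and a
#' defocused one and sums the two results, emulating in-focus structure
#' embedded in out-of-focus haze as encountered when imaging deep inside
#' thick samples.
#'
#' @inheritParams renderRawFrame
#' @param psfEmFocused,psfEmDefocused in-focus and defocused emission PSFs.
#' @return a numeric `H x W` matrix.
#' @export
renderDefocusMixture <- function(sample, pattern, psfEmFocused,
                                 psfEmDefocused) {
  renderRawFrame(sample, pattern, psfEmFocused) +
    renderRawFrame(sample, pattern, psfEmDefocused)
}

#' Poisson and Gaussian corruption of a frame
#'
#' Applies shot noise (a Poisson draw on `photonScale * frame`, divided
#' back by `photonScale`) followed by additive Gaussian read noise of
#' standard deviation `gaussSigma`, then clips at zero (detector counts are
#' nonnegative). Deterministic under `seed`.
#'
#' @param frame nonnegative numeric matrix.
#' @param gaussSigma read-noise standard deviation (intensity units, >= 0).
#' @param photonScale photons per intensity unit (> 0), or `NA` to disable
#'   shot noise.
#' @param seed integer seed or `NULL`.
#' @return a corrupted matrix of the same shape, minimum >= 0.
#' @export
corruptFrame <- function(frame, gaussSigma = 0, photonScale = NA,
                         seed = NULL) {
  stopIfNot(gaussSigma >= 0, "gaussSigma must be >= 0")
  stopIfNot(is.na(photonScale) || photonScale > 0,
            "photonScale must be positive or NA")
  withSeed(seed, {
    out <- frame
    if (!is.na(photonScale))
      out <- matrix(stats::rpois(length(out), photonScale * out) / photonScale,
                    nrow(out), ncol(out))
    if (gaussSigma > 0)
      out <- out + matrix(stats::rnorm(length(out), 0, gaussSigma),
                          nrow(out), ncol(out))
    pmax(out, 0)
  })
}

#' Simulate a full raw multifocal stack
#'
#' Renders one raw frame per schedule entry (pattern, excitation of the
#' sample, emission blur, optional defocus mixture) and corrupts frame `i`
#' with seed `seed + i`, assembling a [RawStack-class].
#'
#' @param sample a [SampleMap-class].
#' @param schedule an [IlluminationSchedule-class] matching the sample grid.
#' @param psfEx,psfEm excitation and emission [PsfKernel-class] objects.
#' @param noise list with `gaussSigma` and `photonScale` as in
#'   [corruptFrame()]; the default is noiseless.
#' @param seed integer base seed (or `NULL` for no noise seeding).
#' @param defocusPsf optional defocused emission PSF; when given, frames are
#'   rendered with [renderDefocusMixture()].
#' @return a [RawStack-class].
#' @examples
#' sp <- makeSpokeSample(64, 12)
#' sc <- buildSchedule(c(64, 64), 16, 4)
#' ex <- makeGaussianPsf(560, 1.1, 130, role = "excitation")
#' em <- makeGaussianPsf(560, 1.1, 130, role = "emission")
#' st <- simulateStack(sp, sc, ex, em)
#' nFrames(st)
#' @export
simulateStack <- function(sample, schedule, psfEx, psfEm,
                          noise = list(gaussSigma = 0, photonScale = NA),
                          seed = NULL, defocusPsf = NULL) {
  d <- sampleDensity(sample)
  stopIfNot(all(dim(d) == schedule@frameShape),
            "sample grid must match schedule frameShape")
  if (is.null(noise$gaussSigma)) noise$gaussSigma <- 0
  if (is.null(noise$photonScale)) noise$photonScale <- NA
  m <- schedule@nFrames
  frames <- array(0, c(schedule@frameShape[1], schedule@frameShape[2], m))
  for (i in seq_len(m)) {
    pat <- renderPattern(schedule, i, psfEx)
    fr <- if (is.null(defocusPsf)) renderRawFrame(sample, pat, psfEm)
          else renderDefocusMixture(sample, pat, psfEm, defocusPsf)
    if (noise$gaussSigma > 0 || !is.na(noise$photonScale))
      fr <- corruptFrame(fr, noise$gaussSigma, noise$photonScale,
                         seed = if (is.null(seed)) NULL else seed + i)
    frames[, , i] <- fr
  }
  new("RawStack", frames = frames, schedule = schedule,
      pixelSizeNm = pixelSizeNm(sample), noise = noise,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Wide-field image of a stack
#'
#' The pixelwise sum of all raw multifocal frames: the diffraction-limited
#' baseline an ordinary camera exposure would record.
#'
#' @param stack a [RawStack-class].
#' @return a numeric `H x W` matrix.
#' @export
widefield <- function(stack) {
  fr <- stackFrames(stack)
  stopIfNot(dim(fr)[3] >= 1, "stack is empty")
  rowSums(fr, dims = 2)
}
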