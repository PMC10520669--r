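#' Build a scanned multifocal illumination schedule
#'
#' Lays out a square lattice of laser foci with period `spacingPx` and
#' scans it in raster order with step `stepPx` in both axes. With
#' `stepPx = 1` the scan visits every offset of the `spacingPx x spacingPx`
#' unit cell exactly once (`spacingPx^2` frames, e.g. 256 frames for the
#' default 16 px lattice); `stepPx = q` visits every `q`-th offset, giving
#' `(spacingPx/q)^2` frames — `q = 2` is the fourfold fewer-frames mode.
#'
#' @param frameShape integer `(H, W)` of the raw frames; both must be
#'   divisible by `spacingPx`.
#' @param spacingPx lattice period in pixels (default 16).
#' @param stepPx scan step in pixels; must divide `spacingPx`.
#' @return an [IlluminationSchedule-class].
#' @examples
#' sched <- buildSchedule(c(64, 64), spacingPx = 16, stepPx = 1)
#' nFrames(sched)
#' @export
buildSchedule <- function(frameShape, spacingPx = 16L, stepPx = 1L) {
  frameShape <- as.integer(frameShape)
  spacingPx <- as.integer(spacingPx); stepPx <- as.integer(stepPx)
  stopIfNot(length(frameShape) == 2 && all(frameShape > 0),
            "frameShape must be two positive integers")
  stopIfNot(spacingPx >= 1 && stepPx >= 1, "spacing and step must be >= 1")
  stopIfNot(all(frameShape %% spacingPx == 0),
            "spacingPx must divide both frame dimensions")
  stopIfNot(spacingPx %% stepPx == 0, "stepPx must divide spacingPx")
  nPer <- spacingPx %/% stepPx
  offs <- expand.grid(dx = (seq_len(nPer) - 1L) * stepPx,
                      dy = (seq_len(nPer) - 1L) * stepPx)
  # row-major enumeration: dy outer, dx inner
  scanOffsets <- cbind(dy = offs$dy, dx = offs$dx)
  foci <- lapply(seq_len(nrow(scanOffsets)), function(i) {
    latticeFoci(frameShape, spacingPx, scanOffsets[i, 1], scanOffsets[i, 2])
  })
  new("IlluminationSchedule", frameShape = frameShape,
      spacingPx = spacingPx, stepPx = stepPx,
      nFrames = nrow(scanOffsets), scanOffsets = scanOffsets, foci = foci)
}

# integer focus lattice for one (dy, dx) offset, 1-based coordinates
latticeFoci <- function(frameShape, spacingPx, dy, dx) {
  rows <- seq.int(1L + dy, frameShape[1], by = spacingPx)
  cols <- seq.int(1L + dx, frameShape[2], by = spacingPx)
  as.matrix(expand.grid(row = rows, col = cols))
}

#' Render one multispot illumination pattern
#'
#' Realises the pattern \eqn{p_i(u) = \sum_j \delta(r - b_{ij}) \otimes
#' h_{ex}(u)}: a delta comb at the frame's focus positions convolved with
#' the excitation PSF (zero-padded boundaries).
#'
#' @param schedule an [IlluminationSchedule-class].
#' @param frameIndex frame number (1-based).
#' @param psfEx excitation [PsfKernel-class].
#' @return a numeric `H x W` matrix.
#' @export
renderPattern <- function(schedule, frameIndex, psfEx) {
  stopIfNot(frameIndex >= 1 && frameIndex <= schedule@nFrames,
            "frameIndex out of range")
  comb <- matrix(0, schedule@frameShape[1], schedule@frameShape[2])
  f <- schedule@foci[[frameIndex]]
  comb[cbind(f[, 1], f[, 2])] <- 1
  convZero(comb, psfMatrix(psfEx))
}
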