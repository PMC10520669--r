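# render one noiseless raw frame for a given lattice offset without
# building a full schedule (used by the fewer-frames pair generator)
renderFrameAt <- function(sample, spacingPx, dy, dx, psfEx, psfEm) {
  d <- dim(sampleDensity(sample))
  foci <- latticeFoci(d, spacingPx, dy, dx)
  comb <- matrix(0, d[1], d[2])
  comb[cbind(foci[, 1], foci[, 2])] <- 1
  pat <- convZero(comb, psfMatrix(psfEx))
  list(frame = renderRawFrame(sample, pat, psfEm), foci = foci)
}

# shared noise heuristic: photon budget so the brightest pixel of the
# clean frame collects `peakPhotons` photons, read noise ~1% of the peak
pairNoise <- function(cleanFrame, peakPhotons = 200) {
  pk <- max(cleanFrame)
  if (pk <= 0) return(list(photonScale = NA, gaussSigma = 0))
  list(photonScale = peakPhotons / pk, gaussSigma = 0.01 * pk)
}

finishDataset <- function(inputs, targets, manifest, scheme, splitTrain,
                          seed) {
  P <- length(inputs)
  stopIfNot(P >= 2, "need at least two pairs")
  di <- dim(inputs[[1]]); dt <- dim(targets[[1]])
  xin <- array(0, c(di, 1L, P)); xtg <- array(0, c(dt, 1L, P))
  for (p in seq_len(P)) { xin[, , 1, p] <- inputs[[p]]; xtg[, , 1, p] <- targets[[p]] }
  normConst <- max(max(xin), max(xtg))
  xin <- xin / normConst; xtg <- xtg / normConst
  perm <- withSeed(seed * 7L + 11L, sample.int(P))
  nTrain <- floor(splitTrain * P)
  list(input = xin, target = xtg, scheme = scheme, normConst = normConst,
       manifest = manifest, trainIdx = perm[seq_len(nTrain)],
       valIdx = perm[seq.int(nTrain + 1L, P)])
}

#' Generate standard training pairs
#'
#' Each pair couples one noisy raw multifocal frame (the network input)
#' with the conventional single-frame reconstruction of the same noiseless
#' frame (pinholing, reassignment and per-frame Richardson-Lucy; the
#' ground-truth target). Samples default to spoke phantoms whose lobe
#' count is randomised per sample, mixed with random filament/blob
#' structures for diversity. Both sides are normalised by the dataset
#' maximum; pairs are split 70/30 into training and validation by a seeded
#' shuffle.
#'
#' @param schedule an [IlluminationSchedule-class]; one schedule frame is
#'   drawn at random per pair.
#' @param psfEx,psfEm excitation and emission PSFs.
#' @param nPairs number of pairs (>= 2).
#' @param seed integer seed controlling samples, frame choice and noise.
#' @param samples optional list of [SampleMap-class] objects to draw from
#'   instead of the internal generator.
#' @param reconOpts options passed to [reconstructSingleFrame()]
#'   (default: per-frame deconvolution with 20 iterations).
#' @param splitTrain training fraction (default 0.7).
#' @param peakPhotons photon budget at the brightest pixel (default 200).
#' @return a dataset list with `input` (`[H, W, 1, P]`), `target`
#'   (`[2H, 2W, 1, P]`), `normConst`, `manifest`, `trainIdx`, `valIdx`.
#' @export
makeTrainingPairs <- function(schedule, psfEx, psfEm, nPairs, seed = 1L,
                              samples = NULL, reconOpts = list(),
                              splitTrain = 0.7, peakPhotons = 200) {
  stopIfNot(nPairs >= 2, "nPairs must be >= 2")
  if (is.null(reconOpts$deconvolve)) reconOpts$deconvolve <- TRUE
  shape <- schedule@frameShape
  inputs <- list(); targets <- list(); man <- list()
  p <- 0L; draw <- 0L
  while (p < nPairs) {
    draw <- draw + 1L
    s <- if (!is.null(samples)) samples[[(draw - 1L) %% length(samples) + 1L]]
    else withSeed(seed + 131L * draw, {
      kind <- sample(c("spoke", "filaments", "blobs"), 1,
                     prob = c(0.5, 0.25, 0.25))
      if (kind == "spoke")
        makeSpokeSample(shape[1], nLobes = sample(12:64, 1))
      else makeRandomStructureSample(shape[1], kind,
                                     seed = seed + 131L * draw)
    })
    if (max(sampleDensity(s)) <= 0) {
      warning("skipping degenerate all-zero sample")
      next
    }
    fi <- withSeed(seed + 977L * draw, sample.int(nFrames(schedule), 1))
    pat <- renderPattern(schedule, fi, psfEx)
    clean <- renderRawFrame(s, pat, psfEm)
    ns <- pairNoise(clean, peakPhotons)
    noisy <- corruptFrame(clean, ns$gaussSigma, ns$photonScale,
                          seed = seed + 3L * draw)
    tgt <- reconstructSingleFrame(clean, fociOf(schedule, fi), psfEm,
                                  reconOpts)
    p <- p + 1L
    inputs[[p]] <- noisy
    targets[[p]] <- srMatrix(tgt)
    man[[p]] <- data.frame(pair = p, sample = s@descriptor, frame = fi)
  }
  finishDataset(inputs, targets, do.call(rbind, man), "standard",
                splitTrain, seed)
}

#' Generate fewer-frames (shifted-focus) training pairs
#'
#' Implements the fourfold-reduction training scheme: the scan step is 2
#' in both axes, and for every scan position the lattice is additionally
#' shifted to the four offsets `(0,0), (0,1), (1,0), (1,1)`. The input is
#' the noisy raw frame at offset `(0,0)`; the target is the sum of the
#' four single-frame reconstructions, i.e. the information a full-step
#' scan would have contributed at those positions.
#'
#' @param samples list of [SampleMap-class] objects (or `NULL` to generate
#'   randomised spokes internally, one per `nPairs %/% (spacing/2)^2`
#'   positions).
#' @param spacingPx lattice period (must be even).
#' @inheritParams makeTrainingPairs
#' @return a dataset list as in [makeTrainingPairs()] with
#'   `scheme = "shifted4"`.
#' @export
makeShiftedPairs <- function(samples, spacingPx, psfEx, psfEm, nPairs,
                             seed = 1L, reconOpts = list(),
                             splitTrain = 0.7, peakPhotons = 200) {
  stopIfNot(spacingPx %% 2 == 0, "spacingPx must be divisible by 2")
  if (is.null(reconOpts$deconvolve)) reconOpts$deconvolve <- TRUE
  nPer <- (spacingPx %/% 2L)^2
  if (is.null(samples)) {
    nSamp <- ceiling(nPairs / nPer)
    samples <- lapply(seq_len(nSamp), function(i)
      withSeed(seed + 577L * i,
               makeSpokeSample(64L, nLobes = sample(12:64, 1))))
  }
  inputs <- list(); targets <- list(); man <- list()
  p <- 0L
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    base <- expand.grid(dx = seq(0L, spacingPx - 2L, by = 2L),
                        dy = seq(0L, spacingPx - 2L, by = 2L))
    for (b in seq_len(nrow(base))) {
      if (p >= nPairs) break
      dy <- base$dy[b]; dx <- base$dx[b]
      shifts <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
      tgt <- NULL; input <- NULL
      for (k in 1:4) {
        rf <- renderFrameAt(s, spacingPx, dy + shifts[k, 1],
                            dx + shifts[k, 2], psfEx, psfEm)
        rec <- reconstructSingleFrame(rf$frame, rf$foci, psfEm, reconOpts)
        tgt <- if (is.null(tgt)) srMatrix(rec) else tgt + srMatrix(rec)
        if (k == 1) {
          ns <- pairNoise(rf$frame, peakPhotons)
          input <- corruptFrame(rf$frame, ns$gaussSigma, ns$photonScale,
                                seed = seed + 13L * (p + 1L))
        }
      }
      p <- p + 1L
      inputs[[p]] <- input
      targets[[p]] <- tgt
      man[[p]] <- data.frame(pair = p, sample = s@descriptor,
                             dy = dy, dx = dx)
    }
  }
  finishDataset(inputs, targets, do.call(rbind, man), "shifted4",
                splitTrain, seed)
}

#' Generate defocus-mixture training pairs for thick samples
#'
#' As [makeTrainingPairs()], but the network input is rendered as the sum
#' of an in-focus and a defocused emission path (out-of-focus haze) and
#' corrupted with a high Poisson noise level, while the target is
#' reconstructed from the focused-only render. Trains the network to
#' reject scattered and out-of-focus light.
#'
#' @inheritParams makeTrainingPairs
#' @param defocusPsf the defocused emission [PsfKernel-class] (e.g. 3 um).
#' @param peakPhotons photon budget (default 50: low-SNR regime).
#' @return a dataset list with `scheme = "defocus"`.
#' @export
makeDefocusPairs <- function(schedule, psfEx, psfEm, defocusPsf, nPairs,
                             seed = 1L, samples = NULL, reconOpts = list(),
                             splitTrain = 0.7, peakPhotons = 50) {
  stopIfNot(nPairs >= 2, "nPairs must be >= 2")
  if (is.null(reconOpts$deconvolve)) reconOpts$deconvolve <- TRUE
  shape <- schedule@frameShape
  inputs <- list(); targets <- list(); man <- list()
  for (p in seq_len(nPairs)) {
    s <- if (!is.null(samples)) samples[[(p - 1L) %% length(samples) + 1L]]
    else withSeed(seed + 131L * p,
                  makeSpokeSample(shape[1], nLobes = sample(12:64, 1)))
    fi <- withSeed(seed + 977L * p, sample.int(nFrames(schedule), 1))
    pat <- renderPattern(schedule, fi, psfEx)
    focused <- renderRawFrame(s, pat, psfEm)
    mixed <- focused + renderRawFrame(s, pat, defocusPsf)
    ns <- pairNoise(mixed, peakPhotons)
    inputs[[p]] <- corruptFrame(mixed, ns$gaussSigma, ns$photonScale,
                                seed = seed + 3L * p)
    targets[[p]] <- srMatrix(reconstructSingleFrame(focused,
                                                    fociOf(schedule, fi),
                                                    psfEm, reconOpts))
    man[[p]] <- data.frame(pair = p, sample = s@descriptor, frame = fi)
  }
  finishDataset(inputs, targets, do.call(rbind, man), "defocus",
                splitTrain, seed)
}
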