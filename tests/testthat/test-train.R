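smallSchedule <- function() buildSchedule(c(32L, 32L), 8L, 2L)

test_that("standard pairs couple noisy frames with per-frame targets", {
  p <- psfPair()
  ds <- makeTrainingPairs(smallSchedule(), p$ex, p$em, nPairs = 10,
                          seed = 3)
  expect_equal(dim(ds$input), c(32, 32, 1, 10))
  expect_equal(dim(ds$target), c(64, 64, 1, 10))
  expect_equal(max(max(ds$input), max(ds$target)), 1)  # dataset max = 1
  expect_equal(length(ds$trainIdx), 7)                 # 70/30 split
  expect_equal(length(ds$valIdx), 3)
  expect_length(intersect(ds$trainIdx, ds$valIdx), 0)
  ds2 <- makeTrainingPairs(smallSchedule(), p$ex, p$em, nPairs = 10,
                           seed = 3)
  expect_identical(ds$input, ds2$input)                # seeded
  expect_identical(ds$manifest, ds2$manifest)
  ds3 <- makeTrainingPairs(smallSchedule(), p$ex, p$em, nPairs = 10,
                           seed = 4)
  expect_false(identical(ds$input, ds3$input))
})

test_that("shifted-focus pairs implement the fourfold-reduction scheme", {
  p <- psfPair()
  s <- makeSpokeSample(32, 10)
  ds <- makeShiftedPairs(list(s), 8L, p$ex, p$em, nPairs = 16, seed = 2)
  expect_equal(dim(ds$input)[4], 16)                   # (8/2)^2 per sample
  expect_equal(dim(ds$target), c(64, 64, 1, 16))
  # fourfold reduction: a step-2 schedule has a quarter of the frames
  expect_equal(nFrames(buildSchedule(c(32L, 32L), 8L, 2L)),
               nFrames(buildSchedule(c(32L, 32L), 8L, 1L)) / 4)
  # the target of the first pair is the sum of the four shifted
  # single-frame reconstructions (recomputed independently here)
  tgt <- matrix(0, 64, 64)
  for (sh in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
    rf <- msimsr:::renderFrameAt(s, 8L, sh[1], sh[2], p$ex, p$em)
    tgt <- tgt + srMatrix(reconstructSingleFrame(rf$frame, rf$foci, p$em,
                                                 list(deconvolve = TRUE)))
  }
  expect_equal(ds$target[, , 1, 1] * ds$normConst, tgt, tolerance = 1e-9)
  expect_error(makeShiftedPairs(list(s), 7L, p$ex, p$em, 4), "divisible")
})

test_that("defocus pairs add an out-of-focus component to the input only", {
  p <- psfPair()
  d3 <- makeGaussianPsf(560, 1.1, 130, defocusUm = 1.5, role = "emission")
  sc <- buildSchedule(c(64L, 64L), 16L, 4L)
  s <- makeSpokeSample(64, 14)
  ds <- makeDefocusPairs(sc, p$ex, p$em, d3, nPairs = 4, seed = 9,
                         samples = list(s), peakPhotons = 1e7)
  expect_equal(dim(ds$input)[4], 4)
  # at a huge photon budget the input flux is ~2x the focused-only flux
  fi <- ds$manifest$frame[1]
  pat <- renderPattern(sc, fi, p$ex)
  focused <- renderRawFrame(s, pat, p$em)
  expect_equal(sum(ds$input[, , 1, 1] * ds$normConst), 2 * sum(focused),
               tolerance = 0.1)
  ds2 <- makeDefocusPairs(sc, p$ex, p$em, d3, nPairs = 4, seed = 9,
                          samples = list(s), peakPhotons = 1e7)
  expect_identical(ds2$input, ds$input)
})

test_that("training reduces the validation loss and keeps the best model", {
  p <- psfPair()
  ds <- makeTrainingPairs(smallSchedule(), p$ex, p$em, nPairs = 24,
                          seed = 5)
  model <- msimNetwork(compactNetworkConfig(), seed = 7)
  res <- trainNetwork(model, ds, trainConfig(epochs = 3, batch = 4,
                                             seed = 7))
  h <- res$history
  expect_equal(nrow(h), 4)                      # epoch 0 + 3 epochs
  expect_lt(min(h$valLoss[-1]), h$valLoss[1])   # training helps
  # the retained parameters reproduce the best validation loss
  best <- min(h$valLoss)
  got <- msimsr:::evalLoss(res$model, ds, ds$valIdx, lossConfig(), 4L)
  expect_equal(got, best, tolerance = 1e-12)
  # checkpoint round trip is exact
  ck <- tempfile(fileext = ".rds")
  saveModel(res$model, ck)
  re <- loadModel(ck)
  expect_equal(msimsr:::evalLoss(re, ds, ds$valIdx, lossConfig(), 4L),
               best, tolerance = 1e-15)
  x <- matrix(runif(32 * 32), 32)
  expect_identical(msimForward(re, x), msimForward(res$model, x))
})

test_that("stack inference sums per-frame network outputs", {
  p <- psfPair()
  sp <- makeSpokeSample(32, 8)
  sc <- smallSchedule()
  st <- simulateStack(sp, sc, p$ex, p$em,
                      noise = list(gaussSigma = 0.001, photonScale = 1000),
                      seed = 2)
  model <- msimNetwork(networkConfig(encoderWidths = c(2L, 3L, 4L, 5L),
                                     denseConfigs = list(list(L = 0L),
                                                         list(L = 0L),
                                                         list(L = 0L)),
                                     useDropout = FALSE), seed = 3)
  model@state$normConst <- 0.5
  sr <- inferStack(model, st)
  expect_s4_class(sr, "SRImage")
  expect_equal(sr@provenance, "deep")
  expect_equal(dim(srMatrix(sr)), c(64, 64))
  expect_identical(srMatrix(inferStack(model, st)), srMatrix(sr))
  # equals the explicit per-frame sum
  manual <- matrix(0, 64, 64)
  for (i in seq_len(nFrames(st))) {
    o <- msimForward(model, stackFrames(st)[, , i] / 0.5)
    manual <- manual + o[, , 1, 1]
  }
  expect_equal(srMatrix(sr), pmax(manual * 0.5, 0), tolerance = 1e-9)
})
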