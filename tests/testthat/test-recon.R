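test_that("lattice detection recovers the simulated foci exactly", {
  p <- psfPair()
  u <- uniformSample(64)
  sc <- buildSchedule(c(64L, 64L), 16L, 4L)
  for (i in c(1L, 6L, 16L)) {
    fr <- renderRawFrame(u, renderPattern(sc, i, p$ex), p$em)
    det <- detectLattice(fr, 16)
    truth <- fociOf(sc, i)
    truth <- truth[order(truth[, 1], truth[, 2]), ]
    expect_equal(nrow(det), (64 / 16)^2)
    expect_equal(unname(det), unname(matrix(as.numeric(truth),
                                            nrow(truth))))
  }
  expect_error(detectLattice(matrix(0, 32, 32), 8), "zero")
})

test_that("digital pinholes attenuate light away from foci", {
  foci <- rbind(c(9, 9), c(9, 25), c(25, 9), c(25, 25))
  fr <- matrix(1, 32, 32)
  ph <- applyPinholes(fr, foci, pinholeSigmaPx = 2)
  expect_equal(ph[9, 9], 1)           # mask peak 1 at a focus
  expect_true(all(ph <= fr + 1e-12))
  expect_lte(sum(ph), sum(fr))
  # >= 98% attenuation at 3 sigma from every focus
  d <- sqrt((9 - 15)^2 + (9 - 15)^2)  # pixel (15,15): 8.49 px > 3*2 sigma
  expect_lt(ph[15, 15], 0.02)
  expect_error(applyPinholes(fr, foci, -1), "positive")
})

test_that("pixel reassignment deposits at x + b and conserves flux", {
  # zero displacement: pixel at the focus lands at the doubled position
  fr <- matrix(0, 16, 16); fr[5, 7] <- 2
  out <- reassignFrame(fr, rbind(c(5, 7)))
  expect_equal(out[9, 13], 2)         # 2*5-1, 2*7-1
  expect_equal(sum(out), 2)
  # displaced pixel: b + d maps to 2b + d (half-distance rule, doubled grid)
  fr2 <- matrix(0, 16, 16); fr2[5 + 3, 7 - 2] <- 1
  out2 <- reassignFrame(fr2, rbind(c(5, 7)))
  expect_equal(out2[9 + 3, 13 - 2], 1)
  # random multi-focus instances match the brute-force oracle exactly
  for (s in 1:5) {
    fr3 <- msimsr:::withSeed(s, matrix(rpois(32 * 32, 2), 32))
    foci <- msimsr:::withSeed(100 + s,
      cbind(sample.int(32, 6), sample.int(32, 6)))
    expect_identical(reassignFrame(fr3, foci),
                     reassignOracle(fr3, foci))
    expect_equal(sum(reassignFrame(fr3, foci)), sum(fr3))
  }
})

test_that("stack summation is elementary and order-invariant", {
  ms <- lapply(1:4, function(i) matrix(i, 8, 8))
  expect_equal(sumStack(ms[1]), ms[[1]])
  expect_equal(sumStack(ms), sumStack(rev(ms)))
  expect_equal(sum(sumStack(ms)), sum(vapply(ms, sum, numeric(1))))
  expect_error(sumStack(list()), "at least one")
})

test_that("Richardson-Lucy sharpens while conserving flux", {
  p <- psfPair()
  expect_equal(richardsonLucy(matrix(2, 16, 16), p$em, 0L),
               matrix(2, 16, 16))
  # blurred point supported in the interior
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  blurred <- msimsr:::convZero(img, psfMatrix(p$em))
  rec <- richardsonLucy(blurred, p$em, 20L)
  expect_true(all(rec >= 0))
  expect_equal(sum(rec), sum(blurred), tolerance = 0.01)
  expect_gt(max(rec), max(blurred))   # peak strictly increases
  bad <- p$em; bad@kernel <- bad@kernel * 2
  expect_error(richardsonLucy(blurred, bad, 5L), "normalized")
})

test_that("conventional reconstruction has the doubled-grid contract", {
  p <- psfPair()
  sp <- makeSpokeSample(64, 16)
  sc <- buildSchedule(c(64L, 64L), 16L, 2L)
  st <- simulateStack(sp, sc, p$ex, p$em)
  sr <- reconstructConventional(st, p$em, list(nIter = 5))
  expect_s4_class(sr, "SRImage")
  expect_equal(dim(srMatrix(sr)), c(128, 128))
  expect_equal(pixelSizeNm(sr), 65)
  expect_true(all(srMatrix(sr) >= 0))
  sr2 <- reconstructConventional(st, p$em, list(nIter = 5))
  expect_identical(srMatrix(sr), srMatrix(sr2))   # deterministic
  expect_error(reconstructConventional(st, p$em, list(bogus = 1)),
               "unknown")
})

test_that("detected-mode reconstruction matches oracle mode when noiseless", {
  p <- psfPair()
  sp <- makeSpokeSample(64, 16)
  sc <- buildSchedule(c(64L, 64L), 16L, 4L)
  st <- simulateStack(sp, sc, p$ex, p$em)
  a <- reconstructConventional(st, p$em, list(nIter = 3))
  b <- reconstructConventional(st, p$em,
                               list(nIter = 3, fociMode = "detected"))
  expect_equal(srMatrix(a), srMatrix(b), tolerance = 1e-6)
})

test_that("single-frame reconstructions sum to the stack reconstruction", {
  p <- psfPair()
  sp <- makeRandomStructureSample(32, "blobs", seed = 2)
  sc <- buildSchedule(c(32L, 32L), 8L, 2L)
  st <- simulateStack(sp, sc, p$ex, p$em)
  manual <- matrix(0, 64, 64)
  for (i in seq_len(nFrames(st))) {
    one <- reconstructSingleFrame(stackFrames(st)[, , i], fociOf(sc, i),
                                  p$em)
    expect_equal(sum(srMatrix(one)),
                 sum(applyPinholes(stackFrames(st)[, , i],
                                   fociOf(sc, i), psfSigma(p$em))),
                 tolerance = 1e-9)   # flux conserved pre-deconvolution
    manual <- manual + srMatrix(one)
  }
  full <- reconstructConventional(st, p$em, list(deconvolve = FALSE))
  expect_equal(manual, srMatrix(full), tolerance = 1e-12)
  # pipeline monotonicity: adding frames never decreases the summed total
  half <- buildSchedule(c(32L, 32L), 8L, 2L)
  expect_gte(sum(srMatrix(full)),
             sum(srMatrix(reconstructSingleFrame(stackFrames(st)[, , 1],
                                                 fociOf(sc, 1), p$em))))
})
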