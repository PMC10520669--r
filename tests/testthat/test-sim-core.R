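test_that("spoke sample follows the radial cosine law", {
  sp <- makeSpokeSample(128, nLobes = 12)
  d <- sampleDensity(sp)
  expect_true(all(is.finite(d)) && all(d >= 0))
  expect_equal(max(d), 1)
  # along theta = 0 (to the right of center) the density is maximal
  c0 <- (128 + 1) / 2
  row <- d[ceiling(c0), ]
  expect_gt(min(row[100:120]), 0.99)
  # lobe count on a circle: strict local maxima with wraparound
  th <- seq(0, 2 * pi, length.out = 1441)[-1441]
  v <- bilinearAt(d, c0 + 40 * sin(th), c0 + 40 * cos(th))
  expect_equal(countCircularMaxima(v), 12)
  expect_error(makeSpokeSample(8), "sizePx")
})

test_that("random structure samples are seeded and plausibly sparse", {
  a <- makeRandomStructureSample(64, "filaments", seed = 3)
  b <- makeRandomStructureSample(64, "filaments", seed = 3)
  expect_identical(sampleDensity(a), sampleDensity(b))
  c2 <- makeRandomStructureSample(64, "filaments", seed = 4)
  expect_false(identical(sampleDensity(a), sampleDensity(c2)))
  for (s in 1:10) {
    fr <- mean(sampleDensity(
      makeRandomStructureSample(64, "filaments", seed = s)) > 0)
    expect_gt(fr, 0.01)
    expect_lt(fr, 0.5)
  }
  bl <- makeRandomStructureSample(64, "blobs", seed = 1)
  expect_equal(max(sampleDensity(bl)), 1)
  expect_error(makeRandomStructureSample(64, "squares"), "arg")
})

test_that("Gaussian PSF has the stated width and normalization", {
  psf <- makeGaussianPsf(560, 1.1, 130, role = "emission")
  expect_equal(psfSigma(psf), 0.21 * 560 / 1.1 / 130, tolerance = 1e-12)
  k <- psfMatrix(psf)
  expect_equal(sum(k), 1, tolerance = 1e-9)
  expect_equal(nrow(k) %% 2, 1)
  expect_equal(k, k[nrow(k):1, ncol(k):1])
  # FWHM of the rendered central row matches 2.355 sigma within 5%
  mid <- (nrow(k) + 1) / 2
  w <- fwhm(k[mid, ], 1)
  expect_equal(w, 2.3548 * psfSigma(psf), tolerance = 0.05)
  # defocus widens monotonically
  d3 <- makeGaussianPsf(560, 1.1, 130, defocusUm = 3, role = "emission")
  expect_gt(psfSigma(d3), psfSigma(psf))
  d1 <- makeGaussianPsf(560, 1.1, 130, defocusUm = 1, role = "emission")
  expect_gt(psfSigma(d3), psfSigma(d1))
  expect_error(makeGaussianPsf(560, 1.1, 5000, role = "emission"), "0.2")
  # two-photon mode sharpens
  tp <- makeGaussianPsf(560, 1.1, 130, role = "excitation", twoPhoton = TRUE)
  expect_equal(psfSigma(tp), psfSigma(psf) / sqrt(2), tolerance = 1e-12)
})

test_that("schedule cardinality and offsets obey the scan geometry", {
  for (sp in c(8L, 16L)) for (st in c(1L, 2L, 4L)) {
    sc <- buildSchedule(c(32L, 32L), sp, st)
    expect_equal(nFrames(sc) * st^2, sp^2)
    offs <- sc@scanOffsets
    expect_equal(nrow(unique(offs)), nFrames(sc))   # each offset once
    expect_true(all(offs %% st == 0))
    expect_equal(nrow(fociOf(sc, 1)), (32 / sp)^2)
    for (i in seq_len(nFrames(sc))) {
      f <- fociOf(sc, i)
      expect_true(all(f >= 1 & f <= 32))
      # square lattice with period sp along both axes
      expect_equal(sort(unique(diff(sort(unique(f[, 1]))))), sp)
    }
  }
  expect_error(buildSchedule(c(30, 32), 16, 1), "divide")
  expect_error(buildSchedule(c(32, 32), 16, 3), "divide")
})

test_that("pattern rendering realizes the focus comb convolved with the PSF", {
  sc <- buildSchedule(c(32L, 32L), 8L, 4L)
  p <- psfPair()
  # identity kernel: the binary comb itself
  idk <- new("PsfKernel", kernel = matrix(1, 1, 1), sigmaPx = 0.3,
             wavelengthNm = 560, na = 1.1, defocusUm = 0,
             role = "excitation")
  pat <- renderPattern(sc, 2, idk)
  comb <- matrix(0, 32, 32)
  f <- fociOf(sc, 2)
  comb[cbind(f[, 1], f[, 2])] <- 1
  expect_equal(pat, comb, tolerance = 1e-12)
  # total intensity = number of foci (interior kernels sum to 1)
  sc2 <- buildSchedule(c(64L, 64L), 16L, 4L)
  pat2 <- renderPattern(sc2, 6, p$ex)   # offsets away from the border
  expect_equal(sum(pat2), nrow(fociOf(sc2, 6)), tolerance = 1e-3)
  # value at a focus equals the kernel peak when foci are well separated
  f2 <- fociOf(sc2, 6)
  expect_equal(pat2[f2[5, 1], f2[5, 2]], max(psfMatrix(p$ex)),
               tolerance = 1e-6)
  expect_error(renderPattern(sc2, 300, p$ex), "range")
})

test_that("raw-frame formation is linear with conserved flux", {
  p <- psfPair()
  sc <- buildSchedule(c(32L, 32L), 8L, 4L)
  pat <- renderPattern(sc, 4, p$ex)   # interior lattice offset
  z <- uniformSample(32)
  zero <- new("SampleMap", density = matrix(0, 32, 32), pixelSizeNm = 130,
              descriptor = "zero")
  expect_equal(renderRawFrame(zero, pat, p$em), matrix(0, 32, 32))
  # constant sample: total = c * pattern total (away from borders this is
  # near-exact; zero padding removes a little border flux)
  fr <- renderRawFrame(z, pat, p$em)
  expect_equal(sum(fr), sum(pat), tolerance = 0.02)
  # linearity to 1e-9
  s1 <- makeRandomStructureSample(32, "blobs", seed = 1)
  s2 <- makeRandomStructureSample(32, "blobs", seed = 2)
  mix <- new("SampleMap", density = 2 * sampleDensity(s1) +
               0.5 * sampleDensity(s2), pixelSizeNm = 130,
             descriptor = "mix")
  lhs <- renderRawFrame(mix, pat, p$em)
  rhs <- 2 * renderRawFrame(s1, pat, p$em) +
    0.5 * renderRawFrame(s2, pat, p$em)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # point source at a focus: a scaled shifted copy of the emission PSF
  f <- fociOf(sc, 4)
  pt <- matrix(0, 32, 32); pt[f[5, 1], f[5, 2]] <- 1
  ptS <- new("SampleMap", density = pt, pixelSizeNm = 130, descriptor = "pt")
  frame <- renderRawFrame(ptS, pat, p$em)
  expected <- renderOracle(pt, pat, psfMatrix(p$em))
  expect_equal(frame, expected, tolerance = 1e-9)
  expect_error(renderRawFrame(ptS, pat[1:16, ], p$em), "shape")
})

test_that("defocus mixture doubles flux and degenerates correctly", {
  p <- psfPair()
  d3 <- makeGaussianPsf(560, 1.1, 130, defocusUm = 1.5, role = "emission")
  sc <- buildSchedule(c(64L, 64L), 16L, 4L)
  pat <- renderPattern(sc, 6, p$ex)
  s <- makeRandomStructureSample(64, "blobs", seed = 7)
  one <- renderRawFrame(s, pat, p$em)
  expect_equal(renderDefocusMixture(s, pat, p$em, p$em), 2 * one,
               tolerance = 1e-12)
  mixed <- renderDefocusMixture(s, pat, p$em, d3)
  # flux bookkeeping: both paths carry the full excited flux (within the
  # border loss of the wider defocused kernel)
  expect_equal(sum(mixed), 2 * sum(one), tolerance = 0.1)
})

test_that("noise corruption is seeded, nonnegative and unbiased", {
  fr <- matrix(runif(64 * 64, 1, 10), 64)
  a <- corruptFrame(fr, 0.5, 100, seed = 3)
  b <- corruptFrame(fr, 0.5, 100, seed = 3)
  expect_identical(a, b)
  expect_gte(min(a), 0)
  c2 <- corruptFrame(fr, 0.5, 100, seed = 4)
  expect_false(identical(a, c2))
  # enormous photon budget: relative deviation < 1%
  hi <- corruptFrame(fr, 0, 1e6, seed = 1)
  expect_lt(mean(abs(hi - fr) / fr), 0.01)
  expect_error(corruptFrame(fr, -1, NA), "gaussSigma")
})

test_that("stack simulation composes frames reproducibly", {
  p <- psfPair()
  sp <- makeSpokeSample(32, 8)
  sc <- buildSchedule(c(32L, 32L), 8L, 4L)
  st1 <- simulateStack(sp, sc, p$ex, p$em,
                       noise = list(gaussSigma = 0.01, photonScale = 500),
                       seed = 5)
  st2 <- simulateStack(sp, sc, p$ex, p$em,
                       noise = list(gaussSigma = 0.01, photonScale = 500),
                       seed = 5)
  expect_identical(stackFrames(st1), stackFrames(st2))
  expect_equal(dim(stackFrames(st1)), c(32, 32, nFrames(sc)))
  # widefield: permutation-invariant pixelwise sum
  wf <- widefield(st1)
  expect_equal(wf, apply(stackFrames(st1), c(1, 2), sum), tolerance = 1e-12)
  expect_equal(sum(wf), sum(stackFrames(st1)), tolerance = 1e-6)
})

test_that("uniform-coverage scan sums to the emission-blurred sample", {
  # with step 1 every pixel hosts a focus exactly once, so the summed
  # excitation is flat in the interior and the noiseless stack sum equals
  # sample (x) h_em away from the border
  p <- psfPair()
  s <- makeRandomStructureSample(32, "blobs", seed = 11)
  sc <- buildSchedule(c(32L, 32L), 8L, 1L)
  st <- simulateStack(s, sc, p$ex, p$em)
  wf <- widefield(st)
  expected <- msimsr:::convZero(sampleDensity(s), psfMatrix(p$em))
  inner <- 9:24
  expect_equal(wf[inner, inner], expected[inner, inner], tolerance = 0.02)
})
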