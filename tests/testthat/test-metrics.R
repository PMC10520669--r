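test_that("PSNR/NRMSE/MSE follow the 8-bit conventions", {
  a <- matrix(runif(256, 0, 3), 16)
  m0 <- psnrNrmseMse(a, a)
  expect_equal(m0$mse, 0)
  expect_equal(m0$nrmse, 0)
  expect_equal(m0$psnr_db, Inf)
  # closed form: ramp spanning 0..255 with a uniform offset of 16 levels
  y <- matrix(rep(0:255, each = 4), 32)
  m <- psnrNrmseMse(y, y + 16, bit8 = FALSE)
  expect_equal(m$mse, 256)
  expect_equal(m$psnr_db, 20 * log10(255 / 16), tolerance = 1e-12)
  expect_equal(m$nrmse, 16 / 255, tolerance = 1e-12)
  # algebraic identity on random pairs
  for (s in 1:20) {
    pr <- exact8bitPair(16, s)
    m <- psnrNrmseMse(pr$y, pr$yref)
    expect_equal(m$psnr_db, 20 * log10(255) - 10 * log10(m$mse),
                 tolerance = 1e-9)
  }
  expect_error(psnrNrmseMse(matrix(1, 4, 4), matrix(2, 4, 4)), "flat")
})

test_that("SSIM is symmetric, maximal at identity, and matches an oracle", {
  a <- matrix(runif(1024), 32)
  b <- a + 0.2 * matrix(runif(1024), 32)
  expect_equal(ssimIndex(a, a), 1, tolerance = 1e-9)
  expect_equal(ssimIndex(a, b), ssimIndex(b, a), tolerance = 1e-12)
  for (s in 1:3) {
    pr <- exact8bitPair(32, s)
    got <- ssimIndex(pr$y, pr$yref)
    want <- ssimOracle(pr$y * 255, pr$yref * 255, (0.01 * 255)^2,
                       (0.03 * 255)^2)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("resolution scaling recovers a constructed degradation", {
  set.seed(21)
  sr <- msimsr:::convZero(matrix(runif(64 * 64), 64),
                          msimsr:::gaussKernelMatrix(1.2))
  down <- msimsr:::blockMean2(sr)
  ref <- 1.7 * msimsr:::convZero(down, msimsr:::gaussKernelMatrix(2)) + 0.3
  fit <- resolutionScale(sr, ref)
  expect_equal(dim(fit$irs), dim(ref))
  expect_equal(fit$sigma, 2, tolerance = 0.05)
  expect_equal(fit$a, 1.7, tolerance = 0.01)
  expect_equal(fit$b, 0.3, tolerance = 0.01)
  expect_lt(sqrt(mean((fit$irs - ref)^2)), 1e-6 * sqrt(mean(ref^2)))
  expect_equal(rseRsp(ref, fit$irs)$rsp, 1, tolerance = 1e-6)
  # exact downsample: identity transform recovered
  fit0 <- resolutionScale(sr, down)
  expect_equal(fit0$sigma, 0, tolerance = 1e-6)
  expect_equal(fit0$a, 1, tolerance = 1e-6)
  expect_equal(fit0$b, 0, tolerance = 1e-6)
})

test_that("RSE/RSP have their definitional properties", {
  set.seed(4)
  ref <- matrix(runif(256), 16)
  expect_equal(rseRsp(ref, ref), list(rse = 0, rsp = 1))
  aff <- rseRsp(ref, 2 * ref + 5)
  expect_equal(aff$rsp, 1, tolerance = 1e-12)
  expect_gt(aff$rse, 0)
  for (s in 1:10) {
    x <- matrix(rnorm(256), 16); y <- matrix(rnorm(256), 16)
    got <- rseRsp(x, y)$rsp
    want <- mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(rseRsp(matrix(1, 4, 4), ref[1:4, 1:4]), "variance")
})

test_that("error maps compose scaling and absolute difference", {
  set.seed(5)
  sr <- msimsr:::convZero(matrix(runif(32 * 32), 32),
                          msimsr:::gaussKernelMatrix(1))
  ref <- msimsr:::blockMean2(sr)
  em <- errorMap(sr, ref)
  expect_true(all(em$map >= 0))
  expect_lt(max(em$map), 1e-8)            # perfect case
  expect_equal(em$rse, sqrt(mean(em$map^2)), tolerance = 1e-12)
  expect_equal(pixelwiseDiff(ref, ref), matrix(0, 16, 16))
  expect_equal(pixelwiseDiff(ref, sr[1:16, 1:16]),
               pixelwiseDiff(sr[1:16, 1:16], ref))
})

test_that("FWHM interpolates half-maximum crossings", {
  x <- seq_len(101)
  gauss <- exp(-(x - 51)^2 / (2 * 25))
  expect_equal(fwhm(gauss, 10), 2.3548 * 5 * 10, tolerance = 0.01)
  tri <- c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5, 0.25, 0)
  expect_equal(fwhm(tri, 1), 4)           # half-width w = FWHM for a triangle
  expect_error(fwhm(seq(0, 1, 0.1)), "crossing")
})
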