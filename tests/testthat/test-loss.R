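test_that("MS-SSIM equals 1 at identity and is symmetric", {
  set.seed(8)
  y <- matrix(runif(96 * 96), 96)
  cfg <- lossConfig(msScales = 3L, beta = c(0.2, 0.5, 0.3))
  expect_equal(msSSIM(y, y, cfg), 1, tolerance = 1e-9)
  z <- pmin(y + 0.1 * matrix(runif(96 * 96), 96), 1)
  expect_equal(msSSIM(y, z, cfg), msSSIM(z, y, cfg), tolerance = 1e-12)
  expect_lt(msSSIM(y, z, cfg), 1)
})

test_that("single-scale MS-SSIM reduces to the SSIM of the metrics module", {
  cfg1 <- lossConfig(msScales = 1L, beta = 1)
  for (s in 1:3) {
    pr <- exact8bitPair(64, s)
    # the pair quantizes exactly, so the unit-range computation and the
    # 8-bit computation of ssimIndex are the same number
    expect_equal(msSSIM(pr$y, pr$yref, cfg1), ssimIndex(pr$y, pr$yref),
                 tolerance = 1e-6)
  }
})

test_that("scale count adapts to the patch size with renormalised weights", {
  y <- matrix(runif(64 * 64), 64)
  expect_error(msSSIM(y, y, lossConfig()), "at least")
  v <- msSSIM(y, y, lossConfig(), autoReduce = TRUE)
  expect_equal(v, 1, tolerance = 1e-9)
  cfgA <- msimsr:::adaptLossScales(lossConfig(), c(64, 64))
  expect_equal(cfgA$msScales, 3L)            # 64 / 2^2 = 16 >= 11
  expect_equal(sum(cfgA$beta), 1)            # total weight preserved
})

test_that("the composite loss is zero iff the images agree", {
  set.seed(12)
  y <- matrix(runif(64 * 64), 64)
  expect_equal(msimLoss(y, y), 0, tolerance = 1e-9)
  for (s in 1:20) {
    pert <- y + matrix(rnorm(64 * 64, 0, 0.02), 64)
    expect_gt(msimLoss(y, pmax(pert, 0)), 1e-6)
  }
})

test_that("loss terms decompose as configured", {
  set.seed(13)
  y <- matrix(runif(64 * 64, 0.1, 0.9), 64)
  z <- pmin(y + 0.05, 1)
  # alpha = 1: pure structural term
  l1 <- msimLoss(y, z, lossConfig(alpha = 1, msScales = 2L,
                                  beta = c(0.5, 0.5)))
  ms <- msSSIM(y, z, lossConfig(msScales = 2L, beta = c(0.5, 0.5)))
  expect_equal(l1, 1 - ms, tolerance = 1e-12)
  # alpha = 0 and a constant error: the Gaussian-weighted L1 term is the
  # constant itself (unit-sum kernel)
  e <- 0.07
  l0 <- msimLoss(y, y + e, lossConfig(alpha = 0, msScales = 1L, beta = 1))
  expect_equal(l0, e, tolerance = 1e-9)
  expect_error(lossConfig(alpha = 2), "alpha")
  expect_error(lossConfig(beta = c(1, 1)), "beta")
})
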