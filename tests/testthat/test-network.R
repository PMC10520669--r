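# a deliberately tiny architecture keeps these structural tests fast
tinyConfig <- function(...) {
  networkConfig(encoderWidths = c(2L, 3L, 4L, 5L),
                denseConfigs = list(list(L = 0L), list(L = 1L, k = 2L),
                                    list(L = 2L, k = 2L)), ...)
}

test_that("forward pass doubles the spatial dimensions", {
  model <- msimNetwork(tinyConfig(), seed = 1)
  for (n in c(32L, 64L)) {
    out <- msimForward(model, matrix(runif(n * n), n))
    expect_equal(dim(out), c(2L * n, 2L * n, 1L, 1L))
    expect_true(all(out >= 0))   # final ReLU keeps the image nonnegative
  }
  expect_error(msimForward(model, matrix(0, 20, 20)), "divisible by 8")
})

test_that("evaluation mode is deterministic, training dropout is not", {
  model <- msimNetwork(tinyConfig(useDropout = TRUE), seed = 2)
  x <- matrix(runif(32 * 32), 32)
  msimForward(model, x)  # materialise parameters
  a <- msimForward(model, x)
  b <- msimForward(model, x)
  expect_identical(a, b)
  set.seed(1); t1 <- msimForward(model, x, training = TRUE)$out$val
  set.seed(2); t2 <- msimForward(model, x, training = TRUE)$out$val
  expect_false(identical(t1, t2))
})

test_that("dense connections respect the growth-rate channel arithmetic", {
  # {L = 0}: the skip is an exact pass-through
  cfgL0 <- networkConfig(encoderWidths = c(2L, 3L, 4L, 5L),
                         denseConfigs = list(list(L = 0L), list(L = 0L),
                                             list(L = 0L)))
  model <- msimNetwork(cfgL0, seed = 1)
  msimForward(model, matrix(runif(32 * 32), 32))
  expect_false(any(grepl("^skip", ls(model@state$params))))
  # {L, k}: the transition conv maps C0 + L*k channels back to the input
  cfg <- networkConfig(encoderWidths = c(4L, 8L, 16L, 32L),
                       denseConfigs = list(list(L = 0L),
                                           list(L = 3L, k = 32L),
                                           list(L = 5L, k = 8L)))
  model2 <- msimNetwork(cfg, seed = 1)
  out <- msimForward(model2, matrix(runif(32 * 32), 32))
  expect_equal(dim(out)[1:2], c(64L, 64L))
  p <- model2@state$params
  # skip2 acts on the 8-channel encoder stage: C0 = 8, L = 3, k = 32
  expect_equal(dim(p[["skip2.t.c1.w"]]), c(1L, 1L, 8L + 3L * 32L, 8L))
  # bottlenecks emit 4k then k channels
  expect_equal(dim(p[["skip2.l1.c1.w"]])[4], 128L)
  expect_equal(dim(p[["skip2.l1.c2.w"]])[4], 32L)
  # skip3 on the 4-channel stage: C0 = 4, L = 5, k = 8
  expect_equal(dim(p[["skip3.t.c1.w"]]), c(1L, 1L, 4L + 5L * 8L, 4L))
  # decoder upsampling halves the channel count with a 1x1 conv
  expect_equal(dim(p[["dec1.half.w"]]), c(1L, 1L, 32L, 16L))
  expect_error(networkConfig(denseConfigs = list(list(L = 0L),
                                                 list(L = 3L),
                                                 list(L = 5L, k = 8L))),
               "growth rate")
})

test_that("every ablation toggle yields a working architecture", {
  x <- matrix(runif(16 * 16), 16)
  for (skip in c("dense", "concat", "residual"))
    for (up in c("nearest", "transposed"))
      for (bn in c(TRUE, FALSE))
        for (dr in c(TRUE, FALSE)) {
          model <- msimNetwork(tinyConfig(skipMode = skip,
                                          upsampleMode = up,
                                          useBn = bn, useDropout = dr),
                               seed = 1)
          out <- msimForward(model, x)
          expect_equal(dim(out), c(32L, 32L, 1L, 1L),
                       info = paste(skip, up, bn, dr))
        }
})

test_that("introspected parameter count matches closed-form arithmetic", {
  model <- msimNetwork(compactNetworkConfig(), seed = 1)
  msimForward(model, matrix(runif(32 * 32), 32))
  # independent tally: conv k*k*cin*cout + cout, BN 2 per channel
  conv <- function(k, cin, cout, bn = TRUE)
    k * k * cin * cout + cout + if (bn) 2 * cout else 0
  w <- c(4, 8, 16, 32)
  expected <- 0
  cin <- 1
  for (i in 1:4) {                       # encoder double convs
    expected <- expected + conv(3, cin, w[i]) + conv(3, w[i], w[i])
    cin <- w[i]
  }
  # dense blocks batch-normalise their *inputs* (pre-activation), so BN
  # parameters follow the input channel counts there
  bconv <- function(k, cin, cout) k * k * cin * cout + cout  # conv only
  dense <- function(C0, L, k)
    conv(3, C0, C0) +                    # initial conv (post-activation BN)
    sum(vapply(seq_len(L), function(l) {
      cin <- C0 + (l - 1) * k
      2 * cin + bconv(1, cin, 4 * k) +   # BN(in) + 1x1 bottleneck
        2 * (4 * k) + bconv(3, 4 * k, k) # BN + 3x3 growth conv
    }, numeric(1))) +
    2 * (C0 + L * k) + bconv(1, C0 + L * k, C0) + 2 * C0  # transition
  expected <- expected + dense(8, 1, 8) + dense(4, 2, 4)   # skip2, skip3
  for (i in 1:3) {                       # decoder stages
    cu <- w[5 - i]                       # channels entering the upsample
    expected <- expected + conv(1, cu, cu / 2, bn = FALSE)
    cc <- cu / 2 + w[4 - i]              # concat with the (dense) skip
    expected <- expected + conv(3, cc, w[4 - i]) +
      conv(3, w[4 - i], w[4 - i])
  }
  expected <- expected + conv(3, 4, 4) + conv(1, 4, 1, bn = FALSE)
  expect_equal(nParameters(model), expected)
})

test_that("a single optimisation step reduces the loss in most seeds", {
  # one genuine synthetic pair (raw frame -> single-frame reconstruction)
  p <- psfPair()
  ds <- makeTrainingPairs(buildSchedule(c(32L, 32L), 8L, 2L), p$ex, p$em,
                          nPairs = 2, seed = 42)
  x <- ds$input[, , , 1, drop = FALSE]
  tgt <- ds$target[, , , 1, drop = FALSE]
  lc <- lossConfig(msScales = 1L, beta = 1)
  wins <- 0L
  for (s in 1:10) {
    model <- msimNetwork(compactNetworkConfig(), seed = s)
    st <- model@state
    fw <- msimForward(model, x, training = TRUE)
    l0 <- msimsr:::msimLossNode(fw$out, msimsr:::tpConst(tgt), lc)
    msimsr:::nnBackward(l0)
    adam <- new.env(); adam$t <- 0
    msimsr:::adamStep(st, fw$ctx$pnodes, adam, 1e-3)
    fw2 <- msimForward(model, x, training = TRUE)
    l1 <- msimsr:::msimLossNode(fw2$out, msimsr:::tpConst(tgt), lc)
    wins <- wins + (l1$val < l0$val)
  }
  expect_gte(wins, 9L)
})
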