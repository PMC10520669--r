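# Shared fixtures and independent oracles used across the suite.
# Everything is generated in code; no data files are read.

psfPair <- function(pixelSizeNm = 130) {
  list(ex = makeGaussianPsf(560, 1.1, pixelSizeNm, role = "excitation"),
       em = makeGaussianPsf(560, 1.1, pixelSizeNm, role = "emission"))
}

uniformSample <- function(sizePx, pixelSizeNm = 130) {
  new("SampleMap", density = matrix(1, sizePx, sizePx),
      pixelSizeNm = pixelSizeNm, descriptor = "uniform")
}

# bilinear interpolation of a matrix at continuous (row, col) positions
bilinearAt <- function(m, y, x) {
  y0 <- pmax(1, pmin(nrow(m) - 1, floor(y))); y1 <- y0 + 1
  x0 <- pmax(1, pmin(ncol(m) - 1, floor(x))); x1 <- x0 + 1
  fy <- y - y0; fx <- x - x0
  m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    m[cbind(y1, x0)] * fy * (1 - fx) +
    m[cbind(y0, x1)] * (1 - fy) * fx +
    m[cbind(y1, x1)] * fy * fx
}

# strict local maxima of a cyclic sequence
countCircularMaxima <- function(v) {
  prev <- v[c(length(v), seq_len(length(v) - 1))]
  nxt <- v[c(seq_len(length(v) - 1) + 1, 1)]
  sum(v > prev & v > nxt)
}

# nearest-neighbor 2x upsampling (baseline for super-resolution checks)
nnUpsample <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                            rep(seq_len(ncol(m)), each = 2)]

# Direct evaluation of the image-formation integral: every source pixel u
# scatters density(u) * pattern(u) * kernel(x - u) into the output.
# O(N^2 K^2) double loop, independent of the FFT path under test.
renderOracle <- function(density, pattern, kernel) {
  H <- nrow(density); W <- ncol(density)
  r <- (nrow(kernel) - 1) / 2
  out <- matrix(0, H, W)
  src <- density * pattern
  for (j in seq_len(W)) for (i in seq_len(H)) {
    v <- src[i, j]
    if (v == 0) next
    for (dj in -r:r) {
      cj <- j + dj
      if (cj < 1 || cj > W) next
      for (di in -r:r) {
        ci <- i + di
        if (ci < 1 || ci > H) next
        out[ci, cj] <- out[ci, cj] + v * kernel[di + r + 1, dj + r + 1]
      }
    }
  }
  out
}

# Brute-force half-distance pixel reassignment on the doubled canvas:
# nearest focus by exhaustive distance scan with lexicographic tie-break,
# deposit at x + round(b) in doubled-grid indices.
reassignOracle <- function(frame, foci) {
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(0, 2 * H, 2 * W)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    v <- frame[i, j]
    if (v == 0) next
    d2 <- (foci[, 1] - i)^2 + (foci[, 2] - j)^2
    cand <- which(d2 == min(d2))
    if (length(cand) > 1) {
      o <- order(foci[cand, 1], foci[cand, 2])
      cand <- cand[o[1]]
    }
    ti <- i + round(foci[cand, 1]) - 1
    tj <- j + round(foci[cand, 2]) - 1
    out[ti, tj] <- out[ti, tj] + v
  }
  out
}

# Independent sliding-window SSIM: explicit double loop over valid 11x11
# windows with Gaussian weights, no convolution machinery.
ssimOracle <- function(y, yref, c1, c2) {
  g <- exp(-((-5):5)^2 / (2 * 1.5^2))
  w <- outer(g, g); w <- w / sum(w)
  H <- nrow(y); W <- ncol(y)
  vals <- c()
  for (j in 6:(W - 5)) for (i in 6:(H - 5)) {
    wy <- y[(i - 5):(i + 5), (j - 5):(j + 5)]
    wr <- yref[(i - 5):(i + 5), (j - 5):(j + 5)]
    mu1 <- sum(w * wy); mu2 <- sum(w * wr)
    s11 <- sum(w * wy^2) - mu1^2
    s22 <- sum(w * wr^2) - mu2^2
    s12 <- sum(w * wy * wr) - mu1 * mu2
    vals <- c(vals, (2 * mu1 * mu2 + c1) * (2 * s12 + c2) /
                ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)))
  }
  mean(vals)
}

# images whose joint 8-bit quantization is exact (values on the 0..255/255
# grid including both extremes), so unit-range and 8-bit SSIM coincide
exact8bitPair <- function(n, seed) {
  msimsr:::withSeed(seed, {
    y <- matrix(sample(0:255, n * n, replace = TRUE), n) / 255
    yref <- matrix(sample(0:255, n * n, replace = TRUE), n) / 255
    y[1] <- 0; y[2] <- 1
    list(y = y, yref = yref)
  })
}
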