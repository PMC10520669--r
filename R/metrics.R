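#' @name metrics
#' @title Quantitative image-quality metrics
#'
#' @description Fidelity metrics computed on 8-bit quantized images, the
#' convention under which the reported values of this field are comparable:
#' both images of a pair are linearly rescaled to a shared 0-255 range
#' (round-half-even) before PSNR, NRMSE, MSE and SSIM are evaluated.
NULL

# linear rescale of a pair to a shared 0..255 range, round-half-even
quantizePair8 <- function(y, yref) {
  lo <- min(y, yref); hi <- max(y, yref)
  stopIfNot(hi > lo, "cannot quantize: images are jointly constant")
  list(y = round((y - lo) / (hi - lo) * 255),
       yref = round((yref - lo) / (hi - lo) * 255))
}

#' Peak signal-to-noise ratio, NRMSE and MSE
#'
#' Quantizes the pair to 8 bits, then computes the mean squared error,
#' `PSNR = 20 log10(255 / sqrt(MSE))` and
#' `NRMSE = sqrt(MSE) / (max(Y) - min(Y))`. Identical images give MSE 0,
#' NRMSE 0 and `PSNR = Inf`.
#'
#' @param y image under test (numeric matrix).
#' @param yref reference image of the same dimensions.
#' @param bit8 quantize to 8 bits first (default `TRUE`).
#' @return list with `psnr_db`, `nrmse`, `mse`.
#' @export
psnrNrmseMse <- function(y, yref, bit8 = TRUE) {
  stopIfNot(all(dim(y) == dim(yref)), "images must have the same dimensions")
  if (bit8) { q <- quantizePair8(y, yref); y <- q$y; yref <- q$yref }
  mse <- mean((y - yref)^2)
  rngY <- diff(range(y))
  if (rngY <= 0) stop("NRMSE undefined: flat image", call. = FALSE)
  psnr <- if (mse == 0) Inf else 20 * log10(255 / sqrt(mse))
  list(psnr_db = psnr, nrmse = sqrt(mse) / rngY, mse = mse)
}

#' Structural similarity index (single scale)
#'
#' Mean SSIM over 11x11 Gaussian windows (sigma 1.5) with the standard
#' stabilising constants \eqn{c_1 = (0.01 \cdot 255)^2},
#' \eqn{c_2 = (0.03 \cdot 255)^2} on 8-bit quantized images. Symmetric in
#' its arguments and equal to 1 iff the images are identical.
#'
#' @inheritParams psnrNrmseMse
#' @return a scalar in `[-1, 1]`.
#' @export
ssimIndex <- function(y, yref, bit8 = TRUE) {
  stopIfNot(all(dim(y) == dim(yref)), "images must have the same dimensions")
  dataRange <- 255
  if (bit8) {
    if (max(y) == min(y) && max(yref) == min(yref) && y[1] == yref[1])
      return(1)
    q <- quantizePair8(y, yref); y <- q$y; yref <- q$yref
  }
  c1 <- (0.01 * dataRange)^2; c2 <- (0.03 * dataRange)^2
  w <- gaussKernelMatrix(1.5, radius = 5L)   # 11 x 11, sum 1
  mu1 <- convValid(y, w); mu2 <- convValid(yref, w)
  s11 <- convValid(y * y, w) - mu1^2
  s22 <- convValid(yref * yref, w) - mu2^2
  s12 <- convValid(y * yref, w) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

# 'valid' windowed convolution: zero-padded FFT conv, borders cropped
convValid <- function(x, k) {
  r <- (nrow(k) - 1) / 2
  y <- convZero(x, k)
  y[(r + 1):(nrow(y) - r), (r + 1):(ncol(y) - r)]
}

#' Resolution-scale a super-resolution image against a reference
#'
#' Builds the resolution-scaled image \eqn{I_{RS}}: the `2H x 2W`
#' super-resolution image is downsampled by 2 (2x2 block mean) and a
#' Gaussian blur of width `sigma` plus an affine intensity map
#' `a * x + b` are fitted to minimize the RMS mismatch against the
#' diffraction-limited reference (golden-section search over
#' `sigma` in `[0, 10]` px, closed-form least squares for `a`, `b`).
#'
#' @param sr an [SRImage-class] or a `2H x 2W` matrix.
#' @param reference `H x W` reference image (e.g. a wide-field image).
#' @return list with `irs` (the resolution-scaled image), `a`, `b`,
#'   `sigma`.
#' @export
resolutionScale <- function(sr, reference) {
  srm <- if (is(sr, "SRImage")) srMatrix(sr) else sr
  stopIfNot(all(dim(srm) == 2 * dim(reference)),
            "sr must be exactly twice the reference dimensions")
  down <- blockMean2(srm)
  maxR <- (min(dim(down)) - 1) %/% 2   # kernel must fit inside the image
  fitFor <- function(sigma) {
    bl <- if (sigma < 1e-3) down
          else convZero(down, gaussKernelMatrix(sigma,
                 radius = min(max(1, ceiling(4 * sigma)), maxR)))
    x <- as.vector(bl); r <- as.vector(reference)
    vx <- stats::var(x)
    a <- if (vx > 0) stats::cov(x, r) / vx else 0
    b <- mean(r) - a * mean(x)
    err <- sqrt(mean((a * bl + b - reference)^2))
    list(err = err, a = a, b = b, irs = a * bl + b)
  }
  # golden-section on sigma in [0, 10]
  phi <- (sqrt(5) - 1) / 2
  lo <- 0; hi <- 10
  x1 <- hi - phi * (hi - lo); x2 <- lo + phi * (hi - lo)
  f1 <- fitFor(x1)$err; f2 <- fitFor(x2)$err
  for (i in 1:40) {
    if (f1 < f2) { hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- fitFor(x1)$err
    } else { lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- fitFor(x2)$err }
  }
  sigma <- (lo + hi) / 2
  best <- fitFor(sigma)
  atZero <- fitFor(0)
  if (atZero$err <= best$err) { sigma <- 0; best <- atZero }
  if (!is.finite(best$err)) stop("resolution scaling failed", call. = FALSE)
  list(irs = best$irs, a = best$a, b = best$b, sigma = sigma)
}

blockMean2 <- function(x) {
  y <- avgpool2_fwd_cpp(array(x, c(dim(x), 1, 1)))
  matrix(y, dim(y)[1], dim(y)[2])
}

#' Resolution-scaled error and Pearson coefficient
#'
#' `rse` is the root-mean-square difference between the reference and the
#' resolution-scaled image; `rsp` is their Pearson correlation
#' (affine-invariant, in `[-1, 1]`).
#'
#' @param reference,irs matrices of identical dimensions.
#' @return list with `rse` and `rsp`.
#' @export
rseRsp <- function(reference, irs) {
  stopIfNot(all(dim(reference) == dim(irs)), "dimension mismatch")
  if (stats::var(as.vector(reference)) == 0 ||
      stats::var(as.vector(irs)) == 0)
    stop("RSP undefined: zero-variance image", call. = FALSE)
  list(rse = sqrt(mean((reference - irs)^2)),
       rsp = stats::cor(as.vector(reference), as.vector(irs)))
}

#' Error map between a reference and a super-resolution image
#'
#' Composes [resolutionScale()] and a per-pixel absolute difference,
#' returning the artifact map together with the global RSE/RSP scores.
#'
#' @inheritParams resolutionScale
#' @return list with `map` (matrix of `|reference - irs|`), `rse`, `rsp`,
#'   and the scaling parameters `a`, `b`, `sigma`.
#' @export
errorMap <- function(sr, reference) {
  rs <- resolutionScale(sr, reference)
  sc <- rseRsp(reference, rs$irs)
  list(map = abs(reference - rs$irs), rse = sc$rse, rsp = sc$rsp,
       a = rs$a, b = rs$b, sigma = rs$sigma)
}

#' Pixelwise absolute difference of two images
#'
#' @param imgA,imgB matrices of identical dimensions.
#' @return `|imgA - imgB|`.
#' @export
pixelwiseDiff <- function(imgA, imgB) {
  stopIfNot(all(dim(imgA) == dim(imgB)), "dimension mismatch")
  abs(imgA - imgB)
}

#' Full width at half maximum of an intensity profile
#'
#' Locates the half-maximum crossings on each side of the global maximum
#' by linear interpolation between samples and returns their distance in
#' physical units.
#'
#' @param profile numeric vector of intensity samples.
#' @param spacingNm physical distance between consecutive samples.
#' @return the FWHM in the units of `spacingNm`.
#' @export
fwhm <- function(profile, spacingNm = 1) {
  stopIfNot(length(profile) >= 3, "profile too short")
  im <- which.max(profile)
  h <- max(profile) / 2
  left <- NA_real_
  for (i in seq(im - 1, 1)) {
    if (im == 1) break
    if (profile[i] <= h) {
      left <- i + (h - profile[i]) / (profile[i + 1] - profile[i])
      break
    }
  }
  right <- NA_real_
  if (im < length(profile)) {
    for (i in seq(im + 1, length(profile))) {
      if (profile[i] <= h) {
        right <- i - 1 + (profile[i - 1] - h) / (profile[i - 1] - profile[i])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right))
    stop("no half-maximum crossing on one side", call. = FALSE)
  (right - left) * spacingNm
}
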