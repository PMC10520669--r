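#' Loss configuration
#'
#' Settings of the composite training loss
#' \eqn{L = \alpha\,(1 - \mathrm{MS\mbox{-}SSIM}(Y,\bar Y)) +
#' (1-\alpha)\, \overline{G \otimes |Y - \bar Y|}}: a multi-scale
#' structural-similarity term traded off against a Gaussian-weighted L1
#' term. Images are expected on the normalised `[0, 1]` scale, so the SSIM
#' stabilisers use a dynamic range of 1.
#'
#' @param alpha tradeoff between the MS-SSIM and L1 terms (default 0.75).
#' @param gKernelSize,gSigma size and width of the Gaussian kernel `G`
#'   that aggregates the absolute error locally (defaults 9 and 1.5).
#' @param msScales number of dyadic scales `M` (default 5; reduced
#'   automatically for patches too small to support all scales, with the
#'   `beta` weights renormalised to the same total).
#' @param beta per-scale exponents (default `c(0.1, 0.3, 0.3, 0.2, 0.1)`).
#' @param c1,c2 SSIM stabilising constants (defaults `(0.01)^2`,
#'   `(0.03)^2` for unit dynamic range).
#' @return a validated config list.
#' @export
lossConfig <- function(alpha = 0.75, gKernelSize = 9L, gSigma = 1.5,
                       msScales = 5L, beta = c(0.1, 0.3, 0.3, 0.2, 0.1),
                       c1 = 1e-4, c2 = 9e-4) {
  stopIfNot(alpha >= 0 && alpha <= 1, "alpha must be in [0, 1]")
  stopIfNot(length(beta) == msScales, "beta length must equal msScales")
  stopIfNot(all(beta > 0), "all beta must be positive")
  stopIfNot(gKernelSize %% 2 == 1, "gKernelSize must be odd")
  list(alpha = alpha, gKernelSize = as.integer(gKernelSize),
       gSigma = gSigma, msScales = as.integer(msScales), beta = beta,
       c1 = c1, c2 = c2)
}

# reduce M for small images: scale j needs floor(dim / 2^(j-1)) >= 11;
# beta is renormalised to preserve the original total weight
adaptLossScales <- function(cfg, dims) {
  M <- cfg$msScales
  while (M > 1 && min(dims[1:2]) / 2^(M - 1) < 11) M <- M - 1L
  if (M == cfg$msScales) return(cfg)
  beta <- cfg$beta[seq_len(M)]
  cfg$beta <- beta * sum(cfg$beta) / sum(beta)
  cfg$msScales <- M
  cfg
}

asTensor4 <- function(x) {
  if (is.matrix(x)) return(array(x, c(dim(x), 1L, 1L)))
  stopIfNot(length(dim(x)) == 4, "expected a matrix or [H, W, 1, N] array")
  x
}

# geometric-combination factor: mean(map)^beta; an exponent of exactly 1
# needs no clamping (and keeps the M = 1 case identical to plain SSIM),
# fractional exponents clamp the base away from zero for stability
powTerm <- function(meanNode, beta) {
  if (abs(beta - 1) < 1e-12) return(meanNode)
  tpScalarPow(tpClampMin(meanNode, 1e-6), beta)
}

# MS-SSIM as a graph node. Contrast-structure means at scales 1..M-1;
# the coarsest scale contributes the full (luminance x cs) SSIM mean, so
# M = 1 reduces exactly to single-scale SSIM. Windows are 11x11 sigma-1.5
# Gaussians evaluated on the valid region; 2x2 mean downsampling between
# scales. Negative component means are clamped at 1e-6 before the
# geometric combination.
msSSIMNode <- function(y, yref, cfg) {
  w <- gaussKernel1d(1.5, radius = 5L)
  M <- cfg$msScales
  terms <- NULL
  for (j in seq_len(M)) {
    if (j > 1) { y <- tpAvgPool(y); yref <- tpAvgPool(yref) }
    if (min(dim(y$val)[1:2]) < 11)
      stop(sprintf("image too small for %d MS-SSIM scales: needs at least %d px per side",
                   M, 11 * 2^(M - 1)), call. = FALSE)
    mu1 <- tpCropBorder(tpConvSep(y, w), 5L)
    mu2 <- tpCropBorder(tpConvSep(yref, w), 5L)
    s11 <- tpSub(tpCropBorder(tpConvSep(tpMul(y, y), w), 5L),
                 tpMul(mu1, mu1))
    s22 <- tpSub(tpCropBorder(tpConvSep(tpMul(yref, yref), w), 5L),
                 tpMul(mu2, mu2))
    s12 <- tpSub(tpCropBorder(tpConvSep(tpMul(y, yref), w), 5L),
                 tpMul(mu1, mu2))
    csNum <- tpScalarAffine(s12, 2, cfg$c2)
    csDen <- tpScalarAffine(tpAdd(s11, s22), 1, cfg$c2)
    cs <- tpDiv(csNum, csDen)
    if (j < M) {
      term <- powTerm(tpMean(cs), cfg$beta[j])
    } else {
      lNum <- tpScalarAffine(tpMul(mu1, mu2), 2, cfg$c1)
      lDen <- tpScalarAffine(tpAdd(tpMul(mu1, mu1), tpMul(mu2, mu2)), 1,
                             cfg$c1)
      ssimMap <- tpMul(tpDiv(lNum, lDen), cs)
      term <- powTerm(tpMean(ssimMap), cfg$beta[M])
    }
    terms <- if (is.null(terms)) term else tpScalarMul(terms, term)
  }
  terms
}

#' Multi-scale structural similarity
#'
#' Evaluates MS-SSIM between two images on the normalised `[0, 1]` scale:
#' contrast/structure terms over `M` dyadic scales and the luminance term
#' at the coarsest scale, combined geometrically with the `beta`
#' exponents. Symmetric in its arguments; 1 iff identical.
#'
#' @param y,yref numeric matrices (or `[H, W, 1, N]` arrays) of identical
#'   dimensions.
#' @param cfg a [lossConfig()].
#' @param autoReduce if `TRUE`, reduce the scale count for small images
#'   instead of erroring.
#' @return a scalar in `(0, 1]`.
#' @export
msSSIM <- function(y, yref, cfg = lossConfig(), autoReduce = FALSE) {
  y <- asTensor4(y); yref <- asTensor4(yref)
  stopIfNot(all(dim(y) == dim(yref)), "images must have the same dimensions")
  if (autoReduce) cfg <- adaptLossScales(cfg, dim(y))
  msSSIMNode(tpConst(y), tpConst(yref), cfg)$val
}

# composite loss as a graph node (inputs on the normalised scale)
msimLossNode <- function(y, yref, cfg) {
  cfg <- adaptLossScales(cfg, dim(y$val))
  ms <- msSSIMNode(y, yref, cfg)
  g <- gaussKernel1d(cfg$gSigma, radius = (cfg$gKernelSize - 1L) %/% 2L)
  l1 <- tpMean(tpCropBorder(tpConvSep(tpAbs(tpSub(y, yref)), g),
                            (cfg$gKernelSize - 1L) %/% 2L))
  tpScalarAdd(tpScalarAffine(ms, -cfg$alpha, cfg$alpha),
              tpScalarAffine(l1, 1 - cfg$alpha, 0))
}

#' Composite MS-SSIM + Gaussian-weighted L1 loss
#'
#' The training objective
#' \eqn{L = \alpha\,(1-\mathrm{MS\mbox{-}SSIM}) + (1-\alpha)\,
#' \overline{G \otimes |Y-\bar Y|}} where `G` is the unit-sum
#' `gKernelSize x gKernelSize` Gaussian of width `gSigma` and the bar is
#' the mean over the valid region. Zero iff the images are identical.
#'
#' @inheritParams msSSIM
#' @return a nonnegative scalar.
#' @export
msimLoss <- function(y, yref, cfg = lossConfig()) {
  y <- asTensor4(y); yref <- asTensor4(yref)
  stopIfNot(all(dim(y) == dim(yref)), "images must have the same dimensions")
  msimLossNode(tpConst(y), tpConst(yref), cfg)$val
}
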