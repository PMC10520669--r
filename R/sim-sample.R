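#' Synthetic spoke (Siemens-star) resolution phantom
#'
#' Builds the radial test sample whose fluorescence density is
#' \eqn{\rho(r,\theta) \propto 1 + \cos(n_{lobes}\,\theta)} in polar
#' coordinates about the grid center. The spoke spacing shrinks toward the
#' center, so a single phantom probes resolution continuously; changing
#' `nLobes` changes the spoke width.
#'
#' @param sizePx side length of the square grid (>= 32).
#' @param nLobes number of angular intensity lobes (default 48).
#' @param pixelSizeNm physical pixel size in nanometres (default 130).
#' @return a [SampleMap-class] with peak density 1.
#' @examples
#' sp <- makeSpokeSample(64, nLobes = 12)
#' range(sampleDensity(sp))
#' @export
makeSpokeSample <- function(sizePx, nLobes = 48L, pixelSizeNm = 130) {
  stopIfNot(length(sizePx) == 1 && sizePx >= 32, "sizePx must be >= 32")
  stopIfNot(length(nLobes) == 1 && nLobes >= 1, "nLobes must be >= 1")
  stopIfNot(pixelSizeNm > 0, "pixelSizeNm must be positive")
  c0 <- (sizePx + 1) / 2
  x <- matrix(rep(seq_len(sizePx) - c0, each = sizePx), sizePx)   # col offsets
  y <- matrix(rep(seq_len(sizePx) - c0, times = sizePx), sizePx)  # row offsets
  theta <- atan2(y, x)
  dens <- (1 + cos(nLobes * theta)) / 2
  dens <- dens / max(dens)
  new("SampleMap", density = dens, pixelSizeNm = pixelSizeNm,
      descriptor = sprintf("spoke n_lobes=%d", as.integer(nLobes)))
}

#' Random structured phantoms for training diversity
#'
#' Generates deterministic pseudo-random samples in two styles:
#' `"filaments"` (curved line segments, loosely resembling cytoskeletal
#' networks) and `"blobs"` (a mixture of Gaussian spots of varying width,
#' loosely resembling vesicles or mitochondria). Peak density is 1.
#'
#' @param sizePx side length of the square grid (>= 32).
#' @param style `"filaments"` or `"blobs"`.
#' @param seed integer seed; the same seed reproduces the same sample.
#' @param pixelSizeNm physical pixel size in nanometres.
#' @return a [SampleMap-class].
#' @export
makeRandomStructureSample <- function(sizePx, style = c("filaments", "blobs"),
                                      seed = 1L, pixelSizeNm = 130) {
  stopIfNot(length(sizePx) == 1 && sizePx >= 32, "sizePx must be >= 32")
  style <- match.arg(style)
  dens <- withSeed(seed, {
    acc <- matrix(0, sizePx, sizePx)
    if (style == "filaments") {
      nLines <- max(4L, round(sizePx / 12))
      for (l in seq_len(nLines)) {
        pos <- runif(2, 1, sizePx)
        ang <- runif(1, 0, 2 * pi)
        curv <- rnorm(1, 0, 0.08)
        nSteps <- round(sizePx * runif(1, 0.8, 2))
        for (s in seq_len(nSteps)) {
          ang <- ang + curv + rnorm(1, 0, 0.03)
          pos <- pos + c(sin(ang), cos(ang))
          r <- round(pos[1]); cc <- round(pos[2])
          if (r < 1 || r > sizePx || cc < 1 || cc > sizePx) break
          acc[r, cc] <- acc[r, cc] + 1
        }
      }
      # ~1 px wide smoothing so filaments are resolvable but still sparse
      acc <- convZero(acc, gaussKernelMatrix(0.7))
    } else {
      nBlobs <- max(6L, round(sizePx / 8))
      c0 <- seq_len(sizePx)
      for (b in seq_len(nBlobs)) {
        mu <- runif(2, sizePx * 0.1, sizePx * 0.9)
        sg <- runif(1, 1, sizePx / 16)
        amp <- runif(1, 0.3, 1)
        gx <- exp(-((c0 - mu[2])^2) / (2 * sg^2))
        gy <- exp(-((c0 - mu[1])^2) / (2 * sg^2))
        acc <- acc + amp * outer(gy, gx)
      }
    }
    acc
  })
  if (max(dens) > 0) dens <- dens / max(dens)
  dens[dens < 1e-4] <- 0
  new("SampleMap", density = dens, pixelSizeNm = pixelSizeNm,
      descriptor = sprintf("%s seed=%d", style, as.integer(seed)))
}
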