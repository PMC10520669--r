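#' Write and read raw stacks as multi-page TIFF
#'
#' Stacks are stored as one float32 page per frame. Because baseline TIFF
#' float samples live in `[0, 1]`, values are divided by a power-of-two
#' scale factor (exact in floating point) recorded in a JSON sidecar
#' (`<path>.json`) together with the acquisition metadata (lattice
#' spacing, scan step, pixel size, noise, seed), so the round trip is
#' lossless at float32 precision.
#'
#' @param stack a [RawStack-class].
#' @param path output TIFF path.
#' @param bits 32 (float) or 16 (uint16, with the same recorded scale).
#' @return `writeStack` returns `path` invisibly; `readStack` returns the
#'   restored [RawStack-class].
#' @export
writeStack <- function(stack, path, bits = 32L) {
  fr <- stackFrames(stack)
  mx <- max(fr)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  if (bits == 16L) scale <- mx          # use the full uint16 range
  pages <- lapply(seq_len(dim(fr)[3]), function(i)
    if (scale > 0) fr[, , i] / scale else fr[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  reduce = FALSE)
  sched <- stack@schedule
  meta <- list(spacing_px = sched@spacingPx, step_px = sched@stepPx,
               frame_shape = as.integer(sched@frameShape),
               n_frames = sched@nFrames,
               pixel_size_nm = stack@pixelSizeNm,
               noise = list(gauss_sigma = stack@noise$gaussSigma,
                            photon_scale = stack@noise$photonScale),
               seed = stack@seed, scale = scale, bits = as.integer(bits))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3)
    stop("unsupported format: multi-channel/RGB TIFF", call. = FALSE)
  sidecar <- paste0(path, ".json")
  stopIfNot(file.exists(sidecar), "missing metadata sidecar (.json)")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  d <- dim(pages[[1]])
  frames <- array(0, c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * scale
  sched <- buildSchedule(meta$frame_shape, meta$spacing_px, meta$step_px)
  ps <- if (is.null(meta$noise$photon_scale)) NA_real_
        else as.numeric(meta$noise$photon_scale)
  new("RawStack", frames = frames, schedule = sched,
      pixelSizeNm = meta$pixel_size_nm,
      noise = list(gaussSigma = meta$noise$gauss_sigma, photonScale = ps),
      seed = if (is.null(meta$seed)) NA_real_ else as.numeric(meta$seed))
}

# single-image float TIFF with the same power-of-two scaling scheme
writeImageTiff <- function(img, path) {
  mx <- max(img)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  tiff::writeTIFF(img / scale, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

readImageTiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3)
    stop("unsupported format: multi-channel/RGB TIFF", call. = FALSE)
  sidecar <- paste0(path, ".json")
  scale <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)$scale else 1
  img * scale
}

#' Pseudocolor PNG export (visualisation only)
#'
#' Maps an intensity image through a named palette and writes a PNG.
#' Never part of any quantitative path.
#'
#' @param img numeric matrix.
#' @param path output PNG path.
#' @param palette palette name for [grDevices::hcl.colors()].
#' @export
exportPng <- function(img, path, palette = "viridis") {
  cols <- grDevices::hcl.colors(256, palette)
  rgb <- grDevices::col2rgb(cols) / 255
  idx <- pmin(255L, pmax(0L, floor((img - min(img)) /
                                     max(1e-12, diff(range(img))) * 255))) + 1L
  arr <- array(0, c(nrow(img), ncol(img), 3))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, idx], nrow(img))
  png::writePNG(arr, path)
  invisible(path)
}

# ---- run configuration ---------------------------------------------------

runConfigDefaults <- function() {
  list(
    seed = 1L, log_level = "info",
    simulate = list(sample = "spoke", size = 256L, n_lobes = 48L,
                    spacing = 16L, step = 1L, pixel_size_nm = 130,
                    wavelength_nm = 560, na = 1.1, gauss_sigma = 0,
                    photon_scale = NA, defocus_um = 0, two_photon = FALSE),
    network = list(encoder_widths = c(32L, 64L, 128L, 256L),
                   dense_L = c(0L, 3L, 5L), dense_k = c(0L, 32L, 8L),
                   dropout_p = 0.5, skip_mode = "dense",
                   upsample_mode = "nearest", use_bn = TRUE,
                   use_dropout = TRUE),
    loss = list(alpha = 0.75, g_kernel_size = 9L, g_sigma = 1.5,
                ms_scales = 5L, beta = c(0.1, 0.3, 0.3, 0.2, 0.1)),
    train = list(lr = 1e-3, epochs = 50L, batch = 8L, n_pairs = 5120L,
                 split_train = 0.7, scheme = "standard"),
    reconstruct = list(method = "conventional", foci_mode = "oracle",
                       pinhole_sigma_px = NA, n_iter = 20L,
                       deconvolve = TRUE, denoise_sigma = 1,
                       threshold_frac = 0.3),
    evaluate = list(bit8 = TRUE))
}

#' Load a run configuration (YAML or JSON)
#'
#' Fills unspecified keys with package defaults and rejects unknown keys,
#' naming the offending key path. An empty file yields all defaults.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`), or `NULL` for
#'   pure defaults.
#' @return the resolved configuration list.
#' @export
loadRunConfig <- function(path = NULL) {
  defaults <- runConfigDefaults()
  if (is.null(path)) return(defaults)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  mergeConfig(defaults, user, "")
}

mergeConfig <- function(def, usr, prefix) {
  for (nm in names(usr)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (!nm %in% names(def))
      stop("unknown config key: ", key, call. = FALSE)
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      def[[nm]] <- mergeConfig(def[[nm]], as.list(usr[[nm]]), key)
    } else {
      def[[nm]] <- usr[[nm]]
    }
  }
  def
}

# ---- fixtures ------------------------------------------------------------

# order-dependent numeric summary used to fingerprint generated fixtures
summaryHash <- function(x) {
  v <- as.numeric(x)
  w <- seq_along(v) %% 997
  sprintf("%d:%.10e:%.10e", length(v), sum(v), sum(v * w))
}

#' Generate the named small test fixtures
#'
#' Deterministically creates `spoke-64` (64 px spoke phantom), `bead-64`
#' (a single sub-resolution emitter) and `stack-64-s8` (a noisy raw stack
#' of the spoke under an 8 px lattice at unit step, 64 frames), writes
#' them under `outdir` and returns their summary fingerprints. The test
#' suite regenerates these in code, so no external download is ever
#' needed.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed.
#' @return list with per-fixture paths and fingerprints.
#' @export
makeFixtures <- function(outdir, seed = 7L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spoke <- makeSpokeSample(64L, nLobes = 48L)
  bead <- beadSample(64L)
  ex <- makeGaussianPsf(560, 1.1, 130, role = "excitation")
  em <- makeGaussianPsf(560, 1.1, 130, role = "emission")
  sched <- buildSchedule(c(64L, 64L), spacingPx = 8L, stepPx = 1L)
  stack <- simulateStack(spoke, sched, ex, em,
                         noise = list(gaussSigma = 0.002, photonScale = 2000),
                         seed = seed)
  writeImageTiff(sampleDensity(spoke), file.path(outdir, "spoke-64.tif"))
  writeImageTiff(sampleDensity(bead), file.path(outdir, "bead-64.tif"))
  writeStack(stack, file.path(outdir, "stack-64-s8.tif"))
  out <- list(
    `spoke-64` = list(path = file.path(outdir, "spoke-64.tif"),
                      hash = summaryHash(sampleDensity(spoke))),
    `bead-64` = list(path = file.path(outdir, "bead-64.tif"),
                     hash = summaryHash(sampleDensity(bead))),
    `stack-64-s8` = list(path = file.path(outdir, "stack-64-s8.tif"),
                         hash = summaryHash(stackFrames(stack)),
                         n_frames = nFrames(stack)))
  jsonlite::write_json(out, file.path(outdir, "fixtures.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}

# a single sub-resolution emitter at the grid center (for FWHM probes)
beadSample <- function(sizePx, pixelSizeNm = 130) {
  d <- matrix(0, sizePx, sizePx)
  d[sizePx / 2, sizePx / 2] <- 1
  new("SampleMap", density = d, pixelSizeNm = pixelSizeNm,
      descriptor = sprintf("bead size=%d", sizePx))
}
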