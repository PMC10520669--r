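#' @name msimsr-accessors
#' @title Accessors for msimsr data classes
#'
#' @description Small accessor generics so user code never reaches into
#' slots: `sampleDensity()` returns the ground-truth density matrix,
#' `psfMatrix()`/`psfSigma()` the rendered kernel and its width,
#' `frameShape()`, `spacingPx()`, `stepPx()`, `nFrames()` and `fociOf()`
#' interrogate an illumination schedule, `stackFrames()` returns the raw
#' frame array, and `srMatrix()` the reconstructed image matrix.
#'
#' @param object an msimsr object.
#' @param i frame index.
#' @return the corresponding slot value.
NULL

#' @rdname msimsr-accessors
#' @export
setGeneric("sampleDensity", function(object) standardGeneric("sampleDensity"))
#' @rdname msimsr-accessors
#' @export
setGeneric("pixelSizeNm", function(object) standardGeneric("pixelSizeNm"))
#' @rdname msimsr-accessors
#' @export
setGeneric("psfMatrix", function(object) standardGeneric("psfMatrix"))
#' @rdname msimsr-accessors
#' @export
setGeneric("psfSigma", function(object) standardGeneric("psfSigma"))
#' @rdname msimsr-accessors
#' @export
setGeneric("frameShape", function(object) standardGeneric("frameShape"))
#' @rdname msimsr-accessors
#' @export
setGeneric("spacingPx", function(object) standardGeneric("spacingPx"))
#' @rdname msimsr-accessors
#' @export
setGeneric("stepPx", function(object) standardGeneric("stepPx"))
#' @rdname msimsr-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname msimsr-accessors
#' @export
setGeneric("fociOf", function(object, i) standardGeneric("fociOf"))
#' @rdname msimsr-accessors
#' @export
setGeneric("stackFrames", function(object) standardGeneric("stackFrames"))
#' @rdname msimsr-accessors
#' @export
setGeneric("srMatrix", function(object) standardGeneric("srMatrix"))

#' @rdname msimsr-accessors
#' @export
setMethod("sampleDensity", "SampleMap", function(object) object@density)
#' @rdname msimsr-accessors
#' @export
setMethod("pixelSizeNm", "SampleMap", function(object) object@pixelSizeNm)
#' @rdname msimsr-accessors
#' @export
setMethod("pixelSizeNm", "RawStack", function(object) object@pixelSizeNm)
#' @rdname msimsr-accessors
#' @export
setMethod("pixelSizeNm", "SRImage", function(object) object@pixelSizeNm)
#' @rdname msimsr-accessors
#' @export
setMethod("psfMatrix", "PsfKernel", function(object) object@kernel)
#' @rdname msimsr-accessors
#' @export
setMethod("psfSigma", "PsfKernel", function(object) object@sigmaPx)
#' @rdname msimsr-accessors
#' @export
setMethod("frameShape", "IlluminationSchedule", function(object) object@frameShape)
#' @rdname msimsr-accessors
#' @export
setMethod("frameShape", "RawStack",
          function(object) object@schedule@frameShape)
#' @rdname msimsr-accessors
#' @export
setMethod("spacingPx", "IlluminationSchedule", function(object) object@spacingPx)
#' @rdname msimsr-accessors
#' @export
setMethod("stepPx", "IlluminationSchedule", function(object) object@stepPx)
#' @rdname msimsr-accessors
#' @export
setMethod("nFrames", "IlluminationSchedule", function(object) object@nFrames)
#' @rdname msimsr-accessors
#' @export
setMethod("nFrames", "RawStack", function(object) object@schedule@nFrames)
#' @rdname msimsr-accessors
#' @export
setMethod("fociOf", "IlluminationSchedule", function(object, i) {
  if (i < 1 || i > object@nFrames) stop("frame index out of range")
  object@foci[[i]]
})
#' @rdname msimsr-accessors
#' @export
setMethod("fociOf", "FociSet", function(object, i) object@foci[[i]])
#' @rdname msimsr-accessors
#' @export
setMethod("stackFrames", "RawStack", function(object) object@frames)
#' @rdname msimsr-accessors
#' @export
setMethod("srMatrix", "SRImage", function(object) object@image)

setMethod("show", "SampleMap", function(object) {
  d <- dim(object@density)
  cat(sprintf("SampleMap %dx%d px (%.0f nm/px) peak=%.3g  %s\n",
              d[1], d[2], object@pixelSizeNm, max(object@density),
              object@descriptor))
})

setMethod("show", "PsfKernel", function(object) {
  cat(sprintf("PsfKernel (%s) sigma=%.3f px, %dx%d, lambda=%.0f nm NA=%.2f defocus=%.1f um\n",
              object@role, object@sigmaPx, nrow(object@kernel),
              ncol(object@kernel), object@wavelengthNm, object@na,
              object@defocusUm))
})

setMethod("show", "IlluminationSchedule", function(object) {
  cat(sprintf("IlluminationSchedule %dx%d px, spacing=%d step=%d -> %d frames (%d foci/frame)\n",
              object@frameShape[1], object@frameShape[2], object@spacingPx,
              object@stepPx, object@nFrames, nrow(object@foci[[1]])))
})

setMethod("show", "RawStack", function(object) {
  d <- dim(object@frames)
  ns <- object@noise
  cat(sprintf("RawStack %d frames of %dx%d px (%.0f nm/px), gaussSigma=%.3g photonScale=%s\n",
              d[3], d[1], d[2], object@pixelSizeNm, ns$gaussSigma,
              ifelse(is.na(ns$photonScale), "none",
                     format(ns$photonScale))))
})

setMethod("show", "SRImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("SRImage %dx%d px (%.1f nm/px), provenance=%s, %d frames used\n",
              d[1], d[2], object@pixelSizeNm, object@provenance,
              object@nFramesUsed))
})

setMethod("show", "FociSet", function(object) {
  cat(sprintf("FociSet (%s): %d frames, %s foci in frame 1\n",
              object@detectionMode, length(object@foci),
              nrow(object@foci[[1]])))
})
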