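#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname accessors
#' @export
setGeneric("elementPositions", function(x) standardGeneric("elementPositions"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Apply a forward model to an image
#'
#' @param model a [ForwardModel-class].
#' @param x image: matrix of the geometry's grid shape, a
#'   [ReconImage-class], or an already-vectorized numeric vector.
#' @return a [SignalFrame-class] of simulated signals.
#' @export
setGeneric("applyModel", function(model, x) standardGeneric("applyModel"))

#' Apply the adjoint of a forward model to signals
#'
#' @param model a [ForwardModel-class].
#' @param x signals: a [SignalFrame-class], an nElements x nSamples matrix,
#'   or a stacked numeric vector.
#' @return numeric matrix, the back-projected image on the geometry grid.
#' @export
setGeneric("applyAdjoint", function(model, x) standardGeneric("applyAdjoint"))

# -- accessor methods ---------------------------------------------------

#' Accessors for msotpipe classes
#'
#' Small read-only accessors; user code should use these rather than `@`.
#'
#' @param x an object of the documented classes.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("pixels", "ReconImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "USImage", function(x) x@pixels)
#' @rdname accessors
setMethod("wavelengths", "MultispectralFrame", function(x) x@wavelengths)
#' @rdname accessors
setMethod("wavelengths", "ChromophoreLibrary", function(x) x@wavelengths)
#' @rdname accessors
setMethod("samplingRate", "SignalFrame", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "ProbeGeometry", function(x) x@samplingRate)
#' @rdname accessors
setMethod("signalData", "SignalFrame", function(x) x@data)
#' @rdname accessors
setMethod("elementPositions", "ProbeGeometry", function(x) x@elementPositions)
#' @rdname accessors
setMethod("provenance", "ReconImage", function(x) x@provenance)

# -- show methods -------------------------------------------------------

setMethod("show", "ProbeGeometry", function(object) {
  cat(sprintf(
    "ProbeGeometry: %d elements on a %.0f-degree arc (chord %.1f mm)\n",
    object@nElements, object@arcCoverage, object@endpointDistance))
  cat(sprintf("  interface at y = %.2f mm; SoS water %.0f / tissue %.0f m/s\n",
              object@interfaceDepth, object@sosWater, object@sosTissue))
  cat(sprintf("  sampling %.2f MHz x %d samples; FOV %.0f x %.0f mm on %d x %d px\n",
              object@samplingRate / 1e6, object@nSamples,
              object@fov[1], object@fov[2],
              object@gridShape[1], object@gridShape[2]))
})

setMethod("show", "ForwardModel", function(object) {
  cat(sprintf("ForwardModel (%s SoS): %d x %d sparse, %.2e nonzeros\n",
              object@sosMode, nrow(object@matrix), ncol(object@matrix),
              length(object@matrix@x)))
  cat(sprintf("  TIR kernel length %d (origin %d)\n",
              length(object@tir@samples), object@tir@originIndex))
})

setMethod("show", "SignalFrame", function(object) {
  cat(sprintf("SignalFrame: %d elements x %d samples at %.2f MHz",
              nrow(object@data), ncol(object@data), object@samplingRate / 1e6))
  if (is.finite(object@wavelength))
    cat(sprintf(", lambda = %.0f nm", object@wavelength))
  cat("\n")
})

setMethod("show", "ReconImage", function(object) {
  cat(sprintf("ReconImage: %d x %d px", nrow(object@pixels), ncol(object@pixels)))
  if (is.finite(object@wavelength))
    cat(sprintf(", lambda = %.0f nm", object@wavelength))
  if (length(object@provenance))
    cat(sprintf(" [%s]", paste(names(object@provenance), collapse = ", ")))
  cat("\n")
})

setMethod("show", "MultispectralFrame", function(object) {
  d <- dim(object@data)
  cat(sprintf("MultispectralFrame %d: %d x %d px, %d wavelengths (%g-%g nm)\n",
              object@frameIndex, d[1], d[2], d[3],
              min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "DisplacementField", function(object) {
  m <- sqrt(object@dx^2 + object@dy^2)
  cat(sprintf("DisplacementField: %d x %d px, |d| mean %.3f / max %.3f px\n",
              nrow(object@dx), ncol(object@dx), mean(m), max(m)))
})

setMethod("show", "AffineTransform2D", function(object) {
  cat("AffineTransform2D [A | t] (pixels, centre-origin):\n")
  print(round(object@matrix, 5))
})

setMethod("show", "ChromophoreLibrary", function(object) {
  cat(sprintf("ChromophoreLibrary: %d wavelengths (%g-%g nm), channels: %s\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths),
              paste(colnames(object@spectra), collapse = ", ")))
})

setMethod("show", "USImage", function(object) {
  cat(sprintf("USImage: %d x %d px, t = %.3f s\n",
              nrow(object@pixels), ncol(object@pixels), object@timestamp))
})
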