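#' @import methods
#' @importFrom Matrix sparseMatrix crossprod t
#' @importFrom stats median quantile rnorm runif optimize sd var convolve
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

#' ProbeGeometry: handheld arc probe and imaging grid
#'
#' Describes the detection geometry of a handheld optoacoustic probe:
#' piezoelectric elements on a circular arc, a planar acoustic interface
#' separating the coupling-cavity medium (heavy water) from tissue, the
#' acquisition clock, and the reconstruction grid.
#'
#' The coordinate frame is 2-D, in millimetres: \code{x} lateral (0 at the
#' probe axis), \code{y} depth, increasing away from the probe. Elements lie
#' strictly above the interface (\code{y < interfaceDepth}); the imaging
#' grid lies at or below it. The grid is pixel-centred: pixel \code{[i, j]}
#' (row \code{i} = depth, column \code{j} = lateral) sits at
#' \code{x = xmin + (j-1)*pitch}, \code{y = interfaceDepth + (i-1)*pitch}.
#'
#' @slot nElements integer, number of detector elements.
#' @slot arcCoverage numeric, angular coverage of the arc in degrees.
#' @slot endpointDistance numeric, chord between first and last element, mm.
#' @slot interfaceDepth numeric, y of the planar water/tissue interface, mm.
#' @slot sosWater numeric, speed of sound in the cavity (heavy water), m/s.
#' @slot sosTissue numeric, speed of sound in tissue, m/s.
#' @slot samplingRate numeric, samples per second.
#' @slot nSamples integer, samples per acquired trace.
#' @slot fov numeric length-2, field of view (x-width, y-depth), mm.
#' @slot gridShape integer length-2, image grid (rows, cols).
#' @slot elementPositions numeric matrix nElements x 2, element (x, y), mm.
#'
#' @seealso [probeGeometry()] for the user constructor.
#' @export
setClass("ProbeGeometry", representation(
  nElements = "integer",
  arcCoverage = "numeric",
  endpointDistance = "numeric",
  interfaceDepth = "numeric",
  sosWater = "numeric",
  sosTissue = "numeric",
  samplingRate = "numeric",
  nSamples = "integer",
  fov = "numeric",
  gridShape = "integer",
  elementPositions = "matrix"
))

setValidity("ProbeGeometry", function(object) {
  msg <- character()
  if (object@nElements < 1L) msg <- c(msg, "nElements must be >= 1")
  if (object@arcCoverage <= 0 || object@arcCoverage >= 360)
    msg <- c(msg, "arcCoverage must be in (0, 360) degrees")
  if (object@endpointDistance <= 0) msg <- c(msg, "endpointDistance must be > 0")
  if (object@sosWater <= 0 || object@sosTissue <= 0)
    msg <- c(msg, "speeds of sound must be > 0")
  if (length(object@fov) != 2L || any(object@fov <= 0))
    msg <- c(msg, "fov must be two positive lengths (mm)")
  if (length(object@gridShape) != 2L || any(object@gridShape < 2L))
    msg <- c(msg, "gridShape must be two integers >= 2")
  if (object@samplingRate < 2 * 8e6)
    msg <- c(msg, "samplingRate must satisfy Nyquist for the 8 MHz upper cut-off (>= 16 MHz)")
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (!is.matrix(object@elementPositions) ||
      nrow(object@elementPositions) != object@nElements ||
      ncol(object@elementPositions) != 2L)
    msg <- c(msg, "elementPositions must be an nElements x 2 matrix")
  else if (any(object@elementPositions[, 2] >= object@interfaceDepth))
    msg <- c(msg, "all elements must lie strictly above the interface (y < interfaceDepth)")
  if (length(msg)) msg else TRUE
})

#' TIRKernel: total impulse response of the detection chain
#'
#' A shared 1-D temporal kernel summarizing the electro-mechanical response
#' of the transducer/amplifier chain, applied by convolution in the acoustic
#' forward model. A delta kernel (single 1 at the origin) acts as the
#' identity.
#'
#' @slot samples numeric vector, unitless impulse response sampled at the
#'   geometry's sampling rate.
#' @slot originIndex integer, 1-based index of the t = 0 sample.
#' @seealso [tirKernel()], [deltaKernel()]
#' @export
setClass("TIRKernel", representation(
  samples = "numeric",
  originIndex = "integer"
))

setValidity("TIRKernel", function(object) {
  msg <- character()
  if (length(object@samples) < 1L) msg <- c(msg, "kernel must be non-empty")
  if (!all(is.finite(object@samples))) msg <- c(msg, "kernel values must be finite")
  if (object@originIndex < 1L || object@originIndex > length(object@samples))
    msg <- c(msg, "originIndex must index into samples")
  if (length(msg)) msg else TRUE
})

#' ForwardModel: discretized acoustic forward operator
#'
#' Sparse linear operator mapping an initial-pressure image (vectorized
#' column-major) to stacked per-element time traces. Rows are ordered
#' element-major: row \code{(i-1)*nSamples + k} is sample \code{k} of
#' element \code{i}. Travel times follow Fermat's principle through the
#' two-medium geometry (or straight rays in uniform mode), with 2-D
#' geometric decay, a discrete temporal derivative, and TIR convolution
#' baked into the matrix.
#'
#' @slot matrix a \code{dgCMatrix}, (nElements*nSamples) x nPixels.
#' @slot geometry the [ProbeGeometry-class] used to build it.
#' @slot tir the [TIRKernel-class] baked into the operator.
#' @slot sosMode character, \code{"dual"} or \code{"uniform"}.
#' @seealso [assembleForwardModel()], [applyModel()], [applyAdjoint()]
#' @export
setClass("ForwardModel", representation(
  matrix = "dgCMatrix",
  geometry = "ProbeGeometry",
  tir = "TIRKernel",
  sosMode = "character"
))

setValidity("ForwardModel", function(object) {
  g <- object@geometry
  msg <- character()
  if (!object@sosMode %in% c("dual", "uniform"))
    msg <- c(msg, "sosMode must be 'dual' or 'uniform'")
  if (nrow(object@matrix) != g@nElements * g@nSamples)
    msg <- c(msg, "matrix rows must equal nElements * nSamples")
  if (ncol(object@matrix) != prod(g@gridShape))
    msg <- c(msg, "matrix cols must equal prod(gridShape)")
  if (length(msg)) msg else TRUE
})

#' SignalFrame: per-element acoustic time series at one wavelength
#'
#' @slot data numeric matrix, nElements x nSamples.
#' @slot samplingRate numeric, samples per second.
#' @slot wavelength numeric, illumination wavelength in nm (NA if n/a).
#' @export
setClass("SignalFrame", representation(
  data = "matrix",
  samplingRate = "numeric",
  wavelength = "numeric"
))

setValidity("SignalFrame", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' ReconImage: a reconstructed single-wavelength image
#'
#' Initial-pressure map in arbitrary units on the geometry grid, together
#' with acquisition wavelength and reconstruction provenance (band-pass
#' variant, regularization weight, speed-of-sound mode, solver settings).
#'
#' @slot pixels numeric matrix (rows = depth, cols = lateral).
#' @slot wavelength numeric, nm (NA if not applicable).
#' @slot provenance list of reconstruction parameters.
#' @export
setClass("ReconImage", representation(
  pixels = "matrix",
  wavelength = "numeric",
  provenance = "list"
))

setValidity("ReconImage", function(object) {
  if (!is.numeric(object@pixels)) return("pixels must be numeric")
  TRUE
})

#' MultispectralFrame: one multispectral stack of reconstructed images
#'
#' Ordered set of single-wavelength images on a shared grid; the standard
#' acquisition covers 28 wavelengths, 700-970 nm in 10 nm steps.
#'
#' @slot data numeric 3-D array, rows x cols x nWavelengths.
#' @slot wavelengths numeric vector, nm, strictly increasing.
#' @slot frameIndex integer, position in the acquired sequence.
#' @export
setClass("MultispectralFrame", representation(
  data = "array",
  wavelengths = "numeric",
  frameIndex = "integer"
))

setValidity("MultispectralFrame", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array (rows x cols x wavelengths)")
  else if (dim(object@data)[3] != length(object@wavelengths))
    msg <- c(msg, "third dimension must match length(wavelengths)")
  if (is.unsorted(object@wavelengths, strictly = TRUE))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' DisplacementField: a dense 2-D warp
#'
#' Pixelwise displacement vectors \code{(dx, dy)} in pixel units, using the
#' pull-back convention: the warped image at pixel \code{x} samples the
#' source image at \code{x + d(x)}.
#'
#' @slot dx numeric matrix, lateral (column) displacement in pixels.
#' @slot dy numeric matrix, depth (row) displacement in pixels.
#' @slot smoothnessScale numeric, Gaussian smoothing scale used, pixels.
#' @export
setClass("DisplacementField", representation(
  dx = "matrix",
  dy = "matrix",
  smoothnessScale = "numeric"
))

setValidity("DisplacementField", function(object) {
  msg <- character()
  if (!all(dim(object@dx) == dim(object@dy)))
    msg <- c(msg, "dx and dy must share a shape")
  if (!all(is.finite(object@dx)) || !all(is.finite(object@dy)))
    msg <- c(msg, "displacements must be finite")
  if (length(msg)) msg else TRUE
})

#' AffineTransform2D: a 2-D affine map in pixel coordinates
#'
#' Stored as a 2x3 matrix \code{[A | t]} acting on (col, row) coordinates
#' relative to the image centre: \code{x' = A x + t}.
#'
#' @slot matrix numeric 2x3 matrix (linear part | translation, pixels).
#' @export
setClass("AffineTransform2D", representation(matrix = "matrix"))

setValidity("AffineTransform2D", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || nrow(m) != 2L || ncol(m) != 3L)
    return("matrix must be numeric 2x3")
  if (abs(det(m[, 1:2])) < .Machine$double.eps * 100)
    return("linear part must be non-singular")
  TRUE
})

#' USImage: a grayscale ultrasound frame
#'
#' @slot pixels numeric matrix, non-negative echo intensity.
#' @slot timestamp numeric, acquisition time in seconds.
#' @export
setClass("USImage", representation(
  pixels = "matrix",
  timestamp = "numeric"
))

setValidity("USImage", function(object) {
  msg <- character()
  if (!all(is.finite(object@pixels))) msg <- c(msg, "pixels must be finite")
  if (any(object@pixels < 0)) msg <- c(msg, "echo intensity must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ChromophoreLibrary: absorption spectra of tissue chromophores
#'
#' Matrix of absorption spectra (rows = wavelengths, columns = HbO2, Hb,
#' fat, water) on a nm wavelength grid, in relative absorption units, used
#' for constrained linear unmixing.
#'
#' @slot wavelengths numeric vector, nm.
#' @slot spectra numeric matrix, length(wavelengths) x 4, columns named
#'   \code{HbO2, Hb, fat, water}.
#' @seealso [chromophoreLibrary()], [defaultChromophoreLibrary()]
#' @export
setClass("ChromophoreLibrary", representation(
  wavelengths = "numeric",
  spectra = "matrix"
))

setValidity("ChromophoreLibrary", function(object) {
  msg <- character()
  if (nrow(object@spectra) != length(object@wavelengths))
    msg <- c(msg, "spectra rows must match wavelengths")
  if (any(object@spectra < 0)) msg <- c(msg, "absorption must be non-negative")
  if (is.null(colnames(object@spectra)))
    msg <- c(msg, "spectra columns must be named")
  if (any(apply(object@spectra, 2, function(col) all(col == 0))))
    msg <- c(msg, "no chromophore column may be all zero")
  if (length(msg)) msg else TRUE
})
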