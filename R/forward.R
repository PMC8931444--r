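#' Assemble the discretized acoustic forward model
#'
#' Builds the sparse operator mapping a vectorized (column-major) image of
#' initial pressure to stacked per-element time traces. For every
#' pixel/element pair the arrival time is the Fermat refracted travel time
#' through the two-medium geometry (\code{sosMode = "dual"}) or the straight
#' ray at the tissue speed (\code{"uniform"}). Each pixel contributes a
#' wavelet at its arrival time built from: linear interpolation of the
#' fractional arrival sample onto the sampling grid, 2-D geometric decay
#' \code{1/sqrt(r)} with \code{r} the (refracted) path length, a discrete
#' central temporal derivative, and convolution with the TIR kernel.
#'
#' Pixels whose wavelet falls entirely outside the recording window yield
#' all-zero columns; their count is reported with a message, not an error.
#'
#' @param geometry a [ProbeGeometry-class].
#' @param tir a [TIRKernel-class]; [deltaKernel()] leaves traces unconvolved.
#' @param sosMode \code{"dual"} (default) or \code{"uniform"}.
#' @return a [ForwardModel-class].
#' @seealso [applyModel()], [applyAdjoint()], [reconstruct()]
#' @export
assembleForwardModel <- function(geometry, tir = deltaKernel(),
                                 sosMode = c("dual", "uniform")) {
  sosMode <- match.arg(sosMode)
  stopifnot(is(geometry, "ProbeGeometry"), is(tir, "TIRKernel"))
  validObject(geometry); validObject(tir)

  g <- gridCoordinates(geometry)
  nr <- geometry@gridShape[1]; nc <- geometry@gridShape[2]
  nPix <- nr * nc
  nS <- geometry@nSamples
  fs <- geometry@samplingRate
  # column-major pixel coordinates: index p = row + (col-1)*nr
  X <- rep(g$x, each = nr)
  Y <- rep(g$y, times = nc)

  # combined temporal kernel: central derivative then TIR
  deriv <- c(0.5, 0, -0.5); derivOrigin <- 2L
  kc <- .convFull(deriv, tir@samples)
  kcOrigin <- derivOrigin + tir@originIndex - 1L
  keep <- kc != 0
  kOff <- (seq_along(kc) - kcOrigin)[keep]
  kVal <- kc[keep]

  minR <- min(g$pitch) / 2
  pos <- geometry@elementPositions
  triplets <- vector("list", geometry@nElements)
  reached <- logical(nPix)
  for (e in seq_len(geometry@nElements)) {
    if (sosMode == "uniform") {
      r <- sqrt((X - pos[e, 1])^2 + (Y - pos[e, 2])^2)
      tt <- r / geometry@sosTissue * 1e-3
      plen <- r
    } else {
      ft <- .fermatTimes(X, Y, pos[e, 1], pos[e, 2],
                         geometry@interfaceDepth,
                         geometry@sosWater, geometry@sosTissue)
      tt <- ft$time; plen <- ft$pathLength
    }
    amp <- 1 / sqrt(pmax(plen, minR))
    u <- tt * fs + 1           # fractional 1-based arrival sample
    k0 <- floor(u)
    frac <- u - k0
    rowBase <- (e - 1L) * nS
    ii <- jj <- xx <- vector("list", 2L * length(kOff))
    slot <- 0L
    for (m in seq_along(kOff)) {
      for (b in 0:1) {
        rows <- k0 + b + kOff[m]
        w <- if (b == 0) (1 - frac) else frac
        ok <- rows >= 1 & rows <= nS & w != 0
        slot <- slot + 1L
        ii[[slot]] <- rowBase + rows[ok]
        jj[[slot]] <- which(ok)
        xx[[slot]] <- amp[ok] * w[ok] * kVal[m]
      }
    }
    jAll <- unlist(jj, use.names = FALSE)
    reached[unique(jAll)] <- TRUE
    triplets[[e]] <- list(i = unlist(ii, use.names = FALSE), j = jAll,
                          x = unlist(xx, use.names = FALSE))
  }
  nDead <- sum(!reached)
  if (nDead > 0)
    message(nDead, " grid pixel(s) outside the recording window (zero columns)")
  M <- Matrix::sparseMatrix(
    i = unlist(lapply(triplets, `[[`, "i"), use.names = FALSE),
    j = unlist(lapply(triplets, `[[`, "j"), use.names = FALSE),
    x = unlist(lapply(triplets, `[[`, "x"), use.names = FALSE),
    dims = c(geometry@nElements * nS, nPix))
  new("ForwardModel", matrix = methods::as(M, "CsparseMatrix"),
      geometry = geometry, tir = tir, sosMode = sosMode)
}

# full ("open") discrete convolution of two kernels
.convFull <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

.asImageVector <- function(model, x) {
  g <- model@geometry
  if (is(x, "ReconImage")) x <- x@pixels
  if (is.matrix(x)) {
    if (!all(dim(x) == g@gridShape))
      stop("image shape ", paste(dim(x), collapse = "x"),
           " does not match grid ", paste(g@gridShape, collapse = "x"))
    x <- as.vector(x)
  }
  if (length(x) != prod(g@gridShape)) stop("image length mismatch")
  x
}

.asSignalVector <- function(model, x) {
  g <- model@geometry
  if (is(x, "SignalFrame")) x <- x@data
  if (is.matrix(x)) {
    if (nrow(x) != g@nElements || ncol(x) != g@nSamples)
      stop("signal shape does not match geometry (", g@nElements, " x ",
           g@nSamples, ")")
    x <- as.vector(t(x))   # element-major stacking
  }
  if (length(x) != g@nElements * g@nSamples) stop("signal length mismatch")
  x
}

#' @rdname applyModel
setMethod("applyModel", "ForwardModel", function(model, x) {
  v <- .asImageVector(model, x)
  s <- as.numeric(model@matrix %*% v)
  g <- model@geometry
  new("SignalFrame",
      data = t(matrix(s, nrow = g@nSamples, ncol = g@nElements)),
      samplingRate = g@samplingRate,
      wavelength = if (is(x, "ReconImage")) x@wavelength else NA_real_)
})

#' @rdname applyAdjoint
setMethod("applyAdjoint", "ForwardModel", function(model, x) {
  v <- .asSignalVector(model, x)
  p <- as.numeric(Matrix::crossprod(model@matrix, v))
  matrix(p, nrow = model@geometry@gridShape[1],
         ncol = model@geometry@gridShape[2])
})

#' Construct a SignalFrame
#'
#' @param data numeric matrix, nElements x nSamples.
#' @param samplingRate samples per second.
#' @param wavelength illumination wavelength, nm (NA if not applicable).
#' @return a [SignalFrame-class].
#' @export
signalFrame <- function(data, samplingRate, wavelength = NA_real_) {
  new("SignalFrame", data = data, samplingRate = samplingRate,
      wavelength = wavelength)
}

#' Construct a ReconImage
#'
#' @param pixels numeric matrix.
#' @param wavelength nm (NA if not applicable).
#' @param provenance named list of processing parameters.
#' @return a [ReconImage-class].
#' @export
reconImage <- function(pixels, wavelength = NA_real_, provenance = list()) {
  new("ReconImage", pixels = pixels, wavelength = wavelength,
      provenance = provenance)
}
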