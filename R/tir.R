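#' Total impulse response kernels
#'
#' The detection chain (piezo element, amplifier, digitizer) imprints a
#' band-limited temporal signature on every recorded wavelet. The forward
#' model accounts for it by convolving each simulated trace with a shared
#' 1-D total impulse response (TIR) kernel.
#'
#' `tirKernel()` builds the default synthetic kernel: a Gaussian-windowed
#' sinusoid (band-limited derivative-of-Gaussian family) centred at the
#' transducer's nominal frequency. `deltaKernel()` is the identity kernel.
#' `readKernel()` loads a measured kernel from a one-column text file.
#'
#' @param centerFrequency centre frequency in Hz (default 4e6, the nominal
#'   transducer frequency).
#' @param bandwidth fractional bandwidth controlling the Gaussian envelope
#'   width (default 0.6).
#' @param samplingRate samples per second (default 4e7).
#' @return a [TIRKernel-class].
#' @examples
#' k <- tirKernel()
#' length(k@samples)
#' @export
tirKernel <- function(centerFrequency = 4e6, bandwidth = 0.6,
                      samplingRate = 4e7) {
  stopifnot(centerFrequency > 0, bandwidth > 0, samplingRate > 0)
  sigma <- 1 / (pi * bandwidth * centerFrequency)  # envelope scale, s
  half <- ceiling(3 * sigma * samplingRate)
  t <- (-half:half) / samplingRate
  s <- sin(2 * pi * centerFrequency * t) * exp(-t^2 / (2 * sigma^2))
  # odd (derivative-like) kernel; normalize to unit peak
  s <- s / max(abs(s))
  new("TIRKernel", samples = s, originIndex = as.integer(half + 1L))
}

#' @rdname tirKernel
#' @export
deltaKernel <- function() {
  new("TIRKernel", samples = 1, originIndex = 1L)
}

#' @rdname tirKernel
#' @param path one-column text file of kernel samples.
#' @param originIndex 1-based index of the t = 0 sample; defaults to the
#'   sample of maximum absolute value.
#' @export
readKernel <- function(path, originIndex = NULL) {
  s <- scan(path, what = numeric(), quiet = TRUE)
  if (!length(s)) stop("empty kernel file: ", path)
  if (is.null(originIndex)) originIndex <- which.max(abs(s))
  new("TIRKernel", samples = s, originIndex = as.integer(originIndex))
}

#' @rdname tirKernel
#' @param kernel a [TIRKernel-class].
#' @export
writeKernel <- function(kernel, path) {
  writeLines(format(kernel@samples, digits = 17), path)
  invisible(path)
}
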