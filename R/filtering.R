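#' BandpassSpec: Butterworth band-pass description
#'
#' The band-pass applied to raw signals before reconstruction: an 8th-order
#' Butterworth low-pass at 8 MHz cascaded with a 2nd-order Butterworth
#' high-pass at the lower cut-off (LCO). Three LCO variants are standard:
#' 100 kHz, 300 kHz and 700 kHz (pass-bands 0.1-8, 0.3-8, 0.7-8 MHz),
#' trading out-of-plane signal suppression against signal-to-noise.
#'
#' @slot lowCutoff Hz.
#' @slot highCutoff Hz.
#' @slot lpOrder low-pass order.
#' @slot hpOrder high-pass order.
#' @seealso [bandpassSpec()], [lcoPreset()], [bandpass()]
#' @export
setClass("BandpassSpec", representation(
  lowCutoff = "numeric",
  highCutoff = "numeric",
  lpOrder = "integer",
  hpOrder = "integer"
))

setValidity("BandpassSpec", function(object) {
  msg <- character()
  if (!(object@lowCutoff > 0 && object@lowCutoff < object@highCutoff))
    msg <- c(msg, "must have 0 < lowCutoff < highCutoff")
  if (object@lpOrder < 1L || object@hpOrder < 1L)
    msg <- c(msg, "filter orders must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname bandpass
#' @export
bandpassSpec <- function(lowCutoff = 1e5, highCutoff = 8e6,
                         lpOrder = 8L, hpOrder = 2L) {
  new("BandpassSpec", lowCutoff = lowCutoff, highCutoff = highCutoff,
      lpOrder = as.integer(lpOrder), hpOrder = as.integer(hpOrder))
}

#' @rdname bandpass
#' @param lco lower cut-off preset in kHz: 100, 300 or 700.
#' @export
lcoPreset <- function(lco = c(100, 300, 700)) {
  lco <- match.arg(as.character(lco[1]), c("100", "300", "700"))
  bandpassSpec(lowCutoff = as.numeric(lco) * 1e3)
}

# causal single pass of the LP(8) * HP(2) cascade over one trace
.butterCascade <- function(x, spec, fs) {
  ny <- fs / 2
  lp <- signal::butter(spec@lpOrder, spec@highCutoff / ny, type = "low")
  hp <- signal::butter(spec@hpOrder, spec@lowCutoff / ny, type = "high")
  as.numeric(signal::filter(hp, signal::filter(lp, x)))
}

# effective impulse-response length of the cascade (decay below 1e-8 of peak)
.cascadeIRLength <- function(spec, fs, maxLen = 8192L) {
  h <- .butterCascade(c(1, numeric(maxLen - 1L)), spec, fs)
  idx <- which(abs(h) > 1e-8 * max(abs(h)))
  if (!length(idx)) 1L else max(idx)
}

#' Butterworth band-pass filtering of signal frames
#'
#' Applies the band-pass of \code{spec} to every element trace. The default
#' mode is zero-phase (forward-backward application of the causal cascade),
#' which preserves arrival times and therefore does not bias the model-based
#' inversion; \code{mode = "causal"} gives the single-pass filter whose
#' magnitude response is -3 dB at each cut-off (the zero-phase response is
#' the square of the single-pass magnitude). Traces are reflect-padded by
#' three times the cascade's effective impulse-response length before
#' filtering.
#'
#' @param signals a [SignalFrame-class].
#' @param spec a [BandpassSpec-class]; see [lcoPreset()].
#' @param mode \code{"zero-phase"} (default) or \code{"causal"}.
#' @return a filtered [SignalFrame-class].
#' @examples
#' fs <- 4e7
#' x <- matrix(sin(2 * pi * 2e6 * (0:999) / fs), nrow = 1)
#' f <- bandpass(signalFrame(x, fs), lcoPreset(100))
#' @export
bandpass <- function(signals, spec, mode = c("zero-phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(is(signals, "SignalFrame"), is(spec, "BandpassSpec"))
  validObject(spec)
  fs <- signals@samplingRate
  if (spec@highCutoff >= fs / 2)
    stop("highCutoff must be below the Nyquist frequency ", fs / 2, " Hz")
  if (!all(is.finite(signals@data))) stop("signals must be finite")
  n <- ncol(signals@data)
  pad <- min(3L * .cascadeIRLength(spec, fs), n - 1L)
  filt1 <- function(x) {
    if (pad > 0) {
      xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
    } else xp <- x
    y <- .butterCascade(xp, spec, fs)
    y[(pad + 1):(pad + n)]
  }
  out <- t(apply(signals@data, 1L, function(x) {
    if (mode == "causal") {
      y <- filt1(x)
    } else {
      y <- filt1(x)
      y <- rev(filt1(rev(y)))
    }
    y
  }))
  new("SignalFrame", data = out, samplingRate = fs,
      wavelength = signals@wavelength)
}
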