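#' Construct a MultispectralFrame
#'
#' @param data numeric 3-D array (rows x cols x wavelengths) or a list of
#'   equally-shaped matrices.
#' @param wavelengths numeric vector, nm, strictly increasing. Defaults to
#'   the standard 700-970 nm grid in 10 nm steps when the third dimension
#'   is 28.
#' @param frameIndex position in the acquired sequence.
#' @return a [MultispectralFrame-class].
#' @export
multispectralFrame <- function(data, wavelengths = NULL, frameIndex = 1L) {
  if (is.list(data))
    data <- array(unlist(data), dim = c(dim(data[[1]]), length(data)))
  if (is.null(wavelengths)) {
    if (dim(data)[3] == 28L) wavelengths <- seq(700, 970, by = 10)
    else stop("wavelengths must be given when the stack is not 28 deep")
  }
  new("MultispectralFrame", data = data, wavelengths = wavelengths,
      frameIndex = as.integer(frameIndex))
}

#' Extract one single-wavelength image from a stack
#'
#' @param frame a [MultispectralFrame-class].
#' @param wavelength nm, must be on the frame's grid.
#' @return a [ReconImage-class].
#' @export
frameImage <- function(frame, wavelength) {
  i <- match(wavelength, frame@wavelengths)
  if (is.na(i)) stop("wavelength ", wavelength, " nm not in the stack")
  reconImage(frame@data[, , i], wavelength = wavelength)
}

#' Two-level elastic motion correction and frame compounding
#'
#' Implements the two-step motion-corrected averaging of consecutive
#' multispectral frames:
#' \enumerate{
#'   \item Within each frame, every image at wavelengths up to
#'     \code{t1Upper} (890 nm) is elastically registered to that frame's
#'     \code{referenceWavelength} (800 nm) image (transformations T1).
#'     Above \code{t1Upper} the dominant contrast switches from
#'     hemoglobin to fat and registration to the 800 nm image is
#'     unreliable; those images reuse the T1 of \code{t1Upper}.
#'   \item The per-frame mean of the T1-warped images over
#'     [\code{meanBand}] represents each frame; these means are registered
#'     to the middle frame's mean (transformations T2).
#'   \item Every single-wavelength image is warped once by the composed
#'     field T2 o T1 and the warped images are averaged across frames.
#' }
#'
#' With identical (motion-free) input frames all fields are exactly zero
#' and the output equals the plain arithmetic mean.
#'
#' @param frames list of [MultispectralFrame-class] (default length 3) on a
#'   shared wavelength grid.
#' @param referenceWavelength intra-frame reference, nm (default 800).
#' @param t1Upper highest wavelength registered directly, nm (default 890).
#' @param meanBand wavelength range averaged into the per-frame mean image,
#'   nm (default \code{c(700, 890)}).
#' @param ... registration settings passed to [registerElastic()].
#' @return a list: \code{frame} (the compounded [MultispectralFrame-class]),
#'   \code{t1} (list over frames of lists over wavelengths of
#'   [DisplacementField-class]), \code{t2} (list over frames).
#' @export
correctAndAverage <- function(frames, referenceWavelength = 800,
                              t1Upper = 890, meanBand = c(700, 890), ...) {
  if (!length(frames) || !all(vapply(frames, is, TRUE, "MultispectralFrame")))
    stop("frames must be a list of MultispectralFrame objects")
  wl <- frames[[1]]@wavelengths
  for (f in frames)
    if (!identical(f@wavelengths, wl))
      stop("all frames must share the wavelength grid")
  if (!(referenceWavelength %in% wl))
    stop("reference wavelength missing from the stack")
  if (!(t1Upper %in% wl)) stop("t1Upper wavelength missing from the stack")
  nF <- length(frames)
  d <- dim(frames[[1]]@data)
  zero <- function() displacementField(matrix(0, d[1], d[2]),
                                       matrix(0, d[1], d[2]))
  inBand <- wl >= meanBand[1] & wl <= meanBand[2]
  t1 <- vector("list", nF)
  meanImgs <- vector("list", nF)
  for (n in seq_len(nF)) {
    ref <- frames[[n]]@data[, , match(referenceWavelength, wl)]
    fields <- vector("list", length(wl))
    for (i in seq_along(wl)) {
      if (wl[i] > t1Upper) next  # filled below from t1Upper
      fields[[i]] <- if (wl[i] == referenceWavelength) zero()
      else tryCatch(
        registerElastic(frames[[n]]@data[, , i], ref, ...),
        error = function(e) stop("intra-frame registration failed (frame ",
                                 n, ", ", wl[i], " nm): ",
                                 conditionMessage(e)))
    }
    reuse <- fields[[match(t1Upper, wl)]]
    for (i in which(wl > t1Upper)) fields[[i]] <- reuse
    t1[[n]] <- fields
    warped <- vapply(which(inBand), function(i)
      warpImage(frames[[n]]@data[, , i], fields[[i]]),
      matrix(0, d[1], d[2]))
    meanImgs[[n]] <- apply(warped, c(1, 2), mean)
  }
  mid <- ceiling(nF / 2)
  t2 <- vector("list", nF)
  for (n in seq_len(nF)) {
    t2[[n]] <- if (n == mid) zero()
    else tryCatch(
      registerElastic(meanImgs[[n]], meanImgs[[mid]], ...),
      error = function(e) stop("inter-frame registration failed (frame ",
                               n, "): ", conditionMessage(e)))
  }
  out <- array(0, d)
  for (n in seq_len(nF)) {
    for (i in seq_along(wl)) {
      comp <- composeFields(t2[[n]], t1[[n]][[i]])
      out[, , i] <- out[, , i] +
        warpImage(frames[[n]]@data[, , i], comp) / nF
    }
  }
  list(frame = multispectralFrame(out, wl,
                                  frameIndex = frames[[mid]]@frameIndex),
       t1 = t1, t2 = t2)
}
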