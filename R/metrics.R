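#' RegionMasks: object and background regions for CNR
#'
#' The object region is the tissue band down to a fixed depth (1.5 cm)
#' under the skin line; the background is the area above the skin line.
#'
#' @slot objectMask logical matrix.
#' @slot backgroundMask logical matrix, disjoint from the object mask.
#' @slot skinLine numeric vector, skin depth per image column, mm.
#' @seealso [regionMasksFromSkin()], [computeCNR()]
#' @export
setClass("RegionMasks", representation(
  objectMask = "matrix",
  backgroundMask = "matrix",
  skinLine = "numeric"
))

setValidity("RegionMasks", function(object) {
  msg <- character()
  if (!all(dim(object@objectMask) == dim(object@backgroundMask)))
    msg <- c(msg, "masks must share a shape")
  else if (any(object@objectMask & object@backgroundMask))
    msg <- c(msg, "masks must be disjoint")
  if (!any(object@objectMask) || !any(object@backgroundMask))
    msg <- c(msg, "both masks must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Build CNR region masks from a skin line
#'
#' @param skinLine numeric vector, skin depth per column, mm from the top
#'   image row (recycled if length 1).
#' @param shape image shape (rows, cols).
#' @param pitch pixel pitch in depth, mm/px.
#' @param objectDepth thickness of the object band below the skin, mm
#'   (default 15, i.e. 1.5 cm).
#' @return a [RegionMasks-class].
#' @export
regionMasksFromSkin <- function(skinLine, shape, pitch, objectDepth = 15) {
  nr <- shape[1]; nc <- shape[2]
  skin <- rep_len(skinLine, nc)
  depth <- matrix((seq_len(nr) - 1) * pitch, nr, nc)
  skinM <- matrix(skin, nr, nc, byrow = TRUE)
  obj <- depth > skinM & depth <= skinM + objectDepth
  bkg <- depth < skinM
  new("RegionMasks", objectMask = obj, backgroundMask = bkg, skinLine = skin)
}

#' CNRReport: contrast-to-noise statistics
#'
#' @slot cnrDb CNR in decibels (NA when flagged undefined).
#' @slot muObj,muBkg mean intensities.
#' @slot varObj,varBkg intensity variances.
#' @slot flagged logical, TRUE when the numerator was not positive.
#' @slot denominator "variance" or "sd".
#' @export
setClass("CNRReport", representation(
  cnrDb = "numeric", muObj = "numeric", muBkg = "numeric",
  varObj = "numeric", varBkg = "numeric", flagged = "logical",
  denominator = "character"
))

setMethod("show", "CNRReport", function(object) {
  if (object@flagged)
    cat("CNR: undefined (object mean does not exceed background mean)\n")
  else cat(sprintf("CNR = %.2f dB", object@cnrDb), "\n")
  cat(sprintf("  mu: %.4g / %.4g  var: %.4g / %.4g (obj/bkg), denominator = %s\n",
              object@muObj, object@muBkg, object@varObj, object@varBkg,
              object@denominator))
})

#' Contrast-to-noise ratio between object and background
#'
#' Computes \deqn{CNR = 10 \log_{10}\frac{\mu_{OBJ}-\mu_{BKG}}
#' {\sigma_{OBJ}+\sigma_{BKG}}} where by default \eqn{\sigma} denotes the
#' intensity \emph{variance} within each region (the literal definition
#' this pipeline reports); \code{denominator = "sd"} switches to the
#' conventional standard-deviation form. A non-positive numerator gives a
#' flagged report (\code{cnrDb = NA}) rather than an error, so batch
#' statistics can skip undefined entries. Note that with the variance
#' denominator CNR is invariant to adding a constant to the image but not
#' to rescaling: multiplying by \code{k} shifts CNR by
#' \code{10*log10(1/k)}.
#'
#' @param image numeric matrix or [ReconImage-class].
#' @param masks a [RegionMasks-class].
#' @param denominator \code{"variance"} (default) or \code{"sd"}.
#' @return a [CNRReport-class].
#' @export
computeCNR <- function(image, masks, denominator = c("variance", "sd")) {
  denominator <- match.arg(denominator)
  m <- if (is(image, "ReconImage")) image@pixels else image
  validObject(masks)
  if (!all(is.finite(m))) stop("image must be finite")
  if (!all(dim(m) == dim(masks@objectMask)))
    stop("mask shape must match image shape")
  o <- m[masks@objectMask]; b <- m[masks@backgroundMask]
  muO <- mean(o); muB <- mean(b)
  vO <- var(o); vB <- var(b)
  den <- if (denominator == "variance") vO + vB else sqrt(vO) + sqrt(vB)
  if (den == 0) stop("zero denominator: both regions are constant")
  num <- muO - muB
  flagged <- num <= 0
  cnr <- if (flagged) NA_real_ else 10 * log10(num / den)
  new("CNRReport", cnrDb = cnr, muObj = muO, muBkg = muB,
      varObj = vO, varBkg = vB, flagged = flagged,
      denominator = denominator)
}

#' Full width at half maximum of a line profile
#'
#' Linear-interpolated width between the two half-maximum crossings
#' flanking the profile's unique global maximum. The half level is taken
#' midway between the profile minimum (baseline) and maximum, which makes
#' the measure invariant under positive affine intensity rescaling.
#'
#' @param profile numeric vector of intensity samples with a unique global
#'   maximum above its boundary values.
#' @param pitch sample spacing in micrometres.
#' @return width in micrometres.
#' @export
fwhm <- function(profile, pitch) {
  stopifnot(length(profile) >= 3L, pitch > 0, all(is.finite(profile)))
  pk <- which(profile == max(profile))
  if (any(diff(pk) != 1L))
    stop("profile must have a unique (possibly plateau) global maximum")
  pkL <- min(pk); pkR <- max(pk)
  if (pkL == 1L || pkR == length(profile))
    stop("maximum must be interior to the profile")
  level <- min(profile) + (max(profile) - min(profile)) / 2
  left <- NA_real_
  for (i in seq(pkL - 1L, 1L)) {
    if (profile[i] <= level) {
      left <- i + (level - profile[i]) / (profile[i + 1L] - profile[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(pkR + 1L, length(profile))) {
    if (profile[i] <= level) {
      right <- i - (level - profile[i]) / (profile[i - 1L] - profile[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("no half-maximum crossing on one side of the peak")
  (right - left) * pitch
}
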