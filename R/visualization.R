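# Display transforms used to present reconstructed optoacoustic and
# ultrasound images. All transforms are deterministic and shape-preserving;
# rendered RGB outputs lie in [0,1]^3.

.asMatrixImage <- function(image) {
  if (is(image, "ReconImage") || is(image, "USImage")) image@pixels else image
}

# image percentile; by default over nonzero pixels only, because
# background-dominated images would otherwise pin low percentiles at zero
.imgPercentile <- function(m, p, on = c("nonzero", "all")) {
  on <- match.arg(on)
  v <- as.vector(m)
  if (on == "nonzero" && any(v != 0)) v <- v[v != 0]
  as.numeric(quantile(v, p / 100, names = FALSE))
}

# mean over the border-clipped L1 ball |dx|+|dy| <= r around each pixel
.diamondMean <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dyy in -r:r) {
    for (dxx in -r:r) {
      if (abs(dxx) + abs(dyy) > r) next
      rSrc <- seq_len(nr) + dyy
      cSrc <- seq_len(nc) + dxx
      rOk <- rSrc >= 1 & rSrc <= nr
      cOk <- cSrc >= 1 & cSrc <= nc
      acc[rOk, cOk] <- acc[rOk, cOk] + m[rSrc[rOk], cSrc[cOk]]
      cnt[rOk, cOk] <- cnt[rOk, cOk] + 1
    }
  }
  acc / cnt
}

#' Local contrast normalization
#'
#' Divides each pixel by the larger of (i) the mean intensity over its
#' L1-ball neighborhood of radius \code{r} (clipped at the image border)
#' and (ii) the \code{n}-th percentile of the whole image. The percentile
#' floor keeps isolated bright pixels from being normalized away entirely.
#'
#' @param image non-negative numeric matrix or [ReconImage-class].
#' @param r neighborhood radius, px.
#' @param n percentile (0-100) used as the divisor floor.
#' @param percentileOn compute the percentile over \code{"nonzero"} pixels
#'   (default) or \code{"all"}.
#' @return numeric matrix.
#' @export
localContrastNorm <- function(image, r, n, percentileOn = "nonzero") {
  m <- .asMatrixImage(image)
  stopifnot(r >= 1, all(m >= 0))
  if (all(m == 0)) stop("all-zero image: divisor is zero everywhere")
  p <- .imgPercentile(m, n, percentileOn)
  m / pmax(.diamondMean(m, as.integer(r)), p)
}

#' Sigmoid intensity normalization
#'
#' Maps intensities into [0,1] with a logistic curve anchored so that the
#' \code{Pa}-th and \code{Pb}-th image percentiles map to \code{a} and
#' \code{b}; values outside the percentile range are squeezed smoothly
#' towards 0 and 1.
#'
#' @param image numeric matrix or [ReconImage-class]/[USImage-class].
#' @param Pa,Pb source percentiles (0-100), \code{Pa < Pb}, whose image
#'   values must be distinct.
#' @param a,b target levels, \code{0 < a < b < 1}.
#' @param percentileOn see [localContrastNorm()].
#' @return numeric matrix with values in (0, 1).
#' @export
sigmoidNorm <- function(image, Pa = 2, Pb = 98, a = 0.05, b = 0.95,
                        percentileOn = "nonzero") {
  stopifnot(Pa < Pb, 0 < a, a < b, b < 1)
  m <- .asMatrixImage(image)
  va <- .imgPercentile(m, Pa, percentileOn)
  vb <- .imgPercentile(m, Pb, percentileOn)
  if (va == vb) stop("degenerate percentiles: Pa and Pb values coincide")
  logit <- function(x) log(x / (1 - x))
  z <- (logit(b) - logit(a)) * (m - va) / (vb - va) + logit(a)
  1 / (1 + exp(-z))
}

#' Power-law transform followed by unsharp masking
#'
#' Applies \code{I^gamma}, then \code{I + alpha * (I - G_s * I)} with a
#' Gaussian blur of scale \code{s} pixels.
#'
#' @param image non-negative numeric matrix or image object.
#' @param gamma power exponent, > 0.
#' @param alpha unsharp weight (0 disables sharpening).
#' @param s Gaussian scale, px.
#' @return numeric matrix.
#' @export
powerUnsharp <- function(image, gamma = 1, alpha = 0, s = 2) {
  m <- .asMatrixImage(image)
  if (gamma <= 0) stop("gamma must be > 0")
  stopifnot(all(m >= 0), s > 0)
  m <- m^gamma
  if (alpha != 0) m <- m + alpha * (m - .gaussianBlur(m, s))
  m
}

#' Depth-gain and contrast enhancement of ultrasound
#'
#' Per pixel computes \deqn{I_{enh}(x) = e^{0.15 d}\,
#' \sigma\!\left(\frac{I(x)-0.9}{0.2}\right)} where \eqn{d} is the pixel
#' depth below the tissue surface in centimetres (clamped to 0 above the
#' surface) and \eqn{\sigma} the logistic sigmoid.
#'
#' @param us [USImage-class] or matrix with intensities normalized to [0,1].
#' @param skinLine numeric vector, surface depth per column, mm from the
#'   top row (recycled if length 1).
#' @param pitch pixel pitch in depth, mm/px.
#' @return numeric matrix.
#' @export
enhanceUS <- function(us, skinLine = 0, pitch = 0.1) {
  m <- .asMatrixImage(us)
  if (any(m < 0) || any(m > 1)) stop("us must be normalized to [0, 1]")
  nr <- nrow(m); nc <- ncol(m)
  depthMm <- matrix((seq_len(nr) - 1) * pitch, nr, nc) -
    matrix(rep_len(skinLine, nc), nr, nc, byrow = TRUE)
  dCm <- pmax(depthMm, 0) / 10
  exp(0.15 * dCm) / (1 + exp(-(m - 0.9) / 0.2))
}

#' ColorMap2D: bilinear two-channel colormap
#'
#' Maps a pair of normalized intensities (low-band, high-band) to RGB by
#' bilinear interpolation among four corner colors given at
#' (low, high) = (0,0), (1,0), (0,1), (1,1).
#'
#' @slot corner00,corner10,corner01,corner11 RGB triplets in [0,1]^3.
#' @seealso [colorMap2D()], [renderDualBand()]
#' @export
setClass("ColorMap2D", representation(
  corner00 = "numeric", corner10 = "numeric",
  corner01 = "numeric", corner11 = "numeric"
))

setValidity("ColorMap2D", function(object) {
  for (s in c("corner00", "corner10", "corner01", "corner11")) {
    v <- slot(object, s)
    if (length(v) != 3L || any(v < 0) || any(v > 1))
      return("corner colors must be RGB triplets in [0,1]")
  }
  TRUE
})

#' @rdname ColorMap2D-class
#' @param corner00,corner10,corner01,corner11 RGB triplets in [0,1]^3 at
#'   (low, high) = (0,0), (1,0), (0,1), (1,1). Defaults: black, red,
#'   yellow, white (large low-frequency structures render red, fine
#'   high-frequency detail yellow-white).
#' @return a [ColorMap2D-class].
#' @export
colorMap2D <- function(corner00 = c(0, 0, 0), corner10 = c(1, 0, 0),
                       corner01 = c(1, 1, 0), corner11 = c(1, 1, 1)) {
  new("ColorMap2D", corner00 = corner00, corner10 = corner10,
      corner01 = corner01, corner11 = corner11)
}

#' Dual-band rendering
#'
#' Fuses two normalized reconstructions of the same signals -- a
#' low-cut-off (broadband, large structures) and a high-cut-off (fine
#' detail) band-pass variant -- into one RGB image by evaluating a 2-D
#' colormap at each pixel's (low, high) pair.
#'
#' @param low,high numeric matrices in [0,1] (e.g. from [sigmoidNorm()]),
#'   equal shape.
#' @param cmap a [ColorMap2D-class].
#' @return numeric array rows x cols x 3 in [0,1].
#' @export
renderDualBand <- function(low, high, cmap = colorMap2D()) {
  low <- .asMatrixImage(low); high <- .asMatrixImage(high)
  if (!all(dim(low) == dim(high))) stop("low and high must share a shape")
  stopifnot(all(low >= 0 & low <= 1), all(high >= 0 & high <= 1))
  out <- array(0, c(dim(low), 3L))
  for (ch in 1:3) {
    out[, , ch] <-
      (1 - low) * (1 - high) * cmap@corner00[ch] +
      low * (1 - high) * cmap@corner10[ch] +
      (1 - low) * high * cmap@corner01[ch] +
      low * high * cmap@corner11[ch]
  }
  out
}

#' Chromophore unmixing rendering
#'
#' Routes the unmixed coefficient channels to display colors:
#' oxyhemoglobin to red, deoxyhemoglobin to blue, fat to green; the water
#' coefficient is not displayed.
#'
#' @param coeffs a [CoefficientMaps-class] with channels named
#'   \code{HbO2, Hb, fat} (water optional, ignored).
#' @param normalize divide each displayed channel by its maximum
#'   (default TRUE); channels are clipped to [0,1] either way.
#' @return numeric array rows x cols x 3 in [0,1].
#' @export
renderUnmixing <- function(coeffs, normalize = TRUE) {
  stopifnot(is(coeffs, "CoefficientMaps"))
  pick <- function(name) {
    i <- match(name, coeffs@channels)
    if (is.na(i)) stop("missing channel: ", name)
    m <- coeffs@maps[, , i]
    if (normalize && max(m) > 0) m <- m / max(m)
    pmin(pmax(m, 0), 1)
  }
  d <- dim(coeffs@maps)
  out <- array(0, c(d[1], d[2], 3L))
  out[, , 1] <- pick("HbO2")
  out[, , 3] <- pick("Hb")
  out[, , 2] <- pick("fat")
  out
}

# boundary of a logical mask: mask pixels with a 4-neighbor outside the mask
.maskBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !inner
}

#' Hybrid optoacoustic / ultrasound overlay
#'
#' Alpha-blends the optoacoustic image, rendered in a single hue, over the
#' grayscale ultrasound base: per channel,
#' \code{out = (1 - a) * US + a * hue}, with the blending weight \code{a}
#' equal to the normalized optoacoustic intensity. An optional tumor mask
#' is drawn as a contour (its boundary pixels set to \code{contourColor});
#' the mask interior is left untinted.
#'
#' @param oa numeric matrix in [0,1], the normalized optoacoustic image.
#' @param us numeric matrix in [0,1], grayscale ultrasound, same shape.
#' @param mask optional logical matrix (tumor core); only its boundary is
#'   drawn.
#' @param hue RGB triplet for the optoacoustic overlay (default red).
#' @param contourColor RGB triplet for the mask contour (default white).
#' @return numeric array rows x cols x 3 in [0,1].
#' @export
renderHybrid <- function(oa, us, mask = NULL, hue = c(1, 0, 0),
                         contourColor = c(1, 1, 1)) {
  oa <- .asMatrixImage(oa); us <- .asMatrixImage(us)
  if (!all(dim(oa) == dim(us))) stop("oa and us must share a shape")
  stopifnot(all(oa >= 0 & oa <= 1), all(us >= 0 & us <= 1))
  out <- array(0, c(dim(us), 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - oa) * us + oa * hue[ch]
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(us))) stop("mask shape mismatch")
    bnd <- .maskBoundary(mask)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[bnd] <- contourColor[ch]
      out[, , ch] <- plane
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Write an RGB render or grayscale image to PNG/TIFF
#'
#' @param image matrix in [0,1] or rows x cols x 3 array in [0,1].
#' @param path output file, extension .png or .tif/.tiff.
#' @param params optional named list echoed to a JSON sidecar
#'   (\code{<path>.json}) for reproducibility.
#' @return the path, invisibly.
#' @export
writeRender <- function(image, path, params = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(image, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(image, path, bits.per.sample = 32L)
  else stop("unsupported extension: ", ext)
  if (!is.null(params))
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
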