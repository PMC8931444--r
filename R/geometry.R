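#' Construct a handheld arc-probe geometry
#'
#' Places \code{nElements} detector elements on a circular arc subtending
#' \code{arcCoverage} degrees with chord \code{endpointDistance} between the
#' first and last element, concave towards increasing depth. The arc is
#' positioned so that its deepest elements (the endpoints) sit
#' \code{elementClearance} mm above the planar water/tissue interface; the
#' imaging grid starts at the interface and extends \code{fov[2]} mm deeper.
#'
#' @param nElements number of elements (default 256).
#' @param arcCoverage arc coverage in degrees (default 145).
#' @param endpointDistance chord between the endpoint elements, mm (default 60).
#' @param interfaceDepth y of the planar water/tissue interface, mm (default 10).
#' @param elementClearance vertical clearance of the endpoint elements above
#'   the interface, mm (default 4).
#' @param sosWater speed of sound in the heavy-water cavity, m/s (default 1397).
#' @param sosTissue speed of sound in tissue, m/s (default 1510).
#' @param samplingRate samples per second (default 4e7).
#' @param nSamples samples per trace (default 2048).
#' @param fov field of view (width, depth), mm (default c(40, 40)).
#' @param gridShape image grid (rows, cols) (default c(401, 401)).
#' @return a validated [ProbeGeometry-class].
#' @examples
#' g <- probeGeometry(nElements = 64, gridShape = c(101, 101))
#' g
#' @export
probeGeometry <- function(nElements = 256L,
                          arcCoverage = 145,
                          endpointDistance = 60,
                          interfaceDepth = 10,
                          elementClearance = 4,
                          sosWater = 1397,
                          sosTissue = 1510,
                          samplingRate = 4e7,
                          nSamples = 2048L,
                          fov = c(40, 40),
                          gridShape = c(401L, 401L)) {
  theta <- arcCoverage * pi / 180
  radius <- endpointDistance / (2 * sin(theta / 2))
  # arc centre depth chosen so endpoint elements clear the interface
  yc <- interfaceDepth - elementClearance + radius * cos(theta / 2)
  phi <- seq(-theta / 2, theta / 2, length.out = nElements)
  pos <- cbind(x = radius * sin(phi), y = yc - radius * cos(phi))
  new("ProbeGeometry",
      nElements = as.integer(nElements),
      arcCoverage = arcCoverage,
      endpointDistance = endpointDistance,
      interfaceDepth = interfaceDepth,
      sosWater = sosWater,
      sosTissue = sosTissue,
      samplingRate = samplingRate,
      nSamples = as.integer(nSamples),
      fov = fov,
      gridShape = as.integer(gridShape),
      elementPositions = pos)
}

#' Pixel-centre coordinates of the imaging grid
#'
#' @param geometry a [ProbeGeometry-class].
#' @return list with \code{x} (per column, mm), \code{y} (per row, mm), and
#'   \code{pitch} (x, y pixel pitch, mm).
#' @export
gridCoordinates <- function(geometry) {
  nr <- geometry@gridShape[1]
  nc <- geometry@gridShape[2]
  pitch <- c(geometry@fov[1] / (nc - 1), geometry@fov[2] / (nr - 1))
  list(x = -geometry@fov[1] / 2 + (seq_len(nc) - 1) * pitch[1],
       y = geometry@interfaceDepth + (seq_len(nr) - 1) * pitch[2],
       pitch = pitch)
}

# Vectorized refracted (Fermat) travel times from one element to many pixels.
# The minimum over single-breakpoint paths crossing the planar interface is
# found by bisection on the derivative of the path time, which is monotone
# increasing in the breakpoint abscissa (the path time is convex).
# Returns seconds, plus the refracted path length (mm) for amplitude decay.
.fermatTimes <- function(px, py, ex, ey, d, cw, ct) {
  stopifnot(ey < d)
  n <- length(px)
  tt <- numeric(n)
  plen <- numeric(n)
  onIf <- py <= d + 1e-12
  if (any(onIf)) {
    # pixel at the interface: water-only straight path
    r <- sqrt((px[onIf] - ex)^2 + (py[onIf] - ey)^2)
    tt[onIf] <- r / cw * 1e-3
    plen[onIf] <- r
  }
  below <- !onIf
  if (any(below)) {
    bx <- px[below]; by <- py[below]
    lo <- pmin(ex, bx); hi <- pmax(ex, bx)
    h1 <- d - ey            # element height above interface (> 0)
    h2 <- by - d            # pixel depth below interface (> 0)
    deriv <- function(x) {
      r1 <- sqrt((x - ex)^2 + h1^2)
      r2 <- sqrt((bx - x)^2 + h2^2)
      (x - ex) / (cw * r1) + (x - bx) / (ct * r2)
    }
    for (it in seq_len(90)) {
      mid <- (lo + hi) / 2
      neg <- deriv(mid) < 0
      lo <- ifelse(neg, mid, lo)
      hi <- ifelse(neg, hi, mid)
    }
    xb <- (lo + hi) / 2
    r1 <- sqrt((xb - ex)^2 + h1^2)
    r2 <- sqrt((bx - xb)^2 + h2^2)
    tt[below] <- (r1 / cw + r2 / ct) * 1e-3
    plen[below] <- r1 + r2
  }
  list(time = tt, pathLength = plen)
}

#' Propagation time from an image pixel to a detector element
#'
#' In \code{"dual"} mode, returns the Fermat (minimum-time) propagation time
#' over all single-breakpoint paths crossing the planar water/tissue
#' interface; with equal speeds on both sides this reduces to the straight
#' ray. In \code{"uniform"} mode the interface is ignored and the straight
#' path at the tissue speed is used.
#'
#' @param pixel numeric length-2 (x, y) in mm, on or below the interface in
#'   dual mode.
#' @param element numeric length-2 (x, y) in mm, above the interface.
#' @param geometry a [ProbeGeometry-class] (supplies interface and speeds).
#' @param sosMode \code{"dual"} (default) or \code{"uniform"}.
#' @return travel time in seconds.
#' @examples
#' g <- probeGeometry(sosWater = 1500, sosTissue = 1500, interfaceDepth = 10)
#' computeTravelTime(c(0, 15), c(0, 0), g)  # 15 mm / 1500 m/s = 1e-5 s
#' @export
computeTravelTime <- function(pixel, element, geometry,
                              sosMode = c("dual", "uniform")) {
  sosMode <- match.arg(sosMode)
  stopifnot(length(pixel) == 2L, length(element) == 2L)
  r <- sqrt(sum((pixel - element)^2))
  if (r == 0) return(0)
  if (sosMode == "uniform")
    return(r / geometry@sosTissue * 1e-3)
  d <- geometry@interfaceDepth
  if (element[2] >= d)
    stop("element must lie above the interface (water side)")
  if (pixel[2] < d - 1e-9)
    stop("pixel above the interface is not modeled in dual mode")
  .fermatTimes(pixel[1], pixel[2], element[1], element[2], d,
               geometry@sosWater, geometry@sosTissue)$time
}
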