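#' Phantom: synthetic chromophore concentration maps
#'
#' Ground-truth digital phantom on the imaging grid: one non-negative
#' concentration map per chromophore, built from geometric primitives
#' (disk/ellipse vessels, a skin layer). Overlapping structures add.
#'
#' @slot maps numeric 3-D array rows x cols x channels, >= 0.
#' @slot channels character, chromophore names matching the library.
#' @slot structures list of the generating primitives.
#' @slot seed integer seed the phantom was built with.
#' @seealso [makePhantom()], [pressureMap()]
#' @export
setClass("Phantom", representation(
  maps = "array",
  channels = "character",
  structures = "list",
  seed = "integer"
))

setValidity("Phantom", function(object) {
  msg <- character()
  if (length(dim(object@maps)) != 3L)
    msg <- c(msg, "maps must be rows x cols x channels")
  else if (dim(object@maps)[3] != length(object@channels))
    msg <- c(msg, "third dimension must match channels")
  if (any(object@maps < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@maps)
  cat(sprintf("Phantom: %d x %d px, %d chromophores, %d structure(s), seed %d\n",
              d[1], d[2], d[3], length(object@structures), object@seed))
})

#' NoiseSpec: acquisition noise description
#'
#' @slot whiteSigma std. dev. of i.i.d. white noise per signal channel.
#' @slot coherentAmp amplitude of a time-domain noise trace shared by all
#'   channels (reconstructs onto isochrone rings).
#' @slot spikeProb probability of a multiplicative single-wavelength spike
#'   per image pixel.
#' @slot spikeAmp multiplicative amplitude of a spike.
#' @seealso [noiseSpec()], [injectSignalNoise()], [injectNoiseAndMotion()]
#' @export
setClass("NoiseSpec", representation(
  whiteSigma = "numeric",
  coherentAmp = "numeric",
  spikeProb = "numeric",
  spikeAmp = "numeric"
))

setValidity("NoiseSpec", function(object) {
  if (object@whiteSigma < 0 || object@coherentAmp < 0 ||
      object@spikeProb < 0 || object@spikeProb > 1 || object@spikeAmp < 0)
    return("noise parameters must be non-negative (spikeProb in [0,1])")
  TRUE
})

#' @rdname NoiseSpec-class
#' @param whiteSigma,coherentAmp,spikeProb,spikeAmp see slots.
#' @return a [NoiseSpec-class].
#' @export
noiseSpec <- function(whiteSigma = 0, coherentAmp = 0, spikeProb = 0,
                      spikeAmp = 3) {
  new("NoiseSpec", whiteSigma = whiteSigma, coherentAmp = coherentAmp,
      spikeProb = spikeProb, spikeAmp = spikeAmp)
}

# run expr with a temporary RNG state seeded by `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a synthetic phantom
#'
#' Structures are given as a list of primitives:
#' \itemize{
#'   \item \code{list(type = "disk", center = c(x, y) mm, radius = mm,
#'     concentration = named numeric)} -- an elliptical vessel when
#'     \code{radius} has length 2 (rx, ry);
#'   \item \code{list(type = "skin", depth = mm below the interface,
#'     thickness = mm, concentration = named numeric)} -- a horizontal
#'     layer.
#' }
#' Concentration names must be library channels; overlapping structures
#' are additive. The same seed always reproduces the same phantom.
#'
#' @param structures list of primitives (see above).
#' @param geometry a [ProbeGeometry-class] (supplies grid and FOV).
#' @param channels chromophore channel names (default the library's four).
#' @param seed integer seed stored with the phantom (the deterministic
#'   primitives here do not draw random numbers; presets do).
#' @return a [Phantom-class].
#' @export
makePhantom <- function(structures, geometry,
                        channels = c("HbO2", "Hb", "fat", "water"),
                        seed = 1L) {
  g <- gridCoordinates(geometry)
  nr <- geometry@gridShape[1]; nc <- geometry@gridShape[2]
  X <- matrix(g$x, nr, nc, byrow = TRUE)
  Y <- matrix(g$y, nr, nc)
  maps <- array(0, c(nr, nc, length(channels)))
  xr <- range(g$x); yr <- range(g$y)
  for (st in structures) {
    conc <- st$concentration
    if (is.null(names(conc)) || !all(names(conc) %in% channels))
      stop("structure concentrations must be named after channels")
    if (identical(st$type, "disk")) {
      rad <- rep_len(st$radius, 2L)
      if (st$center[1] - rad[1] < xr[1] || st$center[1] + rad[1] > xr[2] ||
          st$center[2] - rad[2] < yr[1] || st$center[2] + rad[2] > yr[2])
        stop("disk structure outside the field of view")
      inside <- ((X - st$center[1]) / rad[1])^2 +
        ((Y - st$center[2]) / rad[2])^2 <= 1
    } else if (identical(st$type, "skin")) {
      top <- geometry@interfaceDepth + st$depth
      if (top < yr[1] || top + st$thickness > yr[2])
        stop("skin layer outside the field of view")
      inside <- Y >= top & Y <= top + st$thickness
    } else stop("unknown structure type: ", st$type)
    for (ch in names(conc)) {
      k <- match(ch, channels)
      maps[, , k] <- maps[, , k] + conc[[ch]] * inside
    }
  }
  new("Phantom", maps = maps, channels = channels,
      structures = structures, seed = as.integer(seed))
}

#' A reproducible vessel-grid phantom preset
#'
#' Scatters pure-chromophore disk "vessels" (HbO2, Hb, fat) of varying
#' radius below a water/fat skin layer; placement is drawn from the seeded
#' RNG, so a given seed always yields the same phantom.
#'
#' @param geometry a [ProbeGeometry-class].
#' @param nVessels number of disks (default 6).
#' @param seed integer seed (default 7).
#' @return a [Phantom-class].
#' @export
vesselGridPhantom <- function(geometry, nVessels = 6L, seed = 7L) {
  g <- gridCoordinates(geometry)
  xr <- range(g$x); yr <- range(g$y)
  .withSeed(seed, {
    structures <- list(list(
      type = "skin", depth = 0.08 * diff(yr), thickness = 0.04 * diff(yr),
      concentration = c(water = 0.4, fat = 0.3)))
    chroms <- c("HbO2", "Hb", "fat")
    for (i in seq_len(nVessels)) {
      rad <- runif(1, 0.02, 0.05) * diff(xr)
      cx <- runif(1, xr[1] + 1.2 * rad, xr[2] - 1.2 * rad)
      cy <- runif(1, yr[1] + 0.25 * diff(yr), yr[2] - 1.2 * rad)
      conc <- c(1)
      names(conc) <- chroms[(i - 1L) %% 3L + 1L]
      structures[[i + 1L]] <- list(type = "disk", center = c(cx, cy),
                                   radius = rad, concentration = conc)
    }
    makePhantom(structures, geometry, seed = seed)
  })
}

#' Initial-pressure map of a phantom at one wavelength
#'
#' \code{p0(x, lambda) = sum_k conc_k(x) * absorption_k(lambda)}, optionally
#' attenuated by a single-exponential depth fluence model
#' \code{exp(-muEff(lambda) * depth_cm)}. Fluence decay is off by default:
#' without it the ground truth stays linear in the chromophore maps, which
#' is what inversion tests need; switch it on to demonstrate spectral
#' coloring.
#'
#' @param phantom a [Phantom-class].
#' @param lambda wavelength, nm (must be on the library grid).
#' @param library a [ChromophoreLibrary-class].
#' @param geometry a [ProbeGeometry-class] (needed for depth when
#'   \code{fluence} is on).
#' @param fluence logical, apply depth decay (default FALSE).
#' @param muEffScale effective attenuation per unit absorption, 1/cm
#'   (default 0.35).
#' @return numeric matrix, the p0 image.
#' @export
pressureMap <- function(phantom, lambda, library = defaultChromophoreLibrary(),
                        geometry = NULL, fluence = FALSE, muEffScale = 0.35) {
  i <- match(lambda, library@wavelengths)
  if (is.na(i)) stop("lambda not on the library grid")
  d <- dim(phantom@maps)
  p <- matrix(0, d[1], d[2])
  for (k in seq_along(phantom@channels)) {
    ch <- match(phantom@channels[k], colnames(library@spectra))
    if (is.na(ch)) stop("phantom channel missing from library: ",
                        phantom@channels[k])
    p <- p + phantom@maps[, , k] * library@spectra[i, ch]
  }
  if (fluence) {
    if (is.null(geometry)) stop("geometry needed for fluence decay")
    g <- gridCoordinates(geometry)
    depthCm <- (g$y - geometry@interfaceDepth) / 10
    muEff <- muEffScale * sum(library@spectra[i, ]) / ncol(library@spectra)
    p <- p * matrix(exp(-muEff * depthCm), d[1], d[2])
  }
  p
}

#' Direct-summation signal simulation (forward oracle)
#'
#' Simulates per-element time traces from a p0 image by dense summation:
#' every source pixel deposits a derivative-shaped, TIR-convolved wavelet
#' at its Fermat refracted travel time with \code{1/sqrt(r)} geometric
#' decay. Travel times are computed by dense breakpoint sampling of the
#' interface followed by golden-section refinement -- an implementation
#' independent of the sparse matrix assembly in
#' [assembleForwardModel()], so the two can cross-check each other.
#'
#' @param p0 numeric matrix on the geometry grid (e.g. [pressureMap()]).
#' @param geometry a [ProbeGeometry-class].
#' @param tir a [TIRKernel-class].
#' @param wavelength recorded in the output frame, nm.
#' @return a [SignalFrame-class].
#' @export
simulateSignals <- function(p0, geometry, tir = deltaKernel(),
                            wavelength = NA_real_) {
  stopifnot(is.matrix(p0), all(dim(p0) == geometry@gridShape))
  g <- gridCoordinates(geometry)
  nr <- geometry@gridShape[1]; nc <- geometry@gridShape[2]
  fs <- geometry@samplingRate
  nS <- geometry@nSamples
  X <- rep(g$x, each = nr)
  Y <- rep(g$y, times = nc)
  vals <- as.vector(p0)
  act <- which(vals != 0)
  out <- matrix(0, geometry@nElements, nS)
  if (!length(act)) {
    return(signalFrame(out, fs, wavelength))
  }
  # derivative wavelet convolved with the TIR, by full convolution
  wave <- convolve(c(0.5, 0, -0.5), rev(tir@samples), type = "open")
  waveOrigin <- 2L + tir@originIndex - 1L
  offs <- seq_along(wave) - waveOrigin
  d <- geometry@interfaceDepth
  cw <- geometry@sosWater; ct <- geometry@sosTissue
  px <- X[act]; py <- Y[act]; src <- vals[act]
  minR <- min(g$pitch) / 2
  gr <- (sqrt(5) - 1) / 2
  for (e in seq_len(geometry@nElements)) {
    ex <- geometry@elementPositions[e, 1]
    ey <- geometry@elementPositions[e, 2]
    pathTime <- function(x) {
      sqrt((x - ex)^2 + (d - ey)^2) / cw +
        sqrt((px - x)^2 + (py - d)^2) / ct
    }
    # coarse dense scan of interface breakpoints
    lo <- pmin(ex, px); hi <- pmax(ex, px)
    nScan <- 33L
    best <- lo; bestT <- pathTime(lo)
    for (q in seq_len(nScan)) {
      xq <- lo + (hi - lo) * (q - 1) / (nScan - 1)
      tq <- pathTime(xq)
      better <- tq < bestT
      best[better] <- xq[better]
      bestT[better] <- tq[better]
    }
    span <- (hi - lo) / (nScan - 1)
    a <- pmax(best - span, lo); b <- pmin(best + span, hi)
    # golden-section refinement
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- pathTime(x1); f2 <- pathTime(x2)
    for (q in seq_len(48L)) {
      takeLeft <- f1 < f2
      b <- ifelse(takeLeft, x2, b)
      a <- ifelse(takeLeft, a, x1)
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      f1 <- pathTime(x1); f2 <- pathTime(x2)
    }
    xb <- (a + b) / 2
    r1 <- sqrt((xb - ex)^2 + (d - ey)^2)
    r2 <- sqrt((px - xb)^2 + (py - d)^2)
    onIf <- py <= d + 1e-12
    tSec <- ifelse(onIf, sqrt((px - ex)^2 + (py - ey)^2) / cw,
                   r1 / cw + r2 / ct) * 1e-3
    rTot <- ifelse(onIf, sqrt((px - ex)^2 + (py - ey)^2), r1 + r2)
    amp <- src / sqrt(pmax(rTot, minR))
    u <- tSec * fs + 1
    k0 <- floor(u); frac <- u - k0
    trace <- numeric(nS)
    for (m in seq_along(offs)) {
      for (bshift in 0:1) {
        idx <- k0 + bshift + offs[m]
        w <- if (bshift == 0) (1 - frac) else frac
        ok <- idx >= 1 & idx <= nS
        if (!any(ok)) next
        agg <- rowsum(amp[ok] * w[ok] * wave[m], idx[ok])
        trace[as.integer(rownames(agg))] <-
          trace[as.integer(rownames(agg))] + agg[, 1]
      }
    }
    out[e, ] <- trace
  }
  signalFrame(out, fs, wavelength)
}

#' Add acquisition noise to a signal frame
#'
#' White Gaussian noise independently per element, plus a shared
#' (coherent) time-domain noise trace added to all elements; in the
#' reconstruction the coherent component piles up on isochrones and shows
#' as ring artifacts.
#'
#' @param signals a [SignalFrame-class].
#' @param noise a [NoiseSpec-class].
#' @param seed integer seed.
#' @return a [SignalFrame-class].
#' @export
injectSignalNoise <- function(signals, noise, seed = 1L) {
  stopifnot(is(signals, "SignalFrame"), is(noise, "NoiseSpec"))
  validObject(noise)
  d <- dim(signals@data)
  .withSeed(seed, {
    out <- signals@data
    if (noise@whiteSigma > 0)
      out <- out + matrix(rnorm(prod(d), sd = noise@whiteSigma), d[1], d[2])
    if (noise@coherentAmp > 0) {
      shared <- noise@coherentAmp *
        cumsum(rnorm(d[2])) / sqrt(seq_len(d[2]))   # band-limited-ish drift
      out <- out + matrix(shared, d[1], d[2], byrow = TRUE)
    }
    signalFrame(out, signals@samplingRate, signals@wavelength)
  })
}

# a smooth random displacement field: sum of Gaussian bumps, scaled to
# maxAmplitude pixels
.randomSmoothField <- function(nr, nc, maxAmplitude, nBumps = 3L) {
  dx <- matrix(0, nr, nc); dy <- matrix(0, nr, nc)
  for (i in seq_len(nBumps)) {
    cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
    sg <- runif(1, 0.15, 0.3) * min(nr, nc)
    bump <- exp(-((matrix(seq_len(nr), nr, nc) - cy)^2 +
                    (matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx)^2) /
                  (2 * sg^2))
    dx <- dx + runif(1, -1, 1) * bump
    dy <- dy + runif(1, -1, 1) * bump
  }
  mag <- max(sqrt(dx^2 + dy^2))
  if (mag > 0) {
    dx <- dx * maxAmplitude / mag
    dy <- dy * maxAmplitude / mag
  }
  displacementField(dx, dy)
}

#' Inject image-domain noise and motion into multispectral frames
#'
#' Applies, in order: a seeded smooth random warp per frame (and optional
#' per-wavelength jitter), and multiplicative single-wavelength spikes
#' (value multiplied by \code{1 + spikeAmp} at spiked pixels) that emulate
#' noise peaks at arbitrary wavelengths. The ground-truth fields are
#' returned so registration accuracy can be scored.
#'
#' @param frames list of [MultispectralFrame-class].
#' @param noise a [NoiseSpec-class] (only \code{spikeProb}, \code{spikeAmp}
#'   are used here; signal-domain terms belong to [injectSignalNoise()]).
#' @param motionMax maximum warp magnitude per frame, px (default 0).
#' @param seed integer seed.
#' @return list: \code{frames} (same shapes), \code{fields} (ground-truth
#'   [DisplacementField-class] per frame).
#' @export
injectNoiseAndMotion <- function(frames, noise = noiseSpec(),
                                 motionMax = 0, seed = 1L) {
  stopifnot(all(vapply(frames, is, TRUE, "MultispectralFrame")))
  validObject(noise)
  d <- dim(frames[[1]]@data)
  if (motionMax > min(d[1], d[2]) / 4)
    stop("motion amplitude beyond a quarter of the image is not supported")
  .withSeed(seed, {
    fields <- vector("list", length(frames))
    out <- frames
    for (n in seq_along(frames)) {
      fields[[n]] <- .randomSmoothField(d[1], d[2], motionMax)
      arr <- frames[[n]]@data
      if (motionMax > 0)
        for (i in seq_len(d[3]))
          arr[, , i] <- .warpBilinear(arr[, , i], fields[[n]]@dx,
                                      fields[[n]]@dy)
      if (noise@spikeProb > 0) {
        for (i in seq_len(d[3])) {
          hit <- matrix(runif(d[1] * d[2]) < noise@spikeProb, d[1], d[2])
          arr[, , i] <- arr[, , i] * (1 + noise@spikeAmp * hit)
        }
      }
      out[[n]]@data <- arr
    }
    list(frames = out, fields = fields)
  })
}
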