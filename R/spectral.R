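#' CoefficientMaps: per-pixel chromophore coefficients
#'
#' @slot maps numeric 3-D array, rows x cols x channels, all >= 0.
#' @slot channels character vector of channel names.
#' @export
setClass("CoefficientMaps", representation(
  maps = "array",
  channels = "character"
))

setValidity("CoefficientMaps", function(object) {
  msg <- character()
  if (length(dim(object@maps)) != 3L)
    msg <- c(msg, "maps must be rows x cols x channels")
  else if (dim(object@maps)[3] != length(object@channels))
    msg <- c(msg, "third dimension must match channels")
  if (any(object@maps < 0)) msg <- c(msg, "coefficients must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoefficientMaps", function(object) {
  d <- dim(object@maps)
  cat(sprintf("CoefficientMaps: %d x %d px, channels: %s\n", d[1], d[2],
              paste(object@channels, collapse = ", ")))
})

#' Spectral median adjustment
#'
#' Replaces every pixel of the single-wavelength image at \code{lambda} by
#' the median of its spectrum over a narrow wavelength window
#' (\code{lambda +/- halfWindow}); on the standard 10 nm grid the default
#' 20 nm half-window spans 5 wavelengths. Absorption of endogenous
#' chromophores varies smoothly with wavelength, so a median over a few
#' neighboring wavelengths passes real structure through while rejecting
#' single-wavelength noise such as the isochrone ring artifacts of
#' coherent electrical noise. At the grid boundary the window is truncated
#' to the available wavelengths.
#'
#' @param stack a [MultispectralFrame-class].
#' @param lambda centre wavelength, nm; must be on the stack's grid.
#' @param halfWindow half-width of the window, nm (default 20).
#' @return a [ReconImage-class] at \code{lambda}.
#' @export
spectralMedian <- function(stack, lambda, halfWindow = 20) {
  stopifnot(is(stack, "MultispectralFrame"))
  if (!(lambda %in% stack@wavelengths))
    stop("lambda ", lambda, " nm is not on the stack's wavelength grid")
  sel <- which(abs(stack@wavelengths - lambda) <= halfWindow + 1e-9)
  sub <- stack@data[, , sel, drop = FALSE]
  med <- apply(sub, c(1, 2), median)
  reconImage(med, wavelength = lambda,
             provenance = list(spectralMedian = TRUE,
                               windowWavelengths = stack@wavelengths[sel]))
}

#' Construct a chromophore absorption library
#'
#' @param wavelengths numeric vector, nm.
#' @param spectra non-negative matrix, rows = wavelengths, named columns.
#' @return a [ChromophoreLibrary-class].
#' @export
chromophoreLibrary <- function(wavelengths, spectra) {
  new("ChromophoreLibrary", wavelengths = wavelengths,
      spectra = as.matrix(spectra))
}

#' Read a chromophore library from CSV
#'
#' Expected columns: \code{wavelength, HbO2, Hb, fat, water} (extra
#' chromophore columns are kept).
#'
#' @param path CSV file path.
#' @return a [ChromophoreLibrary-class].
#' @export
readChromophoreLibrary <- function(path) {
  tab <- read.csv(path)
  if (!"wavelength" %in% names(tab)) stop("CSV must have a wavelength column")
  sp <- as.matrix(tab[, setdiff(names(tab), "wavelength"), drop = FALSE])
  chromophoreLibrary(tab$wavelength, sp)
}

#' The bundled chromophore library
#'
#' Absorption spectra of oxyhemoglobin, deoxyhemoglobin, fat and water on
#' the 700-970 nm grid at 10 nm steps, in relative units. The bundled
#' table is a synthetic representative library: smooth parametric curves
#' reproducing the qualitative near-infrared features that drive unmixing
#' (deoxyhemoglobin falling across the range with its ~760 nm absorption
#' bump, oxyhemoglobin rising, the lipid peak near 930 nm, water rising
#' towards 970 nm). For quantitative work substitute a measured
#' tabulation via [readChromophoreLibrary()].
#'
#' @return a [ChromophoreLibrary-class].
#' @export
defaultChromophoreLibrary <- function() {
  path <- system.file("extdata", "chromophores_synthetic.csv",
                      package = "msotpipe", mustWork = TRUE)
  readChromophoreLibrary(path)
}

#' Constrained linear spectral unmixing
#'
#' Per pixel, solves the non-negative least-squares problem
#' \deqn{\min_{c \ge 0} \|S c - p\|_2} where the columns of \code{S} are
#' the library absorption spectra evaluated on the stack's wavelength grid
#' and \code{p} is the observed pixel spectrum.
#'
#' @param stack a [MultispectralFrame-class].
#' @param library a [ChromophoreLibrary-class] whose wavelength grid covers
#'   the stack's.
#' @return a [CoefficientMaps-class] with one channel per library column.
#' @export
unmix <- function(stack, library = defaultChromophoreLibrary()) {
  stopifnot(is(stack, "MultispectralFrame"), is(library, "ChromophoreLibrary"))
  validObject(library)
  idx <- match(stack@wavelengths, library@wavelengths)
  if (anyNA(idx))
    stop("stack wavelengths must be a subset of the library grid")
  S <- library@spectra[idx, , drop = FALSE]
  d <- dim(stack@data)
  nPix <- d[1] * d[2]
  P <- matrix(stack@data, nrow = nPix, ncol = d[3])   # pixels x wavelengths
  out <- matrix(0, nPix, ncol(S))
  nzero <- rowSums(P != 0) > 0
  for (i in which(nzero))
    out[i, ] <- pracma::lsqnonneg(S, P[i, ])$x
  new("CoefficientMaps",
      maps = array(out, dim = c(d[1], d[2], ncol(S))),
      channels = colnames(S))
}
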