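# Versioned on-disk container for acquisitions: a directory holding a JSON
# manifest (schema version + scalar attributes) and an R serialization of
# the array payload. Groups mirror the acquisition structure: signals
# (elements x samples x wavelengths x frames), us (frames + timestamps),
# geometry, masks. Round trips are lossless.

.CONTAINER_SCHEMA <- "1.0"

#' Write an acquisition container
#'
#' @param container a named list; recognized groups:
#'   \code{signals} (numeric array, elements x samples x wavelengths x
#'   frames) with required attributes \code{samplingRate} (scalar) and
#'   \code{wavelengths} (vector) and optional \code{timestamps};
#'   \code{us} (array, rows x cols x frames) with \code{usTimestamps};
#'   \code{geometry} (a [ProbeGeometry-class]); \code{masks} (named list of
#'   logical matrices). Unknown entries are rejected.
#' @param path directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @export
writeContainer <- function(container, path) {
  known <- c("signals", "samplingRate", "wavelengths", "timestamps",
             "us", "usTimestamps", "geometry", "masks")
  bad <- setdiff(names(container), known)
  if (length(bad))
    stop("unknown container group(s): ", paste(bad, collapse = ", "))
  if (!is.null(container$signals)) {
    if (is.null(container$samplingRate))
      stop("schema error: /signals requires attribute 'samplingRate'")
    if (is.null(container$wavelengths))
      stop("schema error: /signals requires attribute 'wavelengths'")
    if (length(dim(container$signals)) != 4L)
      stop("schema error: /signals must be a 4-D array ",
           "(elements x samples x wavelengths x frames)")
  }
  if (!is.null(container$us) && is.null(container$usTimestamps))
    stop("schema error: /us requires attribute 'usTimestamps'")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema_version = .CONTAINER_SCHEMA,
                   groups = names(container),
                   samplingRate = container$samplingRate,
                   wavelengths = container$wavelengths,
                   timestamps = container$timestamps,
                   usTimestamps = container$usTimestamps)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(container, file.path(path, "payload.rds"), version = 3)
  invisible(path)
}

#' Read an acquisition container
#'
#' @param path directory written by [writeContainer()].
#' @return the container list.
#' @export
readContainer <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("not a container (missing manifest.json): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, .CONTAINER_SCHEMA))
    stop("container schema version '", manifest$schema_version,
         "' needs upgrading; this build reads version ", .CONTAINER_SCHEMA)
  readRDS(file.path(path, "payload.rds"))
}

#' Write a reconstructed image as 32-bit float TIFF with a JSON sidecar
#'
#' @param image a [ReconImage-class] or numeric matrix.
#' @param path output .tif path; provenance and wavelength go to
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeReconTIFF <- function(image, path) {
  m <- if (is(image, "ReconImage")) image@pixels else image
  # TIFF storage expects [0,1]; intensities are unit-free, so store the
  # affinely rescaled image and record the original range in the sidecar
  mn <- min(m); mx <- max(m)
  scaled <- if (mx > mn) (m - mn) / (mx - mn) else m * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(wavelength = if (is(image, "ReconImage")) image@wavelength
               else NA,
               intensityMin = mn, intensityMax = mx,
               provenance = if (is(image, "ReconImage")) image@provenance
               else list())
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
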