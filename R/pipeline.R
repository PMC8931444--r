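# Pipeline orchestration: the off-line image-formation steps run as a
# fixed DAG on a (possibly synthetic) acquisition:
#   1 band-pass -> 2 dual-SoS reconstruction -> 3 motion correction ->
#   4 frame averaging -> 5 single-SoS reconstruction -> 6 affine estimate
#   -> 8 US warping -> 9 US averaging.
# Scanner US reconstruction (7) and manual tumor segmentation (10) are
# inputs carried through the container.

#' Build a run configuration
#'
#' A fully serializable description of one pipeline run; a run is
#' reproducible from its configuration plus inputs alone.
#'
#' @param geometry named list of [probeGeometry()] arguments.
#' @param lco band-pass lower cut-off preset, kHz (100, 300 or 700).
#' @param alpha regularization weight (relative scale; see
#'   [reconConfig()]).
#' @param reconIterations iteration cap of the solver.
#' @param nFrames number of multispectral frames compounded (default 3).
#' @param motionCorrection logical, apply elastic motion correction.
#' @param registration named list of [registerElastic()] settings.
#' @param spectralHalfWindow nm (default 20).
#' @param seed integer master seed.
#' @param synthetic named list for synthetic input generation
#'   (\code{nVessels}, \code{noise} parameters, \code{motionMax}).
#' @return a named list of class \code{msotRunConfig}.
#' @export
runConfig <- function(geometry = list(nElements = 32L, nSamples = 512L,
                                      samplingRate = 2e7,
                                      gridShape = c(51L, 51L),
                                      fov = c(20, 20)),
                      lco = 100,
                      alpha = 1e-4,
                      reconIterations = 80L,
                      nFrames = 3L,
                      motionCorrection = TRUE,
                      registration = list(iterations = 20L),
                      spectralHalfWindow = 20,
                      seed = 1L,
                      synthetic = list(nVessels = 4L, whiteSigma = 0,
                                       motionMax = 0)) {
  cfg <- list(geometry = geometry, lco = lco, alpha = alpha,
              reconIterations = reconIterations, nFrames = nFrames,
              motionCorrection = motionCorrection,
              registration = registration,
              spectralHalfWindow = spectralHalfWindow,
              seed = seed, synthetic = synthetic)
  class(cfg) <- "msotRunConfig"
  cfg
}

#' @rdname runConfig
#' @param path YAML file.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads exponent forms without a signed exponent (e.g. 2.0e7)
  # as strings; coerce numeric-looking scalars back
  fix <- function(x) {
    if (is.list(x)) return(lapply(x, fix))
    if (is.character(x) &&
        all(grepl("^[-+]?[0-9.]+([eE][-+]?[0-9]+)?$", x)))
      return(as.numeric(x))
    x
  }
  do.call(runConfig, fix(cfg))
}

#' @rdname runConfig
#' @param config a run configuration.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Stable hash of a run configuration
#'
#' Polynomial rolling hash (two independent multipliers modulo the
#' Mersenne prime 2^31 - 1) over the canonical JSON serialization;
#' recorded in every artifact sidecar so outputs can be traced to their
#' configuration.
#'
#' @param config a run configuration (any serializable list).
#' @return character, 16 hex digits.
#' @export
configHash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  p <- 2^31 - 1
  h1 <- 17; h2 <- 37
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% p
    h2 <- (h2 * 131 + b) %% p
  }
  sprintf("%08x%08x", h1, h2)
}

#' Generate a synthetic multispectral acquisition container
#'
#' Simulates arc-detector signals for every wavelength and frame from a
#' seeded vessel phantom (direct-summation simulator), optionally with
#' white/coherent signal noise, and fabricates co-acquired ultrasound
#' frames (a normalized echogenicity map derived from the phantom) at the
#' 6.25 Hz ultrasound rate.
#'
#' @param config a [runConfig()] list.
#' @param wavelengthSubset optional subset of the 700-970 nm grid to
#'   simulate (default: all 28).
#' @return a container list (see [writeContainer()]).
#' @export
synthesizeAcquisition <- function(config, wavelengthSubset = NULL) {
  geom <- do.call(probeGeometry, config$geometry)
  wl <- if (is.null(wavelengthSubset)) seq(700, 970, by = 10)
  else wavelengthSubset
  phantom <- vesselGridPhantom(geom, nVessels = config$synthetic$nVessels,
                               seed = config$seed)
  lib <- defaultChromophoreLibrary()
  nF <- config$nFrames
  sig <- array(0, c(geom@nElements, geom@nSamples, length(wl), nF))
  ns <- noiseSpec(whiteSigma = config$synthetic$whiteSigma %||% 0)
  for (i in seq_along(wl)) {
    p0 <- pressureMap(phantom, wl[i], lib)
    s <- simulateSignals(p0, geom, wavelength = wl[i])
    for (n in seq_len(nF)) {
      sn <- if (ns@whiteSigma > 0)
        injectSignalNoise(s, ns, seed = config$seed + 1000L * n + i)
      else s
      sig[, , i, n] <- sn@data
    }
  }
  # fabricated ultrasound: echogenicity from total chromophore content
  echo <- apply(phantom@maps, c(1, 2), sum)
  if (max(echo) > 0) echo <- echo / max(echo)
  frameDur <- 1.1
  usRate <- 6.25
  usT <- seq(0, nF * frameDur, by = 1 / usRate)
  us <- array(rep(echo, length(usT)), c(dim(echo), length(usT)))
  list(signals = sig, samplingRate = geom@samplingRate, wavelengths = wl,
       timestamps = (seq_len(nF) - 1) * frameDur,
       us = us, usTimestamps = usT, geometry = geom,
       masks = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the image-formation pipeline
#'
#' Executes the off-line processing DAG on a container (synthesized from
#' the config when \code{container} is NULL), writing every intermediate
#' artifact with a JSON sidecar carrying the configuration hash, and a log
#' with per-step wall times.
#'
#' @param config a [runConfig()] list.
#' @param outDir artifact directory (created).
#' @param container optional acquisition container (see
#'   [readContainer()]); synthesized when NULL.
#' @param wavelengthSubset optional wavelength subset for synthetic runs.
#' @return invisibly, a list with the final averaged frame, the spectral
#'   median image, the affine, the averaged US, and paths of emitted
#'   artifacts.
#' @export
runPipeline <- function(config, outDir, container = NULL,
                        wavelengthSubset = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  logPath <- file.path(outDir, "log.txt")
  cat(sprintf("run %s started %s\n", hash, format(Sys.time())),
      file = logPath)
  stepLog <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    cat(sprintf("step %-22s %8.2f s\n", name,
                proc.time()[["elapsed"]] - t0),
        file = logPath, append = TRUE)
    res
  }
  sidecar <- function(name, extra = list()) {
    jsonlite::write_json(c(list(configHash = hash), extra),
                         file.path(outDir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (is.null(container))
    container <- stepLog("synthesize",
                         synthesizeAcquisition(config, wavelengthSubset))
  geom <- container$geometry
  wl <- container$wavelengths
  nF <- dim(container$signals)[4]
  writeContainer(container, file.path(outDir, "acquisition"))
  sidecar("acquisition")

  spec <- lcoPreset(config$lco)
  tir <- deltaKernel()
  modelDual <- stepLog("model_dual",
                       assembleForwardModel(geom, tir, "dual"))
  modelSingle <- stepLog("model_single",
                         assembleForwardModel(geom, tir, "uniform"))
  cfgRec <- reconConfig(alpha = config$alpha,
                        maxIterations = config$reconIterations)

  # steps 1-2: band-pass + dual-SoS reconstruction, per wavelength/frame
  frames <- stepLog("filter_reconstruct", {
    lapply(seq_len(nF), function(n) {
      imgs <- lapply(seq_along(wl), function(i) {
        s <- signalFrame(container$signals[, , i, n],
                         container$samplingRate, wl[i])
        f <- bandpass(s, spec)
        suppressWarnings(reconstruct(f, modelDual, cfgRec))@pixels
      })
      multispectralFrame(imgs, wl, frameIndex = n)
    })
  })
  saveRDS(frames, file.path(outDir, "recon_dual.rds"))
  sidecar("recon_dual", list(lco = config$lco, alpha = config$alpha))

  # steps 3-4: motion correction + averaging
  averaged <- stepLog("motion_average", {
    if (config$motionCorrection && nF > 1) {
      ca <- do.call(correctAndAverage,
                    c(list(frames = frames), config$registration))
      saveRDS(ca[c("t1", "t2")], file.path(outDir, "motion_fields.rds"))
      sidecar("motion_fields")
      ca$frame
    } else {
      acc <- Reduce(`+`, lapply(frames, function(f) f@data))
      saveRDS(list(), file.path(outDir, "motion_fields.rds"))
      sidecar("motion_fields", list(skipped = TRUE))
      multispectralFrame(acc / nF, wl, frameIndex = ceiling(nF / 2))
    }
  })
  saveRDS(averaged, file.path(outDir, "averaged_frame.rds"))
  sidecar("averaged_frame")

  # spectral median at the reference wavelength (when on the grid)
  refWl <- if (800 %in% wl) 800 else wl[ceiling(length(wl) / 2)]
  med <- stepLog("spectral_median",
                 spectralMedian(averaged, refWl,
                                halfWindow = config$spectralHalfWindow))
  writeReconTIFF(reconImage(med@pixels / max(max(med@pixels), 1),
                            med@wavelength, med@provenance),
                 file.path(outDir, "spectral_median.tif"))
  sidecar("spectral_median", list(wavelength = refWl))

  # step 5: single-SoS reconstruction of the reference wavelength
  iRef <- match(refWl, wl)
  singleRef <- stepLog("recon_single", {
    s <- signalFrame(container$signals[, , iRef, ceiling(nF / 2)],
                     container$samplingRate, refWl)
    suppressWarnings(reconstruct(bandpass(s, spec), modelSingle, cfgRec))
  })
  saveRDS(singleRef, file.path(outDir, "recon_single.rds"))
  sidecar("recon_single")

  # step 6: affine between the two variants
  dualRef <- frameImage(averaged, refWl)
  affine <- stepLog("affine_estimate", {
    tryCatch(estimateAffine(dualRef@pixels, singleRef@pixels),
             warning = function(w) affineTransform2D())
  })
  saveRDS(affine, file.path(outDir, "affine.rds"))
  sidecar("affine")

  # steps 8-9: US warping into the dual-SoS frame, then averaging over the
  # acquisition window of the middle multispectral frame
  usOut <- stepLog("us_process", {
    if (is.null(container$us)) NULL
    else {
      usFrames <- lapply(seq_len(dim(container$us)[3]), function(k)
        usImage(container$us[, , k], container$usTimestamps[k]))
      t0 <- container$timestamps[ceiling(nF / 2)]
      avg <- averageConcurrentUS(usFrames, c(t0, t0 + 1.1))
      warpUS(avg, affine)
    }
  })
  if (!is.null(usOut)) {
    saveRDS(usOut, file.path(outDir, "us_averaged.rds"))
    sidecar("us_averaged")
  }

  cat(sprintf("run %s finished %s\n", hash, format(Sys.time())),
      file = logPath, append = TRUE)
  invisible(list(averaged = averaged, spectralMedian = med,
                 affine = affine, us = usOut,
                 artifacts = list.files(outDir)))
}
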