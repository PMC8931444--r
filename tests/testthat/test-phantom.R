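test_that("phantom construction: empty, reproducible, in-FOV checks", {
  g <- deskGeometry(nElements = 4L, gridShape = c(21L, 21L))
  empty <- makePhantom(list(), g)
  expect_true(all(empty@maps == 0))
  p1 <- vesselGridPhantom(g, nVessels = 5L, seed = 7L)
  p2 <- vesselGridPhantom(g, nVessels = 5L, seed = 7L)
  expect_identical(p1@maps, p2@maps)
  p3 <- vesselGridPhantom(g, nVessels = 5L, seed = 8L)
  expect_false(identical(p1@maps, p3@maps))
  expect_error(makePhantom(list(list(type = "disk", center = c(0, 100),
                                     radius = 2,
                                     concentration = c(Hb = 1))), g),
               "outside")
  expect_error(makePhantom(list(list(type = "disk", center = c(0, 15),
                                     radius = 1,
                                     concentration = c(melanin = 1))), g),
               "named after channels")
})

test_that("a pure-Hb disk is brighter at 700 nm than at 880 nm", {
  g <- deskGeometry(nElements = 4L, gridShape = c(21L, 21L))
  ph <- makePhantom(list(list(type = "disk", center = c(0, 15), radius = 2,
                              concentration = c(Hb = 1))), g)
  lib <- defaultChromophoreLibrary()
  p700 <- pressureMap(ph, 700, lib)
  p880 <- pressureMap(ph, 880, lib)
  inside <- ph@maps[, , match("Hb", ph@channels)] > 0
  expect_true(all(p700[inside] > p880[inside]))
  # matches a direct library lookup
  iHb <- match("Hb", colnames(lib@spectra))
  expect_equal(max(p700),
               as.numeric(lib@spectra[match(700, wavelengths(lib)), iHb]))
})

test_that("the direct simulator agrees with the sparse forward model", {
  g <- deskGeometry(nElements = 12L, gridShape = c(31L, 31L))
  ph <- vesselGridPhantom(g, nVessels = 4L, seed = 7L)
  p0 <- pressureMap(ph, 800)
  direct <- simulateSignals(p0, g)
  viaModel <- applyModel(assembleForwardModel(g), p0)
  relRMS <- sqrt(mean((signalData(direct) - signalData(viaModel))^2)) /
    sqrt(mean(signalData(viaModel)^2))
  expect_lt(relRMS, 0.02)
  expect_true(all(signalData(simulateSignals(p0 * 0, g)) == 0))
})

test_that("single-pixel sources arrive within one sample of the oracle time", {
  g <- deskGeometry(nElements = 6L, gridShape = c(21L, 21L))
  img <- matrix(0, 21, 21); img[11, 8] <- 1
  gc <- gridCoordinates(g)
  sf <- simulateSignals(img, g)
  for (e in seq_len(6L)) {
    tt <- computeTravelTime(c(gc$x[8], gc$y[11]),
                            elementPositions(g)[e, ], g)
    trace <- signalData(sf)[e, ]
    onset <- which(trace != 0)[1]
    expect_lt(abs(onset - (tt * g@samplingRate + 1)), 2.5)
  }
})

test_that("signal noise injection is seeded and zero noise is identity", {
  g <- deskGeometry(nElements = 6L, gridShape = c(21L, 21L))
  s <- simulateSignals(pressureMap(vesselGridPhantom(g, 3L, 7L), 800), g)
  n1 <- injectSignalNoise(s, noiseSpec(whiteSigma = 0.1), seed = 5L)
  n2 <- injectSignalNoise(s, noiseSpec(whiteSigma = 0.1), seed = 5L)
  expect_identical(signalData(n1), signalData(n2))
  clean <- injectSignalNoise(s, noiseSpec(), seed = 5L)
  expect_identical(signalData(clean), signalData(s))
})

test_that("coherent channel-shared noise reconstructs onto isochrone rings", {
  g <- deskGeometry(nElements = 16L, gridShape = c(31L, 31L))
  mdl <- assembleForwardModel(g)
  quiet <- signalFrame(matrix(0, 16, g@nSamples), g@samplingRate)
  noisy <- injectSignalNoise(quiet, noiseSpec(coherentAmp = 1), seed = 4L)
  rNoise <- reconstruct(noisy, mdl, reconConfig(alpha = 1e-4,
                                                maxIterations = 80L))
  rClean <- reconstruct(quiet, mdl, reconConfig(alpha = 1e-4,
                                                maxIterations = 80L))
  # annulus at mid-depth of the image
  gc <- gridCoordinates(g)
  yy <- matrix(gc$y, 31, 31); xx <- matrix(gc$x, 31, 31, byrow = TRUE)
  e1 <- elementPositions(g)[8, ]
  rr <- sqrt((xx - e1[1])^2 + (yy - e1[2])^2)
  ann <- rr > quantile(rr, 0.4) & rr < quantile(rr, 0.6)
  expect_gt(sum(pixels(rNoise)[ann]^2), sum(pixels(rClean)[ann]^2))
})

test_that("image noise and motion injection is seeded, guarded, reversible", {
  f <- multispectralFrame(array(runif(16 * 16 * 28), c(16, 16, 28)))
  frames <- list(f, f, f)
  id <- injectNoiseAndMotion(frames, noiseSpec(), motionMax = 0, seed = 1L)
  expect_identical(id$frames[[1]]@data, f@data)
  expect_true(all(vapply(id$fields, function(d) max(abs(d@dx)),
                         numeric(1)) == 0))
  a <- injectNoiseAndMotion(frames, noiseSpec(spikeProb = 0.05),
                            motionMax = 2, seed = 9L)
  b <- injectNoiseAndMotion(frames, noiseSpec(spikeProb = 0.05),
                            motionMax = 2, seed = 9L)
  expect_identical(a$frames[[2]]@data, b$frames[[2]]@data)
  expect_error(injectNoiseAndMotion(frames, noiseSpec(), motionMax = 10),
               "quarter")
})

test_that("simulate-filter-reconstruct-average-median-unmix keeps identity", {
  g <- probeGeometry(nElements = 32L, samplingRate = 2e7, nSamples = 768L,
                     gridShape = c(41L, 41L), fov = c(20, 20))
  ph <- vesselGridPhantom(g, nVessels = 4L, seed = 7L)
  lib <- defaultChromophoreLibrary()
  mdl <- suppressMessages(assembleForwardModel(g))
  wl <- seq(700, 970, by = 10)
  imgs <- lapply(wl, function(l) {
    s <- simulateSignals(pressureMap(ph, l, lib), g)
    f <- bandpass(s, lcoPreset(100))
    pixels(suppressWarnings(
      reconstruct(f, mdl, reconConfig(alpha = 1e-5, maxIterations = 120L))))
  })
  fr <- multispectralFrame(imgs, wl)
  ca <- correctAndAverage(list(fr, fr, fr))
  med <- lapply(wl, function(l) pixels(spectralMedian(ca$frame, l)))
  cm <- unmix(multispectralFrame(med, wl), lib)
  correct <- 0; total <- 0
  am <- apply(cm@maps, c(1, 2), which.max)
  for (k in seq_along(ph@channels)) {
    others <- apply(ph@maps[, , -k, drop = FALSE], c(1, 2), sum)
    pure <- ph@maps[, , k] > 0 & others == 0
    correct <- correct + sum(am[pure] == k)
    total <- total + sum(pure)
  }
  expect_gt(total, 10)
  expect_gte(correct / total, 0.95)
})
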