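test_that("spectral median: constant spectra, window size, boundaries", {
  wl <- seq(700, 970, by = 10)
  arr <- array(rep(5, 4 * 4 * 28), c(4, 4, 28))
  st <- multispectralFrame(arr, wl)
  expect_true(all(pixels(spectralMedian(st, 800)) == 5))
  # interior window holds exactly 5 wavelengths on the 10 nm grid
  expect_length(provenance(spectralMedian(st, 800))$windowWavelengths, 5L)
  # boundary windows truncate to the available wavelengths
  expect_length(provenance(spectralMedian(st, 700))$windowWavelengths, 3L)
  expect_length(provenance(spectralMedian(st, 960))$windowWavelengths, 4L)
  expect_error(spectralMedian(st, 805), "grid")
})

test_that("a single-wavelength spike is fully rejected by the median", {
  wl <- seq(700, 970, by = 10)
  # smooth spectrum with a gentle local maximum at 850 nm: the centre
  # sample sits above its window median, so a spike there is invisible
  smooth <- 1 + 0.5 * exp(-((wl - 850) / 25)^2)
  arr <- array(rep(smooth, each = 9), c(3, 3, 28))
  spiked <- arr
  i <- match(850, wl)
  spiked[2, 2, i] <- spiked[2, 2, i] * 10
  stClean <- multispectralFrame(arr, wl)
  stSpiked <- multispectralFrame(spiked, wl)
  mClean <- pixels(spectralMedian(stClean, 850))
  mSpiked <- pixels(spectralMedian(stSpiked, 850))
  expect_equal(mSpiked, mClean)
  # and the spiked amplitude itself never surfaces
  expect_true(all(mSpiked < min(spiked[2, 2, i])))
  # the output is the median of the 4 unspiked neighbors + spiked centre,
  # i.e. an unspiked window value
  winUnspiked <- smooth[(i - 2):(i + 2)]
  expect_equal(mSpiked[2, 2],
               median(c(winUnspiked[-3], spiked[2, 2, i])))
})

test_that("spectral median is idempotent on monotone spectra and bounded", {
  wl <- seq(700, 970, by = 10)
  set.seed(12)
  arr <- array(0, c(5, 5, 28))
  base <- sort(runif(28))                    # monotone within every window
  for (i in 1:28) arr[, , i] <- base[i] * matrix(runif(25, 0.9, 1.1) * 0 + 1, 5, 5)
  st <- multispectralFrame(arr, wl)
  for (l in c(700, 800, 900, 970)) {
    m <- pixels(spectralMedian(st, l))
    sel <- which(abs(wl - l) <= 20)
    # median of a monotone window is the (interior) centre sample
    expect_equal(m[1, 1], median(base[sel]))
    expect_gte(min(m), min(base[sel]))
    expect_lte(max(m), max(base[sel]))
  }
})

test_that("unmixing recovers exact mixtures and clips negative targets", {
  lib <- defaultChromophoreLibrary()
  S <- lib@spectra
  wl <- wavelengths(lib)
  # pure first chromophore
  pure <- multispectralFrame(array(rep(S[, 1], each = 4), c(2, 2, 28)), wl)
  cm <- unmix(pure, lib)
  expect_equal(cm@maps[1, 1, ], c(1, 0, 0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  # random non-negative mixtures, noiseless
  set.seed(44)
  for (k in 1:20) {
    cs <- runif(4, 0, 2) * rbinom(4, 1, 0.7)
    p <- as.numeric(S %*% cs)
    st <- multispectralFrame(array(rep(p, each = 1), c(1, 1, 28)), wl)
    expect_lt(max(abs(unmix(st, lib)@maps[1, 1, ] - cs)), 1e-8)
  }
  # a negated spectrum has the zero vector as its non-negative minimizer
  neg <- multispectralFrame(array(rep(-S[, 1], each = 1), c(1, 1, 28)), wl)
  expect_true(all(unmix(neg, lib)@maps == 0))
})

test_that("constrained residual is bounded below by unconstrained LS", {
  lib <- defaultChromophoreLibrary()
  S <- lib@spectra
  wl <- wavelengths(lib)
  set.seed(55)
  for (k in 1:10) {
    p <- rnorm(28)
    st <- multispectralFrame(array(p, c(1, 1, 28)), wl)
    cNN <- unmix(st, lib)@maps[1, 1, ]
    cLS <- as.numeric(qr.solve(S, p))
    rNN <- sqrt(sum((S %*% cNN - p)^2))
    rLS <- sqrt(sum((S %*% cLS - p)^2))
    expect_gte(rNN + 1e-12, rLS)
    if (all(cLS >= 0)) expect_equal(rNN, rLS, tolerance = 1e-8)
  }
})

test_that("library I/O round-trips and rejects degenerate columns", {
  lib <- defaultChromophoreLibrary()
  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength = wavelengths(lib), lib@spectra),
            tmp, row.names = FALSE)
  lib2 <- readChromophoreLibrary(tmp)
  expect_equal(lib2@spectra, lib@spectra, tolerance = 1e-12)
  expect_error(chromophoreLibrary(1:3, cbind(a = c(0, 0, 0), b = 1:3)),
               "zero")
})
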