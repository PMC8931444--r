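test_that("CNR follows the variance-denominator formula exactly", {
  # regions engineered to have exact statistics:
  # object mean 1, background mean 0, both variances 0.05
  msk <- regionMasksFromSkin(2, c(40, 20), 0.25, objectDepth = 5)
  img <- matrix(0, 40, 20)
  spread <- rep(c(-1, 1) * sqrt(0.05), length.out = sum(msk@objectMask))
  spread <- spread - mean(spread)
  spread <- spread / sd(spread) * sqrt(0.05)
  img[msk@objectMask] <- 1 + spread
  b <- rep(c(-1, 1) * sqrt(0.05), length.out = sum(msk@backgroundMask))
  b <- (b - mean(b)) / sd(b) * sqrt(0.05)
  img[msk@backgroundMask] <- b
  rep1 <- computeCNR(img, msk)
  expect_equal(rep1@cnrDb, 10 * log10(1 / 0.1), tolerance = 1e-10)
  expect_false(rep1@flagged)
  # sd-denominator escape hatch
  rep2 <- computeCNR(img, msk, denominator = "sd")
  expect_equal(rep2@cnrDb, 10 * log10(1 / (2 * sqrt(0.05))),
               tolerance = 1e-10)
})

test_that("non-positive contrast flags the report instead of NaN", {
  msk <- regionMasksFromSkin(2, c(40, 20), 0.25, objectDepth = 5)
  set.seed(3)
  img <- matrix(rnorm(800), 40, 20)   # equal means
  r <- computeCNR(img, msk)
  expect_true(r@flagged)
  expect_true(is.na(r@cnrDb))
})

test_that("CNR shift and scale behavior match the printed formula", {
  msk <- regionMasksFromSkin(2, c(60, 30), 0.25, objectDepth = 8)
  set.seed(9)
  img <- matrix(rnorm(1800, sd = 0.2), 60, 30)
  img[msk@objectMask] <- img[msk@objectMask] + 1
  base <- computeCNR(img, msk)@cnrDb
  # adding a constant shifts both means equally: CNR unchanged, exactly
  expect_equal(computeCNR(img + 3.21, msk)@cnrDb, base, tolerance = 1e-12)
  # scaling by k changes CNR by 10*log10(1/k) under the variance denominator
  for (k in c(0.5, 2, 10))
    expect_equal(computeCNR(img * k, msk)@cnrDb, base + 10 * log10(1 / k),
                 tolerance = 1e-10)
})

test_that("averaging three i.i.d. frames raises CNR by about 4.77 dB", {
  msk <- regionMasksFromSkin(2, c(80, 80), 0.25, objectDepth = 12)
  scene <- matrix(0, 80, 80)
  scene[msk@objectMask] <- 1
  set.seed(10)
  noisy <- function() scene + matrix(rnorm(6400, sd = 0.2), 80, 80)
  f1 <- noisy(); f2 <- noisy(); f3 <- noisy()
  gain <- computeCNR((f1 + f2 + f3) / 3, msk)@cnrDb -
    computeCNR(f1, msk)@cnrDb
  expect_lt(abs(gain - 10 * log10(3)), 0.5)
})

test_that("FWHM: closed forms, plateaus, and the crossing-scan oracle", {
  x <- seq(-1000, 1000, by = 5)
  gauss <- exp(-x^2 / (2 * 100^2))
  expect_equal(fwhm(gauss, 5), 2 * sqrt(2 * log(2)) * 100, tolerance = 0.02)
  # rectangular pulse: width recovered to within one sample pitch
  rect <- c(rep(0, 20), rep(1, 41), rep(0, 20))
  expect_lt(abs(fwhm(rect, 5) - 200), 5 + 1e-9)
  # positive affine rescaling leaves the width unchanged
  expect_equal(fwhm(3 * gauss + 2, 5), fwhm(gauss, 5), tolerance = 1e-9)
  # brute-force crossing scan agrees exactly on an asymmetric profile
  set.seed(6)
  prof <- exp(-((x + 40) / 180)^2) + 0.3 * exp(-((x - 300) / 700)^2)
  w <- fwhm(prof, 5)
  lev <- min(prof) + (max(prof) - min(prof)) / 2
  pk <- which.max(prof)
  li <- max(which(prof[1:(pk - 1)] <= lev))
  ri <- pk + min(which(prof[(pk + 1):length(prof)] <= lev))
  lpos <- li + (lev - prof[li]) / (prof[li + 1] - prof[li])
  rpos <- ri - (lev - prof[ri]) / (prof[ri - 1] - prof[ri])
  expect_equal(w, (rpos - lpos) * 5, tolerance = 1e-12)
  # error cases
  expect_error(fwhm(c(1, 2, 3), 5), "interior")
  expect_error(fwhm(c(0, 1, 0.8, 1, 0), 5), "unique")
})

test_that("region masks validate disjointness and emptiness", {
  expect_error(new("RegionMasks",
                   objectMask = matrix(TRUE, 2, 2),
                   backgroundMask = matrix(TRUE, 2, 2),
                   skinLine = 0) , "disjoint")
  # a skin line at the top row leaves no background region
  expect_error(regionMasksFromSkin(0, c(4, 4), 1, objectDepth = 2),
               "non-empty")
  expect_error(computeCNR(matrix(Inf, 40, 20),
                          regionMasksFromSkin(2, c(40, 20), 0.25, 5)),
               "finite")
})
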