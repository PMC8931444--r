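test_that("local contrast normalization matches a naive per-pixel oracle", {
  set.seed(4)
  img <- matrix(runif(32 * 32), 32, 32)
  r <- 3L; n <- 50
  out <- localContrastNorm(img, r, n, percentileOn = "all")
  pn <- quantile(as.vector(img), n / 100, names = FALSE)
  brute <- img
  for (i in 1:32) for (j in 1:32) {
    acc <- 0; cnt <- 0
    for (di in -r:r) for (dj in -r:r) {
      if (abs(di) + abs(dj) > r) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 32 && jj >= 1 && jj <= 32) {
        acc <- acc + img[ii, jj]; cnt <- cnt + 1
      }
    }
    brute[i, j] <- img[i, j] / max(acc / cnt, pn)
  }
  expect_equal(out, brute, tolerance = 1e-15)
  # constant image: local mean equals the percentile equals the value
  expect_true(all(localContrastNorm(matrix(2, 8, 8), 2, 30) == 1))
  expect_error(localContrastNorm(matrix(0, 8, 8), 2, 30), "zero")
  # isolated bright pixel is floored by the percentile
  spike <- matrix(0.01, 21, 21); spike[11, 11] <- 5
  o <- localContrastNorm(spike, 1, 90, percentileOn = "all")
  p90 <- quantile(as.vector(spike), 0.9, names = FALSE)
  expect_lte(o[11, 11], 5 / p90 + 1e-12)
})

test_that("sigmoid normalization anchors the percentile range to [a, b]", {
  # 101 evenly spaced values: percentiles land exactly on samples
  img <- matrix(seq(0, 1, length.out = 101), 101, 1)
  a <- 0.1; b <- 0.9; Pa <- 10; Pb <- 90
  out <- sigmoidNorm(img, Pa, Pb, a, b, percentileOn = "all")
  va <- quantile(as.vector(img), Pa / 100, names = FALSE)
  vb <- quantile(as.vector(img), Pb / 100, names = FALSE)
  expect_equal(out[img == va], a, tolerance = 1e-9)
  expect_equal(out[img == vb], b, tolerance = 1e-9)
  expect_true(all(out > 0 & out < 1))
  expect_true(all(diff(out[, 1]) > 0))       # strictly increasing
  expect_error(sigmoidNorm(matrix(1, 4, 4), 10, 90, 0.1, 0.9,
                           percentileOn = "all"), "degenerate")
})

test_that("power law and unsharp masking behave as specified", {
  set.seed(5)
  img <- matrix(runif(400), 20, 20)
  expect_equal(powerUnsharp(img, gamma = 1, alpha = 0), img)
  expect_equal(powerUnsharp(img, gamma = 2, alpha = 0), img^2)
  # constants are fixed points of unsharp masking
  expect_equal(powerUnsharp(matrix(3, 10, 10), 1, alpha = 0.8, s = 2),
               matrix(3, 10, 10), tolerance = 1e-12)
  # sharpening increases the maximum gradient across a step edge
  step <- matrix(rep(c(0.2, 0.8), each = 160), 16, 20)
  sharp <- powerUnsharp(step, 1, alpha = 1, s = 1.5)
  gmax <- function(m) max(abs(m[, -1] - m[, -ncol(m)]))
  expect_gt(gmax(sharp), gmax(step))
  expect_error(powerUnsharp(img, gamma = 0), "gamma")
})

test_that("ultrasound depth-gain enhancement matches the printed constants", {
  expect_equal(enhanceUS(matrix(0.9, 1, 1), 0, 0.1)[1, 1], 0.5)
  # 2 cm deep at 0.1 mm pitch is row 201
  col <- enhanceUS(matrix(0.9, 201, 1), 0, 0.1)
  expect_equal(col[201, 1], exp(0.3) * 0.5, tolerance = 1e-9)
  # gain is strictly increasing in depth at fixed intensity
  expect_true(all(diff(col[, 1]) > 0))
  # pixels above the surface are clamped to depth zero
  shifted <- enhanceUS(matrix(0.5, 10, 1), skinLine = 0.45, pitch = 0.1)
  expect_equal(shifted[1, 1], shifted[2, 1])  # both above/at the surface
  expect_error(enhanceUS(matrix(2, 2, 2)), "normalized")
})

test_that("dual-band rendering interpolates corner colors bilinearly", {
  cm <- colorMap2D()
  low <- matrix(c(0, 1, 0.5, 0.25), 2, 2)
  high <- matrix(c(0, 1, 0.5, 0.75), 2, 2)
  out <- renderDualBand(low, high, cm)
  expect_equal(out[1, 1, ], cm@corner00)
  expect_equal(out[2, 1, ], cm@corner11)
  mid <- (cm@corner00 + cm@corner10 + cm@corner01 + cm@corner11) / 4
  expect_equal(out[1, 2, ], mid)
  set.seed(8)
  l2 <- matrix(runif(100), 10, 10); h2 <- matrix(runif(100), 10, 10)
  o2 <- renderDualBand(l2, h2, cm)
  expect_true(all(o2 >= 0 & o2 <= 1))
  expect_error(renderDualBand(l2, h2[1:5, ], cm), "shape")
})

test_that("unmixing and hybrid renders route channels and contours", {
  maps <- array(0, c(4, 4, 4))
  maps[1, 1, 1] <- 2                      # pure HbO2 pixel
  maps[2, 2, 4] <- 9                      # water is never displayed
  cm <- new("CoefficientMaps", maps = maps,
            channels = c("HbO2", "Hb", "fat", "water"))
  rgb <- renderUnmixing(cm)
  expect_gt(rgb[1, 1, 1], 0)
  expect_equal(rgb[1, 1, 2], 0); expect_equal(rgb[1, 1, 3], 0)
  expect_equal(rgb[2, 2, ], c(0, 0, 0))
  # zero optoacoustic overlay: hybrid equals replicated grayscale US
  us <- matrix(seq(0, 1, length.out = 36), 6, 6)
  hyb <- renderHybrid(matrix(0, 6, 6), us)
  for (ch in 1:3) expect_equal(hyb[, , ch], us)
  # a square mask draws exactly its boundary in the contour color
  mask <- matrix(FALSE, 6, 6); mask[2:5, 2:5] <- TRUE
  hyb2 <- renderHybrid(matrix(0, 6, 6), us, mask = mask)
  bnd <- mask
  bnd[3:4, 3:4] <- FALSE                  # interior excluded
  for (ch in 1:3) {
    expect_true(all(hyb2[, , ch][bnd] == 1))
    expect_equal(hyb2[, , ch][!bnd], us[!bnd])  # interior untinted
  }
})

test_that("renders round-trip through PNG", {
  set.seed(9)
  img <- array(runif(48), c(4, 4, 3))
  tmp <- tempfile(fileext = ".png")
  writeRender(img, tmp, params = list(gamma = 0.5))
  expect_true(file.exists(tmp))
  expect_true(file.exists(paste0(tmp, ".json")))
  back <- png::readPNG(tmp)
  expect_equal(back, img, tolerance = 1 / 255)
})
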