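test_that("probe geometry places elements on the arc above the interface", {
  g <- probeGeometry()
  pos <- elementPositions(g)
  expect_equal(nrow(pos), 256L)
  # chord between the endpoint elements
  expect_equal(sqrt(sum((pos[256, ] - pos[1, ])^2)), 60, tolerance = 1e-10)
  # all on a common circle (constant radius about the fitted centre)
  theta <- 145 * pi / 180
  R <- 60 / (2 * sin(theta / 2))
  centre <- c(0, pos[128, 2] + R * cos(asin(pos[128, 1] / R)))
  rad <- sqrt((pos[, 1] - centre[1])^2 + (pos[, 2] - centre[2])^2)
  expect_lt(diff(range(rad)), 1e-9)
  expect_true(all(pos[, 2] < g@interfaceDepth))
  # invalid geometries are rejected
  expect_error(probeGeometry(samplingRate = 1e6), "Nyquist")
  # negative clearance pushes the endpoint elements below the interface
  expect_error(probeGeometry(elementClearance = -5), "above the interface")
})

test_that("travel time reduces to straight rays in uniform media", {
  g <- probeGeometry(sosWater = 1500, sosTissue = 1500, interfaceDepth = 10)
  expect_equal(computeTravelTime(c(0, 15), c(0, 0), g), 1e-5)
  # pixel exactly on the interface: water-only path
  g2 <- probeGeometry(sosWater = 1400, sosTissue = 1540, interfaceDepth = 10)
  expect_equal(computeTravelTime(c(0, 10), c(0, 0), g2), 0.01 / 1400,
               tolerance = 1e-12)
  # equal speeds: dual mode equals the straight-line time off-axis too
  p <- c(7, 23); e <- c(-3, -2)
  straight <- sqrt(sum((p - e)^2)) / 1500 * 1e-3
  expect_equal(computeTravelTime(p, e, g), straight, tolerance = 1e-9)
})

test_that("refracted travel time matches the breakpoint-scan oracle", {
  g <- probeGeometry(sosWater = 1397, sosTissue = 1540, interfaceDepth = 10)
  t1 <- computeTravelTime(c(5, 20), c(0, 0), g)
  o1 <- oracleTravelTime(c(5, 20), c(0, 0), 10, 1397, 1540)
  expect_lt(abs(t1 - o1) / o1, 1e-6)
  set.seed(21)
  for (i in 1:20) {
    pix <- c(runif(1, -15, 15), runif(1, 10, 45))
    ele <- c(runif(1, -25, 25), runif(1, -15, 5))
    tt <- computeTravelTime(pix, ele, g)
    oo <- oracleTravelTime(pix, ele, 10, 1397, 1540)
    expect_lt(abs(tt - oo) / oo, 1e-6)
  }
})

test_that("Fermat time never exceeds other single-breakpoint paths", {
  g <- probeGeometry(sosWater = 1397, sosTissue = 1560, interfaceDepth = 10)
  set.seed(31)
  for (i in 1:100) {
    pix <- c(runif(1, -15, 15), runif(1, 10.5, 45))
    ele <- c(runif(1, -25, 25), runif(1, -15, 5))
    tt <- computeTravelTime(pix, ele, g)
    xs <- seq(min(ele[1], pix[1]), max(ele[1], pix[1]), length.out = 41)
    other <- (sqrt((xs - ele[1])^2 + (10 - ele[2])^2) / 1397 +
                sqrt((pix[1] - xs)^2 + (pix[2] - 10)^2) / 1560) * 1e-3
    expect_true(all(tt <= other + 1e-15))
  }
})

test_that("travel time is monotone in pixel depth at fixed lateral offset", {
  g <- probeGeometry(sosWater = 1397, sosTissue = 1510, interfaceDepth = 10)
  e <- c(4, -3)
  depths <- seq(10, 45, by = 0.5)
  tt <- vapply(depths, function(d) computeTravelTime(c(6, d), e, g),
               numeric(1))
  expect_true(all(diff(tt) >= -1e-15))
})

test_that("invalid pixel/element placements are rejected", {
  g <- probeGeometry(interfaceDepth = 10)
  expect_error(computeTravelTime(c(0, 5), c(0, 0), g), "above the interface")
  expect_error(computeTravelTime(c(0, 20), c(0, 12), g), "water side")
})
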