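# Shared fixtures, generated in code at test time.

# a small desk-scale probe for fast model assembly
deskGeometry <- function(nElements = 16L, gridShape = c(31L, 31L),
                         fov = c(15, 15), nSamples = 768L,
                         sosWater = 1397, sosTissue = 1510) {
  probeGeometry(nElements = nElements, samplingRate = 2e7,
                nSamples = nSamples, gridShape = gridShape, fov = fov,
                sosWater = sosWater, sosTissue = sosTissue)
}

# dense smooth texture: the canonical fixture for registration tests
textureImage <- function(n = 96L, seed = 9L, sigma = 1.5) {
  set.seed(seed)
  m <- msotpipe:::.gaussianBlur(matrix(runif(n * n), n, n), sigma)
  (m - min(m)) / (max(m) - min(m))
}

# Gaussian-bump displacement field with given peak amplitudes (px)
bumpField <- function(n, ampX, ampY, center = (n + 1) / 2, sigma = n / 8) {
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  yy <- matrix(seq_len(n), n, n)
  b <- exp(-((xx - center)^2 + (yy - center)^2) / (2 * sigma^2))
  displacementField(ampX * b, ampY * b)
}

# residual misalignment of a recovered field d against a known true warp g:
# r(x) = d(x) + g(x + d(x)); zero iff the recovery inverts the warp exactly
residualEPE <- function(recovered, truth) {
  rx <- recovered@dx +
    msotpipe:::.warpBilinear(truth@dx, recovered@dx, recovered@dy)
  ry <- recovered@dy +
    msotpipe:::.warpBilinear(truth@dy, recovered@dx, recovered@dy)
  sqrt(rx^2 + ry^2)
}

# independent travel-time oracle: exhaustive breakpoint scan over the
# interface followed by golden-section (stats::optimize) refinement
oracleTravelTime <- function(pixel, element, d, cw, ct, nScan = 4001L) {
  f <- function(x) {
    sqrt((x - element[1])^2 + (d - element[2])^2) / cw +
      sqrt((pixel[1] - x)^2 + (pixel[2] - d)^2) / ct
  }
  lo <- min(element[1], pixel[1]) - 1e-9
  hi <- max(element[1], pixel[1]) + 1e-9
  xs <- seq(lo, hi, length.out = nScan)
  ts <- f(xs)
  i <- which.min(ts)
  a <- xs[max(1L, i - 1L)]; b <- xs[min(nScan, i + 1L)]
  opt <- stats::optimize(f, c(a, b), tol = 1e-12)
  min(opt$objective, ts[i]) * 1e-3
}
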