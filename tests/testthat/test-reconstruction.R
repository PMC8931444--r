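reconFixture <- function() {
  g <- deskGeometry(nElements = 8L, gridShape = c(20L, 20L), fov = c(10, 10))
  mdl <- suppressMessages(assembleForwardModel(g))
  set.seed(42)
  p0 <- matrix(runif(prod(g@gridShape)), g@gridShape[1], g@gridShape[2])
  s <- applyModel(mdl, p0)
  list(g = g, mdl = mdl, p0 = p0, s = s,
       sv = as.vector(t(signalData(s))))
}

test_that("all-zero signals reconstruct to the all-zero image", {
  fx <- reconFixture()
  z <- signalFrame(matrix(0, fx$g@nElements, fx$g@nSamples),
                   fx$g@samplingRate)
  rec <- reconstruct(z, fx$mdl, reconConfig(alpha = 1e-3))
  expect_true(all(pixels(rec) == 0))
})

test_that("unconstrained mode matches a dense Tikhonov solve", {
  fx <- reconFixture()
  M <- as.matrix(fx$mdl@matrix)
  alpha <- 0.5
  rec <- reconstruct(fx$s, fx$mdl,
                     reconConfig(alpha = alpha, maxIterations = 2000L,
                                 tolerance = 1e-13, nonneg = FALSE,
                                 alphaScale = "absolute"))
  dense <- solve(crossprod(M) + alpha * diag(ncol(M)),
                 crossprod(M, fx$sv))
  relerr <- sqrt(sum((as.vector(pixels(rec)) - dense)^2)) /
    sqrt(sum(dense^2))
  expect_lt(relerr, 1e-6)
})

test_that("solution norm shrinks monotonically over an alpha sweep", {
  fx <- reconFixture()
  alphas <- 10^seq(-6, 0, by = 1)
  nrm <- vapply(alphas, function(a) {
    r <- reconstruct(fx$s, fx$mdl,
                     reconConfig(alpha = a, maxIterations = 400L))
    sqrt(sum(pixels(r)^2))
  }, numeric(1))
  expect_true(all(diff(nrm) <= 1e-9 * nrm[-length(nrm)]))
})

test_that("non-negativity holds and the constrained objective dominates", {
  fx <- reconFixture()
  for (a in c(1e-3, 1e-1)) {
    rc <- reconstruct(fx$s, fx$mdl,
                      reconConfig(alpha = a, maxIterations = 1500L,
                                  tolerance = 1e-13))
    ru <- reconstruct(fx$s, fx$mdl,
                      reconConfig(alpha = a, maxIterations = 1500L,
                                  tolerance = 1e-13, nonneg = FALSE))
    expect_gte(min(pixels(rc)), 0)
    ae <- provenance(rc)$alphaEffective
    obj <- function(r) {
      rr <- as.numeric(fx$mdl@matrix %*% as.vector(pixels(r))) - fx$sv
      sum(rr^2) + ae * sum(pixels(r)^2)
    }
    # minimizing over the non-negative cone cannot beat the global minimum
    expect_gte(obj(rc) + 1e-9 * obj(ru), obj(ru))
  }
})

test_that("noiseless simulate-then-invert recovers the phantom", {
  g <- deskGeometry(nElements = 16L, gridShape = c(31L, 31L))
  mdl <- assembleForwardModel(g)
  ph <- vesselGridPhantom(g, nVessels = 4L, seed = 5L)
  p0 <- pressureMap(ph, 800)
  s <- applyModel(mdl, p0)
  rec <- reconstruct(s, mdl, reconConfig(alpha = 1e-6,
                                         maxIterations = 300L))
  expect_gte(cor(as.vector(pixels(rec)), as.vector(p0)), 0.90)
})

test_that("non-finite signals are rejected; iteration cap warns", {
  fx <- reconFixture()
  bad <- signalFrame(matrix(NaN, fx$g@nElements, fx$g@nSamples),
                     fx$g@samplingRate)
  expect_error(reconstruct(bad, fx$mdl), "finite")
  expect_warning(
    reconstruct(fx$s, fx$mdl,
                reconConfig(alpha = 1e-6, maxIterations = 12L,
                            tolerance = 1e-16)),
    "iteration cap")
})

test_that("L-curve selection: single candidate, rejection, and corner", {
  fx <- reconFixture()
  expect_equal(selectAlphaLcurve(fx$s, fx$mdl, 0.01)$alpha, 0.01)
  expect_error(selectAlphaLcurve(fx$s, fx$mdl, c(0.01, 0.1)), "at least 3")
  expect_error(selectAlphaLcurve(fx$s, fx$mdl, c(0.1, 0.01, 1)),
               "increasing")
  # degenerate curve: zero signals make every candidate solve to zero
  z <- signalFrame(matrix(0, fx$g@nElements, fx$g@nSamples),
                   fx$g@samplingRate)
  expect_error(selectAlphaLcurve(z, fx$mdl, 10^seq(-4, 0)), "degenerate")
})

test_that("L-curve picks near the error-optimal alpha on a noisy problem", {
  g <- deskGeometry()
  mdl <- assembleForwardModel(g)
  ph <- vesselGridPhantom(g, nVessels = 4L, seed = 5L)
  p0 <- pressureMap(ph, 800)
  s0 <- applyModel(mdl, p0)
  noisy <- injectSignalNoise(
    s0, noiseSpec(whiteSigma = 0.05 * max(abs(signalData(s0)))), seed = 11L)
  alphas <- 10^seq(-6, 0, by = 0.5)
  cfg <- reconConfig(maxIterations = 300L)
  sel <- selectAlphaLcurve(noisy, mdl, alphas, cfg)
  errs <- vapply(alphas, function(a) {
    cfg@alpha <- a
    sqrt(sum((pixels(reconstruct(noisy, mdl, cfg)) - p0)^2))
  }, numeric(1))
  iSel <- match(sel$alpha, alphas)
  iBest <- which.min(errs)
  expect_lte(abs(iSel - iBest), 1L)
})

test_that("L-curve selection is invariant to joint model/signal rescaling", {
  fx <- reconFixture()
  noisy <- injectSignalNoise(
    fx$s, noiseSpec(whiteSigma = 0.05 * max(abs(signalData(fx$s)))),
    seed = 3L)
  alphas <- 10^seq(-5, -1, by = 1)
  cfg <- reconConfig(maxIterations = 200L)
  sel1 <- selectAlphaLcurve(noisy, fx$mdl, alphas, cfg)
  mdl2 <- fx$mdl
  mdl2@matrix <- fx$mdl@matrix * 3.7
  noisy2 <- signalFrame(signalData(noisy) * 3.7, noisy@samplingRate)
  sel2 <- selectAlphaLcurve(noisy2, mdl2, alphas, cfg)
  expect_equal(sel1$alpha, sel2$alpha)
})
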