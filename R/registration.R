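#' Elastic (deformable) image registration
#'
#' Iteratively optimizes a smooth dense displacement field that maximizes a
#' locally-normalized cross-correlation similarity (square window of radius
#' \code{windowRadius}) between the warped moving image and the fixed
#' image, in the spirit of neighborhood cross-correlation driven
#' demons-type registration. To handle larger displacements the
#' optimization runs sequentially on quarter-, half- and full-resolution
#' images, each level initializing the next. The procedure uses no
#' randomness: identical inputs give identical fields.
#'
#' @param moving,fixed numeric matrices or [ReconImage-class] of equal shape;
#'   \code{fixed} must not be constant.
#' @param windowRadius radius of the local correlation window, px (default 4).
#' @param smoothingSigma Gaussian smoothing of the field per iteration, px
#'   (default 2).
#' @param iterations iterations per resolution level (default 50).
#' @param stepSize maximum field update per iteration, px (default 1).
#' @param levels integer downsampling factors, coarse to fine
#'   (default \code{c(4, 2, 1)}).
#' @return a [DisplacementField-class] \code{d} such that
#'   \code{warpImage(moving, d)} is aligned to \code{fixed}.
#' @export
registerElastic <- function(moving, fixed, windowRadius = 4L,
                            smoothingSigma = 2, iterations = 50L,
                            stepSize = 1, levels = c(4L, 2L, 1L)) {
  mv <- if (is(moving, "ReconImage")) moving@pixels else moving
  fx <- if (is(fixed, "ReconImage")) fixed@pixels else fixed
  if (!all(dim(mv) == dim(fx))) stop("moving and fixed must share a shape")
  if (max(fx) == min(fx))
    stop("fixed image is constant: local correlation is undefined")
  nr <- nrow(fx); nc <- ncol(fx)
  dx <- dy <- NULL
  for (fac in levels) {
    nrL <- max(8L, ceiling(nr / fac)); ncL <- max(8L, ceiling(nc / fac))
    fxL <- .resizeBilinear(.gaussianBlur(fx, max(0, (fac - 1) / 2)), nrL, ncL)
    mvL <- .resizeBilinear(.gaussianBlur(mv, max(0, (fac - 1) / 2)), nrL, ncL)
    if (is.null(dx)) {
      dx <- matrix(0, nrL, ncL); dy <- matrix(0, nrL, ncL)
    } else {
      sr <- (nrL - 1) / (nrow(dx) - 1); sc <- (ncL - 1) / (ncol(dx) - 1)
      dx <- .resizeBilinear(dx, nrL, ncL) * sc
      dy <- .resizeBilinear(dy, nrL, ncL) * sr
    }
    upd <- .ccDemonsLevel(mvL, fxL, dx, dy, windowRadius, smoothingSigma,
                          iterations, stepSize)
    dx <- upd$dx; dy <- upd$dy
  }
  displacementField(dx, dy, smoothingSigma)
}

# one resolution level of the local-correlation driven field optimization
.ccDemonsLevel <- function(mv, fx, dx, dy, r, sigma, iterations, stepSize) {
  nr <- nrow(fx); nc <- ncol(fx)
  cnt <- .boxCount(nr, nc, r)
  fxMean <- .boxSum(fx, r) / cnt
  F <- fx - fxMean
  Bsum <- .boxSum(F * F, r)
  eps <- 1e-12 * max(1, max(abs(fx))^2)
  for (it in seq_len(iterations)) {
    w <- .warpBilinear(mv, dx, dy)
    Mc <- w - .boxSum(w, r) / cnt
    A <- .boxSum(F * Mc, r)
    C <- .boxSum(Mc * Mc, r)
    ok <- (Bsum > eps) & (C > eps)
    coef <- matrix(0, nr, nc)
    coef[ok] <- 2 * A[ok] / (Bsum[ok] * C[ok]) * (F[ok] - (A[ok] / C[ok]) * Mc[ok])
    # intensity gradient of the warped moving image (central differences)
    gx <- cbind(w[, 2] - w[, 1], (w[, -(1:2), drop = FALSE] - w[, 1:(nc - 2), drop = FALSE]) / 2,
                w[, nc] - w[, nc - 1])
    gy <- rbind(w[2, ] - w[1, ], (w[-(1:2), , drop = FALSE] - w[1:(nr - 2), , drop = FALSE]) / 2,
                w[nr, ] - w[nr - 1, ])
    fxF <- coef * gx
    fyF <- coef * gy
    # fluid-like smoothing of the update, then step-size normalization
    fxF <- .gaussianBlur(fxF, 1)
    fyF <- .gaussianBlur(fyF, 1)
    mag <- sqrt(fxF^2 + fyF^2)
    mmax <- max(mag)
    if (mmax < 1e-10) break
    sc <- stepSize / mmax
    dx <- dx + sc * fxF
    dy <- dy + sc * fyF
    # elastic regularization of the total field
    dx <- .gaussianBlur(dx, sigma)
    dy <- .gaussianBlur(dy, sigma)
  }
  list(dx = dx, dy = dy)
}
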