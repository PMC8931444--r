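#' Construct a 2-D affine transform
#'
#' @param matrix numeric 2x3 \code{[A | t]} acting on centre-origin
#'   (col, row) pixel coordinates; defaults to the identity.
#' @return an [AffineTransform2D-class].
#' @export
affineTransform2D <- function(matrix = cbind(diag(2), c(0, 0))) {
  new("AffineTransform2D", matrix = matrix)
}

#' @rdname affineTransform2D
#' @param angle rotation in degrees.
#' @param scale isotropic scale factor.
#' @param shift numeric length-2 translation (x, y), pixels.
#' @export
affineFromParams <- function(angle = 0, scale = 1, shift = c(0, 0)) {
  th <- angle * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  affineTransform2D(cbind(A, shift))
}

# pull-back displacement field of an affine in centre-origin coordinates
.affineField <- function(affine, nr, nc) {
  A <- affine@matrix[, 1:2]
  t <- affine@matrix[, 3]
  cc0 <- (nc + 1) / 2; rr0 <- (nr + 1) / 2
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc0
  y <- matrix(seq_len(nr), nr, nc) - rr0
  sx <- A[1, 1] * x + A[1, 2] * y + t[1]
  sy <- A[2, 1] * x + A[2, 2] * y + t[2]
  list(dx = sx - x, dy = sy - y)
}

#' Warp an image by an affine transform
#'
#' Pull-back resampling with bilinear interpolation and replicated
#' borders; the identity transform returns the input unchanged.
#'
#' @param image numeric matrix, [ReconImage-class] or [USImage-class].
#' @param affine an [AffineTransform2D-class] (must be invertible).
#' @return same type as \code{image}.
#' @export
warpAffine <- function(image, affine) {
  validObject(affine)
  m <- if (is(image, "ReconImage") || is(image, "USImage")) image@pixels else image
  f <- .affineField(affine, nrow(m), ncol(m))
  out <- .warpBilinear(m, f$dx, f$dy)
  if (is(image, "ReconImage") || is(image, "USImage")) {
    image@pixels <- out
    image
  } else out
}

#' @rdname warpAffine
#' @param us a [USImage-class].
#' @export
warpUS <- function(us, affine) {
  stopifnot(is(us, "USImage"))
  out <- warpAffine(us, affine)
  out@pixels <- pmax(out@pixels, 0)
  out
}

# global normalized cross-correlation of two equally shaped matrices
.ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(0)
  sum(a * b) / den
}

#' Estimate the affine between two reconstructions
#'
#' Finds the affine transform that maps \code{oaSingle} (uniform
#' speed-of-sound reconstruction) onto \code{oaDual} (two-medium
#' reconstruction) by maximizing normalized cross-correlation with a
#' deterministic multi-resolution simplex search initialized at the
#' identity. The returned transform is the one to apply (via
#' [warpUS()]/[warpAffine()]) to images living in the single-SoS frame,
#' e.g. scanner ultrasound, to bring them into the dual-SoS frame.
#' If the search cannot improve on the identity, the identity is returned
#' with a warning.
#'
#' @param oaDual,oaSingle numeric matrices or [ReconImage-class], equal
#'   shape, both non-constant.
#' @param levels multi-resolution factors, coarse to fine (default c(4, 2, 1)).
#' @param maxit simplex iterations per level (default 400).
#' @return an [AffineTransform2D-class].
#' @export
estimateAffine <- function(oaDual, oaSingle, levels = c(4L, 2L, 1L),
                           maxit = 400L) {
  fx <- if (is(oaDual, "ReconImage")) oaDual@pixels else oaDual
  mv <- if (is(oaSingle, "ReconImage")) oaSingle@pixels else oaSingle
  if (!all(dim(fx) == dim(mv))) stop("images must share a shape")
  if (max(fx) == min(fx) || max(mv) == min(mv))
    stop("constant image: affine similarity is undefined")
  par <- c(1, 0, 0, 1, 0, 0)   # a11 a12 a21 a22 tx ty
  for (fac in levels) {
    nrL <- max(12L, ceiling(nrow(fx) / fac))
    ncL <- max(12L, ceiling(ncol(fx) / fac))
    fxL <- .resizeBilinear(.gaussianBlur(fx, max(0, (fac - 1) / 2)), nrL, ncL)
    mvL <- .resizeBilinear(.gaussianBlur(mv, max(0, (fac - 1) / 2)), nrL, ncL)
    scaleT <- ncol(fxL) / ncol(fx)   # translation in level pixels
    obj <- function(p) {
      aff <- affineTransform2D(matrix(c(p[1], p[3], p[2], p[4],
                                        p[5], p[6]), 2, 3))
      if (abs(det(aff@matrix[, 1:2])) < 1e-6) return(1)
      -.ncc(.warpBilinear(mvL, .affineField(aff, nrL, ncL)$dx,
                          .affineField(aff, nrL, ncL)$dy), fxL)
    }
    p0 <- par
    p0[5:6] <- p0[5:6] * scaleT
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10,
                                       parscale = c(0.05, 0.05, 0.05, 0.05,
                                                    1, 1)))
    par <- fit$par
    par[5:6] <- par[5:6] / scaleT
  }
  aff <- affineTransform2D(matrix(c(par[1], par[3], par[2], par[4],
                                    par[5], par[6]), 2, 3))
  nccId <- .ncc(mv, fx)
  nccFit <- .ncc(warpAffine(mv, aff), fx)
  if (nccFit < nccId - 1e-12) {
    warning("affine search did not improve on the identity; returning identity")
    return(affineTransform2D())
  }
  aff
}

#' Construct a USImage
#'
#' @param pixels non-negative numeric matrix of echo intensity.
#' @param timestamp acquisition time, seconds.
#' @return a [USImage-class].
#' @export
usImage <- function(pixels, timestamp = 0) {
  new("USImage", pixels = pixels, timestamp = timestamp)
}

#' Average ultrasound frames concurrent with an optoacoustic frame
#'
#' Selects the frames whose timestamps fall inside the closed interval
#' \code{window} (the acquisition span of one multispectral optoacoustic
#' frame, typically 1.1 s) and returns their arithmetic mean.
#'
#' @param usSequence list of [USImage-class].
#' @param window numeric length-2, closed time interval in seconds.
#' @return a [USImage-class] timestamped at the window midpoint.
#' @export
averageConcurrentUS <- function(usSequence, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  ts <- vapply(usSequence, function(u) u@timestamp, numeric(1))
  sel <- which(ts >= window[1] & ts <= window[2])
  if (!length(sel))
    stop(sprintf("no US frame inside the window [%g, %g] s",
                 window[1], window[2]))
  acc <- Reduce(`+`, lapply(usSequence[sel], function(u) u@pixels))
  usImage(acc / length(sel), timestamp = mean(window))
}
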