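# Shared dense image primitives: bilinear resampling with border
# replication, separable Gaussian smoothing, summed-area-table box sums,
# and pyramid resizing. These back both the elastic registration and the
# visualization transforms, so all modules share one interpolation
# convention (pull-back sampling, replicated borders).

# sample img at (rows + dy, cols + dx), bilinear, replicated borders
.warpBilinear <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- matrix(seq_len(nr), nr, nc) + dy
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + dx
  rr <- pmin(pmax(rr, 1), nr)
  cc <- pmin(pmax(cc, 1), nc)
  r0 <- floor(rr); c0 <- floor(cc)
  r0 <- pmin(r0, nr - 1L); c0 <- pmin(c0, nc - 1L)
  if (nr == 1L) r0[] <- 1L
  if (nc == 1L) c0[] <- 1L
  fr <- rr - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  i00 <- cbind(as.vector(r0), as.vector(c0))
  i01 <- cbind(as.vector(r0), as.vector(c1))
  i10 <- cbind(as.vector(r1), as.vector(c0))
  i11 <- cbind(as.vector(r1), as.vector(c1))
  v <- (1 - fr) * (1 - fc) * img[i00] + (1 - fr) * fc * img[i01] +
    fr * (1 - fc) * img[i10] + fr * fc * img[i11]
  matrix(v, nr, nc)
}

# 1-D Gaussian kernel, unit sum
.gaussKernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicated borders
.gaussianBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- .gaussKernel(sigma)
  half <- (length(k) - 1L) / 2L
  nr <- nrow(img); nc <- ncol(img)
  padIdx <- function(n) pmin(pmax(seq_len(n + 2L * half) - half, 1L), n)
  # along rows (vertical)
  p <- img[padIdx(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (m in seq_along(k))
    out <- out + k[m] * p[(m - 1L) + seq_len(nr), , drop = FALSE]
  # along cols (horizontal)
  p <- out[, padIdx(nc), drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (m in seq_along(k))
    out2 <- out2 + k[m] * p[, (m - 1L) + seq_len(nc), drop = FALSE]
  out2
}

# summed-area table with a zero top row / left column
.sat <- function(m) {
  s <- rbind(0, apply(m, 2, cumsum))
  cbind(0, t(apply(s, 1, cumsum)))
}

# per-pixel sum over the border-clipped square window of radius r
.boxSum <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  S <- .sat(img)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- pmax(rows - r, 1L); r2 <- pmin(rows + r, nr)
  c1 <- pmax(cols - r, 1L); c2 <- pmin(cols + r, nc)
  # S is (nr+1) x (nc+1); window sum = S[r2+1,c2+1]-S[r1,c2+1]-S[r2+1,c1]+S[r1,c1]
  A <- S[r2 + 1L, , drop = FALSE][, c2 + 1L, drop = FALSE]
  B <- S[r1, , drop = FALSE][, c2 + 1L, drop = FALSE]
  C <- S[r2 + 1L, , drop = FALSE][, c1, drop = FALSE]
  D <- S[r1, , drop = FALSE][, c1, drop = FALSE]
  A - B - C + D
}

# per-pixel count of pixels in the clipped window (same clipping as .boxSum)
.boxCount <- function(nr, nc, r) {
  rows <- pmin(seq_len(nr) + r, nr) - pmax(seq_len(nr) - r, 1L) + 1L
  cols <- pmin(seq_len(nc) + r, nc) - pmax(seq_len(nc) - r, 1L) + 1L
  outer(rows, cols)
}

# bilinear resize (corner-aligned), used for pyramid up/down sampling
.resizeBilinear <- function(img, nrOut, ncOut) {
  nr <- nrow(img); nc <- ncol(img)
  rSrc <- if (nrOut == 1L) rep(1, 1) else (seq_len(nrOut) - 1) * (nr - 1) / (nrOut - 1) + 1
  cSrc <- if (ncOut == 1L) rep(1, 1) else (seq_len(ncOut) - 1) * (nc - 1) / (ncOut - 1) + 1
  # sample img at the corner-aligned source grid rSrc x cSrc
  rr <- matrix(rSrc, nrOut, ncOut)
  cc <- matrix(cSrc, nrOut, ncOut, byrow = TRUE)
  r0 <- pmin(floor(rr), nr - 1L); if (nr == 1L) r0[] <- 1L
  c0 <- pmin(floor(cc), nc - 1L); if (nc == 1L) c0[] <- 1L
  fr <- rr - r0; fc <- cc - c0
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  v <- (1 - fr) * (1 - fc) * img[cbind(as.vector(r0), as.vector(c0))] +
    (1 - fr) * fc * img[cbind(as.vector(r0), as.vector(c1))] +
    fr * (1 - fc) * img[cbind(as.vector(r1), as.vector(c0))] +
    fr * fc * img[cbind(as.vector(r1), as.vector(c1))]
  matrix(v, nrOut, ncOut)
}

# smoothed 2x downsampling for the registration pyramid
.pyrDown <- function(img) {
  s <- .gaussianBlur(img, 1)
  .resizeBilinear(s, max(2L, ceiling(nrow(img) / 2)), max(2L, ceiling(ncol(img) / 2)))
}

#' Construct a DisplacementField
#'
#' @param dx,dy numeric matrices of lateral (column) and depth (row)
#'   displacements, pixels.
#' @param smoothnessScale Gaussian smoothing scale associated with the
#'   field, pixels.
#' @return a [DisplacementField-class].
#' @export
displacementField <- function(dx, dy, smoothnessScale = 0) {
  new("DisplacementField", dx = dx, dy = dy,
      smoothnessScale = smoothnessScale)
}

#' Warp an image by a displacement field
#'
#' Pull-back warping: the output at pixel \code{x} samples the input at
#' \code{x + d(x)} with bilinear interpolation and replicated borders. A
#' zero field returns the input exactly.
#'
#' @param image numeric matrix or [ReconImage-class].
#' @param field a [DisplacementField-class] of the same shape.
#' @return same type as \code{image}.
#' @export
warpImage <- function(image, field) {
  m <- if (is(image, "ReconImage")) image@pixels else image
  if (!all(dim(m) == dim(field@dx)))
    stop("field shape must match image shape")
  out <- .warpBilinear(m, field@dx, field@dy)
  if (is(image, "ReconImage")) {
    image@pixels <- out
    image
  } else out
}

#' Compose two displacement fields
#'
#' Returns the field of "warp by \code{first}, then by \code{second}":
#' \code{d(x) = d2(x) + d1(x + d2(x))}, evaluated by resampling
#' \code{first} with bilinear interpolation.
#'
#' @param second,first [DisplacementField-class] objects of equal shape.
#' @return a [DisplacementField-class].
#' @export
composeFields <- function(second, first) {
  if (!all(dim(second@dx) == dim(first@dx)))
    stop("fields must share a shape")
  dx <- second@dx + .warpBilinear(first@dx, second@dx, second@dy)
  dy <- second@dy + .warpBilinear(first@dy, second@dx, second@dy)
  displacementField(dx, dy, max(second@smoothnessScale, first@smoothnessScale))
}
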