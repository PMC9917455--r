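#' @keywords internal
"_PACKAGE"

## Images throughout the package are numeric base-R matrices indexed
## [row (y), col (x)], intensities in [0, 1]; pixel coordinates are 0-based
## with the origin at the top-left corner and boxes half-open [x0,x1)x[y0,y1).

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Check that a value is a single finite number
#' @noRd
.check_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (x < lo || x > hi)
    .stopf("'%s' = %g outside allowed range [%g, %g]", name, x, lo, hi)
  invisible(x)
}

## Deterministic seed derivation: combine a base seed with stream labels,
## keeping the result a valid 32-bit integer.
.derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(h)
}

.smoothstep <- function(t) t * t * (3 - 2 * t)

## Lattice hash -> [0,1), deterministic and platform-stable (pure arithmetic).
.hash2 <- function(ix, iy, seed) {
  h <- (ix * 127.1 + iy * 311.7 + seed * 74.7) %% 6283.18530717959
  v <- sin(h) * 43758.5453123
  v - floor(v)
}

#' Band-limited value-noise texture
#'
#' Deterministic smooth pseudo-random field evaluated at arbitrary world
#' coordinates, so that different cameras observing the same scene point see
#' identical texture. Several octaves of lattice value noise with smoothstep
#' interpolation.
#'
#' @param x,y numeric vectors (same length) of coordinates, any real units.
#' @param seed integer controlling the lattice values.
#' @param scale base lattice spacing in the units of `x`/`y`.
#' @param octaves number of octaves (each halves the spacing and amplitude).
#' @return numeric vector in \[0, 1\], same length as `x`.
#' @export
value_noise <- function(x, y, seed = 0L, scale = 1, octaves = 3L) {
  stopifnot(length(x) == length(y), scale > 0, octaves >= 1)
  out <- numeric(length(x))
  amp <- 1
  tot <- 0
  s <- scale
  for (o in seq_len(octaves)) {
    xs <- x / s
    ys <- y / s
    ix <- floor(xs); iy <- floor(ys)
    fx <- .smoothstep(xs - ix); fy <- .smoothstep(ys - iy)
    os <- .derive_seed(seed, o)
    v00 <- .hash2(ix, iy, os);     v10 <- .hash2(ix + 1, iy, os)
    v01 <- .hash2(ix, iy + 1, os); v11 <- .hash2(ix + 1, iy + 1, os)
    v <- (v00 * (1 - fx) + v10 * fx) * (1 - fy) +
         (v01 * (1 - fx) + v11 * fx) * fy
    out <- out + amp * v
    tot <- tot + amp
    amp <- amp / 2
    s <- s / 2
  }
  out / tot
}

## --- separable Gaussian blur via banded convolution matrices ---------------

.gauss_band <- function(n, sigma) {
  # n x n convolution matrix with renormalized truncated Gaussian rows
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in -r:r) {
    ii <- idx + j
    ok <- ii >= 1 & ii <= n
    M[cbind(idx[ok], ii[ok])] <- M[cbind(idx[ok], ii[ok])] + k[j + r + 1]
  }
  M / rowSums(M)
}

#' Gaussian blur of an image matrix
#'
#' Separable Gaussian convolution with edge renormalization (kernel mass
#' falling outside the image is redistributed, so flat fields stay flat).
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; 0 returns the input.
#' @return blurred matrix of the same dimensions.
#' @export
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Ky <- .gauss_band(nrow(img), sigma)
  Kx <- .gauss_band(ncol(img), sigma)
  Ky %*% img %*% t(Kx)
}

## Box mean filter (same edge renormalization), used for adaptive thresholds.
.box_band <- function(n, r) {
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in -r:r) {
    ii <- idx + j
    ok <- ii >= 1 & ii <= n
    M[cbind(idx[ok], ii[ok])] <- M[cbind(idx[ok], ii[ok])] + 1
  }
  M / rowSums(M)
}

.box_mean <- function(img, r) {
  if (r <= 0) return(img)
  .box_band(nrow(img), r) %*% img %*% t(.box_band(ncol(img), r))
}

## Shift a matrix by integer (dy, dx), padding with `fill`.
.shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

## Quantize [0,1] doubles to a bit depth and back (simulates ADC rounding).
.quantize <- function(img, bit_depth = 8L) {
  if (!bit_depth %in% c(8L, 16L)) .stopf("unsupported bit depth %s", bit_depth)
  q <- 2^bit_depth - 1
  round(.clamp(img, 0, 1) * q) / q
}
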