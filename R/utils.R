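# Shared numeric helpers.
#
# Image convention used throughout the package: a grayscale frame is a numeric
# matrix with dim = c(height, width), values in [0, 255]. Pixel coordinates are
# 0-based with x rightward (columns) and y downward (rows); the pixel at
# (x, y) lives at image[y + 1, x + 1] and its center is at the integer
# coordinate itself.

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards so generation never perturbs user simulations.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Bilinear image sampling at sub-pixel coordinates
#'
#' Samples a grayscale image at arbitrary (possibly fractional) 0-based
#' coordinates using bilinear interpolation. Coordinates are clamped to the
#' image border (edge replication).
#'
#' @param img numeric matrix, `dim = c(height, width)`.
#' @param x,y numeric vectors of equal length, 0-based pixel coordinates.
#' @return numeric vector of interpolated intensities.
#' @export
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x1 + 1)]
  i01 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (i00 * (1 - fx) + i10 * fx) * (1 - fy) + (i01 * (1 - fx) + i11 * fx) * fy
}

# 2-D FFT helpers (base stats::fft is already n-dimensional for matrices).
fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Periodic Hann window of length n (raised cosine, used for boundary-effect
# suppression in circulant tracking).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

vnorm <- function(v) sqrt(sum(v^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
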