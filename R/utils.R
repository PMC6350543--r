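# Internal conventions used throughout the package:
#  * images are base-R arrays: H x W matrices (grayscale/masks) or H x W x 3
#    arrays (RGB), values in [0, 1]; row = y, column = x
#  * pixel coordinates are 0-based, x right / y down, pixel centers at integers,
#    so point (x, y) corresponds to matrix element [y + 1, x + 1]
#  * world units are centimetres

#' @import stats
#' @import utils
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Convert an RGB array to grayscale luminance
#'
#' Uses Rec. 601 luma weights on linear channel values.
#'
#' @param img H x W x 3 numeric array in `[0, 1]`.
#' @return H x W numeric matrix.
#' @export
rgb_to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# sRGB -> CIE LAB, vectorized over pixels; returns H x W x 3 array
rgb_to_lab <- function(img) {
  d <- dim(img)
  m <- matrix(img, ncol = 3L)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

# Bilinear sampling of matrix `m` at 0-based points (x, y); outside -> `fill`
bilinear_sample <- function(m, x, y, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  x0c <- pmin(pmax(x0, 0), w - 1); y0c <- pmin(pmax(y0, 0), h - 1)
  x1c <- pmin(x0c + 1, w - 1);     y1c <- pmin(y0c + 1, h - 1)
  idx <- function(xx, yy) yy + 1 + xx * h  # column-major linear index
  v <- (1 - fx) * (1 - fy) * m[idx(x0c, y0c)] +
       fx * (1 - fy) * m[idx(x1c, y0c)] +
       (1 - fx) * fy * m[idx(x0c, y1c)] +
       fx * fy * m[idx(x1c, y1c)]
  v[!ok] <- fill
  v
}

# Nearest-neighbor sampling at 0-based points; outside -> fill
nearest_sample <- function(m, x, y, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  xi <- round(x); yi <- round(y)
  ok <- xi >= 0 & yi >= 0 & xi <= w - 1 & yi <= h - 1
  v <- rep(fill, length(x))
  v[ok] <- m[cbind(yi[ok] + 1, xi[ok] + 1)]
  v
}

# Isotropic Gaussian blur of an H x W matrix (replicated boundary)
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(2L, ceiling(3 * sigma))
  r <- min(r, (min(dim(m)) - 1L) %/% 2L)  # kernel must fit inside the image
  if (r < 1L) return(m)
  out <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma,
                                           radius = 2L * r + 1L,
                                           boundary = "replicate"))
  matrix(out, nrow(m), ncol(m))
}

# Central-difference gradients (replicated edges); returns list(gx, gy)
image_gradients <- function(m) {
  h <- nrow(m); w <- ncol(m)
  xl <- m[, c(1, 1:(w - 1)), drop = FALSE]
  xr <- m[, c(2:w, w), drop = FALSE]
  yu <- m[c(1, 1:(h - 1)), , drop = FALSE]
  yd <- m[c(2:h, h), , drop = FALSE]
  list(gx = (xr - xl) / 2, gy = (yd - yu) / 2)
}

# Even-odd-rule point-in-polygon (0-based pixel coords); poly is n x 2 (x, y)
points_in_polygon <- function(px, py, poly) {
  res <- pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = TRUE)
  as.logical(res)
}

# Seeded value-noise field over a chart rectangle: smooth pseudo-random texture
# with `octaves` octaves of bilinear lattice noise, base cell `scale_cm`.
# Returns a closure (u, v) -> value in [-1, 1].
value_noise_2d <- function(seed, scale_cm = 0.8, octaves = 2L) {
  set.seed(seed)
  lattices <- lapply(seq_len(octaves), function(o) {
    n <- 64L
    matrix(runif(n * n, -1, 1), n, n)
  })
  function(u, v) {
    out <- 0
    amp <- 1; tot <- 0
    for (o in seq_along(lattices)) {
      lat <- lattices[[o]]
      n <- nrow(lat)
      s <- scale_cm / 2^(o - 1)
      gu <- (u / s) %% n; gv <- (v / s) %% n
      i0 <- floor(gu); j0 <- floor(gv)
      fu <- gu - i0; fv <- gv - j0
      # smoothstep for C1 continuity
      fu <- fu * fu * (3 - 2 * fu); fv <- fv * fv * (3 - 2 * fv)
      i1 <- (i0 + 1) %% n; j1 <- (j0 + 1) %% n
      id <- function(i, j) (i %% n) + 1 + (j %% n) * n
      val <- (1 - fu) * (1 - fv) * lat[id(i0, j0)] +
             fu * (1 - fv) * lat[id(i1, j0)] +
             (1 - fu) * fv * lat[id(i0, j1)] +
             fu * fv * lat[id(i1, j1)]
      out <- out + amp * val
      tot <- tot + amp
      amp <- amp / 2
    }
    out / tot
  }
}

# Shoelace area of a polygon given as n x 2 matrix (any units)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, 1:(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
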