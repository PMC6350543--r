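# Shared fixtures, built once per test run, and small independent oracles.

# standard flat phantom (14.137 cm^2 ellipse) with its ruler detection
fix_flat <- local({
  spec <- phantom_scene_spec(shape = phantom_shape("ellipse", area_cm2 = 14.137))
  r <- render_flat_phantom(spec)
  det <- detect_ruler(r$image)
  list(spec = spec, image = r$image, truth = r$truth, det = det,
       px_per_cm = 1050 / 30)
})

# high-curvature cylinder variant of the same scene
fix_cyl <- local({
  spec <- phantom_scene_spec(support = list(type = "cylinder", radius_cm = 8.5),
                             shape = phantom_shape("ellipse", area_cm2 = 14.137))
  r <- render_cylinder_phantom(spec)
  list(spec = spec, image = r$image, truth = r$truth)
})

# brute-force Otsu threshold: exhaustive between-class variance maximization
oracle_otsu <- function(x, levels = 256) {
  h <- tabulate(pmin(floor(x * levels) + 1L, levels), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  best_t <- NA; best_v <- -Inf
  for (k in seq_len(levels - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best_v) { best_v <- v; best_t <- mids[k] + 0.5 / levels }
  }
  best_t
}

# even-odd-rule point-in-polygon, written independently of the package path
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py)
    slope_ok <- px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi
    inside <- xor(inside, cross & slope_ok)
    j <- i
  }
  inside
}

# closed-form eigenvalues of a symmetric 2x2 matrix via the quadratic formula
oracle_eigen2 <- function(a, b, c) {
  tr <- a + c; d <- sqrt(pmax((a - c)^2 + 4 * b^2, 0))
  c((tr + d) / 2, (tr - d) / 2)
}

# plain 8x8 linear-system homography solve (h33 fixed to 1)
oracle_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

rotate_image_90 <- function(img) {
  # 90 degrees clockwise: (x, y) -> (h - 1 - y, x)
  if (length(dim(img)) == 3L) {
    out <- array(0, dim = c(dim(img)[2], dim(img)[1], dim(img)[3]))
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- t(img[nrow(img):1, , ch])
    out
  } else t(img[nrow(img):1, ])
}
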