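#' Structure tensor eigen-maps of a grayscale image
#'
#' Computes the per-pixel 2x2 structure tensor (Gaussian-windowed outer
#' products of the smoothed image gradient) and its eigen-decomposition.
#' One large eigenvalue marks an edge, two large eigenvalues mark a corner;
#' both criteria drive the checkerboard ruler detection.
#'
#' @param gray H x W numeric matrix.
#' @param gradient_sigma Gaussian scale for the derivative (px).
#' @param window_sigma Gaussian scale of the tensor window (px); should stay
#'   well below the checker square size so neighboring corners stay separated.
#' @return A `tensor_maps` object: matrices `l1` >= `l2` >= 0 and `orientation`
#'   (radians, direction of the dominant eigenvector).
#' @export
structure_tensor_maps <- function(gray, gradient_sigma = 1, window_sigma = 3) {
  if (length(dim(gray)) != 2L) stopf("structure_tensor_maps expects a single-channel image")
  sm <- gauss_blur(gray, gradient_sigma)
  g <- image_gradients(sm)
  j11 <- gauss_blur(g$gx * g$gx, window_sigma)
  j22 <- gauss_blur(g$gy * g$gy, window_sigma)
  j12 <- gauss_blur(g$gx * g$gy, window_sigma)
  tr <- j11 + j22
  dd <- sqrt(pmax((j11 - j22)^2 + 4 * j12^2, 0))
  l1 <- (tr + dd) / 2
  l2 <- pmax((tr - dd) / 2, 0)
  ang <- 0.5 * atan2(2 * j12, j11 - j22)
  structure(list(l1 = l1, l2 = l2, orientation = ang,
                 gradient_sigma = gradient_sigma, window_sigma = window_sigma,
                 smoothed = sm),
            class = "tensor_maps")
}

#' Detect corner candidates from structure tensor maps
#'
#' Local maxima of the smaller eigenvalue above `quality * max(l2)`,
#' non-maximum suppressed at `min_separation`, refined to sub-pixel accuracy
#' by a quadratic fit.
#'
#' @param maps a [structure_tensor_maps()] result.
#' @param quality relative response threshold in (0, 1).
#' @param min_separation minimum distance between reported corners (px).
#' @return A `corner_set` data frame with 0-based columns `x`, `y`, `response`
#'   and a logical `is_checkerboard` column (all `NA` until classified).
#' @export
detect_corners <- function(maps, quality = 0.15, min_separation = 6) {
  l2 <- maps$l2
  h <- nrow(l2); w <- ncol(l2)
  mx <- max(l2)
  if (mx <= 1e-12) return(empty_corner_set())  # flat image: numerical dust only
  thr <- quality * mx
  # strict 8-neighbor local maxima (interior pixels only)
  ii <- 2:(h - 1); jj <- 2:(w - 1)
  c0 <- l2[ii, jj]
  ismax <- c0 >= thr &
    c0 >= l2[ii - 1, jj] & c0 >= l2[ii + 1, jj] &
    c0 >= l2[ii, jj - 1] & c0 >= l2[ii, jj + 1] &
    c0 >= l2[ii - 1, jj - 1] & c0 >= l2[ii - 1, jj + 1] &
    c0 >= l2[ii + 1, jj - 1] & c0 > l2[ii + 1, jj + 1]
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_corner_set())
  ry <- idx[, 1] + 1L; rx <- idx[, 2] + 1L   # matrix indices
  resp <- l2[cbind(ry, rx)]
  ord <- order(resp, decreasing = TRUE)
  ry <- ry[ord]; rx <- rx[ord]; resp <- resp[ord]
  keep <- logical(length(ry))
  accx <- numeric(0); accy <- numeric(0)
  for (k in seq_along(ry)) {
    if (!length(accx) || min((accx - rx[k])^2 + (accy - ry[k])^2) >= min_separation^2) {
      keep[k] <- TRUE; accx <- c(accx, rx[k]); accy <- c(accy, ry[k])
    }
  }
  ry <- ry[keep]; rx <- rx[keep]; resp <- resp[keep]
  # sub-pixel refinement: a checkerboard corner is a saddle point of the
  # smoothed intensity (locally g ~ k (x - x0)(y - y0)); fit a quadric in a
  # small window and move to its stationary point when it is a saddle
  px <- rx - 1; py <- ry - 1  # 0-based
  sm <- maps$smoothed
  if (!is.null(sm)) {
    rad <- 3L
    off <- expand.grid(ox = -rad:rad, oy = -rad:rad)
    A <- cbind(1, off$ox, off$oy, off$ox^2, off$ox * off$oy, off$oy^2)
    Pinv <- solve(crossprod(A), t(A))  # 6 x m
    for (it in 1:2) {
      cx <- round(px); cy <- round(py)
      V <- matrix(NA_real_, length(px), nrow(off))
      for (k in seq_len(nrow(off)))
        V[, k] <- bilinear_sample(sm, cx + off$ox[k], cy + off$oy[k], fill = NA)
      cf <- V %*% t(Pinv)  # n x 6: (a, b, c, d, e, f)
      det2 <- 4 * cf[, 4] * cf[, 6] - cf[, 5]^2
      ok <- !is.na(det2) & det2 < -1e-12 & stats::complete.cases(V)
      dx <- dy <- rep(NA_real_, length(px))
      dx[ok] <- (-2 * cf[ok, 6] * cf[ok, 2] + cf[ok, 5] * cf[ok, 3]) / det2[ok]
      dy[ok] <- (cf[ok, 5] * cf[ok, 2] - 2 * cf[ok, 4] * cf[ok, 3]) / det2[ok]
      ok <- ok & !is.na(dx) & abs(dx) <= 2 & abs(dy) <= 2
      px[ok] <- cx[ok] + dx[ok]; py[ok] <- cy[ok] + dy[ok]
    }
    px <- clamp(px, rx - 1 - rad, rx - 1 + rad)
    py <- clamp(py, ry - 1 - rad, ry - 1 + rad)
  }
  out <- data.frame(x = px, y = py, response = resp,
                    is_checkerboard = NA)
  class(out) <- c("corner_set", "data.frame")
  out
}

empty_corner_set <- function() {
  out <- data.frame(x = numeric(0), y = numeric(0), response = numeric(0),
                    is_checkerboard = logical(0))
  class(out) <- c("corner_set", "data.frame")
  out
}

# median nearest-neighbor distance within a point set (px)
corner_spacing <- function(pts) {
  if (nrow(pts) < 2L) return(NA_real_)
  nn <- RANN::nn2(pts, pts, k = 2L)
  stats::median(nn$nn.dists[, 2])
}

#' Classify corners as checkerboard corners
#'
#' Places an axis-aligned square window at each corner and compares the mean
#' intensities of small patches at the four window corners diagonally: a
#' checkerboard corner has two dark quadrants on one diagonal and two light
#' quadrants on the other, so each diagonal pair is internally similar while
#' the two pairs differ strongly.
#'
#' @param image RGB array or grayscale matrix.
#' @param corners a `corner_set`.
#' @param window_px full window edge length; default 0.6 x the median corner
#'   spacing.
#' @param similar_frac,different_frac thresholds as fractions of the image
#'   intensity range: diagonal mates must agree within `similar_frac`, the two
#'   diagonals must differ by more than `different_frac`.
#' @return The `corner_set` with `is_checkerboard` filled in; corners whose
#'   window leaves the image are dropped.
#' @export
classify_checkerboard_corners <- function(image, corners, window_px = NULL,
                                          similar_frac = 0.15,
                                          different_frac = 0.25) {
  gray <- rgb_to_gray(image)
  if (nrow(corners) == 0L) return(corners)
  if (is.null(window_px)) {
    sp <- corner_spacing(cbind(corners$x, corners$y))
    window_px <- max(4, 0.6 * sp)
  }
  h <- window_px / 2
  rng <- diff(range(gray))
  if (rng <= 0) { corners$is_checkerboard <- FALSE; return(corners) }
  # 3x3 sample cloud around each window corner for robust patch means
  offs <- expand.grid(ox = -1:1, oy = -1:1)
  patch_mean <- function(cx, cy) {
    acc <- 0
    for (k in seq_len(nrow(offs)))
      acc <- acc + bilinear_sample(gray, cx + offs$ox[k], cy + offs$oy[k], fill = NA)
    acc / nrow(offs)
  }
  tl <- patch_mean(corners$x - h, corners$y - h)
  br <- patch_mean(corners$x + h, corners$y + h)
  tr <- patch_mean(corners$x + h, corners$y - h)
  bl <- patch_mean(corners$x - h, corners$y + h)
  ok <- !(is.na(tl) | is.na(br) | is.na(tr) | is.na(bl))
  simA <- abs(tl - br) <= similar_frac * rng
  simB <- abs(tr - bl) <= similar_frac * rng
  diffAB <- abs((tl + br) / 2 - (tr + bl) / 2) >= different_frac * rng
  corners <- corners[ok, , drop = FALSE]
  corners$is_checkerboard <- (simA & simB & diffAB)[ok]
  class(corners) <- c("corner_set", "data.frame")
  corners
}

#' Medial centerline of the ruler from its checkerboard corners
#'
#' Applies the Euclidean distance transform to the corner points; its ridge
#' between the two corner rows traces the ruler midline.  Ridge points (the
#' transverse local maxima of the transform) are fitted with a smoothing
#' spline in the corner set's principal-axis frame.
#'
#' @param corners a `corner_set` (only rows with `is_checkerboard == TRUE` are
#'   used; if none are flagged, all corners are used).
#' @param image_size `c(width, height)` of the source image.
#' @return A `centerline` object: sampled curve points (`x`, `y`, arc length
#'   `s`), the local frame, and an evaluation function.
#' @export
centerline_from_corners <- function(corners, image_size) {
  pts <- corners
  if (any(pts$is_checkerboard %in% TRUE))
    pts <- pts[pts$is_checkerboard %in% TRUE, , drop = FALSE]
  if (nrow(pts) < 4L) stopf("need at least 4 checkerboard corners")
  P <- cbind(pts$x, pts$y)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  # deterministic frame: axis points along its dominant positive direction,
  # perp is the left normal (positive image-y side is "lower")
  if (axis[which.max(abs(axis))] < 0) axis <- -axis
  perp <- c(-axis[2], axis[1])
  if (perp[2] < 0) perp <- -perp
  s <- Pc %*% axis; t <- Pc %*% perp
  if (diff(range(t)) < 2) stopf("ruler rows not separable")
  if (diff(range(s)) < 2) stopf("ruler rows not separable")
  spacing <- corner_spacing(P)

  # distance transform of the corner points on the pixel grid
  h <- image_size[2]; w <- image_size[1]
  m <- matrix(1, h, w)
  m[cbind(clamp(round(P[, 2]), 0, h - 1) + 1, clamp(round(P[, 1]), 0, w - 1) + 1)] <- 0
  dt <- matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(m))), h, w)

  # transverse ridge scan in the principal-axis frame
  band <- range(t) + c(0.25, -0.25) * diff(range(t))
  ss <- seq(min(s) - 0.45 * spacing, max(s) + 0.45 * spacing, by = 1)
  tt <- seq(band[1], band[2], by = 0.5)
  ridge_s <- ridge_t <- rep(NA_real_, length(ss))
  for (i in seq_along(ss)) {
    px <- ctr[1] + ss[i] * axis[1] + tt * perp[1]
    py <- ctr[2] + ss[i] * axis[2] + tt * perp[2]
    prof <- bilinear_sample(dt, px, py, fill = -1)
    k <- which.max(prof)
    if (prof[k] <= 0) next
    toff <- 0
    if (k > 1 && k < length(prof)) {
      den <- prof[k - 1] - 2 * prof[k] + prof[k + 1]
      if (abs(den) > 1e-12) toff <- clamp(0.5 * (prof[k - 1] - prof[k + 1]) / den, -1, 1) * 0.5
    }
    ridge_s[i] <- ss[i]; ridge_t[i] <- tt[k] + toff
  }
  keep <- !is.na(ridge_t)
  if (sum(keep) < 4L) stopf("ruler rows not separable")
  fit <- stats::smooth.spline(ridge_s[keep], ridge_t[keep], spar = 0.5)
  eval_fn <- function(sq) {
    tq <- stats::predict(fit, sq)$y
    cbind(ctr[1] + sq * axis[1] + tq * perp[1],
          ctr[2] + sq * axis[2] + tq * perp[2])
  }
  sq <- seq(min(ridge_s[keep]), max(ridge_s[keep]), by = 0.25)
  xy <- eval_fn(sq)
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  structure(list(x = xy[, 1], y = xy[, 2], s = c(0, cumsum(seg)),
                 s_axis = sq, center = ctr, axis = axis, perp = perp,
                 spacing = spacing, fit = fit, eval = eval_fn),
            class = "centerline")
}

# signed transverse coordinate of points relative to the centerline frame
centerline_tcoord <- function(cl, x, y) {
  sp <- (x - cl$center[1]) * cl$axis[1] + (y - cl$center[2]) * cl$axis[2]
  tq <- stats::predict(cl$fit, sp)$y
  tp <- (x - cl$center[1]) * cl$perp[1] + (y - cl$center[2]) * cl$perp[2]
  tp - tq
}

#' Find checker-edge crossings along the centerline
#'
#' Samples the image intensity along the ruler midline, where it alternates
#' between dark and light squares, and reports the sub-pixel positions where
#' the smoothed profile crosses its mid-level with sufficient contrast -- one
#' crossing per interior checker column edge.
#'
#' @param image RGB array or grayscale matrix.
#' @param centerline a [centerline_from_corners()] result.
#' @param smooth_sigma_px Gaussian smoothing of the 1D profile.
#' @param contrast_frac minimum local contrast as a fraction of the profile
#'   range for a crossing to count.
#' @return Data frame with crossing positions: arc length `s`, point `x`, `y`,
#'   and the local tangent `tx`, `ty`.
#' @export
find_edge_crossings <- function(image, centerline, smooth_sigma_px = 1.5,
                                contrast_frac = 0.25) {
  gray <- rgb_to_gray(image)
  prof <- bilinear_sample(gray, centerline$x, centerline$y, fill = NA)
  prof[is.na(prof)] <- stats::median(prof, na.rm = TRUE)
  step <- mean(diff(centerline$s))
  ns <- max(1, round(smooth_sigma_px / step))
  k <- stats::dnorm(seq(-3 * ns, 3 * ns), sd = ns)
  k <- k / sum(k)
  pr <- stats::filter(c(rep(prof[1], 3 * ns), prof, rep(prof[length(prof)], 3 * ns)),
                      k, sides = 2)
  pr <- as.numeric(pr)[(3 * ns + 1):(3 * ns + length(prof))]
  rng <- range(pr)
  if (diff(rng) < 1e-6) stopf("ruler period not recoverable: constant profile")
  mid <- mean(rng)
  d <- pr - mid
  sgn <- sign(d)
  # a crossing is a sign change between consecutive *nonzero* samples: the
  # profile can sit exactly on the mid-level across an antialiased edge
  # pixel, and such a zero run still separates the two plateaus
  nz <- which(sgn != 0)
  if (length(nz) < 2L) stopf("ruler period not recoverable")
  ch <- which(sgn[nz[-1]] * sgn[nz[-length(nz)]] < 0)
  res <- NULL
  half <- max(2, round(0.3 * centerline$spacing / step))
  for (k in ch) {
    i1 <- nz[k]; i2 <- nz[k + 1]
    lo <- max(1, i1 - half); hi <- min(length(pr), i2 + half)
    if (abs(pr[hi] - pr[lo]) < contrast_frac * diff(rng)) next
    frac <- d[i1] / (d[i1] - d[i2])
    s0 <- centerline$s[i1] + frac * (centerline$s[i2] - centerline$s[i1])
    x0 <- centerline$x[i1] + frac * (centerline$x[i2] - centerline$x[i1])
    y0 <- centerline$y[i1] + frac * (centerline$y[i2] - centerline$y[i1])
    tx <- centerline$x[min(i2 + 2, length(pr))] - centerline$x[max(i1 - 1, 1)]
    ty <- centerline$y[min(i2 + 2, length(pr))] - centerline$y[max(i1 - 1, 1)]
    nt <- sqrt(tx^2 + ty^2)
    res <- rbind(res, c(s0, x0, y0, tx / nt, ty / nt))
  }
  if (is.null(res) || nrow(res) < 2L) stopf("ruler period not recoverable")
  # merge near-duplicate crossings
  res <- res[order(res[, 1]), , drop = FALSE]
  keep <- c(TRUE, diff(res[, 1]) > 2)
  res <- res[keep, , drop = FALSE]
  out <- data.frame(s = res[, 1], x = res[, 2], y = res[, 3],
                    tx = res[, 4], ty = res[, 5])
  out
}

#' Refine a checker edge line by PCA over high-eigenvalue pixels
#'
#' Collects pixels with a large dominant eigenvalue (edge response) within a
#' circular window around a detected crossing and fits a line through them
#' with principal component analysis.
#'
#' @param maps a [structure_tensor_maps()] result.
#' @param crossing numeric `c(x, y)` crossing location.
#' @param radius_px circular window radius; per the detection design it should
#'   be about 0.4 x the smallest distance between corner points.
#' @param response_frac pixels above this fraction of the window's maximum
#'   edge response participate in the fit.
#' @return `list(point, direction)`: a point on the line and a unit direction.
#' @export
refine_edge_line <- function(maps, crossing, radius_px, response_frac = 0.4) {
  l1 <- maps$l1
  h <- nrow(l1); w <- ncol(l1)
  x0 <- round(crossing[1]); y0 <- round(crossing[2])
  r <- ceiling(radius_px)
  xs <- max(0, x0 - r):min(w - 1, x0 + r)
  ys <- max(0, y0 - r):min(h - 1, y0 + r)
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  inside <- (gx - crossing[1])^2 + (gy - crossing[2])^2 <= radius_px^2
  vals <- l1[cbind(as.vector(gy) + 1, as.vector(gx) + 1)]
  inside <- as.vector(inside)
  mxv <- max(vals[inside])
  sel <- inside & vals >= response_frac * mxv
  px <- as.vector(gx)[sel]; py <- as.vector(gy)[sel]; wts <- vals[sel]
  if (length(px) < 5L) stopf("too few edge pixels in window")
  ctr <- c(sum(px * wts), sum(py * wts)) / sum(wts)
  dx <- px - ctr[1]; dy <- py - ctr[2]
  C <- matrix(c(sum(wts * dx * dx), sum(wts * dx * dy),
                sum(wts * dx * dy), sum(wts * dy * dy)), 2, 2) / sum(wts)
  ev <- eigen(C, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  list(point = ctr, direction = dir / sqrt(sum(dir^2)))
}

#' Pair corresponding corners across the ruler
#'
#' For each refined checker-edge line, walks from the centerline crossing in
#' both directions along the line to the nearest checkerboard corner on each
#' corner row, yielding a correspondence pair `(p1, p2)` with `p1` on the
#' upper and `p2` on the lower row and `d = ||p1 - p2||` the local scale.
#'
#' @param edge_lines list of [refine_edge_line()] results, one per crossing.
#' @param corners classified `corner_set`.
#' @param centerline the ruler [centerline_from_corners()].
#' @param crossings the data frame from [find_edge_crossings()] (same order as
#'   `edge_lines`).
#' @return A `correspondence_pairs` data frame ordered along the centerline:
#'   `p1x, p1y, p2x, p2y, d, s`.
#' @export
pair_corresponding_points <- function(edge_lines, corners, centerline,
                                      crossings) {
  if (length(edge_lines) < 2L) stopf("need at least 2 edge lines")
  cb <- corners[corners$is_checkerboard %in% TRUE, , drop = FALSE]
  if (nrow(cb) < 2L) stopf("no checkerboard corners to pair")
  tco <- centerline_tcoord(centerline, cb$x, cb$y)
  spacing <- centerline$spacing
  rows <- NULL
  for (i in seq_along(edge_lines)) {
    el <- edge_lines[[i]]
    if (is.null(el)) next
    p <- el$point; v <- el$direction
    dxc <- cb$x - p[1]; dyc <- cb$y - p[2]
    proj <- dxc * v[1] + dyc * v[2]
    perp <- abs(dxc * v[2] - dyc * v[1])
    cand <- perp <= 0.35 * spacing
    up <- cand & tco < 0
    lo <- cand & tco > 0
    if (!any(up) || !any(lo)) {
      warning("correspondence pair dropped: missing corner on one side")
      next
    }
    score <- abs(proj) + 2 * perp  # nearest along the line; tie-broken by alignment
    iu <- which(up)[which.min(score[up])]
    il <- which(lo)[which.min(score[lo])]
    d <- sqrt((cb$x[iu] - cb$x[il])^2 + (cb$y[iu] - cb$y[il])^2)
    if (d <= 0) next
    rows <- rbind(rows, c(cb$x[iu], cb$y[iu], cb$x[il], cb$y[il], d,
                          crossings$s[i]))
  }
  if (is.null(rows) || nrow(rows) < 2L) stopf("fewer than 2 correspondence pairs found")
  rows <- rows[order(rows[, 6]), , drop = FALSE]
  # drop duplicates (two crossings snapping to the same corner pair)
  dup <- c(FALSE, abs(diff(rows[, 1])) < 1 & abs(diff(rows[, 2])) < 1)
  rows <- rows[!dup, , drop = FALSE]
  out <- data.frame(p1x = rows[, 1], p1y = rows[, 2], p2x = rows[, 3],
                    p2y = rows[, 4], d = rows[, 5], s = rows[, 6])
  class(out) <- c("correspondence_pairs", "data.frame")
  out
}

#' Detect the checkerboard ruler in an image
#'
#' Runs the full detection chain: structure tensor, corner detection and
#' checkerboard classification, distance-transform centerline, edge crossings,
#' PCA edge-line refinement and corner pairing.  A first coarse pass estimates
#' the checker square size in pixels; the tensor window and all geometric
#' tolerances are then set relative to it, which keeps the detector
#' independent of how many squares are visible.
#'
#' @param image RGB array or grayscale matrix.
#' @param quality corner quality threshold passed to [detect_corners()].
#' @param manual_points optional n x 2 matrix of corner positions supplied by
#'   the user (e.g. where a reflection hides a corner); they enter the
#'   pairing as trusted checkerboard corners.
#' @return List with `corners`, `centerline`, `crossings`, `edge_lines`,
#'   `pairs`, and the estimated `square_px`.
#' @export
detect_ruler <- function(image, quality = 0.15, manual_points = NULL) {
  gray <- rgb_to_gray(image)
  size <- c(ncol(gray), nrow(gray))
  # coarse pass: small fixed window to estimate the square size
  maps <- structure_tensor_maps(gray, 1, 3)
  corners <- detect_corners(maps, quality = quality, min_separation = 6)
  corners <- classify_checkerboard_corners(gray, corners)
  cb <- corners[corners$is_checkerboard %in% TRUE, , drop = FALSE]
  if (nrow(cb) < 4L) stopf("ruler not found: too few checkerboard corners")
  sq <- corner_spacing(cbind(cb$x, cb$y))
  # refined pass with scale-adapted window
  maps <- structure_tensor_maps(gray, 1, max(2, sq / 4))
  corners <- detect_corners(maps, quality = quality,
                            min_separation = max(4, 0.5 * sq))
  corners <- classify_checkerboard_corners(gray, corners, window_px = 0.6 * sq)
  if (!is.null(manual_points)) {
    manual_points <- rbind(manual_points)
    add <- data.frame(x = manual_points[, 1], y = manual_points[, 2],
                      response = max(corners$response), is_checkerboard = TRUE)
    corners <- rbind(corners, add)
    class(corners) <- c("corner_set", "data.frame")
  }
  cb <- corners[corners$is_checkerboard %in% TRUE, , drop = FALSE]
  if (nrow(cb) < 4L) stopf("ruler not found: too few checkerboard corners")
  sq <- corner_spacing(cbind(cb$x, cb$y))
  cl <- centerline_from_corners(corners, size)
  cr <- find_edge_crossings(gray, cl)
  lines <- lapply(seq_len(nrow(cr)), function(i) {
    tryCatch(refine_edge_line(maps, c(cr$x[i], cr$y[i]), radius_px = 0.4 * sq),
             error = function(e) { warning(conditionMessage(e)); NULL })
  })
  pairs <- pair_corresponding_points(lines, corners, cl, cr)
  list(corners = corners, centerline = cl, crossings = cr,
       edge_lines = lines, pairs = pairs, square_px = sq)
}
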