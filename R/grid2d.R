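#' Homography from four point correspondences
#'
#' Normalized direct linear transform: points are translated/scaled to mean
#' zero and RMS distance sqrt(2), the 8x9 DLT system is solved by SVD and the
#' normalizations undone.
#'
#' @param src,dst 4 x 2 matrices of corresponding points.
#' @return 3 x 3 homography matrix `H` with `dst ~ H src` (homogeneous).
#' @export
homography_from_points <- function(src, dst) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
    T <- matrix(c(sc, 0, -sc * ctr[1], 0, sc, -sc * ctr[2], 0, 0, 1), 3, 3,
                byrow = TRUE)
    list(T = T, p = cbind(sweep(p, 2, ctr) * sc))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  A <- NULL
  for (i in 1:4) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]; u <- nd$p[i, 1]; v <- nd$p[i, 2]
    A <- rbind(A,
      c(-x, -y, -1, 0, 0, 0, u * x, u * y, u),
      c(0, 0, 0, -x, -y, -1, v * x, v * y, v))
  }
  h <- svd(A, nv = 9)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

quad_is_convex <- function(quad) {
  n <- 4
  cr <- numeric(n)
  for (i in 1:n) {
    a <- quad[i, ]; b <- quad[i %% n + 1, ]; c <- quad[(i + 1) %% n + 1, ]
    cr[i] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }
  all(cr > 0) || all(cr < 0)
}

#' Extrapolate the measurement grid over the wound
#'
#' For each correspondence pair the lattice is continued along the line
#' through `p1` and `p2` by placing further points equidistantly with spacing
#' `d = ||p1 - p2||`, starting from the wound-side corner row and extending
#' until the ROI bounding box is covered.  Consecutive extended columns are
#' joined into quadrilaterals; each quad maps to one physical checker square.
#' Directions and spacings are lightly smoothed across neighboring pairs
#' (moving average of 3) to curb extrapolation drift.
#'
#' @param pairs a `correspondence_pairs` data frame.
#' @param roi ROI polygon (on the wound side of the ruler).
#' @param square_edge_cm physical checker square edge (cm), carried into the
#'   grid for area conversion.
#' @param max_rows cap on the number of extrapolated rows.
#' @param margin_rows extra rows beyond the ROI bounding box.
#' @return A `measurement_grid`: node array `(rows+1) x cols+1 x 2`, quads,
#'   spacing/provenance per column.
#' @export
extrapolate_grid <- function(pairs, roi, square_edge_cm = NULL,
                             max_rows = 50L, margin_rows = 1L) {
  if (nrow(pairs) < 2L) stopf("need at least 2 correspondence pairs")
  v <- roi_vertices(roi)
  ctr <- colMeans(v)
  m <- nrow(pairs)
  p1 <- cbind(pairs$p1x, pairs$p1y)
  p2 <- cbind(pairs$p2x, pairs$p2y)
  d <- pairs$d
  u <- (p2 - p1) / d
  # orient all columns towards the ROI: if its centroid lies on the p1 side,
  # swap the roles of the rows
  proj1 <- rowSums(sweep(-p1, 2, ctr, `+`) * u)
  if (stats::median(proj1) < 0) {
    tmp <- p1; p1 <- p2; p2 <- tmp; u <- -u
  }
  # smooth directions and spacings across pairs (window 3)
  smooth3 <- function(x) {
    if (length(x) < 3L) return(x)
    y <- stats::filter(x, rep(1 / 3, 3), sides = 2)
    y[1] <- mean(x[1:2]); y[length(x)] <- mean(x[(length(x) - 1):length(x)])
    as.numeric(y)
  }
  u[, 1] <- smooth3(u[, 1]); u[, 2] <- smooth3(u[, 2])
  u <- u / sqrt(rowSums(u^2))
  d <- smooth3(d)

  base <- p2  # wound-side corner row
  # rows needed to cover the ROI bbox corners along each column
  bb <- cbind(c(min(v[, 1]), max(v[, 1]), max(v[, 1]), min(v[, 1])),
              c(min(v[, 2]), min(v[, 2]), max(v[, 2]), max(v[, 2])))
  kmax <- 0
  for (j in seq_len(m)) {
    pr <- (sweep(bb, 2, base[j, ]) %*% u[j, ]) / d[j]
    kmax <- max(kmax, pr)
  }
  if (kmax <= 0) stopf("degenerate grid: ROI does not lie on the wound side of the ruler")
  K <- min(max_rows, ceiling(kmax) + margin_rows)

  nodes <- array(NA_real_, dim = c(K + 1, m, 2))
  for (k in 0:K) {
    nodes[k + 1, , 1] <- base[, 1] + k * d * u[, 1]
    nodes[k + 1, , 2] <- base[, 2] + k * d * u[, 2]
  }
  structure(list(nodes = nodes, n_rows = K, n_cols = m - 1L,
                 square_edge_cm = square_edge_cm, d = d,
                 pair_index = seq_len(m)),
            class = "measurement_grid")
}

grid_quad <- function(grid, i, j) {
  # quad for row i (1-based), column j: between columns j, j+1 and rows i, i+1
  rbind(grid$nodes[i, j, ], grid$nodes[i, j + 1, ],
        grid$nodes[i + 1, j + 1, ], grid$nodes[i + 1, j, ])
}

#' Flag degenerate grid configurations
#'
#' Mirrors the two exclusion reasons of the validation protocol: a converging
#' grid (a quad collapsing below 25% of its column's first quad) and wound
#' pixels lying outside the grid footprint.
#'
#' @param grid a [extrapolate_grid()] result.
#' @param wound_mask logical H x W wound mask.
#' @return Character vector of warnings (possibly empty).
#' @export
detect_degenerate_grid <- function(grid, wound_mask) {
  warns <- character(0)
  conv <- FALSE
  for (j in seq_len(grid$n_cols)) {
    a1 <- polygon_area(grid_quad(grid, 1, j))
    for (i in seq_len(grid$n_rows)) {
      if (polygon_area(grid_quad(grid, i, j)) < 0.25 * a1) { conv <- TRUE; break }
    }
    if (conv) break
  }
  if (conv) warns <- c(warns, "converging grid pattern in the wound area")
  own <- grid_owner_raster(grid, dim(wound_mask))
  n_out <- sum(wound_mask > 0 & own == 0L)
  if (n_out > 0)
    warns <- c(warns, sprintf("%d wound pixels outside of the grid", n_out))
  warns
}

# raster assigning each pixel to the nearest containing quad (0 = none);
# avoids double counting where bent-grid quads overlap
grid_owner_raster <- function(grid, dims) {
  h <- dims[1]; w <- dims[2]
  own <- matrix(0L, h, w)
  bestd <- matrix(Inf, h, w)
  q <- 0L
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    q <- q + 1L
    quad <- grid_quad(grid, i, j)
    x0 <- max(0, floor(min(quad[, 1]))); x1 <- min(w - 1, ceiling(max(quad[, 1])))
    y0 <- max(0, floor(min(quad[, 2]))); y1 <- min(h - 1, ceiling(max(quad[, 2])))
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
    inside <- rep(TRUE, length(gx))
    for (e in 1:4) {
      a <- quad[e, ]; b <- quad[e %% 4 + 1, ]
      cr <- (b[1] - a[1]) * (gy - a[2]) - (b[2] - a[2]) * (gx - a[1])
      # accept either orientation by fixing sign from the quad's area sign
      inside <- inside & (cr * quad_orientation(quad) >= 0)
    }
    if (!any(inside)) next
    ctr <- colMeans(quad)
    dd <- (gx - ctr[1])^2 + (gy - ctr[2])^2
    idx <- cbind(gy + 1, gx + 1)[inside, , drop = FALSE]
    dl <- dd[inside]
    closer <- dl < bestd[idx]
    own[idx[closer, , drop = FALSE]] <- q
    bestd[idx[closer, , drop = FALSE]] <- dl[closer]
  }
  own
}

quad_orientation <- function(quad) {
  s <- 0
  for (i in 1:4) {
    a <- quad[i, ]; b <- quad[i %% 4 + 1, ]
    s <- s + a[1] * b[2] - b[1] * a[2]
  }
  sign(s)
}

#' Unwarp one grid quadrilateral to a square patch
#'
#' Maps the four quad corners to the corners of an `out_size` x `out_size`
#' square by homography and samples the mask with nearest-neighbor lookup
#' (counts stay integral).
#'
#' @param mask logical/numeric H x W matrix.
#' @param quad 4 x 2 matrix of quad corners (cyclic order, convex).
#' @param out_size output square edge (px).
#' @return `out_size` x `out_size` binary matrix.
#' @export
unwarp_quadrilateral <- function(mask, quad, out_size) {
  if (!quad_is_convex(quad)) stopf("non-convex quadrilateral")
  # square corners at half-pixel bounds so the out_size^2 integer sample
  # positions are cell midpoints strictly inside the quad (clean tiling
  # quadrature: no sample lies on a shared quad edge)
  sq <- cbind(c(-0.5, out_size - 0.5, out_size - 0.5, -0.5),
              c(-0.5, -0.5, out_size - 0.5, out_size - 0.5))
  H <- homography_from_points(sq, quad)
  g <- expand.grid(x = 0:(out_size - 1), y = 0:(out_size - 1))
  p <- apply_homography(H, as.matrix(g))
  v <- nearest_sample(mask + 0, p[, 1], p[, 2], fill = 0)
  # x varies fastest in g; fill by row so the patch keeps row = y, col = x
  matrix(v > 0, out_size, out_size, byrow = TRUE)
}

#' Wound area inside one unwarped square
#'
#' Applies the pixel-count area rule: `A_w = (N_w / N) * square_edge_cm^2`,
#' where `N` and `N_w` are total and wound pixel counts in the unwarped
#' square.
#'
#' @param patch binary matrix from [unwarp_quadrilateral()].
#' @param square_edge_cm physical checker square edge (cm).
#' @return list with `N`, `N_w` and `A_w` (cm^2).
#' @export
square_wound_area <- function(patch, square_edge_cm) {
  N <- length(patch)
  if (N == 0L) stopf("empty patch")
  N_w <- sum(patch > 0)
  list(N = N, N_w = N_w, A_w = (N_w / N) * square_edge_cm^2)
}

#' Measure the 2D wound surface area from a single photograph
#'
#' Full ruler-based pipeline: segmentation (threshold or classifier + Otsu),
#' ROI masking, checkerboard ruler detection, grid extrapolation, per-quad
#' homography unwarping and pixel-count area summation.
#'
#' @param image RGB array.
#' @param roi [roi_polygon()] around the lesion.
#' @param ruler a [ruler_spec()] giving the physical square size.
#' @param model_or_threshold either a numeric luminance threshold (phantom
#'   evaluation mode) or a [train_classifier()] model.
#' @param out_size unwarp resolution; default `max(16, median quad edge px)`.
#' @param manual_points optional user-supplied corner points, see
#'   [detect_ruler()].
#' @return An `area_result`: `total_area_cm2`, `per_square` table, `warnings`.
#' @export
measure_area_2d <- function(image, roi, ruler, model_or_threshold,
                            out_size = NULL, manual_points = NULL) {
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", tag, conditionMessage(e)))
  }
  mask <- stage("seg2d", {
    if (is.numeric(model_or_threshold)) {
      threshold_segment(image, model_or_threshold)
    } else {
      otsu_binarize(predict_probability(model_or_threshold, image))
    }
  })
  mask <- stage("seg2d", apply_roi(mask, roi))
  det <- stage("ruler", detect_ruler(image, manual_points = manual_points))
  grid <- stage("grid2d", extrapolate_grid(det$pairs, roi,
                                           square_edge_cm = ruler$square_edge_cm))
  warns <- detect_degenerate_grid(grid, mask)
  own <- grid_owner_raster(grid, dim(mask))
  if (is.null(out_size)) {
    med <- stats::median(grid$d)
    out_size <- max(16L, round(med))
  }
  sq <- cbind(c(-0.5, out_size - 0.5, out_size - 0.5, -0.5),
              c(-0.5, -0.5, out_size - 0.5, out_size - 0.5))
  g <- as.matrix(expand.grid(x = 0:(out_size - 1), y = 0:(out_size - 1)))
  nq <- grid$n_rows * grid$n_cols
  quads <- vector("list", nq)
  centers <- matrix(NA_real_, nq, 2)
  q <- 0L
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    q <- q + 1L
    quads[[q]] <- grid_quad(grid, i, j)
    centers[q, ] <- colMeans(quads[[q]])
  }
  point_in_quad <- function(p, quad) {
    o <- quad_orientation(quad)
    ins <- rep(TRUE, nrow(p))
    for (e in 1:4) {
      a <- quad[e, ]; b <- quad[e %% 4 + 1, ]
      ins <- ins & (((b[1] - a[1]) * (p[, 2] - a[2]) -
                     (b[2] - a[2]) * (p[, 1] - a[1])) * o >= 0)
    }
    ins
  }
  rows <- list(); q <- 0L; total <- 0
  h <- nrow(mask)
  for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
    q <- q + 1L
    quad <- quads[[q]]
    if (!quad_is_convex(quad)) {
      warns <- c(warns, sprintf("skipped non-convex quad (%d, %d)", i, j))
      next
    }
    H <- homography_from_points(sq, quad)
    p <- apply_homography(H, g)
    xi <- round(p[, 1]); yi <- round(p[, 2])
    ok <- xi >= 0 & yi >= 0 & xi <= ncol(mask) - 1 & yi <= h - 1
    wound <- logical(nrow(p))
    if (any(ok)) {
      lin <- cbind(yi[ok] + 1, xi[ok] + 1)
      wound[ok] <- mask[lin] > 0
      # where the sampled pixel's center is owned by a different quad, keep
      # the sample only if its continuous position is not actually inside
      # that competing quad, or if it is closer to this quad's center
      # (dedup only matters where bent-grid quads truly overlap)
      comp <- rep(0L, nrow(p))
      comp[ok] <- own[lin]
      amb <- which(wound & comp != q & comp > 0L)
      if (length(amb)) {
        for (q2 in unique(comp[amb])) {
          sel <- amb[comp[amb] == q2]
          inq2 <- point_in_quad(p[sel, , drop = FALSE], quads[[q2]])
          if (any(inq2)) {
            s2 <- sel[inq2]
            d1 <- (p[s2, 1] - centers[q, 1])^2 + (p[s2, 2] - centers[q, 2])^2
            d2 <- (p[s2, 1] - centers[q2, 1])^2 + (p[s2, 2] - centers[q2, 2])^2
            wound[s2[d1 > d2]] <- FALSE
          }
        }
      }
    }
    N <- nrow(p); N_w <- sum(wound)
    if (N_w > 0) {
      A_w <- (N_w / N) * ruler$square_edge_cm^2
      total <- total + A_w
      rows[[length(rows) + 1]] <- data.frame(row = i, col = j, N = N,
                                             N_w = N_w, A_w = A_w)
    }
  }
  per_square <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = integer(0), col = integer(0), N = integer(0),
               N_w = integer(0), A_w = numeric(0))
  structure(list(total_area_cm2 = total, per_square = per_square,
                 warnings = warns, square_px = det$square_px,
                 n_pairs = nrow(det$pairs)),
            class = "area_result")
}

#' @export
print.area_result <- function(x, ...) {
  cat(sprintf("Wound surface area: %.3f cm^2 (%d contributing squares)\n",
              x$total_area_cm2, nrow(x$per_square)))
  if (length(x$warnings))
    cat("Warnings:\n", paste0("  - ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.area_result <- function(object, ...) {
  cat(sprintf("Total area: %.3f cm^2\n", object$total_area_cm2))
  if (nrow(object$per_square)) {
    cat(sprintf("Squares contributing: %d; wound pixel fraction range: %.3f-%.3f\n",
                nrow(object$per_square),
                min(object$per_square$N_w / object$per_square$N),
                max(object$per_square$N_w / object$per_square$N)))
  }
  if (length(object$warnings))
    cat("Warnings:\n", paste0("  - ", object$warnings, collapse = "\n"), "\n")
  invisible(object)
}
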