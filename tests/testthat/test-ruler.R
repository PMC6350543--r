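test_that("structure tensor separates edges from corners", {
  # vertical step edge
  g <- matrix(0.1, 40, 40); g[, 21:40] <- 0.9
  maps <- structure_tensor_maps(g, 1, 2)
  expect_s3_class(maps, "tensor_maps")
  expect_true(all(maps$l1 >= maps$l2 - 1e-12))
  expect_true(all(maps$l2 >= 0))
  edge <- maps$l1[20, 20:21]; flat <- maps$l1[20, 5]
  expect_gt(min(edge), 100 * max(flat, 1e-12))
  expect_lt(maps$l2[20, 20] / maps$l1[20, 20], 0.05)
  # orientation perpendicular to a vertical edge: dominant gradient along x
  expect_lt(abs(maps$orientation[20, 20]), 0.1)
  # checkerboard corner: both eigenvalues large
  cb <- matrix(0.1, 40, 40); cb[1:20, 1:20] <- 0.9; cb[21:40, 21:40] <- 0.9
  mc <- structure_tensor_maps(cb, 1, 2)
  expect_gt(mc$l2[20, 20] / mc$l1[20, 20], 0.4)
  # constant image: all-zero tensors, not an error
  m0 <- structure_tensor_maps(matrix(0.5, 20, 20), 1, 2)
  expect_equal(max(m0$l1), 0)
})

test_that("eigenvalue maps match the closed-form quadratic at random pixels", {
  set.seed(11)
  g <- matrix(runif(60 * 60), 60, 60)
  sg <- 1; sw <- 2
  maps <- structure_tensor_maps(g, sg, sw)
  # independent reconstruction of the tensor entries with EBImage kernels
  blur <- function(m, s) {
    r <- max(2, ceiling(3 * s))
    matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = s,
                                             radius = 2 * r + 1,
                                             boundary = "replicate")),
           nrow(m), ncol(m))
  }
  sm <- blur(g, sg)
  h <- nrow(sm); w <- ncol(sm)
  gx <- (sm[, c(2:w, w)] - sm[, c(1, 1:(w - 1))]) / 2
  gy <- (sm[c(2:h, h), ] - sm[c(1, 1:(h - 1)), ]) / 2
  j11 <- blur(gx * gx, sw); j22 <- blur(gy * gy, sw); j12 <- blur(gx * gy, sw)
  idx <- cbind(sample(5:55, 100, TRUE), sample(5:55, 100, TRUE))
  for (k in 1:100) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ev <- oracle_eigen2(j11[i, j], j12[i, j], j22[i, j])
    expect_equal(maps$l1[i, j], ev[1], tolerance = 1e-8)
    expect_equal(maps$l2[i, j], max(ev[2], 0), tolerance = 1e-8)
  }
})

test_that("corner detection finds the interior checkerboard lattice", {
  # blank image: empty set
  m0 <- structure_tensor_maps(matrix(0.5, 64, 64), 1, 2)
  expect_equal(nrow(detect_corners(m0)), 0)
  # fixture: 18 columns x 3 rows -> 2 * 17 interior corners
  cb <- fix_flat$det$corners
  cb <- cb[cb$is_checkerboard %in% TRUE, ]
  expect_equal(nrow(cb), 2 * (fix_flat$spec$ruler$n_cols - 1))
  tr <- fix_flat$truth$ruler_corner_px
  nn <- RANN::nn2(tr, cbind(cb$x, cb$y), k = 1)
  expect_lt(max(nn$nn.dists), 1)
  expect_lt(mean(nn$nn.dists), 0.5)
})

test_that("corner count is invariant under 90-degree rotation", {
  img <- rotate_image_90(fix_flat$image)
  det <- detect_ruler(img)
  cb0 <- sum(fix_flat$det$corners$is_checkerboard %in% TRUE)
  cb1 <- sum(det$corners$is_checkerboard %in% TRUE)
  expect_equal(cb1, cb0)
  expect_equal(nrow(det$pairs), nrow(fix_flat$det$pairs))
  expect_equal(mean(det$pairs$d), mean(fix_flat$det$pairs$d), tolerance = 0.02)
})

test_that("checkerboard classification separates checker corners from plain ones", {
  # ideal checker corner
  g <- matrix(0.1, 41, 41); g[1:20, 1:20] <- 0.9; g[21:41, 21:41] <- 0.9
  cs <- data.frame(x = 20, y = 20, response = 1, is_checkerboard = NA)
  class(cs) <- c("corner_set", "data.frame")
  out <- classify_checkerboard_corners(g, cs, window_px = 10)
  expect_true(out$is_checkerboard[1])
  # corner of a uniform square on plain background: three similar quadrants
  g2 <- matrix(0.9, 41, 41); g2[21:41, 21:41] <- 0.1
  out2 <- classify_checkerboard_corners(g2, cs, window_px = 10)
  expect_false(out2$is_checkerboard[1])
  # on the phantom: no flagged corner inside the lesion area
  cb <- fix_flat$det$corners
  flagged <- cb[cb$is_checkerboard %in% TRUE, ]
  inside <- fix_flat$truth$shape_mask[cbind(round(flagged$y) + 1,
                                            round(flagged$x) + 1)]
  expect_equal(sum(inside), 0)
})

test_that("centerline runs midway between the corner rows", {
  # two straight horizontal rows
  xs <- seq(10, 90, by = 10)
  cs <- data.frame(x = rep(xs, 2), y = rep(c(10, 20), each = length(xs)),
                   response = 1, is_checkerboard = TRUE)
  class(cs) <- c("corner_set", "data.frame")
  cl <- centerline_from_corners(cs, image_size = c(100, 31))
  expect_s3_class(cl, "centerline")
  expect_lt(max(abs(cl$y - 15)), 0.5)
  expect_true(all(diff(cl$s) > 0))
  # collinear corners: rows not separable
  cs1 <- cs[cs$y == 10, ]
  class(cs1) <- c("corner_set", "data.frame")
  expect_error(centerline_from_corners(cs1, c(100, 31)), "not separable")
})

test_that("distance transform agrees with the brute-force nearest-corner oracle", {
  set.seed(4)
  pts <- cbind(sample(5:55, 12), sample(5:25, 12))
  m <- matrix(1, 30, 60)
  m[cbind(pts[, 2] + 1, pts[, 1] + 1)] <- 0
  dt <- matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(m))), 30, 60)
  probes <- cbind(sample(0:59, 50, TRUE), sample(0:29, 50, TRUE))
  for (k in 1:50) {
    d_oracle <- min(sqrt((pts[, 1] - probes[k, 1])^2 + (pts[, 2] - probes[k, 2])^2))
    expect_equal(dt[probes[k, 2] + 1, probes[k, 1] + 1], d_oracle,
                 tolerance = 1e-6)
  }
})

test_that("centerline follows a bent ruler along the mid-arc", {
  # corner rows on concentric circular arcs
  R <- 200; ctr <- c(100, 240)
  th <- seq(-0.35, 0.35, length.out = 14)
  up <- cbind(ctr[1] + (R - 9) * sin(th), ctr[2] - (R - 9) * cos(th))
  lo <- cbind(ctr[1] + (R + 9) * sin(th), ctr[2] - (R + 9) * cos(th))
  cs <- data.frame(x = c(up[, 1], lo[, 1]), y = c(up[, 2], lo[, 2]),
                   response = 1, is_checkerboard = TRUE)
  class(cs) <- c("corner_set", "data.frame")
  cl <- centerline_from_corners(cs, image_size = c(220, 120))
  radial_err <- abs(sqrt((cl$x - ctr[1])^2 + (cl$y - ctr[2])^2) - R)
  # assess the curve between the corner extremes (the short extrapolated
  # ends exist only so that the end crossings stay detectable)
  inside <- cl$s_axis >= min(cl$s_axis) + 6 & cl$s_axis <= max(cl$s_axis) - 6
  expect_lt(max(radial_err[inside]), 1)
})

test_that("edge crossings appear once per checker period", {
  # synthetic alternating profile, period 20 px, along a straight centerline
  g <- matrix(0.95, 40, 200)
  dark <- (floor((0:199) / 20) %% 2) == 0
  g[, dark] <- 0.15
  cl <- list(x = seq(5, 194, by = 0.25), y = rep(20, 757),
             s = seq(0, 189, by = 0.25), s_axis = seq(5, 194, by = 0.25),
             center = c(100, 20), axis = c(1, 0), perp = c(0, 1),
             spacing = 20, eval = NULL)
  class(cl) <- "centerline"
  cr <- find_edge_crossings(g, cl)
  expect_equal(nrow(cr), 9)
  gaps <- diff(cr$s)
  expect_true(all(abs(gaps - 20) < 1))
  # constant profile: no period
  expect_error(find_edge_crossings(matrix(0.5, 40, 200), cl), "not recoverable")
  # fixture: one crossing per interior column edge
  expect_equal(nrow(fix_flat$det$crossings), fix_flat$spec$ruler$n_cols - 1)
})

test_that("edge-line refinement recovers direction via PCA", {
  # vertical edge at x = 50
  g <- matrix(0.1, 100, 100); g[, 51:100] <- 0.9
  maps <- structure_tensor_maps(g, 1, 2)
  ln <- refine_edge_line(maps, c(50, 50), radius_px = 10)
  expect_equal(abs(ln$direction[2]), 1, tolerance = 2e-2)
  expect_equal(ln$point[1], 50, tolerance = 0.5)
  ang_err <- abs(90 - atan2(abs(ln$direction[2]), abs(ln$direction[1])) * 180 / pi)
  expect_lt(ang_err, 1)
  # rotated edge: direction rotates with it
  g30 <- matrix(0.1, 100, 100)
  xx <- matrix(0:99, 100, 100, byrow = TRUE); yy <- matrix(0:99, 100, 100)
  g30[(yy - 50) > tan(pi / 6) * (xx - 50)] <- 0.9
  m30 <- structure_tensor_maps(g30, 1, 2)
  l30 <- refine_edge_line(m30, c(50, 50), radius_px = 10)
  got <- atan2(l30$direction[2], l30$direction[1]) * 180 / pi
  expect_lt(min(abs(got - 30), abs(got + 150)), 1)
  # PCA direction equals the closed-form eigenvector of the scatter matrix
  sel_x <- xx[abs((yy - 50) - tan(pi / 6) * (xx - 50)) < 1.5]
  sel_y <- yy[abs((yy - 50) - tan(pi / 6) * (xx - 50)) < 1.5]
  C <- cov(cbind(sel_x, sel_y))
  lam <- oracle_eigen2(C[1, 1], C[1, 2], C[2, 2])[1]
  v <- c(C[1, 2], lam - C[1, 1]); v <- v / sqrt(sum(v^2))
  expect_equal(abs(sum(v * c(cos(pi / 6), sin(pi / 6)))), 1, tolerance = 1e-3)
})

test_that("correspondence pairs are ordered with the right local scale", {
  pairs <- fix_flat$det$pairs
  expect_equal(nrow(pairs), fix_flat$spec$ruler$n_cols - 1)
  expect_true(all(diff(pairs$s) > 0))
  # d equals the rendered transverse checker extent (one square edge)
  true_d <- 0.5 * fix_flat$px_per_cm
  expect_true(all(abs(pairs$d - true_d) / true_d < 0.02))
  # p1 and p2 lie on opposite sides of the centerline
  expect_true(all(pairs$p1y < pairs$p2y))
})

test_that("detection is independent of the number of visible squares", {
  for (k in c(4, 8, 16)) {
    spec <- phantom_scene_spec(shape = phantom_shape("ellipse", area_cm2 = 4),
                               ruler = ruler_spec(n_cols = k))
    r <- render_flat_phantom(spec)
    det <- detect_ruler(r$image)
    expect_equal(nrow(det$pairs), k - 1)
  }
})
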