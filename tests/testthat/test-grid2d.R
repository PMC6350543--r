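make_pairs <- function(p1s, p2s) {
  d <- sqrt(rowSums((p2s - p1s)^2))
  out <- data.frame(p1x = p1s[, 1], p1y = p1s[, 2], p2x = p2s[, 1],
                    p2y = p2s[, 2], d = d, s = seq_len(nrow(p1s)))
  class(out) <- c("correspondence_pairs", "data.frame")
  out
}

test_that("homography solve agrees with the 8-unknown linear-system oracle", {
  set.seed(21)
  for (rep in 1:5) {
    src <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
    dst <- src + matrix(runif(8, -2, 2), 4, 2) + 10
    H <- homography_from_points(src, dst)
    Ho <- oracle_homography(src, dst)
    expect_equal(H / H[3, 3], Ho / Ho[3, 3], tolerance = 1e-8)
    expect_equal(apply_homography(H, src), dst, tolerance = 1e-8)
  }
})

test_that("grid extrapolation places points equidistantly along the pair line", {
  p1s <- rbind(c(0, 0), c(10, 0), c(20, 0))
  p2s <- rbind(c(0, 10), c(10, 10), c(20, 10))
  roi <- roi_polygon(cbind(c(0, 20, 20, 0), c(20, 20, 45, 45)))
  g <- extrapolate_grid(make_pairs(p1s, p2s), roi, square_edge_cm = 0.5)
  # first column continues (0,10) -> (0,20), (0,30), (0,40), ...
  expect_equal(g$nodes[1, 1, ], c(0, 10))
  expect_equal(g$nodes[2, 1, ], c(0, 20))
  expect_equal(g$nodes[3, 1, ], c(0, 30))
  expect_equal(g$nodes[4, 1, ], c(0, 40))
  # parallel vertical pairs 10 px apart: exact 10 x 10 squares
  q <- lesionmetry:::grid_quad(g, 1, 1)
  expect_equal(q, rbind(c(0, 10), c(10, 10), c(10, 20), c(0, 20)))
  # grid covers the ROI bounding box
  expect_gte(g$n_rows * 10, 35)
})

test_that("grid orientation flips towards the ROI side", {
  p1s <- rbind(c(0, 10), c(10, 10), c(20, 10))
  p2s <- rbind(c(0, 0), c(10, 0), c(20, 0))   # p2 on top, ROI below p1
  roi <- roi_polygon(cbind(c(0, 20, 20, 0), c(20, 20, 40, 40)))
  g <- extrapolate_grid(make_pairs(p1s, p2s), roi, square_edge_cm = 0.5)
  expect_equal(g$nodes[1, 1, 2], 10)  # starts at the wound-side row
  expect_gt(g$nodes[2, 1, 2], g$nodes[1, 1, 2])
  # ROI centered on the ruler itself is degenerate
  roi_on <- roi_polygon(cbind(c(0, 20, 20, 0), c(2, 2, 8, 8)))
  expect_error(extrapolate_grid(make_pairs(p1s, p2s), roi_on, 0.5),
               "degenerate")
})

test_that("grid nodes land on the projected ideal lattice for flat phantoms", {
  det <- fix_flat$det
  roi <- roi_around_mask(fix_flat$truth$shape_mask)
  g <- extrapolate_grid(det$pairs, roi, square_edge_cm = 0.5)
  spec <- fix_flat$spec
  cam <- overhead_camera()
  e <- spec$ruler$square_edge_cm; o <- spec$ruler_offset
  # ideal lattice: all column-edge / extended-row intersections in the chart
  ideal <- NULL
  for (i in 1:4) for (j in seq_len(spec$ruler$n_cols - 1)) {
    ideal <- rbind(ideal, project_points(
      cam, cbind(o[1] + j * e, o[2] + (1 + i) * e, 0)))
  }
  nodes <- NULL
  for (i in 1:min(4, g$n_rows + 1)) for (j in seq_len(g$n_cols + 1)) {
    nodes <- rbind(nodes, g$nodes[i, j, ])
  }
  nn <- RANN::nn2(ideal, nodes, k = 1)
  expect_lt(max(nn$nn.dists), 1)
})

test_that("degenerate grids are flagged", {
  p1s <- rbind(c(0, 0), c(10, 0), c(20, 0))
  p2s <- rbind(c(0, 10), c(10, 10), c(20, 10))
  roi <- roi_polygon(cbind(c(0, 20, 20, 0), c(12, 12, 40, 40)))
  g <- extrapolate_grid(make_pairs(p1s, p2s), roi, 0.5)
  wm <- matrix(FALSE, 60, 40); wm[20:30, 5:15] <- TRUE
  expect_length(detect_degenerate_grid(g, wm), 0)
  # wound outside the grid footprint
  wm2 <- matrix(FALSE, 60, 40); wm2[50:55, 35:39] <- TRUE
  expect_match(detect_degenerate_grid(g, wm2)[1], "outside")
  # strongly converging fan
  th <- seq(-pi / 6, pi / 6, length.out = 5)
  p1f <- cbind(100 + 30 * sin(th), 30 - 30 * (cos(th) - 1))
  p2f <- cbind(100 + 20 * sin(th), 40 - 20 * (cos(th) - 1))
  roi_f <- roi_polygon(cbind(c(60, 140, 140, 60), c(50, 50, 150, 150)))
  gf <- extrapolate_grid(make_pairs(p1f, p2f), roi_f, 0.5, max_rows = 20)
  wmf <- matrix(FALSE, 160, 200); wmf[60:140, 80:120] <- TRUE
  expect_true(any(grepl("converging", detect_degenerate_grid(gf, wmf))))
})

test_that("quad unwarping is exact for axis-aligned squares", {
  set.seed(5)
  mask <- matrix(runif(400) > 0.5, 20, 20)
  quad <- rbind(c(4, 6), c(13, 6), c(13, 15), c(4, 15))
  patch <- unwarp_quadrilateral(mask, quad, 10)
  expect_identical(unname(patch), unname(mask[7:16, 5:14]))
  # full mask -> full patch
  expect_true(all(unwarp_quadrilateral(matrix(TRUE, 20, 20), quad, 8)))
  # non-convex quad is rejected
  bad <- rbind(c(0, 0), c(10, 0), c(2, 3), c(0, 10))
  expect_error(unwarp_quadrilateral(mask, bad, 8), "convex")
})

test_that("the pixel-count area rule is exact", {
  expect_equal(square_wound_area(matrix(TRUE, 10, 10), 0.5)$A_w, 0.25)
  expect_equal(square_wound_area(matrix(FALSE, 10, 10), 0.5)$A_w, 0)
  p <- matrix(FALSE, 10, 10); p[1:37] <- TRUE
  m <- square_wound_area(p, 1)
  expect_equal(m$N, 100); expect_equal(m$N_w, 37); expect_equal(m$A_w, 0.37)
  expect_error(square_wound_area(matrix(logical(0), 0, 0), 1), "empty")
})

test_that("full 2D measurement hits the analytic truth on the flat phantom", {
  roi <- roi_around_mask(fix_flat$truth$shape_mask)
  res <- measure_area_2d(fix_flat$image, roi, fix_flat$spec$ruler,
                         fix_flat$truth$seg_threshold)
  expect_s3_class(res, "area_result")
  rel <- abs(res$total_area_cm2 - 14.137) / 14.137
  expect_lt(rel, 0.03)
  # additivity: the total is exactly the per-square sum
  expect_equal(res$total_area_cm2, sum(res$per_square$A_w))
  # empty wound mask: total 0 (threshold below every luminance)
  res0 <- measure_area_2d(fix_flat$image, roi, fix_flat$spec$ruler, 0.0)
  expect_equal(res0$total_area_cm2, 0)
})

test_that("measured area is monotone in the segmentation mask", {
  roi <- roi_around_mask(fix_flat$truth$shape_mask)
  r1 <- measure_area_2d(fix_flat$image, roi, fix_flat$spec$ruler, 0.30)
  r2 <- measure_area_2d(fix_flat$image, roi, fix_flat$spec$ruler, 0.44)
  r3 <- measure_area_2d(fix_flat$image, roi, fix_flat$spec$ruler, 0.58)
  expect_lte(r1$total_area_cm2, r2$total_area_cm2)
  expect_lte(r2$total_area_cm2, r3$total_area_cm2)
})

test_that("measurement is invariant to the physical square size", {
  sh <- phantom_shape("ellipse", area_cm2 = 9)
  spec1 <- phantom_scene_spec(shape = sh, ruler = ruler_spec(0.5, n_cols = 18))
  spec2 <- phantom_scene_spec(shape = sh, ruler = ruler_spec(1.0, n_cols = 9))
  r1 <- render_flat_phantom(spec1); r2 <- render_flat_phantom(spec2)
  roi1 <- roi_around_mask(r1$truth$shape_mask)
  roi2 <- roi_around_mask(r2$truth$shape_mask)
  a1 <- measure_area_2d(r1$image, roi1, spec1$ruler, 0.44)$total_area_cm2
  a2 <- measure_area_2d(r2$image, roi2, spec2$ruler, 0.44)$total_area_cm2
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("curvature degrades accuracy relative to the flat support", {
  roi_f <- roi_around_mask(fix_flat$truth$shape_mask)
  err_f <- abs(measure_area_2d(fix_flat$image, roi_f, fix_flat$spec$ruler,
                               0.44)$total_area_cm2 - 14.137)
  roi_c <- roi_around_mask(fix_cyl$truth$shape_mask)
  err_c <- abs(measure_area_2d(fix_cyl$image, roi_c, fix_cyl$spec$ruler,
                               0.44)$total_area_cm2 - 14.137)
  expect_gt(err_c, err_f)
})
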