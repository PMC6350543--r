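test_that("2.5D Delaunay meshing produces the expected connectivity", {
  # planar unit square -> 2 triangles
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  m <- triangulate_mesh(sq)
  expect_equal(nrow(m$faces), 2)
  # 10 x 10 planar grid -> 162 triangles (2 (n-1)^2)
  g <- as.matrix(expand.grid(x = 0:9, y = 0:9))
  mg <- triangulate_mesh(cbind(g, 0))
  expect_equal(nrow(mg$faces), 162)
  # collinear points are rejected
  expect_error(triangulate_mesh(cbind(1:5, 2 * (1:5), 0)), "collinear")
})

test_that("planar Delaunay satisfies the empty-circumcircle property", {
  set.seed(31)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 10), 0)
  m <- triangulate_mesh(pts)
  circum <- function(a, b, c) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  viol <- 0
  for (f in seq_len(nrow(m$faces))) {
    tri <- m$faces[f, ]
    cc <- circum(pts[tri[1], 1:2], pts[tri[2], 1:2], pts[tri[3], 1:2])
    dd <- sqrt((pts[-tri, 1] - cc[1])^2 + (pts[-tri, 2] - cc[2])^2)
    viol <- viol + sum(dd < cc[3] - 1e-9)
  }
  expect_equal(viol, 0)
})

test_that("Laplacian smoothing is a fixed point on a plane and denoises", {
  # structured grid mesh: every interior 1-ring is symmetric about its vertex
  ph <- make_mesh_phantom("plane", patch_cm = c(1, 1), extent_cm = c(14, 14),
                          h_cm = 1)
  flat <- ph$mesh
  g <- flat$vertices[, 1:2]
  sm <- smooth_and_fill(flat, iterations = 5)
  expect_lt(max(abs(sm$vertices[, 3])), 1e-12)
  interior <- abs(g[, 1]) < 7 & abs(g[, 2]) < 7
  expect_lt(max(abs(sm$vertices[interior, 1:2] - g[interior, ])), 1e-9)
  # noisy plane: RMS distance to the plane decreases monotonically
  set.seed(2)
  noisy <- flat
  noisy$vertices[, 3] <- rnorm(nrow(g), sd = 0.05)
  rms <- numeric(10)
  cur <- noisy
  for (it in 1:10) {
    cur <- smooth_and_fill(cur, iterations = 1)
    rms[it] <- sqrt(mean(cur$vertices[interior, 3]^2))
  }
  expect_true(all(diff(rms) < 1e-12))
})

test_that("interior holes are filled and the disk topology restored", {
  g <- as.matrix(expand.grid(x = 0:9, y = 0:9))
  m <- triangulate_mesh(cbind(g, 0))
  # remove the faces incident to an interior vertex -> hexagonal hole
  vic <- which(g[, 1] == 5 & g[, 2] == 5)
  drop <- apply(m$faces, 1, function(f) vic %in% f)
  holed <- labeled_mesh(m$vertices, m$faces[!drop, , drop = FALSE],
                        gray = rep(255, nrow(m$vertices)))
  filled <- smooth_and_fill(holed, iterations = 0)
  euler <- function(mm) {
    et <- rbind(mm$faces[, c(1, 2)], mm$faces[, c(2, 3)], mm$faces[, c(3, 1)])
    et <- unique(cbind(pmin(et[, 1], et[, 2]), pmax(et[, 1], et[, 2])))
    length(unique(as.vector(mm$faces))) - nrow(et) + nrow(mm$faces)
  }
  expect_equal(euler(filled), 1)  # disk
  expect_gt(nrow(filled$faces), nrow(holed$faces))
  # gray of the fan vertex is the mean of the loop grays
  expect_equal(filled$gray[length(filled$gray)], 255)
})

test_that("scale calibration follows the reference segment", {
  m <- cube_mesh(1)
  ref <- reference_segment(c(0, 0, 0), c(2, 0, 0), 4)
  expect_equal(calibrate_scale(m, ref)$scale_cm_per_unit, 2)
  ref1 <- reference_segment(c(0, 0, 0), c(1, 0, 0), 1)
  m1 <- calibrate_scale(m, ref1)
  expect_equal(measure_area_3d(m1)$total_area_cm2, mesh_surface_area(m))
  expect_error(reference_segment(c(0, 0, 0), c(0, 0, 0), 1), "coincide")
  # synthetic phantom reference: exact scale recovery on a clean mesh
  ph <- make_mesh_phantom(list(type = "cylinder", radius_cm = 19.5),
                          patch_cm = c(3, 2.5), h_cm = 0.1)
  mm <- ph$mesh
  mm$vertices <- mm$vertices * 0.37
  ref2 <- reference_segment(mm$vertices[ph$reference$a_idx, ],
                            mm$vertices[ph$reference$b_idx, ],
                            ph$reference$true_length_cm)
  expect_equal(calibrate_scale(mm, ref2)$scale_cm_per_unit, 1 / 0.37,
               tolerance = 1e-3)
})

test_that("the two-white-vertex triangle sum implements the area rule", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 2, 0))
  f <- rbind(c(1, 2, 3), c(2, 4, 3))
  m <- labeled_mesh(v, f, gray = c(255, 255, 255, 0), scale_cm_per_unit = 1)
  # unit right triangle fully white: 0.5; second triangle has 2 white -> counts
  expect_equal(measure_area_3d(m)$total_area_cm2, 0.5 + 1.5)
  m$gray <- c(255, 0, 0, 0)  # one white vertex: nothing qualifies
  expect_equal(measure_area_3d(m)$total_area_cm2, 0)
  m$gray <- c(255, 255, 255, 0)
  m$scale_cm_per_unit <- NA_real_
  expect_error(measure_area_3d(m), "not scaled")
  # whitening more vertices never decreases the area
  set.seed(8)
  g <- as.matrix(expand.grid(x = 0:9, y = 0:9))
  mg <- triangulate_mesh(cbind(g, 0))
  mg$scale_cm_per_unit <- 1
  gray <- ifelse(runif(100) < 0.4, 255, 0)
  mg$gray <- gray
  a1 <- measure_area_3d(mg)$total_area_cm2
  gray2 <- gray; gray2[sample(which(gray == 0), 10)] <- 255
  mg$gray <- gray2
  expect_gte(measure_area_3d(mg)$total_area_cm2, a1)
})

test_that("closed meshes reproduce known surface areas", {
  expect_equal(measure_area_3d(cube_mesh(1))$total_area_cm2, 6)
  sph <- uv_sphere_mesh(3, 60, 90)
  expect_gte(nrow(sph$faces), 5000)
  expect_equal(measure_area_3d(sph)$total_area_cm2, 4 * pi * 9,
               tolerance = 0.02)
})

test_that("area measurement is rigid-invariant and scales quadratically", {
  # mesh of exactly the 3 x 3 cm patch, all vertices white
  ph <- make_mesh_phantom("plane", patch_cm = c(3, 3), extent_cm = c(3, 3),
                          h_cm = 0.1)
  m <- ph$mesh; m$scale_cm_per_unit <- 1
  a0 <- measure_area_3d(m)$total_area_cm2
  expect_equal(a0, 9, tolerance = 0.01)
  # rigid transform
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m; m2$vertices <- m$vertices %*% t(R) + rep(c(5, -2, 3), each = nrow(m$vertices))
  expect_equal(measure_area_3d(m2)$total_area_cm2, a0, tolerance = 1e-9)
  # doubling the reference length doubles the linear scale: area x4
  mm <- ph$mesh
  refA <- reference_segment(mm$vertices[ph$reference$a_idx, ],
                            mm$vertices[ph$reference$b_idx, ],
                            ph$reference$true_length_cm)
  refB <- reference_segment(refA$a, refA$b, 2 * refA$true_length_cm)
  aA <- measure_area_3d(calibrate_scale(mm, refA))$total_area_cm2
  aB <- measure_area_3d(calibrate_scale(mm, refB))$total_area_cm2
  expect_equal(aB / aA, 4, tolerance = 1e-9)
})

test_that("mesh phantoms match the published size/curvature grid", {
  cfg <- list(list(r = 19.5, p = c(3.6, 3.0), a = 10.8),
              list(r = 19.5, p = c(4.5, 3.6), a = 16.2),
              list(r = 19.5, p = c(5.4, 4.0), a = 21.6),
              list(r = 8.5, p = c(3.6, 3.0), a = 10.8),
              list(r = 8.5, p = c(4.5, 3.6), a = 16.2))
  for (cf in cfg) {
    ph <- make_mesh_phantom(list(type = "cylinder", radius_cm = cf$r),
                            patch_cm = cf$p, h_cm = 0.1)
    expect_equal(ph$true_patch_area_cm2, cf$a, tolerance = 1e-10)
  }
  # sphere patch area via the latitude-longitude formula vs quadrature
  phs <- make_mesh_phantom(list(type = "sphere", radius_cm = 10),
                           patch_cm = c(4, 3), h_cm = 0.1)
  f <- lesionmetry:::surface_fn(list(type = "sphere", radius_cm = 10))
  n <- 400
  us <- seq(-2, 2, length.out = n + 1); vs <- seq(-1.5, 1.5, length.out = n + 1)
  um <- (us[-1] + us[-(n + 1)]) / 2; vm <- (vs[-1] + vs[-(n + 1)]) / 2
  gq <- expand.grid(u = um, v = vm)
  eps <- 1e-4
  xu <- (f(gq$u + eps, gq$v) - f(gq$u - eps, gq$v)) / (2 * eps)
  xv <- (f(gq$u, gq$v + eps) - f(gq$u, gq$v - eps)) / (2 * eps)
  quad <- sum(sqrt(rowSums(xu^2) * rowSums(xv^2) - rowSums(xu * xv)^2)) *
    diff(us)[1] * diff(vs)[1]
  expect_equal(phs$true_patch_area_cm2, quad, tolerance = 1e-5)
  expect_error(make_mesh_phantom("plane", patch_cm = c(0, 3)), "degenerate")
})

test_that("noisy mesh phantoms survive the smoothing/scaling/area chain", {
  ph <- make_mesh_phantom(list(type = "cylinder", radius_cm = 8.5),
                          patch_cm = c(4.5, 3.6), h_cm = 0.06)
  out <- measure_mesh_phantom(ph, noise_sd_cm = 0.02, unit_scale = 0.63,
                              seed = 4)
  rel <- abs(out$result$total_area_cm2 - ph$true_patch_area_cm2) /
    ph$true_patch_area_cm2
  expect_lt(rel, 0.05)
})

test_that("PLY round-trips meshes and clouds", {
  ph <- make_mesh_phantom("plane", patch_cm = c(2, 2), h_cm = 0.4)
  f <- tempfile(fileext = ".ply")
  write_ply(ph$mesh, f)
  m2 <- read_ply(f)
  expect_equal(m2$vertices, unname(ph$mesh$vertices), tolerance = 1e-6)
  expect_equal(m2$faces, unname(ph$mesh$faces))
  expect_equal(m2$gray, ph$mesh$gray)
})
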