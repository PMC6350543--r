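#' Checkerboard ruler geometry
#'
#' Physical description of the flexible paper ruler: a checkerboard strip of
#' known square size whose corners provide local metric scale.  The board has
#' `n_rows` rows of squares (three by default), so its interior corners lie on
#' two rows, which is what the pairing stage relies on.
#'
#' @param square_edge_cm physical edge length of one checker square (cm).
#' @param n_rows number of checker rows (default 3).
#' @param n_cols number of checker columns.
#' @param colors intensities `c(dark, light)` used when rendering.
#' @return An object of class `ruler_spec`.
#' @export
ruler_spec <- function(square_edge_cm = 0.5, n_rows = 3L, n_cols = 18L,
                       colors = c(0.15, 0.95)) {
  if (square_edge_cm <= 0) stopf("square_edge_cm must be > 0")
  if (n_rows < 2L) stopf("need at least 2 checker rows")
  if (n_cols < 2L) stopf("need at least 2 checker columns")
  structure(list(square_edge_cm = square_edge_cm, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), colors = colors,
                 border_cm = 0.15),
            class = "ruler_spec")
}

#' Shape of analytically known area for a phantom scene
#'
#' @param type `"ellipse"`, `"rectangle"` or `"polygon"`.
#' @param area_cm2 target analytic area; dimensions are derived from it for
#'   ellipse/rectangle.  Ignored for `"polygon"` unless `vertices` is `NULL`.
#' @param aspect width/height ratio (ellipse: a/b; rectangle: w/h).
#' @param center shape center in the chart, `c(u, v)` cm.
#' @param angle in-chart rotation, degrees.
#' @param vertices optional n x 2 matrix of polygon vertices (cm, relative to
#'   `center`); its shoelace area defines the true area.
#' @return A list describing the shape, with exact `area_cm2`.
#' @export
phantom_shape <- function(type = c("ellipse", "rectangle", "polygon"),
                          area_cm2 = 10, aspect = 1.4, center = c(0, 1.2),
                          angle = 0, vertices = NULL) {
  type <- match.arg(type)
  if (type == "polygon") {
    if (is.null(vertices)) {
      # regular hexagon scaled to the requested area
      a <- sqrt(2 * area_cm2 / (3 * sqrt(3)))
      th <- (0:5) * pi / 3
      vertices <- cbind(a * cos(th), a * sin(th))
    }
    area <- polygon_area(vertices)
    out <- list(type = type, vertices = vertices, center = center,
                angle = angle, area_cm2 = area)
  } else if (type == "ellipse") {
    b <- sqrt(area_cm2 / (pi * aspect)); a <- aspect * b
    out <- list(type = type, a = a, b = b, center = center, angle = angle,
                area_cm2 = pi * a * b)
  } else {
    h <- sqrt(area_cm2 / aspect); w <- aspect * h
    out <- list(type = type, w = w, h = h, center = center, angle = angle,
                area_cm2 = w * h)
  }
  if (out$area_cm2 <= 0) stopf("shape area must be > 0")
  out
}

#' Phantom scene specification
#'
#' Describes a synthetic validation scene: a support surface (flat plane or a
#' cylinder of given radius, the latter emulating lesions on curved body
#' parts), a shape of exactly known area playing the wound, and a checkerboard
#' ruler.  Shape and ruler are laid out in the flat 2D chart of the support;
#' because a cylinder is developable, wrapping the chart onto it preserves all
#' areas, so the analytic chart area is the ground truth in both cases.
#'
#' @param support `"flat"` or `list(type = "cylinder", radius_cm = r)`.
#' @param shape a [phantom_shape()].
#' @param ruler a [ruler_spec()].
#' @param ruler_offset chart position `c(u, v)` of the board's top-left corner;
#'   the board extends `n_cols * edge` along u and `n_rows * edge` along v.
#' @param texture_seed integer seed for the skin-texture noise.
#' @return An object of class `phantom_scene_spec`.
#' @export
phantom_scene_spec <- function(support = "flat",
                               shape = phantom_shape(),
                               ruler = ruler_spec(),
                               ruler_offset = NULL,
                               texture_seed = 1L) {
  if (is.character(support)) support <- list(type = support)
  if (!support$type %in% c("flat", "cylinder")) stopf("unknown support type")
  if (support$type == "cylinder" && support$radius_cm <= 0)
    stopf("cylinder radius_cm must be > 0")
  if (is.null(ruler_offset))
    ruler_offset <- c(-ruler$n_cols * ruler$square_edge_cm / 2, -3.9)
  spec <- structure(list(support = support, shape = shape, ruler = ruler,
                         ruler_offset = as.numeric(ruler_offset),
                         texture_seed = as.integer(texture_seed)),
                    class = "phantom_scene_spec")
  bb <- shape_bbox(shape)
  rb <- ruler_bbox(spec)
  if (bb[1] < rb[3] && rb[1] < bb[3] && bb[2] < rb[4] && rb[2] < bb[4])
    stopf("shape and ruler overlap in the chart")
  spec
}

# chart-space bounding boxes -------------------------------------------------

shape_bbox <- function(s) {
  ext <- switch(s$type,
    ellipse = {
      t <- s$angle * pi / 180
      c(sqrt((s$a * cos(t))^2 + (s$b * sin(t))^2),
        sqrt((s$a * sin(t))^2 + (s$b * cos(t))^2))
    },
    rectangle = {
      t <- s$angle * pi / 180
      c(abs(s$w / 2 * cos(t)) + abs(s$h / 2 * sin(t)),
        abs(s$w / 2 * sin(t)) + abs(s$h / 2 * cos(t)))
    },
    polygon = {
      v <- rotate2(s$vertices, s$angle)
      c(max(abs(v[, 1])), max(abs(v[, 2])))
    })
  c(s$center[1] - ext[1], s$center[2] - ext[2],
    s$center[1] + ext[1], s$center[2] + ext[2])
}

ruler_bbox <- function(spec) {
  r <- spec$ruler; o <- spec$ruler_offset; m <- r$border_cm
  c(o[1] - m, o[2] - m,
    o[1] + r$n_cols * r$square_edge_cm + m,
    o[2] + r$n_rows * r$square_edge_cm + m)
}

rotate2 <- function(p, angle_deg) {
  t <- angle_deg * pi / 180
  cbind(cos(t) * p[, 1] - sin(t) * p[, 2],
        sin(t) * p[, 1] + cos(t) * p[, 2])
}

# indicator for chart points inside the shape
shape_indicator <- function(s, u, v) {
  du <- u - s$center[1]; dv <- v - s$center[2]
  t <- -s$angle * pi / 180
  ru <- cos(t) * du - sin(t) * dv
  rv <- sin(t) * du + cos(t) * dv
  switch(s$type,
    ellipse   = (ru / s$a)^2 + (rv / s$b)^2 <= 1,
    rectangle = abs(ru) <= s$w / 2 & abs(rv) <= s$h / 2,
    polygon   = points_in_polygon(ru, rv, s$vertices))
}

# chart-space scene colors: skin + ruler + shape. Returns list(r, g, b, shape)
sample_chart <- function(spec, u, v, noise_fn) {
  skin_base <- c(0.80, 0.62, 0.52)
  wound_col <- c(0.45, 0.13, 0.11)
  n1 <- noise_fn(u, v)
  r <- skin_base[1] + 0.035 * n1
  g <- skin_base[2] + 0.030 * n1
  b <- skin_base[3] + 0.030 * n1

  sh <- shape_indicator(spec$shape, u, v)
  r[sh] <- wound_col[1] + 0.02 * n1[sh]
  g[sh] <- wound_col[2] + 0.015 * n1[sh]
  b[sh] <- wound_col[3] + 0.015 * n1[sh]

  rs <- spec$ruler; o <- spec$ruler_offset; e <- rs$square_edge_cm
  bu <- u - o[1]; bv <- v - o[2]
  wbd <- rs$n_cols * e; hbd <- rs$n_rows * e; m <- rs$border_cm
  onb <- bu >= -m & bu <= wbd + m & bv >= -m & bv <= hbd + m
  if (any(onb)) {
    r[onb] <- 0.98; g[onb] <- 0.98; b[onb] <- 0.98
    onc <- bu >= 0 & bu < wbd & bv >= 0 & bv < hbd
    if (any(onc)) {
      ci <- floor(bu[onc] / e); cj <- floor(bv[onc] / e)
      dark <- (ci + cj) %% 2 == 0
      val <- ifelse(dark, rs$colors[1], rs$colors[2])
      r[onc] <- val; g[onc] <- val; b[onc] <- val
    }
  }
  list(r = clamp(r, 0, 1), g = clamp(g, 0, 1), b = clamp(b, 0, 1), shape = sh)
}

# chart (u, v) -> world 3D points on the support surface
chart_to_world <- function(spec, u, v) {
  if (spec$support$type == "flat") {
    cbind(u, v, 0)
  } else {
    r <- spec$support$radius_cm
    th <- v / r
    cbind(u, r * sin(th), r * (1 - cos(th)))
  }
}

# ray-cast pixel centers onto the support; returns list(u, v, hit)
cast_to_chart <- function(spec, camera, ox = 0, oy = 0) {
  rays <- camera_rays(camera, ox, oy)
  o <- rays$origin
  if (spec$support$type == "flat") {
    tt <- -o[3] / rays$dz
    hit <- rays$dz > 0 & tt > 0
    u <- o[1] + tt * rays$dx
    v <- o[2] + tt * rays$dy
  } else {
    r <- spec$support$radius_cm
    # cylinder axis along x at (y = 0, z = r); surface touches origin
    a <- rays$dy^2 + rays$dz^2
    b <- 2 * (o[2] * rays$dy + (o[3] - r) * rays$dz)
    cc <- o[2]^2 + (o[3] - r)^2 - r^2
    disc <- b^2 - 4 * a * cc
    hit <- disc >= 0
    tt <- matrix(NA_real_, nrow(a), ncol(a))
    tt[hit] <- (-b[hit] - sqrt(disc[hit])) / (2 * a[hit])
    hit <- hit & !is.na(tt) & tt > 0
    x <- o[1] + tt * rays$dx
    y <- o[2] + tt * rays$dy
    z <- o[3] + tt * rays$dz
    u <- x
    v <- r * atan2(y, r - z)
  }
  u[!hit] <- NA; v[!hit] <- NA
  list(u = u, v = v, hit = hit)
}

# shared renderer behind the flat / cylinder entry points.
# `supersample` subpixel rays per axis are averaged per pixel so that checker
# edges antialias and sub-pixel detection is meaningful.
render_phantom <- function(spec, camera, supersample = 2L) {
  if (spec$support$type == "cylinder") {
    bb <- shape_bbox(spec$shape)
    if ((bb[4] - bb[2]) / spec$support$radius_cm > pi)
      stopf("shape angular extent exceeds pi: self-occluding on this cylinder")
  }
  noise_fn <- value_noise_2d(spec$texture_seed)
  h <- camera$size[2]; w <- camera$size[1]
  n <- max(1L, as.integer(supersample))
  offs <- (seq_len(n) - (n + 1) / 2) / n
  ri <- gi <- bi <- cov <- matrix(0, h, w)
  for (ox in offs) for (oy in offs) {
    ch <- cast_to_chart(spec, camera, ox, oy)
    rs <- gs <- bs <- matrix(0.05, h, w)  # dark background off the support
    ms <- matrix(0, h, w)
    if (any(ch$hit)) {
      sc <- sample_chart(spec, ch$u[ch$hit], ch$v[ch$hit], noise_fn)
      rs[ch$hit] <- sc$r; gs[ch$hit] <- sc$g; bs[ch$hit] <- sc$b
      ms[ch$hit] <- as.numeric(sc$shape)
    }
    ri <- ri + rs; gi <- gi + gs; bi <- bi + bs; cov <- cov + ms
  }
  img <- array(c(ri, gi, bi) / n^2, dim = c(h, w, 3))
  msk <- cov / n^2 >= 0.5
  if (!any(msk)) stopf("shape not visible in the rendered image")
  if (any(msk[1, ]) || any(msk[h, ]) || any(msk[, 1]) || any(msk[, w]))
    stopf("shape projects outside image bounds")

  # interior checkerboard corners (two corner rows), exact ground truth
  rs <- spec$ruler; o <- spec$ruler_offset; e <- rs$square_edge_cm
  cu <- o[1] + e * seq_len(rs$n_cols - 1)
  corners <- NULL
  for (j in seq_len(rs$n_rows - 1)) {
    cw <- chart_to_world(spec, cu, rep(o[2] + j * e, length(cu)))
    corners <- rbind(corners, project_points(camera, cw))
  }
  truth <- structure(list(true_area_cm2 = spec$shape$area_cm2,
                          shape_mask = msk,
                          ruler_corner_px = corners,
                          seg_threshold = 0.44,
                          support_params = spec$support,
                          spec = spec),
                     class = "phantom_truth")
  list(image = img, truth = truth)
}

#' Render a flat phantom photograph
#'
#' Renders an RGB image of a flat scene holding a shape of known area, a
#' checkerboard ruler and a skin-toned noise background, by pinhole projection.
#' The returned ground truth carries the exact analytic shape area, the
#' per-pixel shape mask and the projected interior ruler corners.
#'
#' @param spec a [phantom_scene_spec()] with flat support.
#' @param camera a [camera_model()], e.g. [overhead_camera()].
#' @return `list(image, truth)`; `image` is an H x W x 3 array in `[0, 1]`,
#'   `truth` a `phantom_truth` object.
#' @export
render_flat_phantom <- function(spec, camera = overhead_camera()) {
  if (spec$support$type != "flat") stopf("spec support is not flat")
  render_phantom(spec, camera)
}

#' Generate a reproducible batch of phantom scenes
#'
#' Draws shapes with areas uniform over the validation range 1.13-28.09 cm^2,
#' cycling through ellipse / rectangle / hexagon, with mild random aspect,
#' rotation and camera tilt, on the requested supports.
#'
#' @param n number of phantoms.
#' @param support one of `"flat"`, `"low"` (cylinder r = 19.5 cm), `"high"`
#'   (cylinder r = 8.5 cm), `"mixed"` (equal thirds), or a vector of length
#'   `n`.
#' @param seed RNG seed; the batch is fully determined by it.
#' @param tilt_max_deg camera tilt drawn uniformly from `[0, tilt_max_deg]`.
#' @param area_range_cm2 area range to draw from.
#' @return List of `list(spec, camera, tilt_deg, support)` entries.
#' @export
generate_phantom_batch <- function(n, support = "flat", seed = 1,
                                   tilt_max_deg = 0,
                                   area_range_cm2 = c(1.13, 28.09)) {
  set.seed(as.integer(seed))
  if (length(support) == 1L && support == "mixed")
    support <- rep(c("flat", "low", "high"), length.out = n)
  support <- rep(support, length.out = n)
  types <- rep(c("ellipse", "rectangle", "polygon"), length.out = n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sup <- switch(support[i],
                  flat = "flat",
                  low = list(type = "cylinder", radius_cm = 19.5),
                  high = list(type = "cylinder", radius_cm = 8.5),
                  stopf("unknown support class '%s'", support[i]))
    area <- stats::runif(1, area_range_cm2[1], area_range_cm2[2])
    aspect <- stats::runif(1, 1.1, 1.8)
    angle <- if (types[i] == "polygon") 0 else stats::runif(1, -10, 10)
    tilt <- stats::runif(1, 0, tilt_max_deg)
    tseed <- sample.int(1e6, 1)
    shape <- phantom_shape(types[i], area_cm2 = area, aspect = aspect,
                           center = c(0, 1.2), angle = angle)
    spec <- phantom_scene_spec(support = sup, shape = shape,
                               texture_seed = tseed)
    out[[i]] <- list(spec = spec, camera = overhead_camera(tilt_deg = tilt),
                     tilt_deg = tilt, support = support[i])
  }
  out
}

#' Render and measure a phantom batch
#'
#' Renders each scene, derives the user ROI from the true mask (a loose
#' rectangle, as a user would draw), runs the full 2D measurement with
#' threshold segmentation and tabulates errors against the analytic truth.
#'
#' @param batch a [generate_phantom_batch()] result.
#' @param verbose print one line per phantom.
#' @return Data frame with one row per phantom: truth, measurement, absolute
#'   and relative (%) error, support class, warnings/exclusion reason.
#' @export
measure_phantom_batch <- function(batch, verbose = FALSE) {
  rows <- lapply(seq_along(batch), function(i) {
    b <- batch[[i]]
    r <- render_phantom(b$spec, b$camera)
    roi <- roi_around_mask(r$truth$shape_mask)
    res <- tryCatch(
      measure_area_2d(r$image, roi, b$spec$ruler, r$truth$seg_threshold),
      error = function(e) e)
    if (inherits(res, "error")) {
      row <- data.frame(i = i, support = b$support,
                        true_area_cm2 = r$truth$true_area_cm2,
                        measured_cm2 = NA_real_, abs_error_cm2 = NA_real_,
                        rel_error_pct = NA_real_,
                        note = conditionMessage(res))
    } else {
      row <- data.frame(i = i, support = b$support,
                        true_area_cm2 = r$truth$true_area_cm2,
                        measured_cm2 = res$total_area_cm2,
                        abs_error_cm2 = abs(res$total_area_cm2 - r$truth$true_area_cm2),
                        rel_error_pct = 100 * abs(res$total_area_cm2 - r$truth$true_area_cm2) /
                          r$truth$true_area_cm2,
                        note = paste(res$warnings, collapse = "; "))
    }
    if (verbose)
      message(sprintf("phantom %d (%s): true %.2f measured %s", i, b$support,
                      row$true_area_cm2,
                      ifelse(is.na(row$measured_cm2), row$note,
                             sprintf("%.2f (%.2f%%)", row$measured_cm2,
                                     row$rel_error_pct))))
    row
  })
  do.call(rbind, rows)
}

#' Render a cylindrical phantom photograph
#'
#' Same scene as [render_flat_phantom()] but wrapped onto a cylinder of the
#' given radius (axis along world x, apex touching the origin).  Wrapping is an
#' isometry of the chart, so the analytic chart area remains the exact ground
#' truth, while the rendered ruler follows the surface curvature.
#'
#' @inheritParams render_flat_phantom
#' @return `list(image, truth)`.
#' @export
render_cylinder_phantom <- function(spec, camera = overhead_camera()) {
  if (spec$support$type != "cylinder") stopf("spec support is not a cylinder")
  render_phantom(spec, camera)
}
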