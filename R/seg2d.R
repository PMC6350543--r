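#' Per-pixel filter-bank features on RGB and LAB
#'
#' Builds the feature stack for the wound/skin pixel classifier: for each of
#' the six channels (R, G, B, L, a, b) it computes Gaussian smoothings at two
#' scales, the gradient magnitude and the Laplacian, in this fixed order:
#' `<channel>_gauss1`, `<channel>_gauss2`, `<channel>_gradmag`,
#' `<channel>_laplace` for channels `R, G, B, L, a, b` (24 features).
#'
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param sigmas the two Gaussian scales (px).
#' @return A `feature_stack`: H x W x 24 array with a `feature_names`
#'   attribute.
#' @export
extract_features <- function(image, sigmas = c(1, 2)) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stopf("extract_features expects a 3-channel image")
  lab <- rgb_to_lab(image)
  chans <- list(R = image[, , 1], G = image[, , 2], B = image[, , 3],
                L = lab[, , 1], a = lab[, , 2], b = lab[, , 3])
  feats <- list(); nms <- character(0)
  for (cn in names(chans)) {
    ch <- chans[[cn]]
    g1 <- gauss_blur(ch, sigmas[1])
    g2 <- gauss_blur(ch, sigmas[2])
    gr <- image_gradients(g1)
    gm <- sqrt(gr$gx^2 + gr$gy^2)
    h <- nrow(g1); w <- ncol(g1)
    lap <- g1[c(1, 1:(h - 1)), ] + g1[c(2:h, h), ] +
           g1[, c(1, 1:(w - 1))] + g1[, c(2:w, w)] - 4 * g1
    feats <- c(feats, list(g1, g2, gm, lap))
    nms <- c(nms, paste0(cn, "_", c("gauss1", "gauss2", "gradmag", "laplace")))
  }
  out <- array(unlist(feats, use.names = FALSE),
               dim = c(dim(image)[1], dim(image)[2], length(feats)))
  attr(out, "feature_names") <- nms
  class(out) <- "feature_stack"
  out
}

feature_matrix <- function(stack) {
  d <- dim(stack)
  m <- matrix(as.numeric(stack), ncol = d[3])
  colnames(m) <- attr(stack, "feature_names")
  m
}

#' Train the wound/skin random-forest pixel classifier
#'
#' @param stacks a `feature_stack` or list of them.
#' @param label_masks binary mask (or list), 1 = wound, matching each stack.
#' @param n_trees number of trees.
#' @param seed RNG seed: training is reproducible.
#' @param max_pixels maximum training pixels sampled per image.
#' @return A `wound_classifier` (serializable with [saveRDS()]).
#' @export
train_classifier <- function(stacks, label_masks, n_trees = 100, seed = 1,
                             max_pixels = 1e5) {
  if (inherits(stacks, "feature_stack")) stacks <- list(stacks)
  if (!is.list(label_masks)) label_masks <- list(label_masks)
  if (length(stacks) < 1L) stopf("need at least one training image")
  if (length(stacks) != length(label_masks)) stopf("stacks/labels length mismatch")
  set.seed(as.integer(seed))
  Xs <- list(); ys <- list()
  for (i in seq_along(stacks)) {
    X <- feature_matrix(stacks[[i]])
    y <- as.integer(label_masks[[i]] > 0)
    if (length(y) != nrow(X)) stopf("label mask size mismatch")
    idx <- seq_along(y)
    if (length(idx) > max_pixels) idx <- sample(idx, max_pixels)
    Xs[[i]] <- X[idx, , drop = FALSE]; ys[[i]] <- y[idx]
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  if (length(unique(y)) < 2L) stopf("training labels contain a single class")
  rf <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                   ntree = n_trees)
  structure(list(rf = rf, feature_names = colnames(X)),
            class = "wound_classifier")
}

#' Predict the per-pixel wound probability map
#'
#' @param model a [train_classifier()] result.
#' @param image RGB array (features are computed internally) or a
#'   `feature_stack`.
#' @return H x W matrix of wound probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, image) {
  stack <- if (inherits(image, "feature_stack")) image else extract_features(image)
  X <- feature_matrix(stack)
  if (!identical(colnames(X), model$feature_names))
    stopf("feature configuration does not match the trained model")
  p <- stats::predict(model$rf, X, type = "prob")[, "1"]
  matrix(p, dim(stack)[1], dim(stack)[2])
}

#' Binarize a probability map with Otsu's threshold
#'
#' The threshold maximizes the between-class variance of the map's 256-bin
#' histogram.
#'
#' @param prob numeric matrix with values in `[0, 1]`.
#' @return Logical mask; the chosen threshold is attached as attribute
#'   `threshold`.
#' @export
otsu_binarize <- function(prob) {
  if (any(prob < 0 | prob > 1)) stopf("probability map values must lie in [0, 1]")
  if (diff(range(prob)) < .Machine$double.eps) stopf("constant probability map: no threshold exists")
  thr <- EBImage::otsu(EBImage::Image(prob), range = c(0, 1), levels = 256)
  mask <- prob > thr
  attr(mask, "threshold") <- thr
  mask
}

#' User region-of-interest polygon
#'
#' @param vertices n x 2 matrix of 0-based pixel vertices (x, y), n >= 3.
#' @return A `roi_polygon`.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stopf("ROI polygon needs at least 3 vertices")
  if (polygon_area(vertices) <= 0) stopf("degenerate ROI polygon")
  if (polygon_self_intersects(vertices)) stopf("ROI polygon must be simple")
  structure(list(vertices = vertices), class = "roi_polygon")
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[i %% n + 1, ])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    d1 * d2 < 0 && d3 * d4 < 0
  }
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (i == 1 && j == n) next
    si <- seg(i); sj <- seg(j)
    if (inter(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(TRUE)
  }
  FALSE
}

roi_vertices <- function(roi) {
  if (inherits(roi, "roi_polygon")) roi$vertices else as.matrix(roi)
}

#' Mask out everything outside the ROI polygon
#'
#' @param mask logical/binary H x W matrix.
#' @param roi a [roi_polygon()] or n x 2 vertex matrix; must lie within the
#'   image bounds.
#' @return Mask with all pixels outside the polygon set to 0 (even-odd rule).
#' @export
apply_roi <- function(mask, roi) {
  v <- roi_vertices(roi)
  if (nrow(v) < 3L || polygon_area(v) <= 0) stopf("degenerate ROI polygon")
  h <- nrow(mask); w <- ncol(mask)
  if (any(v[, 1] < 0 | v[, 1] > w - 1 | v[, 2] < 0 | v[, 2] > h - 1))
    stopf("ROI polygon outside image bounds")
  idx <- which(mask > 0)
  if (!length(idx)) return(mask)
  px <- (idx - 1) %/% h   # 0-based x
  py <- (idx - 1) %% h    # 0-based y
  inside <- points_in_polygon(px, py, v)
  mask[idx[!inside]] <- FALSE
  mask
}

#' Rectangular ROI around a mask, as drawn loosely by a user
#'
#' @param mask logical matrix.
#' @param margin_px margin around the mask's bounding box.
#' @return A [roi_polygon()] clipped to the image.
#' @export
roi_around_mask <- function(mask, margin_px = 15) {
  idx <- which(mask > 0)
  if (!length(idx)) stopf("empty mask")
  h <- nrow(mask)
  px <- (idx - 1) %/% h; py <- (idx - 1) %% h
  x0 <- max(0, min(px) - margin_px); x1 <- min(ncol(mask) - 1, max(px) + margin_px)
  y0 <- max(0, min(py) - margin_px); y1 <- min(h - 1, max(py) + margin_px)
  roi_polygon(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}

#' Segment by a global intensity threshold
#'
#' Simple luminance thresholding, the segmentation used for phantom
#' evaluation (each phantom gets one suitable threshold).
#'
#' @param image RGB array or grayscale matrix.
#' @param threshold luminance threshold in `[0, 1]`.
#' @param mode `"below"` marks pixels darker than the threshold as wound
#'   (lesions are darker than skin), `"above"` the reverse.
#' @return Logical H x W mask.
#' @export
threshold_segment <- function(image, threshold, mode = c("below", "above")) {
  mode <- match.arg(mode)
  g <- rgb_to_gray(image)
  if (mode == "below") g < threshold else g > threshold
}
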