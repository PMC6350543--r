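#' Write a mesh or point cloud as ASCII PLY
#'
#' Vertices carry optional `red/green/blue` (uchar) and `gray` (float)
#' properties; faces are written for meshes.
#'
#' @param x a [labeled_mesh()] or `sparse_cloud`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path) {
  if (inherits(x, "labeled_mesh")) {
    V <- x$vertices; F <- x$faces; gray <- x$gray; col <- NULL
  } else {
    V <- x$points; F <- NULL; gray <- x$gray
    col <- if (!is.null(x$colors)) round(clamp(x$colors, 0, 1) * 255)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(col))
    writeLines(c("property uchar red", "property uchar green",
                 "property uchar blue"), con)
  if (!is.null(gray)) writeLines("property float gray", con)
  if (!is.null(F))
    writeLines(c(sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices"), con)
  writeLines("end_header", con)
  tab <- V
  if (!is.null(col)) tab <- cbind(tab, col)
  if (!is.null(gray)) tab <- cbind(tab, gray)
  utils::write.table(tab, con, row.names = FALSE, col.names = FALSE)
  if (!is.null(F))
    utils::write.table(cbind(3L, F - 1L), con, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' Read an ASCII PLY file written by this package
#'
#' @param path PLY file.
#' @return A [labeled_mesh()] if faces are present, otherwise a list with
#'   `points` (+ `colors`/`gray` if stored).
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2])) stopf("not an ASCII PLY file")
  hend <- match("end_header", lines)
  header <- lines[seq_len(hend)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", header, value = TRUE)))
  props <- sub("^property \\S+ ", "", grep("^property (float|uchar) ", header, value = TRUE))
  vl <- lines[hend + seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))), nv,
               length(props), byrow = TRUE)
  colnames(vm) <- props
  pts <- unname(vm[, c("x", "y", "z"), drop = FALSE])
  gray <- if ("gray" %in% props) vm[, "gray"] else NULL
  colors <- if (all(c("red", "green", "blue") %in% props))
    vm[, c("red", "green", "blue"), drop = FALSE] / 255 else NULL
  if (length(nf) && nf > 0) {
    fl <- lines[hend + nv + seq_len(nf)]
    fm <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))), nf, 4,
                 byrow = TRUE)
    labeled_mesh(pts, fm[, 2:4] + 1L, gray = gray %||% rep(0, nv))
  } else {
    list(points = pts, colors = colors, gray = gray)
  }
}

#' Write phantom ground truth as a JSON sidecar
#'
#' @param truth a `phantom_truth`.
#' @param image_path path of the rendered image; the sidecar gets the same
#'   stem with extension `.truth.json`, and the shape mask the stem plus
#'   `.mask.png`.
#' @return Sidecar path, invisibly.
#' @export
write_phantom_truth <- function(truth, image_path) {
  stem <- sub("\\.png$", "", image_path)
  side <- paste0(stem, ".truth.json")
  jsonlite::write_json(list(true_area_cm2 = truth$true_area_cm2,
                            seg_threshold = truth$seg_threshold,
                            support = truth$support_params,
                            ruler_corner_px = truth$ruler_corner_px),
                       side, auto_unbox = TRUE, digits = NA)
  png::writePNG(truth$shape_mask * 1, paste0(stem, ".mask.png"))
  invisible(side)
}

#' Read / write an ROI polygon as JSON
#'
#' Format: `{"polygon": [[x, y], ...]}` with 0-based pixel coordinates.
#'
#' @param path JSON file.
#' @return A [roi_polygon()].
#' @export
read_roi_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_polygon(as.matrix(o$polygon))
}

#' @rdname read_roi_json
#' @param roi a [roi_polygon()].
#' @export
write_roi_json <- function(roi, path) {
  jsonlite::write_json(list(polygon = unname(roi_vertices(roi))), path,
                       digits = NA)
  invisible(path)
}
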