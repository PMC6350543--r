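#' Labeled triangle mesh
#'
#' @param vertices n x 3 matrix (mesh units).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param gray per-vertex gray value in `[0, 255]` (wound-ness label).
#' @param scale_cm_per_unit metric scale factor; `NA` until calibrated.
#' @return A `labeled_mesh`.
#' @export
labeled_mesh <- function(vertices, faces, gray = NULL,
                         scale_cm_per_unit = NA_real_) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  if (ncol(vertices) != 3L) stopf("vertices must be n x 3")
  if (ncol(faces) != 3L) stopf("faces must be m x 3")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stopf("face indices out of range")
  if (is.null(gray)) gray <- rep(0, nrow(vertices))
  if (any(gray < 0 | gray > 255)) stopf("gray values must lie in [0, 255]")
  if (!is.na(scale_cm_per_unit) && scale_cm_per_unit <= 0)
    stopf("scale must be > 0")
  # drop degenerate (zero-area) faces
  a <- face_areas(vertices, faces)
  faces <- faces[a > 1e-12 * stats::median(a[a > 0], na.rm = TRUE), , drop = FALSE]
  structure(list(vertices = vertices, faces = faces, gray = as.numeric(gray),
                 scale_cm_per_unit = scale_cm_per_unit),
            class = "labeled_mesh")
}

face_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("labeled_mesh: %d vertices, %d faces, scale = %s cm/unit, %d white vertices\n",
              nrow(x$vertices), nrow(x$faces),
              ifelse(is.na(x$scale_cm_per_unit), "uncalibrated",
                     format(x$scale_cm_per_unit, digits = 4)),
              sum(x$gray > 127)))
  invisible(x)
}

#' Triangulate a point cloud into a surface mesh
#'
#' 2.5D Delaunay meshing: the points are projected onto their total
#' least-squares plane, triangulated in that plane (Delaunay), and the
#' connectivity lifted back to 3D.  Suitable for wound surfaces, which are
#' height fields over a base plane.
#'
#' @param cloud a `sparse_cloud`, or an n x 3 point matrix.
#' @param gray optional per-vertex gray values (taken from the cloud if
#'   present).
#' @return A [labeled_mesh()] (unscaled).
#' @export
triangulate_mesh <- function(cloud, gray = NULL) {
  if (inherits(cloud, "sparse_cloud")) {
    pts <- cloud$points
    if (is.null(gray)) gray <- cloud$gray
  } else pts <- as.matrix(cloud)
  if (nrow(pts) < 3L) stopf("need at least 3 points")
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  sv <- svd(pc, nu = 0)
  if (sv$d[2] < 1e-9 * sv$d[1]) stopf("points are collinear")
  B <- sv$v[, 1:2]  # in-plane basis
  uv <- pc %*% B
  dd <- deldir::deldir(uv[, 1], uv[, 2], suppressMsge = TRUE)
  faces <- deldir::triMat(dd)
  if (is.null(gray)) gray <- rep(0, nrow(pts))
  labeled_mesh(pts, faces, gray = gray)
}

mesh_edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  list(edges = e, key = key, counts = table(key))
}

# boundary loops as ordered vertex index vectors
boundary_loops <- function(faces) {
  et <- mesh_edge_table(faces)
  bkey <- names(et$counts)[et$counts == 1L]
  if (!length(bkey)) return(list())
  be <- do.call(rbind, strsplit(bkey, " "))
  be <- matrix(as.integer(be), ncol = 2)
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  visited_edge <- new.env(hash = TRUE)
  loops <- list()
  for (k in seq_len(nrow(be))) {
    ek <- paste(be[k, 1], be[k, 2])
    if (!is.null(visited_edge[[ek]])) next
    loop <- c(be[k, 1], be[k, 2])
    visited_edge[[ek]] <- TRUE
    repeat {
      cur <- loop[length(loop)]; prev <- loop[length(loop) - 1]
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (nb in nbrs) {
        ek2 <- paste(min(cur, nb), max(cur, nb))
        if (nb != prev && is.null(visited_edge[[ek2]])) { nxt <- nb; break }
      }
      if (is.na(nxt)) break
      visited_edge[[paste(min(cur, nxt), max(cur, nxt))]] <- TRUE
      if (nxt == loop[1]) break
      loop <- c(loop, nxt)
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Laplacian smoothing and hole filling
#'
#' Moves every interior vertex towards the mean of its 1-ring neighbors by
#' `lambda_factor`, for `iterations` rounds (boundary vertices stay fixed),
#' then triangulates interior holes by a fan from each hole-loop centroid.
#' A hole is any closed boundary loop shorter than 75% of the longest
#' boundary loop (the longest is the outer boundary).
#'
#' @param mesh a [labeled_mesh()].
#' @param iterations smoothing rounds.
#' @param lambda_factor step towards the neighborhood mean in `[0, 1]`.
#' @return The smoothed, hole-filled `labeled_mesh`.
#' @export
smooth_and_fill <- function(mesh, iterations = 10, lambda_factor = 0.5) {
  V <- mesh$vertices; F <- mesh$faces
  n <- nrow(V)
  et <- mesh_edge_table(F)
  e <- unique(cbind(pmin(et$edges[, 1], et$edges[, 2]),
                    pmax(et$edges[, 1], et$edges[, 2])))
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  bnd <- unique(unlist(boundary_loops(F)))
  interior <- setdiff(seq_len(n), bnd)
  lam <- lambda_factor
  for (it in seq_len(iterations)) {
    M <- as.matrix(A %*% V) / pmax(deg, 1)
    V[interior, ] <- (1 - lam) * V[interior, , drop = FALSE] +
                     lam * M[interior, , drop = FALSE]
  }
  gray <- mesh$gray
  loops <- boundary_loops(F)
  if (length(loops) > 1L) {
    len <- vapply(loops, function(l) {
      p <- V[c(l, l[1]), , drop = FALSE]
      sum(sqrt(rowSums(diff(p)^2)))
    }, numeric(1))
    outer_i <- which.max(len)
    for (li in seq_along(loops)) {
      if (li == outer_i || len[li] >= 0.75 * len[outer_i]) next
      l <- loops[[li]]
      cen <- colMeans(V[l, , drop = FALSE])
      V <- rbind(V, cen)
      gray <- c(gray, mean(gray[l]))
      ci <- nrow(V)
      nf <- cbind(l, c(l[-1], l[1]), ci)
      F <- rbind(F, nf)
    }
  }
  labeled_mesh(V, F, gray = gray, scale_cm_per_unit = mesh$scale_cm_per_unit)
}

#' Reference segment of known physical length
#'
#' @param endpoint_a,endpoint_b 3-vectors in mesh units.
#' @param true_length_cm the physically measured length (cm).
#' @return A `reference_segment`.
#' @export
reference_segment <- function(endpoint_a, endpoint_b, true_length_cm) {
  if (true_length_cm <= 0) stopf("true_length_cm must be > 0")
  if (sqrt(sum((endpoint_a - endpoint_b)^2)) <= 0)
    stopf("reference endpoints coincide")
  structure(list(a = as.numeric(endpoint_a), b = as.numeric(endpoint_b),
                 true_length_cm = true_length_cm),
            class = "reference_segment")
}

#' Calibrate the metric scale of a mesh from a reference length
#'
#' @param mesh a [labeled_mesh()].
#' @param ref a [reference_segment()] with endpoints in mesh units.
#' @return The mesh with `scale_cm_per_unit = true_length_cm / ||a - b||`.
#' @export
calibrate_scale <- function(mesh, ref) {
  len <- sqrt(sum((ref$a - ref$b)^2))
  if (len <= 0) stopf("zero-length reference segment")
  mesh$scale_cm_per_unit <- ref$true_length_cm / len
  mesh
}

#' Wound surface area of a labeled mesh
#'
#' Sums the areas of all triangles having at least two white vertices
#' (gray value above the threshold), scaled to cm^2.
#'
#' @param mesh a calibrated [labeled_mesh()].
#' @param gray_threshold whiteness threshold (default 127).
#' @return An `area_result` with `total_area_cm2` and the qualifying face
#'   count.
#' @export
measure_area_3d <- function(mesh, gray_threshold = 127) {
  if (is.na(mesh$scale_cm_per_unit)) stopf("mesh is not scaled; run calibrate_scale first")
  white <- mesh$gray > gray_threshold
  nw <- white[mesh$faces[, 1]] + white[mesh$faces[, 2]] + white[mesh$faces[, 3]]
  sel <- nw >= 2
  areas <- face_areas(mesh$vertices, mesh$faces[sel, , drop = FALSE])
  total <- sum(areas) * mesh$scale_cm_per_unit^2
  structure(list(total_area_cm2 = total,
                 per_square = data.frame(),
                 n_faces = sum(sel), warnings = character(0)),
            class = "area_result")
}

#' Total surface area of a mesh in mesh units squared
#'
#' @param mesh a [labeled_mesh()].
#' @return Sum of all face areas (mesh units^2).
#' @export
mesh_surface_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' Closed unit-style cube mesh (12 triangles)
#'
#' @param edge edge length.
#' @return A [labeled_mesh()] with all-white vertices.
#' @export
cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = edge
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = edge
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = edge
  labeled_mesh(v, f, gray = rep(255, 8), scale_cm_per_unit = 1)
}

#' Closed UV-sphere mesh
#'
#' @param r radius.
#' @param n_lat,n_lon latitude/longitude resolution.
#' @return A [labeled_mesh()] with all-white vertices.
#' @export
uv_sphere_mesh <- function(r = 3, n_lat = 60, n_lon = 90) {
  phi <- seq(0, pi, length.out = n_lat + 1)       # 0 = north pole
  lam <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  vid <- function(i, j) {                          # i in 0..n_lat, j in 0..n_lon-1
    if (i == 0) return(1L)
    if (i == n_lat) return(2L)
    2L + (i - 1L) * n_lon + (j %% n_lon) + 1L
  }
  V <- rbind(c(0, 0, r), c(0, 0, -r))
  for (i in 1:(n_lat - 1)) for (j in 0:(n_lon - 1))
    V <- rbind(V, c(r * sin(phi[i + 1]) * cos(lam[j + 1]),
                    r * sin(phi[i + 1]) * sin(lam[j + 1]),
                    r * cos(phi[i + 1])))
  F <- NULL
  for (j in 0:(n_lon - 1)) {
    F <- rbind(F, c(vid(0, 0), vid(1, j), vid(1, j + 1)))
    F <- rbind(F, c(vid(n_lat, 0), vid(n_lat - 1, j + 1), vid(n_lat - 1, j)))
  }
  if (n_lat > 2) for (i in 1:(n_lat - 2)) for (j in 0:(n_lon - 1)) {
    a <- vid(i, j); b <- vid(i + 1, j); c <- vid(i + 1, j + 1); d <- vid(i, j + 1)
    F <- rbind(F, c(a, b, c), c(a, c, d))
  }
  labeled_mesh(V, F, gray = rep(255, nrow(V)), scale_cm_per_unit = 1)
}
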