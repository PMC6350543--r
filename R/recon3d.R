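#' Ordered frame sequence for structure from motion
#'
#' @param frames list of RGB arrays (or grayscale matrices), constant size.
#' @param masks optional list of binary masks aligned with the frames.
#' @return A `frame_sequence`.
#' @export
frame_sequence <- function(frames, masks = NULL) {
  if (length(frames) < 2L) stopf("need at least 2 frames")
  dims <- vapply(frames, function(f) dim(f)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("frames must share one image size")
  if (!is.null(masks) && length(masks) != length(frames))
    stopf("masks must align with frames")
  structure(list(frames = frames, masks = masks,
                 index = seq_along(frames)),
            class = "frame_sequence")
}

#' Extract an ordered, de-duplicated frame sequence
#'
#' Reads numbered PNG frames from a directory (or takes an in-memory list),
#' applies the stride, and drops consecutive duplicates.  Video containers
#' are not decoded; extract frames to a directory first.
#'
#' @param source directory of PNG frames, character vector of PNG paths, or a
#'   list of image arrays.
#' @param stride keep every `stride`-th frame.
#' @return A [frame_sequence()].
#' @export
extract_frames <- function(source, stride = 1L) {
  if (is.character(source) && length(source) == 1L && dir.exists(source)) {
    source <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE))
  }
  if (is.character(source)) {
    if (any(grepl("\\.(mp4|mov|avi|mkv)$", tolower(source))))
      stopf("video decoding is not supported; extract frames to PNG first")
    if (!length(source) || !all(file.exists(source))) stopf("unreadable frame source")
    frames <- lapply(source, png::readPNG)
  } else if (is.list(source)) {
    frames <- source
  } else stopf("unreadable frame source")
  frames <- frames[seq(1, length(frames), by = stride)]
  if (length(frames) > 1L) {
    keep <- c(TRUE, vapply(2:length(frames), function(i)
      !identical(frames[[i]], frames[[i - 1]]), logical(1)))
    frames <- frames[keep]
  }
  if (length(frames) < 2L) stopf("need at least 2 distinct frames after striding")
  frame_sequence(frames)
}

# ---- feature detection and matching ---------------------------------------

# Shi-Tomasi style interest points: minima eigenvalue of the structure
# tensor.  Selection is tiled so that low-contrast regions (e.g. the darker
# wound area) keep their share of features.
harris_features <- function(gray, max_n = 900, min_separation = 6,
                            quality = 0.005, tiles = c(16L, 12L)) {
  maps <- structure_tensor_maps(gray, gradient_sigma = 1, window_sigma = 2)
  pts <- detect_corners(maps, quality = quality, min_separation = min_separation)
  if (nrow(pts) <= max_n) return(pts)
  tx <- pmin(floor(pts$x / ncol(gray) * tiles[1]), tiles[1] - 1)
  ty <- pmin(floor(pts$y / nrow(gray) * tiles[2]), tiles[2] - 1)
  tid <- tx + tiles[1] * ty
  # round-robin by within-tile response rank: every tile contributes its
  # best features before any tile contributes deeper ones
  rank_in_tile <- stats::ave(-pts$response, tid, FUN = rank)
  ord <- order(rank_in_tile, -pts$response)
  pts[sort(ord[seq_len(max_n)]), , drop = FALSE]
}

# normalized intensity patch descriptors (side = 2*rad+1), n x side^2
patch_descriptors <- function(gray, pts, rad = 5L) {
  off <- expand.grid(ox = -rad:rad, oy = -rad:rad)
  D <- matrix(NA_real_, nrow(pts), nrow(off))
  for (k in seq_len(nrow(off)))
    D[, k] <- bilinear_sample(gray, pts$x + off$ox[k], pts$y + off$oy[k], fill = NA)
  ok <- stats::complete.cases(D)
  D <- D - rowMeans(D)
  nr <- sqrt(rowSums(D^2))
  D <- D / pmax(nr, 1e-9)
  list(D = D, ok = ok & nr > 1e-6)
}

# mutual-best matches with a distance ratio test; returns index pairs
match_descriptors <- function(d1, d2, ratio = 0.9) {
  ok1 <- which(d1$ok); ok2 <- which(d2$ok)
  if (length(ok1) < 2L || length(ok2) < 2L) return(cbind(integer(0), integer(0)))
  S <- d1$D[ok1, , drop = FALSE] %*% t(d2$D[ok2, , drop = FALSE])
  best <- max.col(S)
  n1 <- length(ok1)
  s1 <- S[cbind(seq_len(n1), best)]
  S2 <- S; S2[cbind(seq_len(n1), best)] <- -Inf
  s2 <- S2[cbind(seq_len(n1), max.col(S2))]
  dist1 <- sqrt(pmax(2 - 2 * s1, 0)); dist2 <- sqrt(pmax(2 - 2 * s2, 0))
  pass <- s1 > 0.6 & dist1 < ratio * dist2
  # mutual check
  bt <- max.col(t(S))
  mutual <- bt[best] == seq_len(n1)
  sel <- which(pass & mutual)
  cbind(ok1[sel], ok2[best[sel]])
}

# ---- two-view geometry -----------------------------------------------------

intrinsics_matrix <- function(intr) {
  matrix(c(intr$f, 0, intr$cx %||% intr$pp[1],
           0, intr$f, intr$cy %||% intr$pp[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

normalize_px <- function(K, p) {
  cbind((p[, 1] - K[1, 3]) / K[1, 1], (p[, 2] - K[2, 3]) / K[2, 2])
}

eight_point_essential <- function(x1, x2) {
  A <- cbind(x2[, 1] * x1[, 1], x2[, 1] * x1[, 2], x2[, 1],
             x2[, 2] * x1[, 1], x2[, 2] * x1[, 2], x2[, 2],
             x1[, 1], x1[, 2], 1)
  e <- svd(A, nv = 9)$v[, 9]
  E <- matrix(e, 3, 3, byrow = TRUE)
  s <- svd(E)
  s$u %*% diag(c(1, 1, 0)) %*% t(s$v)
}

sampson_px <- function(E, K, p1, p2) {
  Kinv <- solve(K)
  F <- t(Kinv) %*% E %*% Kinv
  x1 <- cbind(p1, 1); x2 <- cbind(p2, 1)
  Fx1 <- x1 %*% t(F)
  Ftx2 <- x2 %*% F
  num <- rowSums(x2 * Fx1)^2
  den <- Fx1[, 1]^2 + Fx1[, 2]^2 + Ftx2[, 1]^2 + Ftx2[, 2]^2
  sqrt(num / pmax(den, 1e-12))
}

# RANSAC essential matrix; p1, p2 are pixel coords (n x 2)
essential_ransac <- function(p1, p2, K, thresh_px = 1, iters = 600) {
  n <- nrow(p1)
  if (n < 8L) stopf("insufficient parallax/texture: fewer than 8 matches")
  if (stats::median(sqrt(rowSums((p1 - p2)^2))) < 0.5)
    stopf("insufficient parallax/texture: near-zero baseline")
  x1 <- normalize_px(K, p1); x2 <- normalize_px(K, p2)
  best <- NULL; best_in <- rep(FALSE, n)
  for (it in seq_len(iters)) {
    s <- sample.int(n, 8L)
    E <- tryCatch(eight_point_essential(x1[s, ], x2[s, ]),
                  error = function(e) NULL)
    if (is.null(E)) next
    inl <- sampson_px(E, K, p1, p2) < thresh_px
    if (sum(inl) > sum(best_in)) { best <- E; best_in <- inl }
  }
  if (is.null(best) || sum(best_in) < 8L)
    stopf("insufficient parallax/texture: fewer than 8 inlier matches")
  E <- eight_point_essential(x1[best_in, , drop = FALSE],
                             x2[best_in, , drop = FALSE])
  inl <- sampson_px(E, K, p1, p2) < thresh_px
  list(E = E, inliers = inl)
}

# linear triangulation for one point given projection matrices and pixels
triangulate_one <- function(Ps, obs) {
  A <- NULL
  for (k in seq_along(Ps)) {
    P <- Ps[[k]]; u <- obs[k, 1]; v <- obs[k, 2]
    A <- rbind(A, u * P[3, ] - P[1, ], v * P[3, ] - P[2, ])
  }
  X <- svd(A, nv = 4)$v[, 4]
  X[1:3] / X[4]
}

# RANSAC homography; returns H and inlier flags (symmetric transfer error)
ransac_homography <- function(p1, p2, thresh_px = 1.5, iters = 300) {
  n <- nrow(p1)
  if (n < 4L) return(list(H = NULL, inliers = rep(FALSE, n)))
  best <- NULL; best_in <- rep(FALSE, n)
  for (it in seq_len(iters)) {
    s <- sample.int(n, 4L)
    H <- tryCatch(homography_from_points(p1[s, ], p2[s, ]),
                  error = function(e) NULL)
    if (is.null(H) || !is.finite(sum(H))) next
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(Hi)) next
    e1 <- sqrt(rowSums((apply_homography(H, p1) - p2)^2))
    e2 <- sqrt(rowSums((apply_homography(Hi, p2) - p1)^2))
    inl <- pmax(e1, e2) < thresh_px
    if (sum(inl) > sum(best_in)) { best <- H; best_in <- inl }
  }
  list(H = best, inliers = best_in)
}

# Decomposition of a calibrated homography H ~ R + t n^T (plane distance
# normalized into t) into its four (R, t, n) interpretations.
decompose_homography <- function(H, K) {
  Hn <- solve(K) %*% H %*% K
  if (det(Hn) < 0) Hn <- -Hn
  sv <- svd(Hn)
  Hn <- Hn / sv$d[2]
  s2 <- (sv$d / sv$d[2])^2      # sigma^2, middle normalized to 1
  if (s2[1] - s2[3] < 1e-9) {
    # pure rotation (zero baseline)
    return(list(list(R = Hn, t = c(0, 0, 0), n = c(0, 0, 1))))
  }
  ev <- eigen(crossprod(Hn), symmetric = TRUE)
  v1 <- ev$vectors[, 1]; v2 <- ev$vectors[, 2]; v3 <- ev$vectors[, 3]
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  s1 <- ev$values[1]; s3 <- ev$values[3]
  u1 <- (sqrt(pmax(1 - s3, 0)) * v1 + sqrt(pmax(s1 - 1, 0)) * v3) /
        sqrt(pmax(s1 - s3, 1e-12))
  u2 <- (sqrt(pmax(1 - s3, 0)) * v1 - sqrt(pmax(s1 - 1, 0)) * v3) /
        sqrt(pmax(s1 - s3, 1e-12))
  out <- list()
  for (u in list(u1, u2)) {
    U1 <- cbind(v2, u, cross3(v2, u))
    W1 <- cbind(Hn %*% v2, Hn %*% u, cross3(Hn %*% v2, Hn %*% u))
    R <- W1 %*% t(U1)
    n <- cross3(v2, u)
    tt <- as.numeric((Hn - R) %*% n)
    for (sgn in c(1, -1)) {
      nn <- sgn * n; ts <- sgn * tt
      if (nn[3] < 0) next  # plane must face the first camera
      out[[length(out) + 1]] <- list(R = R, t = ts, n = nn)
    }
    # keep both sign variants when the normal has no clear z component
    if (abs(n[3]) < 1e-9) {
      out[[length(out) + 1]] <- list(R = R, t = -tt, n = -n)
    }
  }
  out
}

# rotation from an axis-angle vector
rot_from_vec <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
}

skew3 <- function(t) matrix(c(0, t[3], -t[2], -t[3], 0, t[1], t[2], -t[1], 0), 3, 3)

# refine (R, t direction) by minimizing robust Sampson error over matches
refine_relative_pose <- function(R0, t0, K, p1, p2) {
  t0 <- t0 / sqrt(sum(t0^2))
  b0 <- asin(clamp(t0[3], -1, 1)); a0 <- atan2(t0[2], t0[1])
  obj <- function(par) {
    R <- rot_from_vec(par[1:3]) %*% R0
    a <- a0 + par[4]; b <- b0 + par[5]
    tt <- c(cos(b) * cos(a), cos(b) * sin(a), sin(b))
    E <- skew3(tt) %*% R
    s <- sampson_px(E, K, p1, p2)
    sum(pmin(s, 3)^2)
  }
  fit <- stats::optim(rep(0, 5), obj, method = "BFGS",
                      control = list(maxit = 100, reltol = 1e-10))
  R <- rot_from_vec(fit$par[1:3]) %*% R0
  a <- a0 + fit$par[4]; b <- b0 + fit$par[5]
  tt <- c(cos(b) * cos(a), cos(b) * sin(a), sin(b))
  list(R = R, t = tt)
}

# R, t candidates from an essential matrix
decompose_essential <- function(E) {
  s <- svd(E)
  W <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  U <- s$u; V <- s$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  R1 <- U %*% W %*% t(V); R2 <- U %*% t(W) %*% t(V)
  t1 <- U[, 3]; t2 <- -U[, 3]
  list(list(R = R1, t = t1), list(R = R1, t = t2),
       list(R = R2, t = t1), list(R = R2, t = t2))
}

# choose among (R, t) candidates by cheirality (points in front of both
# cameras); candidates may carry a plane normal n (homography path), in
# which case visibility of the plane is also required
pick_by_cheirality <- function(cands, K, p1, p2) {
  x1 <- normalize_px(K, p1); x2 <- normalize_px(K, p2)
  P1 <- cbind(diag(3), 0)
  idx <- round(seq(1, nrow(p1), length.out = min(40L, nrow(p1))))
  score <- vapply(cands, function(cand) {
    if (sqrt(sum(cand$t^2)) < 1e-9) return(-1L)
    P2 <- cbind(cand$R, cand$t)
    npos <- 0L
    for (i in idx) {
      X <- triangulate_one(list(P1, P2), rbind(x1[i, ], x2[i, ]))
      z1 <- X[3]; z2 <- (cand$R %*% X + cand$t)[3]
      ok <- z1 > 0 && z2 > 0
      if (ok && !is.null(cand$n)) ok <- sum(cand$n * c(x1[i, ], 1)) > 0
      npos <- npos + as.integer(ok)
    }
    npos
  }, integer(1))
  if (max(score) < 0) return(NULL)
  top <- which(score >= 0.9 * max(score) & score > 0)
  if (!length(top)) return(NULL)
  if (length(top) > 1L && !is.null(cands[[top[1]]]$n)) {
    # planar two-view geometry admits two exact interpretations; prefer the
    # plane normal closest to the optical axis (the acquisition protocol
    # holds the camera roughly perpendicular to the surface)
    nz <- vapply(cands[top], function(cand) cand$n[3], numeric(1))
    top <- top[which.max(nz)]
  }
  cands[[top[which.max(score[top])]]]
}

# robust relative pose between two views: model selection between an
# essential matrix (general scenes) and a homography (planar / low-parallax
# scenes, where the eight-point problem is degenerate), followed by a
# Sampson-error refinement of (R, t)
pair_relative_geometry <- function(p1, p2, K, ransac_iters = 600) {
  if (stats::median(sqrt(rowSums((p1 - p2)^2))) < 0.5)
    stopf("insufficient parallax/texture: near-zero baseline")
  hr <- ransac_homography(p1, p2, thresh_px = 1.5, iters = min(ransac_iters, 300))
  er <- tryCatch(essential_ransac(p1, p2, K, iters = ransac_iters),
                 error = function(e) NULL)
  nH <- sum(hr$inliers); nE <- if (is.null(er)) 0L else sum(er$inliers)
  # prefer the homography model unless the essential model clearly dominates:
  # wound surfaces are smooth and low-relief, where the eight-point problem
  # is quasi-degenerate while the homography is well conditioned; the
  # Sampson refinement below recovers the out-of-plane signal either way
  if (!is.null(er) && nE > 1.5 * nH) {
    inl <- er$inliers
    cand <- pick_by_cheirality(decompose_essential(er$E), K,
                               p1[inl, , drop = FALSE], p2[inl, , drop = FALSE])
  } else {
    if (is.null(hr$H) || nH < 8L)
      stopf("insufficient parallax/texture: fewer than 8 inlier matches")
    inl <- hr$inliers
    cand <- pick_by_cheirality(decompose_homography(hr$H, K), K,
                               p1[inl, , drop = FALSE], p2[inl, , drop = FALSE])
  }
  if (is.null(cand)) stopf("insufficient parallax/texture: degenerate relative pose")
  rp <- refine_relative_pose(cand$R, cand$t, K,
                             p1[inl, , drop = FALSE], p2[inl, , drop = FALSE])
  E <- skew3(rp$t) %*% rp$R
  inl2 <- sampson_px(E, K, p1, p2) < 1
  if (sum(inl2) < 8L) inl2 <- inl
  list(R = rp$R, t = rp$t, E = E, inliers = inl2)
}

# ---- incremental reconstruction -------------------------------------------

#' Sparse structure-from-motion reconstruction
#'
#' Detects interest points in every frame, matches consecutive frames with
#' normalized-patch descriptors (mutual best + ratio test), estimates the
#' essential matrix per pair with RANSAC on the epipolar constraint, chains
#' camera poses incrementally (two-view relative pose, scale propagated
#' through common tracks) and triangulates every track seen in at least two
#' frames.  Points with median reprojection error above 2 px are discarded.
#' The reconstruction is defined up to global scale.
#'
#' @param frames a [frame_sequence()] or list of images.
#' @param intrinsics `list(f, cx, cy)` in pixels (shared by all frames).
#' @param max_features interest points per frame.
#' @param ransac_iters RANSAC iterations per pair.
#' @param seed RNG seed (RANSAC sampling).
#' @return A `sparse_cloud`: `points` (n x 3), observation table `track`
#'   (`point`, `frame`, `x`, `y`), per-frame `poses` (`R`, `t` with
#'   `X_cam = R X + t`), `intrinsics`.
#' @export
sparse_reconstruct <- function(frames, intrinsics, max_features = 900,
                               ransac_iters = 600, seed = 1L) {
  if (!inherits(frames, "frame_sequence")) frames <- frame_sequence(frames)
  set.seed(as.integer(seed))
  imgs <- frames$frames
  nf <- length(imgs)
  K <- intrinsics_matrix(intrinsics)
  grays <- lapply(imgs, rgb_to_gray)
  feats <- lapply(grays, harris_features, max_n = max_features)
  descs <- mapply(function(g, p) patch_descriptors(g, p),
                  grays, feats, SIMPLIFY = FALSE)

  pair_matches <- vector("list", nf - 1L)
  pair_geom <- vector("list", nf - 1L)
  for (i in seq_len(nf - 1L)) {
    m <- match_descriptors(descs[[i]], descs[[i + 1L]])
    if (nrow(m) < 8L) stopf("insufficient parallax/texture between frames %d and %d", i, i + 1L)
    p1 <- cbind(feats[[i]]$x[m[, 1]], feats[[i]]$y[m[, 1]])
    p2 <- cbind(feats[[i + 1L]]$x[m[, 2]], feats[[i + 1L]]$y[m[, 2]])
    pg <- pair_relative_geometry(p1, p2, K, ransac_iters = ransac_iters)
    pair_matches[[i]] <- m[pg$inliers, , drop = FALSE]
    pair_geom[[i]] <- list(R = pg$R, t = pg$t,
                           p1 = p1[pg$inliers, , drop = FALSE],
                           p2 = p2[pg$inliers, , drop = FALSE])
    if (nrow(pair_matches[[i]]) < 8L)
      stopf("insufficient parallax/texture between frames %d and %d", i, i + 1L)
  }

  # tracks: union-find over (frame, feature) nodes linked by inlier matches
  nfe <- vapply(feats, nrow, integer(1))
  offs <- cumsum(c(0L, nfe))
  parent <- seq_len(sum(nfe))
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (i in seq_len(nf - 1L)) {
    m <- pair_matches[[i]]
    for (r in seq_len(nrow(m))) {
      a <- find(offs[i] + m[r, 1]); b <- find(offs[i + 1L] + m[r, 2])
      if (a != b) parent[b] <- a
    }
  }
  node_frame <- rep(seq_len(nf), nfe)
  node_feat <- unlist(lapply(nfe, seq_len))
  root <- vapply(seq_along(parent), find, integer(1))
  groups <- split(seq_along(parent), root)
  groups <- groups[lengths(groups) >= 2L]
  # a valid track has at most one observation per frame
  groups <- Filter(function(g) !anyDuplicated(node_frame[g]), groups)

  # poses by chaining from the consecutive pair with the most inliers
  ninl <- vapply(pair_matches, nrow, integer(1))
  init <- which.max(ninl)
  poses <- vector("list", nf)
  g0 <- pair_geom[[init]]
  poses[[init]] <- list(R = diag(3), t = c(0, 0, 0))
  poses[[init + 1L]] <- list(R = g0$R, t = g0$t)

  # world points triangulated so far, keyed by track root; helper closures
  track_of_node <- integer(sum(nfe))
  for (gi in seq_along(groups)) track_of_node[groups[[gi]]] <- gi
  obs_px <- function(fr, ft) c(feats[[fr]]$x[ft], feats[[fr]]$y[ft])
  Xw <- matrix(NA_real_, length(groups), 3)

  triangulate_known <- function() {
    # (re)triangulate all tracks with >= 2 posed observations
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      frs <- node_frame[g]
      posed <- !vapply(poses[frs], is.null, logical(1))
      if (sum(posed) < 2L) next
      Ps <- lapply(which(posed), function(k) {
        po <- poses[[frs[k]]]
        cbind(po$R, po$t)
      })
      obs <- do.call(rbind, lapply(which(posed), function(k)
        normalize_px(K, rbind(obs_px(frs[k], node_feat[g[k]])))))
      Xw[gi, ] <<- triangulate_one(Ps, obs)
    }
  }
  triangulate_known()

  extend <- function(i_from, i_to) {
    # pose frame i_to from the pair between i_from and i_to
    pi <- min(i_from, i_to)
    g <- pair_geom[[pi]]
    forward <- i_to > i_from
    # stored geometry maps cam(pi) -> cam(pi+1)
    Rrel <- g$R; trel <- g$t
    if (!forward) { Rrel <- t(g$R); trel <- -t(g$R) %*% g$t }
    Rf <- poses[[i_from]]$R; tf <- poses[[i_from]]$t
    # scale from tracks with known 3D observed in both frames of the pair
    m <- pair_matches[[pi]]
    gidx <- track_of_node[offs[pi] + m[, 1]]
    known <- which(gidx > 0L & !is.na(Xw[pmax(gidx, 1L), 1]))
    if (length(known) < 5L) stopf("insufficient parallax/texture: cannot chain scale at frame %d", i_to)
    # depths of known points in the i_from camera
    Xk <- Xw[gidx[known], , drop = FALSE]
    zk <- (Xk %*% t(Rf))[, 3] + tf[3]
    # two-view triangulation with unit baseline in the pair's local frame
    p1k <- g$p1[known, , drop = FALSE]; p2k <- g$p2[known, , drop = FALSE]
    if (!forward) { tmp <- p1k; p1k <- p2k; p2k <- tmp }
    x1 <- normalize_px(K, p1k); x2 <- normalize_px(K, p2k)
    P1 <- cbind(diag(3), 0); P2 <- cbind(Rrel, trel)
    zloc <- vapply(seq_len(nrow(x1)), function(r)
      triangulate_one(list(P1, P2), rbind(x1[r, ], x2[r, ]))[3], numeric(1))
    ok <- zloc > 0 & zk > 0
    if (sum(ok) < 5L) stopf("insufficient parallax/texture: cannot chain scale at frame %d", i_to)
    s <- stats::median(zk[ok] / zloc[ok])
    Rn <- Rrel %*% Rf
    tn <- as.numeric(Rrel %*% tf) + s * as.numeric(trel)
    poses[[i_to]] <<- list(R = Rn, t = tn)
    triangulate_known()
  }
  if (init + 2L <= nf) for (j in (init + 2L):nf) extend(j - 1L, j)
  if (init - 1L >= 1L) for (j in (init - 1L):1L) extend(j + 1L, j)

  # final filtering on reprojection error and cheirality
  keep <- rep(FALSE, length(groups))
  err <- rep(NA_real_, length(groups))
  for (gi in seq_along(groups)) {
    if (is.na(Xw[gi, 1])) next
    g <- groups[[gi]]
    frs <- node_frame[g]
    e <- numeric(0); okz <- TRUE
    for (k in seq_along(g)) {
      po <- poses[[frs[k]]]
      Xc <- as.numeric(po$R %*% Xw[gi, ] + po$t)
      if (Xc[3] <= 0) { okz <- FALSE; break }
      pr <- c(K[1, 1] * Xc[1] / Xc[3] + K[1, 3], K[2, 2] * Xc[2] / Xc[3] + K[2, 3])
      e <- c(e, sqrt(sum((pr - obs_px(frs[k], node_feat[g[k]]))^2)))
    }
    if (okz) { err[gi] <- stats::median(e); keep[gi] <- err[gi] < 2 }
  }
  if (!any(keep)) stopf("reconstruction failed: no points survive reprojection filtering")
  sel <- which(keep)
  track <- do.call(rbind, lapply(seq_along(sel), function(si) {
    g <- groups[[sel[si]]]
    data.frame(point = si, frame = node_frame[g],
               x = vapply(seq_along(g), function(k) feats[[node_frame[g[k]]]]$x[node_feat[g[k]]], numeric(1)),
               y = vapply(seq_along(g), function(k) feats[[node_frame[g[k]]]]$y[node_feat[g[k]]], numeric(1)))
  }))
  structure(list(points = Xw[sel, , drop = FALSE], track = track,
                 poses = poses, intrinsics = intrinsics,
                 colors = NULL, gray = NULL,
                 reproj_err = err[sel]),
            class = "sparse_cloud")
}

#' @export
print.sparse_cloud <- function(x, ...) {
  cat(sprintf("sparse_cloud: %d points, %d observations, %d frames, median reproj %.2f px\n",
              nrow(x$points), nrow(x$track),
              sum(!vapply(x$poses, is.null, logical(1))),
              stats::median(x$reproj_err %||% NA_real_)))
  invisible(x)
}

#' Remove isolated points from a cloud
#'
#' A point is kept iff at least `min_neighbors` other points lie within
#' `radius`.  Tracks, colors and gray values are carried over.
#'
#' @param cloud a `sparse_cloud`.
#' @param radius neighborhood radius (cloud units); default 2 x the median
#'   nearest-neighbor distance.
#' @param min_neighbors required neighbor count.
#' @return The filtered `sparse_cloud`.
#' @export
filter_isolated_points <- function(cloud, radius = NULL, min_neighbors = 5) {
  n <- nrow(cloud$points)
  if (min_neighbors <= 0) return(cloud)
  if (is.null(radius)) {
    nn <- RANN::nn2(cloud$points, k = 2L)
    radius <- 2 * stats::median(nn$nn.dists[, 2])
  }
  if (radius <= 0) stopf("radius must be > 0")
  k <- min(n, min_neighbors + 1L)
  nn <- RANN::nn2(cloud$points, k = k, searchtype = "radius", radius = radius)
  cnt <- rowSums(nn$nn.idx > 0) - 1L  # exclude self
  keep <- cnt >= min_neighbors
  if (!any(keep)) stopf("over-aggressive filtering: all points removed")
  subset_cloud(cloud, which(keep))
}

subset_cloud <- function(cloud, idx) {
  remap <- integer(nrow(cloud$points)); remap[idx] <- seq_along(idx)
  tr <- cloud$track[cloud$track$point %in% idx, , drop = FALSE]
  tr$point <- remap[tr$point]
  cloud$points <- cloud$points[idx, , drop = FALSE]
  if (!is.null(cloud$colors)) cloud$colors <- cloud$colors[idx, , drop = FALSE]
  if (!is.null(cloud$gray)) cloud$gray <- cloud$gray[idx]
  if (!is.null(cloud$reproj_err)) cloud$reproj_err <- cloud$reproj_err[idx]
  cloud$track <- tr
  cloud
}

#' Colorize a cloud from its track observations
#'
#' Each point's color is the arithmetic mean of the image colors at its
#' track pixels.  Out-of-bounds observations are skipped; points with no
#' valid observation are dropped.
#'
#' @param cloud a `sparse_cloud`.
#' @param frames the [frame_sequence()] (or list of images) used for
#'   reconstruction.
#' @return The cloud with an n x 3 `colors` matrix in `[0, 1]`.
#' @export
colorize_cloud <- function(cloud, frames) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  vals <- observation_values(cloud, frames, channels = 3L)
  ok <- !is.na(vals[, 1])
  if (!all(ok)) cloud <- subset_cloud(cloud, which(ok))
  cloud$colors <- vals[ok, , drop = FALSE]
  cloud
}

#' Gray-colorize a cloud from a binary mask sequence
#'
#' Repeats the color reconstruction with the per-frame segmentation masks:
#' each point's gray value is the mean of the mask values (0/255) over its
#' track observations, yielding the grayscale wound surface.
#'
#' @param cloud a `sparse_cloud`.
#' @param mask_frames list of binary masks aligned with the frames.
#' @return The cloud with per-point `gray` in `[0, 255]`.
#' @export
mask_colorize_cloud <- function(cloud, mask_frames) {
  masks <- lapply(mask_frames, function(m) matrix(as.numeric(m > 0) * 255,
                                                  nrow(m), ncol(m)))
  vals <- observation_values(cloud, masks, channels = 1L)
  ok <- !is.na(vals[, 1])
  if (!all(ok)) cloud <- subset_cloud(cloud, which(ok))
  cloud$gray <- vals[ok, 1]
  cloud
}

# mean per-point sample of images (3 channels) or matrices (1 channel) at
# rounded track pixels; NA when every observation is out of bounds
observation_values <- function(cloud, imgs, channels = 3L) {
  tr <- cloud$track
  n <- nrow(cloud$points)
  acc <- matrix(0, n, channels); cnt <- numeric(n)
  for (fr in unique(tr$frame)) {
    sel <- tr$frame == fr
    img <- imgs[[fr]]
    h <- dim(img)[1]; w <- dim(img)[2]
    xi <- round(tr$x[sel]); yi <- round(tr$y[sel])
    inb <- xi >= 0 & yi >= 0 & xi <= w - 1 & yi <= h - 1
    pid <- tr$point[sel][inb]
    if (!length(pid)) next
    for (ch in seq_len(channels)) {
      m <- if (length(dim(img)) == 3L) img[, , ch] else img
      acc[, ch] <- acc[, ch] + unname(tapply(
        m[cbind(yi[inb] + 1, xi[inb] + 1)],
        factor(pid, levels = seq_len(n)), sum, default = 0))
    }
    cnt <- cnt + tabulate(pid, nbins = n)
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0, ] <- NA_real_
  out
}

#' Full 3D measurement pipeline
#'
#' Frames to area: sparse reconstruction, isolated-point removal, mask-based
#' gray reconstruction, 2.5D Delaunay meshing, Laplacian smoothing and hole
#' filling, metric calibration from a reference segment, and the two-white-
#' vertex triangle area sum.
#'
#' @param frames a [frame_sequence()] or list of images.
#' @param masks list of per-frame binary segmentation masks.
#' @param intrinsics `list(f, cx, cy)`.
#' @param ref reference of known length: either a [reference_segment()] in
#'   reconstruction units, or
#'   `list(frame_a, px_a, frame_b, px_b, true_length_cm)` where each endpoint
#'   is observed at pixel `px_*` (x, y) in two frames given as
#'   `px_a = rbind(c(x_f1, y_f1), c(x_f2, y_f2))` with `frame_a = c(f1, f2)`
#'   and is triangulated in the reconstruction.
#' @param gray_threshold whiteness threshold for qualifying triangles.
#' @param ... passed to [sparse_reconstruct()].
#' @return An `area_result`.
#' @export
measure_pipeline_3d <- function(frames, masks, intrinsics, ref,
                                gray_threshold = 127, ...) {
  stage <- function(tag, expr) tryCatch(expr, error = function(e)
    stopf("[%s] %s", tag, conditionMessage(e)))
  cloud <- stage("recon3d", sparse_reconstruct(frames, intrinsics, ...))
  cloud <- stage("recon3d", filter_isolated_points(cloud))
  cloud <- stage("recon3d", mask_colorize_cloud(cloud, masks))
  mesh <- stage("mesh3d", triangulate_mesh(cloud))
  mesh <- stage("mesh3d", smooth_and_fill(mesh))
  if (!inherits(ref, "reference_segment")) {
    K <- intrinsics_matrix(intrinsics)
    tri_ep <- function(frs, pxs) {
      Ps <- lapply(frs, function(f) {
        po <- cloud$poses[[f]]
        cbind(po$R, po$t)
      })
      triangulate_one(Ps, normalize_px(K, pxs))
    }
    a <- tri_ep(ref$frame_a, ref$px_a)
    b <- tri_ep(ref$frame_b, ref$px_b)
    ref <- reference_segment(a, b, ref$true_length_cm)
  }
  mesh <- stage("mesh3d", calibrate_scale(mesh, ref))
  stage("mesh3d", measure_area_3d(mesh, gray_threshold = gray_threshold))
}
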