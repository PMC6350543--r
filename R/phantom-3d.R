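#' Synthetic mesh phantom with a patch of known geodesic area
#'
#' Builds a structured triangle mesh over a parametric support surface with a
#' rectangular chart patch whose geodesic area is known exactly: cylinders
#' and planes are developable (chart area = surface area); for a sphere the
#' latitude/longitude rectangle formula `r^2 (l2 - l1)(sin p2 - sin p1)` is
#' used; for a bumpy plane the area is obtained by converged fine-grid
#' quadrature of the first fundamental form (numeric, not closed form).
#'
#' @param surface `"plane"`, `list(type = "cylinder", radius_cm = r)`,
#'   `list(type = "sphere", radius_cm = r)`, or
#'   `list(type = "bumpy", amp_cm = a, wavelength_cm = w)`.
#' @param patch_cm `c(width, height)` of the patch in the chart (cm); for a
#'   sphere these are arc lengths `r * dlambda`, `r * dphi` at the equatorial
#'   chart origin.
#' @param extent_cm `c(width, height)` of the whole meshed chart.
#' @param h_cm grid spacing (cm).
#' @param texture_seed seed for the view-rendering texture.
#' @return A `mesh_phantom`: a [labeled_mesh()] plus `patch_vertex_flags`,
#'   `true_patch_area_cm2` and a `reference` (two vertex indices with their
#'   exact 3D distance in cm).
#' @export
make_mesh_phantom <- function(surface = "plane", patch_cm = c(4, 3),
                              extent_cm = NULL, h_cm = 0.04,
                              texture_seed = 1L) {
  if (is.character(surface)) surface <- list(type = surface)
  if (prod(patch_cm) <= 0) stopf("degenerate patch: zero area")
  if (is.null(extent_cm)) extent_cm <- patch_cm + 4
  nu <- max(8L, round(extent_cm[1] / h_cm)); nv <- max(8L, round(extent_cm[2] / h_cm))
  us <- seq(-extent_cm[1] / 2, extent_cm[1] / 2, length.out = nu + 1)
  vs <- seq(-extent_cm[2] / 2, extent_cm[2] / 2, length.out = nv + 1)
  g <- expand.grid(u = us, v = vs)

  f3 <- surface_fn(surface)
  V <- f3(g$u, g$v)
  vid <- function(i, j) i + 1L + j * (nu + 1L)   # i in 0..nu, j in 0..nv
  i0 <- rep(0:(nu - 1), nv); j0 <- rep(0:(nv - 1), each = nu)
  a <- vid(i0, j0); b <- vid(i0 + 1, j0); c <- vid(i0 + 1, j0 + 1); d <- vid(i0, j0 + 1)
  F <- rbind(cbind(a, b, c), cbind(a, c, d))

  inpatch <- abs(g$u) <= patch_cm[1] / 2 & abs(g$v) <= patch_cm[2] / 2
  if (!any(inpatch)) stopf("degenerate patch: no vertices inside")
  area <- patch_true_area(surface, patch_cm)
  if (area <= 0) stopf("degenerate patch: zero area")

  # reference: two chart-axis vertices near the patch mid-line, far apart
  ia <- vid(round(nu * 0.1), round(nv / 2))
  ib <- vid(round(nu * 0.9), round(nv / 2))
  ref_len <- sqrt(sum((V[ia, ] - V[ib, ])^2))

  mesh <- labeled_mesh(V, F, gray = ifelse(inpatch, 255, 0))
  structure(list(mesh = mesh, patch_vertex_flags = inpatch,
                 true_patch_area_cm2 = area,
                 reference = list(a_idx = ia, b_idx = ib,
                                  true_length_cm = ref_len),
                 surface = surface, chart = cbind(g$u, g$v),
                 patch_cm = patch_cm, texture_seed = as.integer(texture_seed)),
            class = "mesh_phantom")
}

# parametric chart -> 3D for each support type (chart units cm)
surface_fn <- function(surface) {
  switch(surface$type,
    plane = function(u, v) cbind(u, v, 0),
    bumpy = function(u, v) {
      a <- surface$amp_cm %||% 0.3; w <- surface$wavelength_cm %||% 2.5
      cbind(u, v, a * sin(2 * pi * u / w) * sin(2 * pi * v / w))
    },
    cylinder = {
      r <- surface$radius_cm
      function(u, v) cbind(u, r * sin(v / r), r * (1 - cos(v / r)))
    },
    sphere = {
      r <- surface$radius_cm
      function(u, v) {
        lam <- u / r; phi <- v / r
        cbind(r * sin(lam) * cos(phi), r * sin(phi), r * (1 - cos(lam) * cos(phi)))
      }
    },
    stopf("unknown surface type"))
}

patch_true_area <- function(surface, patch_cm) {
  switch(surface$type,
    plane = ,
    cylinder = prod(patch_cm),
    sphere = {
      r <- surface$radius_cm
      dl <- patch_cm[1] / r; dp <- patch_cm[2] / r
      r^2 * dl * (sin(dp / 2) - sin(-dp / 2))
    },
    bumpy = {
      # converged quadrature of sqrt(det(first fundamental form))
      f <- surface_fn(surface)
      n <- 600
      us <- seq(-patch_cm[1] / 2, patch_cm[1] / 2, length.out = n + 1)
      vs <- seq(-patch_cm[2] / 2, patch_cm[2] / 2, length.out = n + 1)
      um <- (us[-1] + us[-(n + 1)]) / 2; vm <- (vs[-1] + vs[-(n + 1)]) / 2
      g <- expand.grid(u = um, v = vm)
      eps <- 1e-4
      xu <- (f(g$u + eps, g$v) - f(g$u - eps, g$v)) / (2 * eps)
      xv <- (f(g$u, g$v + eps) - f(g$u, g$v - eps)) / (2 * eps)
      E <- rowSums(xu^2); G <- rowSums(xv^2); Fc <- rowSums(xu * xv)
      sum(sqrt(pmax(E * G - Fc^2, 0))) * diff(us)[1] * diff(vs)[1]
    })
}

#' Render a multi-view image sequence of a mesh phantom
#'
#' Ray-casts the phantom's analytic support surface under each camera with a
#' deterministic high-contrast speckle texture (the trackable "small
#' structures" of the physical phantoms) and a darkened patch region.  Also
#' returns the per-frame binary patch masks that play the role of the
#' segmentation mask sequence.
#'
#' @param phantom a [make_mesh_phantom()] result.
#' @param trajectory list of [camera_model()] poses (>= 2).
#' @return `list(frames, masks, cameras)`; frames are H x W x 3 arrays.
#' @export
render_mesh_views <- function(phantom, trajectory) {
  if (length(trajectory) < 2L) stopf("need at least 2 camera poses")
  noise <- value_noise_2d(phantom$texture_seed, scale_cm = 0.35, octaves = 3L)
  spec <- list(support = phantom$surface)
  frames <- list(); masks <- list()
  for (k in seq_along(trajectory)) {
    cam <- trajectory[[k]]
    ch <- cast_to_chart_surface(phantom$surface, cam)
    h <- cam$size[2]; w <- cam$size[1]
    gray <- matrix(0.03, h, w)
    msk <- matrix(FALSE, h, w)
    if (any(ch$hit)) {
      u <- ch$u[ch$hit]; v <- ch$v[ch$hit]
      tex <- 0.55 + 0.42 * noise(u, v)
      inp <- abs(u) <= phantom$patch_cm[1] / 2 & abs(v) <= phantom$patch_cm[2] / 2
      tex[inp] <- tex[inp] * 0.45
      gray[ch$hit] <- clamp(tex, 0, 1)
      msk[ch$hit] <- inp
    }
    if (!any(msk)) stopf("patch fully occluded in view %d", k)
    frames[[k]] <- array(rep(gray, 3), dim = c(h, w, 3))
    masks[[k]] <- msk
  }
  list(frames = frames, masks = masks, cameras = trajectory)
}

# ray-cast a parametric support surface; closed form per type
cast_to_chart_surface <- function(surface, camera) {
  if (surface$type %in% c("plane", "bumpy")) {
    # bumpy surfaces are rendered with their base plane chart (amplitude is
    # small relative to the viewing distance)
    cast_to_chart(list(support = list(type = "flat")), camera)
  } else if (surface$type == "cylinder") {
    cast_to_chart(list(support = surface), camera)
  } else {
    r <- surface$radius_cm
    rays <- camera_rays(camera)
    o <- rays$origin
    cz <- c(0, 0, r)
    oc <- o - cz
    a <- rays$dx^2 + rays$dy^2 + rays$dz^2
    b <- 2 * (oc[1] * rays$dx + oc[2] * rays$dy + oc[3] * rays$dz)
    cc <- sum(oc^2) - r^2
    disc <- b^2 - 4 * a * cc
    hit <- disc >= 0
    tt <- matrix(NA_real_, nrow(a), ncol(a))
    tt[hit] <- (-b[hit] - sqrt(disc[hit])) / (2 * a[hit])
    hit <- hit & !is.na(tt) & tt > 0
    x <- o[1] + tt * rays$dx; y <- o[2] + tt * rays$dy; z <- o[3] + tt * rays$dz
    # invert the (lambda, phi) chart
    phi <- asin(clamp(y / r, -1, 1))
    lam <- atan2(x, r - z)
    u <- r * lam; v <- r * phi
    u[!hit] <- NA; v[!hit] <- NA
    list(u = u, v = v, hit = hit)
  }
}

#' Measure a mesh phantom through the labeled-mesh pipeline stages
#'
#' Convenience wrapper used in validation: optionally perturbs the phantom
#' vertices with Gaussian noise (emulating reconstruction noise), runs
#' [smooth_and_fill()], [calibrate_scale()] from the phantom's reference
#' segment and [measure_area_3d()].
#'
#' @param phantom a [make_mesh_phantom()] result.
#' @param noise_sd_cm Gaussian vertex perturbation (cm).
#' @param unit_scale arbitrary mesh-unit scale applied before measuring (the
#'   calibration must undo it).
#' @param seed RNG seed for the perturbation.
#' @param iterations,lambda_factor smoothing parameters.
#' @return `list(result, mesh)`: the `area_result` and the processed mesh.
#' @export
measure_mesh_phantom <- function(phantom, noise_sd_cm = 0.02, unit_scale = 1,
                                 seed = 1L, iterations = 10,
                                 lambda_factor = 0.5) {
  mesh <- phantom$mesh
  set.seed(as.integer(seed))
  V <- mesh$vertices
  V <- V + matrix(stats::rnorm(length(V), sd = noise_sd_cm), nrow(V), 3)
  V <- V * unit_scale
  mesh <- labeled_mesh(V, mesh$faces, gray = mesh$gray)
  mesh <- smooth_and_fill(mesh, iterations = iterations,
                          lambda_factor = lambda_factor)
  ref <- reference_segment(mesh$vertices[phantom$reference$a_idx, ],
                           mesh$vertices[phantom$reference$b_idx, ],
                           phantom$reference$true_length_cm)
  mesh <- calibrate_scale(mesh, ref)
  list(result = measure_area_3d(mesh), mesh = mesh)
}
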