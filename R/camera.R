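#' Pinhole camera model
#'
#' A simple calibrated pinhole camera.  The world frame is chosen so that the
#' phantom support surface touches the origin: x right, y down (matching image
#' axes for an untilted camera), z pointing away from the camera.  The camera
#' sits on the negative z side and looks towards +z.
#'
#' @param focal_length_px focal length in pixels (fx = fy).
#' @param image_size integer `c(width, height)` in pixels, each >= 64.
#' @param principal_point image point `c(cx, cy)`; default image center.
#' @param R 3x3 rotation, world to camera (rows are the camera axes in world
#'   coordinates).
#' @param center camera center in world coordinates (cm).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(focal_length_px, image_size,
                         principal_point = (image_size - 1) / 2,
                         R = diag(3), center = c(0, 0, -30)) {
  if (focal_length_px <= 0) stopf("focal_length_px must be > 0")
  if (any(image_size < 64)) stopf("image_size must be at least 64 x 64")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) stopf("R must be a rotation matrix")
  structure(list(f = focal_length_px,
                 size = as.integer(image_size),
                 pp = as.numeric(principal_point),
                 R = R, center = as.numeric(center)),
            class = "camera_model")
}

#' Fronto-parallel (optionally tilted) camera over the phantom origin
#'
#' @param distance_cm camera-to-surface distance along the optical axis.
#' @param tilt_deg rotation of the camera about the world x axis around the
#'   look-at point (0 = perpendicular to the surface).
#' @inheritParams camera_model
#' @return A `camera_model`.
#' @export
overhead_camera <- function(focal_length_px = 1050, image_size = c(720, 540),
                            distance_cm = 30, tilt_deg = 0) {
  t <- tilt_deg * pi / 180
  # camera axes in world coords: optical axis points from center to origin
  zc <- c(0, sin(t), cos(t))
  xc <- c(1, 0, 0)
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])  # z x x
  R <- rbind(xc, yc, zc)
  camera_model(focal_length_px, image_size, R = R,
               center = -distance_cm * zc)
}

#' Project world points to pixel coordinates
#'
#' @param camera a [camera_model()].
#' @param X n x 3 matrix of world points (cm).
#' @return n x 2 matrix of 0-based pixel coordinates (x, y).
#' @export
project_points <- function(camera, X) {
  X <- rbind(X)  # coerce vector to 1 x 3
  Xc <- sweep(X, 2, camera$center) %*% t(camera$R)
  if (any(Xc[, 3] <= 0)) stopf("point behind camera")
  cbind(camera$f * Xc[, 1] / Xc[, 3] + camera$pp[1],
        camera$f * Xc[, 2] / Xc[, 3] + camera$pp[2])
}

# World-frame ray directions (unnormalized) through every pixel center,
# optionally offset by (ox, oy) px for supersampling.
# Returns list(dx, dy, dz) of H x W matrices plus origin.
camera_rays <- function(camera, ox = 0, oy = 0) {
  w <- camera$size[1]; h <- camera$size[2]
  x <- matrix(0:(w - 1) + ox, h, w, byrow = TRUE)
  y <- matrix(0:(h - 1) + oy, h, w)
  dcx <- (x - camera$pp[1]) / camera$f
  dcy <- (y - camera$pp[2]) / camera$f
  Rt <- t(camera$R)
  list(dx = Rt[1, 1] * dcx + Rt[1, 2] * dcy + Rt[1, 3],
       dy = Rt[2, 1] * dcx + Rt[2, 2] * dcy + Rt[2, 3],
       dz = Rt[3, 1] * dcx + Rt[3, 2] * dcy + Rt[3, 3],
       origin = camera$center)
}

#' Camera on an orbit looking at a fixed target
#'
#' Places the camera on a circle of radius `distance_cm` around `target`,
#' rotated `angle_deg` about the world x axis from the overhead position.
#' Used to generate multi-view trajectories for structure-from-motion input.
#'
#' @inheritParams overhead_camera
#' @param angle_deg orbit angle in degrees (0 = overhead).
#' @param target world look-at point.
#' @return A `camera_model`.
#' @export
orbit_camera <- function(angle_deg, focal_length_px = 700,
                         image_size = c(480, 360), distance_cm = 30,
                         target = c(0, 0, 0)) {
  t <- angle_deg * pi / 180
  zc <- c(0, sin(t), cos(t))
  xc <- c(1, 0, 0)
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  camera_model(focal_length_px, image_size, R = rbind(xc, yc, zc),
               center = target - distance_cm * zc)
}
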