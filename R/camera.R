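#' Pinhole camera intrinsics
#'
#' Bundles the pixel focal lengths and principal-point offsets of a pinhole
#' camera. Pixel coordinates are 0-based, `(u, v) = (column, row)`, and refer
#' to pixel centers; `u = fx * x / z + ox`, `v = fy * y / z + oy`.
#'
#' @param fx,fy Pixel focal lengths (pixels); must be positive and finite.
#' @param ox,oy Principal-point offsets from the top-left pixel center
#'   (pixels); must be finite.
#'
#' @return An object of class `camera_intrinsics`.
#' @seealso [unproject_pixel()], [project_point()], [intrinsic_matrix()]
#' @export
#' @examples
#' K <- camera_intrinsics(fx = 300, fy = 300, ox = 128, oy = 96)
#' unproject_pixel(128, 96, depth = 0.5, K)
camera_intrinsics <- function(fx, fy, ox, oy) {
  vals <- c(fx = fx, fy = fy, ox = ox, oy = oy)
  if (length(vals) != 4L || !all(is.finite(vals))) {
    abort("intrinsics must be four finite scalars (fx, fy, ox, oy)")
  }
  if (fx <= 0 || fy <= 0) abort("focal lengths fx, fy must be positive")
  structure(list(fx = fx, fy = fy, ox = ox, oy = oy),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> fx=%.6g fy=%.6g ox=%.6g oy=%.6g\n",
              x$fx, x$fy, x$ox, x$oy))
  invisible(x)
}

#' 3x3 intrinsic matrix K
#'
#' @param intrinsics A [camera_intrinsics()] object.
#' @return A 3x3 numeric matrix.
#' @export
intrinsic_matrix <- function(intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  matrix(c(intrinsics$fx, 0, 0,
           0, intrinsics$fy, 0,
           intrinsics$ox, intrinsics$oy, 1), 3, 3)
}

#' Rigid camera extrinsics [R|t]
#'
#' The extrinsics map world coordinates to camera coordinates:
#' `p_camera = R %*% p_world + t`. The rotation must be a proper rotation
#' (orthonormal, determinant +1) to within 1e-9.
#'
#' @param rotation 3x3 rotation matrix (world to camera).
#' @param translation Length-3 translation (meters).
#'
#' @return An object of class `camera_extrinsics`.
#' @seealso [camera_to_world()], [world_to_camera()]
#' @export
camera_extrinsics <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  R <- as.matrix(rotation)
  t <- as.numeric(translation)
  if (!all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
    abort("rotation must be a finite 3x3 matrix")
  }
  if (length(t) != 3L || !all(is.finite(t))) {
    abort("translation must be a finite 3-vector")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    abort("rotation must be orthonormal with determinant +1 (within 1e-9)")
  }
  structure(list(rotation = R, translation = t), class = "camera_extrinsics")
}

#' @export
print.camera_extrinsics <- function(x, ...) {
  cat("<camera_extrinsics>\nR =\n")
  print(unname(x$rotation))
  cat("t =", format(x$translation), "\n")
  invisible(x)
}

identity_extrinsics <- function() camera_extrinsics(diag(3), c(0, 0, 0))

as_xyz_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    cbind(points$x, points$y, points$z)
  } else {
    m <- as.matrix(points)
    if (is.null(dim(m)) || ncol(m) != 3L) abort("points must be n x 3")
    m
  }
}

#' Unproject pixels to camera-frame 3D points
#'
#' Inverts the pinhole projection for pixels with known depth. Depth values
#' are z-depths: distances along the optical axis, not Euclidean ray ranges,
#' so `z = depth`, `x = (u - ox) * depth / fx`, `y = (v - oy) * depth / fy`.
#'
#' @param u,v Pixel column / row coordinates (0-based, pixel centers).
#'   Recycled against each other and `depth`.
#' @param depth z-depth in meters; every element must be finite and positive.
#' @param intrinsics A [camera_intrinsics()] object.
#'
#' @return A tibble with columns `x`, `y`, `z` (meters, camera frame).
#' @export
#' @examples
#' K <- camera_intrinsics(300, 150, 128, 96)
#' unproject_pixel(98, 126, 1.0, K)  # (-0.1, 0.2, 1.0)
unproject_pixel <- function(u, v, depth, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  n <- max(length(u), length(v), length(depth))
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  depth <- rep_len(as.numeric(depth), n)
  if (any(!is.finite(depth)) || any(depth <= 0)) {
    abort("invalid depth: all depth values must be finite and > 0")
  }
  tibble::tibble(
    x = (u - intrinsics$ox) * depth / intrinsics$fx,
    y = (v - intrinsics$oy) * depth / intrinsics$fy,
    z = depth
  )
}

#' Project camera-frame points to pixel coordinates
#'
#' @param points Camera-frame points: an n x 3 matrix or a data frame with
#'   columns `x`, `y`, `z` (meters); `z` must be positive.
#' @inheritParams unproject_pixel
#' @return A tibble with columns `u`, `v` (pixels).
#' @export
project_point <- function(points, intrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  p <- as_xyz_matrix(points)
  if (any(p[, 3] <= 0)) abort("cannot project points with non-positive z")
  tibble::tibble(
    u = intrinsics$fx * p[, 1] / p[, 3] + intrinsics$ox,
    v = intrinsics$fy * p[, 2] / p[, 3] + intrinsics$oy
  )
}

#' Map camera-frame points to the world frame (and back)
#'
#' With extrinsics `p_camera = R p_world + t`, world recovery is the closed
#' form `p_world = t(R) %*% (p_camera - t)`.
#'
#' @param points n x 3 matrix or data frame with columns `x`, `y`, `z`.
#' @param extrinsics A [camera_extrinsics()] object.
#' @return A tibble with columns `x`, `y`, `z`.
#' @export
camera_to_world <- function(points, extrinsics) {
  stopifnot(inherits(extrinsics, "camera_extrinsics"))
  p <- as_xyz_matrix(points)
  w <- sweep(p, 2, extrinsics$translation) %*% extrinsics$rotation
  tibble::tibble(x = w[, 1], y = w[, 2], z = w[, 3])
}

#' @rdname camera_to_world
#' @export
world_to_camera <- function(points, extrinsics) {
  stopifnot(inherits(extrinsics, "camera_extrinsics"))
  p <- as_xyz_matrix(points)
  cpt <- p %*% t(extrinsics$rotation)
  cpt <- sweep(cpt, 2, extrinsics$translation, `+`)
  tibble::tibble(x = cpt[, 1], y = cpt[, 2], z = cpt[, 3])
}

#' Unproject a depth map to a world-frame point grid
#'
#' Converts every pixel of an H x W depth map into world coordinates, keeping
#' image row/column order. A cell is valid iff its mask bit is set and its
#' depth is valid (finite and positive); depths are never interpolated here.
#'
#' @param depth H x W numeric matrix of z-depths in meters. Non-finite or
#'   non-positive entries mark missing sensor returns.
#' @param mask Optional H x W logical (or 0/1) matrix selecting wound pixels.
#'   `NULL` selects every pixel.
#' @param intrinsics A [camera_intrinsics()] object (at depth resolution).
#' @param extrinsics Optional [camera_extrinsics()]; identity if `NULL`.
#'
#' @return An object of class `point_grid`: a list with H x W matrices `x`,
#'   `y`, `z` (world frame, meters; `NA` where depth is invalid), logical
#'   matrices `valid` (mask AND valid depth) and `depth_ok`, and `dim`.
#' @export
unproject_depth_map <- function(depth, mask = NULL, intrinsics,
                                extrinsics = NULL) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  depth <- as.matrix(depth)
  H <- nrow(depth); W <- ncol(depth)
  if (H < 2 || W < 2) abort("depth map must be at least 2 x 2")
  if (is.null(mask)) {
    mask <- matrix(TRUE, H, W)
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == c(H, W))) {
      abort(sprintf("mask dimensions (%d x %d) must equal depth dimensions (%d x %d)",
                    nrow(mask), ncol(mask), H, W))
    }
    mask <- mask > 0 & !is.na(mask)
  }
  if (is.null(extrinsics)) extrinsics <- identity_extrinsics()
  stopifnot(inherits(extrinsics, "camera_extrinsics"))

  depth_ok <- is.finite(depth) & depth > 0
  z <- ifelse(depth_ok, depth, NA_real_)
  u <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  v <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  xc <- (u - intrinsics$ox) * z / intrinsics$fx
  yc <- (v - intrinsics$oy) * z / intrinsics$fy

  # world = R^T (p_cam - t), expanded per coordinate to stay matrix-shaped
  R <- extrinsics$rotation; t <- extrinsics$translation
  dxc <- xc - t[1]; dyc <- yc - t[2]; dzc <- z - t[3]
  xw <- R[1, 1] * dxc + R[2, 1] * dyc + R[3, 1] * dzc
  yw <- R[1, 2] * dxc + R[2, 2] * dyc + R[3, 2] * dzc
  zw <- R[1, 3] * dxc + R[2, 3] * dyc + R[3, 3] * dzc

  structure(list(x = xw, y = yw, z = zw,
                 valid = mask & depth_ok, mask = mask, depth_ok = depth_ok,
                 dim = c(H, W)),
            class = "point_grid")
}

#' @export
print.point_grid <- function(x, ...) {
  cat(sprintf("<point_grid> %d x %d, %d valid cells\n",
              x$dim[1], x$dim[2], sum(x$valid)))
  invisible(x)
}

#' @exportS3Method
as_tibble.point_grid <- function(x, ...) {
  H <- x$dim[1]; W <- x$dim[2]
  xs <- as.vector(x$x); ys <- as.vector(x$y); zs <- as.vector(x$z)
  ok <- as.vector(x$valid)
  tibble::tibble(
    row = rep(seq_len(H), times = W),
    col = rep(seq_len(W), each = H),
    u = rep(seq_len(W) - 1, each = H),
    v = rep(seq_len(H) - 1, times = W),
    x = xs, y = ys, z = zs,
    valid = ok
  )
}
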