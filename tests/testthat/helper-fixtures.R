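# shared fixtures, built in code at test time

# deterministic random proper rotation via QR decomposition
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# rotation by angle (radians) about a coordinate axis
axis_rotation <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  ca <- cos(angle); sa <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
    y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
    z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3))
}

# point grid sampling a quarter cylinder (radius R, 90 degree span, length L)
# directly in world coordinates with a full mask; rows sweep the arc
quarter_cylinder_grid <- function(R = 0.1, L = 0.2, H = 192, W = 256) {
  phi <- seq(-pi / 4, pi / 4, length.out = H)
  xx <- seq(0, L, length.out = W)
  g <- list(
    x = matrix(rep(xx, each = H), H, W),
    y = matrix(rep(R * sin(phi), times = W), H, W),
    z = matrix(rep(R * cos(phi), times = W), H, W),
    valid = matrix(TRUE, H, W),
    mask = matrix(TRUE, H, W),
    depth_ok = matrix(TRUE, H, W),
    dim = c(H, W)
  )
  class(g) <- "point_grid"
  g
}

# point grid sampling a spherical cap of polar angle theta on radius R;
# rows sweep polar angle (pole to rim), cols sweep the full azimuth
spherical_cap_grid <- function(R = 0.1, theta = pi / 6, H = 256, W = 256) {
  th <- seq(0, theta, length.out = H)
  ph <- seq(0, 2 * pi, length.out = W)
  TH <- matrix(rep(th, times = W), H, W)
  PH <- matrix(rep(ph, each = H), H, W)
  g <- list(
    x = R * sin(TH) * cos(PH),
    y = R * sin(TH) * sin(PH),
    z = R * cos(TH),
    valid = matrix(TRUE, H, W),
    mask = matrix(TRUE, H, W),
    depth_ok = matrix(TRUE, H, W),
    dim = c(H, W)
  )
  class(g) <- "point_grid"
  g
}

# simple flat-scene builder: constant depth, elliptical or rectangular mask
flat_scene <- function(H = 96, W = 128, depth = 0.3, fx = 400, fy = 400,
                       mask_fun = NULL) {
  d <- matrix(depth, H, W)
  K <- camera_intrinsics(fx, fy, (W - 1) / 2, (H - 1) / 2)
  if (is.null(mask_fun)) {
    mask <- matrix(TRUE, H, W)
  } else {
    u <- matrix(rep(seq_len(W) - 1, each = H), H, W)
    v <- matrix(rep(seq_len(H) - 1, times = W), H, W)
    mask <- mask_fun(u, v)
  }
  list(depth = d, mask = mask, K = K)
}

# cache for scenes reused across test files (renders are deterministic)
.scene_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .scene_cache)) assign(key, force(expr), .scene_cache)
  get(key, .scene_cache)
}

back_cylinder_scene <- function() {
  cached("back_cyl", render_phantom(wrap_template(phantom_cylinder(curvature = 0.027))))
}
flat_phantom_scene <- function() {
  cached("flat", render_phantom(wrap_template(phantom_plane())))
}
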