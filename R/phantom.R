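#' Parametric body-surface phantoms
#'
#' Phantom surfaces stand in for the limbs and trunk regions that carry the
#' circular wound template: a plane, a circular cylinder, an elliptical
#' cylinder (the assumed cross-section of extremities) and a sphere. All
#' sizes are given in centimeters, matching caliper practice; curvatures use
#' the full-axis (diameter) convention, so a circular cylinder with
#' curvature `k` (1/cm) has radius `1 / (2 k)` cm.
#'
#' The canonical world frame places the template center at the origin with
#' the outward surface normal along +z. For cylinders the axis runs along
#' the world y axis, so the curved (wrap) direction lies along world x --
#' which the default camera maps to the wider image dimension.
#'
#' @param radius Radius in cm (`phantom_cylinder`, `phantom_sphere`).
#' @param curvature Alternative to `radius` for `phantom_cylinder`:
#'   diameter-convention curvature in 1/cm; radius is `1 / (2 * curvature)`.
#' @param long_axis,short_axis Full ellipse axis lengths in cm
#'   (`phantom_elliptical_cylinder`), `long_axis >= short_axis > 0`.
#' @param side Which vertex of the elliptical cross-section carries the
#'   template: `"flat"` (curvature `short/long^2`) or `"curved"`
#'   (`long/short^2`).
#' @return An object of class `phantom_surface`.
#' @name phantom_surface
#' @seealso [wrap_template()], [render_phantom()], [ground_truth()]
NULL

new_phantom <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "phantom_surface")
}

#' @rdname phantom_surface
#' @export
phantom_plane <- function() new_phantom("plane")

#' @rdname phantom_surface
#' @export
phantom_cylinder <- function(radius = NULL, curvature = NULL) {
  if (is.null(radius) == is.null(curvature)) {
    abort("give exactly one of radius (cm) or curvature (1/cm)")
  }
  if (!is.null(curvature)) {
    if (!is.finite(curvature) || curvature <= 0) abort("curvature must be > 0")
    radius <- 1 / (2 * curvature)
  }
  if (!is.finite(radius) || radius <= 0) abort("radius must be > 0")
  new_phantom("circular_cylinder", radius_cm = radius,
              curvature = 1 / (2 * radius))
}

#' @rdname phantom_surface
#' @export
phantom_elliptical_cylinder <- function(long_axis, short_axis,
                                        side = c("flat", "curved")) {
  side <- match.arg(side)
  if (!is.finite(long_axis) || !is.finite(short_axis) ||
      long_axis <= 0 || short_axis <= 0 || short_axis > long_axis) {
    abort("need full axis lengths with long_axis >= short_axis > 0")
  }
  kappa <- ellipse_curvature(long_axis, short_axis)
  new_phantom("elliptical_cylinder",
              long_axis_cm = long_axis, short_axis_cm = short_axis,
              side = side,
              curvature = if (side == "flat") kappa$flat_side else kappa$curved_side)
}

#' @rdname phantom_surface
#' @export
phantom_sphere <- function(radius) {
  if (!is.finite(radius) || radius <= 0) abort("radius must be > 0")
  new_phantom("sphere", radius_cm = radius, curvature = 1 / (2 * radius))
}

#' @export
print.phantom_surface <- function(x, ...) {
  extra <- switch(x$kind,
    plane = "",
    circular_cylinder = sprintf(" R=%.3g cm (curvature %.4g /cm)", x$radius_cm, x$curvature),
    elliptical_cylinder = sprintf(" axes %.3g x %.3g cm, %s side (curvature %.4g /cm)",
                                  x$long_axis_cm, x$short_axis_cm, x$side, x$curvature),
    sphere = sprintf(" R=%.3g cm (curvature %.4g /cm)", x$radius_cm, x$curvature))
  cat(sprintf("<phantom_surface: %s>%s\n", x$kind, extra))
  invisible(x)
}

# cross-section semi-axes in meters for the canonical frame:
# horizontal (x) semi-axis and vertical (z) semi-axis at the contact vertex
ellcyl_semiaxes <- function(surface) {
  As <- surface$long_axis_cm / 200  # semi = full/2, cm -> m
  Bs <- surface$short_axis_cm / 200
  if (surface$side == "flat") list(h = As, v = Bs) else list(h = Bs, v = As)
}

# cumulative arc length of the cross-section ellipse from the contact
# vertex, as monotone splines t <-> s (t = parametric angle, s in meters)
ellcyl_arclength <- function(h, v, n = 4097) {
  t <- seq(-pi / 2, pi / 2, length.out = n)
  speed <- sqrt((h * cos(t))^2 + (v * sin(t))^2)
  # cumulative trapezoid, s(0) = 0 at the vertex
  cs <- c(0, cumsum((speed[-1] + speed[-n]) / 2 * diff(t)))
  cs <- cs - cs[(n + 1) / 2]
  list(s_of_t = splinefun(t, cs, method = "hyman"),
       t_of_s = splinefun(cs, t, method = "hyman"),
       quarter = cs[n])
}

#' Wrap a circular template of exact area onto a phantom surface
#'
#' On developable surfaces (plane, cylinders) the disc is drawn in the
#' unrolled plane and re-rolled, so its surface area equals the requested
#' area exactly by construction. On spheres the template is the geodesic
#' disc (spherical cap) whose polar angle solves
#' `2 pi R^2 (1 - cos(theta)) = area`.
#'
#' @param surface A [phantom_surface] object.
#' @param area Template surface area in cm^2 (default
#'   [template_area_default()], 43).
#' @return An object of class `template_region`.
#' @export
#' @examples
#' wrap_template(phantom_cylinder(curvature = 0.027))
wrap_template <- function(surface, area = template_area_default()) {
  stopifnot(inherits(surface, "phantom_surface"))
  if (!is.finite(area) || area <= 0) abort("area must be a positive number of cm^2")
  r <- sqrt(area / pi) / 100  # geodesic disc radius, meters
  reg <- list(surface = surface, area_cm2 = area, r_disc = r)
  if (surface$kind == "circular_cylinder") {
    R <- surface$radius_cm / 100
    if (r >= pi * R / 2) {
      abort(sprintf("template too large: disc radius %.3g cm wraps beyond a quarter turn (pi R / 2 = %.3g cm)",
                    r * 100, pi * R / 2 * 100))
    }
  } else if (surface$kind == "elliptical_cylinder") {
    ax <- ellcyl_semiaxes(surface)
    arc <- ellcyl_arclength(ax$h, ax$v)
    if (r >= arc$quarter) {
      abort(sprintf("template too large: disc radius %.3g cm exceeds the quarter-section arc %.3g cm",
                    r * 100, arc$quarter * 100))
    }
    reg$arc <- arc
    reg$semiaxes <- ax
  } else if (surface$kind == "sphere") {
    R <- surface$radius_cm / 100
    c_th <- 1 - (area / 1e4) / (2 * pi * R^2)
    if (c_th <= 0) {  # cap larger than a hemisphere
      abort("template too large: geodesic disc exceeds a hemisphere")
    }
    reg$theta <- acos(c_th)
  }
  structure(reg, class = "template_region")
}

#' @export
print.template_region <- function(x, ...) {
  cat(sprintf("<template_region> %.4g cm^2 disc (r = %.3g cm) on %s\n",
              x$area_cm2, x$r_disc * 100, x$surface$kind))
  invisible(x)
}

# Simpson quadrature on a uniform grid (odd n)
simpson <- function(f, lower, upper, n = 20001) {
  x <- seq(lower, upper, length.out = n)
  w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
  sum(w * f(x)) * (x[2] - x[1]) / 3
}

#' Analytic ground truth for a wrapped template
#'
#' Returns the exact 3D surface area (the construction guarantees it equals
#' the requested template area) and the reference 2D projection area: the
#' area of the region's orthogonal projection onto its best-fit plane, which
#' by symmetry is the tangent plane at the template center. The projection
#' integrals are evaluated by dense deterministic quadrature of the
#' foreshortening factor and serve as the brute-force oracle for the
#' measurement pipeline.
#'
#' @param region A [wrap_template()] region.
#' @return A tibble with `area3d_cm2`, `area2d_cm2` and `ratio_3d_2d`.
#' @export
ground_truth <- function(region) {
  stopifnot(inherits(region, "template_region"))
  r <- region$r_disc
  kind <- region$surface$kind
  a2 <- switch(kind,
    plane = pi * r^2,
    circular_cylinder = {
      R <- region$surface$radius_cm / 100
      simpson(function(s) 2 * sqrt(pmax(r^2 - s^2, 0)) * cos(s / R), -r, r)
    },
    elliptical_cylinder = {
      ax <- region$semiaxes
      t_r <- region$arc$t_of_s(r)
      # ds = L(t) dt; projected width element is |x'(t)| dt = h cos(t) dt
      simpson(function(t) {
        s <- region$arc$s_of_t(t)
        2 * sqrt(pmax(r^2 - s^2, 0)) * ax$h * cos(t)
      }, -t_r, t_r)
    },
    sphere = {
      R <- region$surface$radius_cm / 100
      # projected area element of the cap: cos(g) * R^2 sin(g) dg dphi
      simpson(function(g) 2 * pi * R^2 * sin(g) * cos(g), 0, region$theta)
    })
  tibble::tibble(
    area3d_cm2 = region$area_cm2,
    area2d_cm2 = a2 * 1e4,
    ratio_3d_2d = region$area_cm2 / (a2 * 1e4)
  )
}

# camera extrinsics looking at `target` from `position` (world frame),
# camera x axis kept as close to world +x as possible
look_at_camera <- function(position, target = c(0, 0, 0), up = c(0, 1, 0)) {
  fwd <- target - position
  fwd <- fwd / sqrt(sum(fwd^2))
  xr <- pracma_cross(up, fwd)
  if (sqrt(sum(xr^2)) < 1e-8) xr <- pracma_cross(c(1, 0, 0), fwd)
  xr <- xr / sqrt(sum(xr^2))
  yr <- pracma_cross(fwd, xr)
  R <- rbind(xr, yr, fwd)  # rows = camera axes in world coords
  dimnames(R) <- NULL
  camera_extrinsics(R, -as.vector(R %*% position))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# boundary + center sample of the region, world frame (n x 3), used for
# framing and visibility checks
region_boundary_points <- function(region, n = 720) {
  psi <- seq(0, 2 * pi, length.out = n + 1)[-1]
  r <- region$r_disc
  su <- region$surface
  s <- r * sin(psi)  # arc coordinate (wrap direction)
  a <- r * cos(psi)  # axial / in-plane coordinate
  P <- switch(su$kind,
    plane = cbind(s, a, 0),
    circular_cylinder = {
      R <- su$radius_cm / 100
      phi <- s / R
      cbind(R * sin(phi), a, R * cos(phi) - R)
    },
    elliptical_cylinder = {
      t <- region$arc$t_of_s(s)
      cbind(region$semiaxes$h * sin(t), a,
            region$semiaxes$v * cos(t) - region$semiaxes$v)
    },
    sphere = {
      R <- su$radius_cm / 100
      g <- region$theta              # cap rim polar angle
      b <- atan2(a, s)               # bearing from cap center
      cbind(R * sin(g) * cos(b), R * sin(g) * sin(b), R * cos(g) - R)
    })
  rbind(P, c(0, 0, 0))
}

# nearest positive ray parameter for p = C + sv * D against the canonical
# surface; sv is z-depth when D has unit camera-z component
ray_surface_depth <- function(kind, geom, Cx, Cy, Cz, Dx, Dy, Dz) {
  if (kind == "plane") {
    s <- -Cz / Dz
    s[!is.finite(s) | s <= 0 | abs(Dz) < 1e-12] <- NA_real_
    return(s)
  }
  if (kind == "circular_cylinder") {
    R <- geom$R
    A <- Dx^2 + Dz^2
    B <- 2 * (Cx * Dx + (Cz + R) * Dz)
    C0 <- Cx^2 + (Cz + R)^2 - R^2
  } else if (kind == "elliptical_cylinder") {
    h <- geom$h; v <- geom$v
    A <- (Dx / h)^2 + (Dz / v)^2
    B <- 2 * (Cx * Dx / h^2 + (Cz + v) * Dz / v^2)
    C0 <- (Cx / h)^2 + ((Cz + v) / v)^2 - 1
  } else {  # sphere
    R <- geom$R
    A <- Dx^2 + Dy^2 + Dz^2
    B <- 2 * (Cx * Dx + Cy * Dy + (Cz + R) * Dz)
    C0 <- Cx^2 + Cy^2 + (Cz + R)^2 - R^2
  }
  disc <- B^2 - 4 * A * C0
  s <- (-B - sqrt(pmax(disc, 0))) / (2 * A)
  bad <- !is.finite(s) | disc < 0 | s <= 0
  bad[is.na(bad)] <- TRUE
  s[bad] <- NA_real_
  s
}

# region membership of world points on the canonical surface
region_member <- function(region, X, Y, Z) {
  su <- region$surface
  r <- region$r_disc
  switch(su$kind,
    plane = X^2 + Y^2 <= r^2,
    circular_cylinder = {
      R <- su$radius_cm / 100
      phi <- atan2(X, Z + R)
      (R * phi)^2 + Y^2 <= r^2
    },
    elliptical_cylinder = {
      h <- region$semiaxes$h; v <- region$semiaxes$v
      t <- atan2(X / h, (Z + v) / v)
      ok <- abs(t) <= pi / 2
      s <- ifelse(ok, region$arc$s_of_t(pmin(pmax(t, -pi / 2), pi / 2)), Inf)
      ok & (s^2 + Y^2 <= r^2)
    },
    sphere = {
      R <- su$radius_cm / 100
      g <- acos(pmin(pmax((Z + R) / R, -1), 1))
      g <= region$theta
    })
}

#' Render a LiDAR-style depth map of a phantom scene
#'
#' Casts one ray per pixel from a pinhole camera to the phantom surface
#' (closed-form ray/quadric intersection, no mesh) and records the z-depth
#' of the hit in the camera frame, together with the template mask (a pixel
#' is masked iff its hit point lies inside the wrapped template region).
#' Optional i.i.d. Gaussian depth noise emulates sensor error; the mask
#' stays exact by construction.
#'
#' By default the camera views the template frontally from `distance`
#' meters and the intrinsics are fitted so the template fills the frame with
#' a small border (`margin`); pass explicit `intrinsics` (and/or a `camera`
#' pose from a tilted viewpoint via `camera_tilt`) to override.
#'
#' @param region A [wrap_template()] region.
#' @param resolution Image size as `c(rows, cols)`; default the native depth
#'   sensor grid `c(192, 256)`.
#' @param distance Camera distance to the template center in meters
#'   (default 0.27); must lie in the sensor's working range `[0.1, 5]`.
#' @param intrinsics Optional [camera_intrinsics()]; `NULL` auto-fits.
#' @param camera_tilt Viewing direction tilt in degrees, length 2
#'   `(about world x, about world y)`; the camera orbits the template center
#'   at `distance`. Default `c(0, 0)` (frontal).
#' @param noise_sd Depth noise standard deviation in meters (default 0).
#' @param seed Integer seed for the noise draw (required when
#'   `noise_sd > 0` for reproducibility).
#' @param margin Auto-fit border fraction of the image (default 0.04).
#'
#' @return An object of class `phantom_scene`: list with `depth` (H x W,
#'   meters, `NA` = no return), `mask` (logical H x W), `intrinsics`,
#'   `extrinsics`, `region`, `truth` (from [ground_truth()]) and the render
#'   settings.
#' @export
render_phantom <- function(region, resolution = c(192, 256), distance = 0.27,
                           intrinsics = NULL, camera_tilt = c(0, 0),
                           noise_sd = 0, seed = NULL, margin = 0.04) {
  stopifnot(inherits(region, "template_region"))
  H <- as.integer(resolution[1]); W <- as.integer(resolution[2])
  if (H < 32 || W < 32) abort("resolution must be at least 32 x 32")
  if (distance < 0.1 || distance > 5) {
    abort("camera distance must lie within the sensor working range [0.1, 5] m")
  }
  su <- region$surface

  # camera pose: frontal or orbited by the requested tilt
  tilt <- rep_len(camera_tilt, 2) * pi / 180
  dirv <- c(sin(tilt[2]) * cos(tilt[1]), sin(tilt[1]), cos(tilt[2]) * cos(tilt[1]))
  Cpos <- distance * dirv
  ext <- if (all(tilt == 0)) {
    camera_extrinsics(diag(c(1, -1, -1)), c(0, 0, distance))
  } else {
    look_at_camera(Cpos, c(0, 0, 0), up = c(0, -1, 0))
  }
  R <- ext$rotation; tt <- ext$translation
  Cw <- -as.vector(t(R) %*% tt)  # camera center, world frame

  bpts <- region_boundary_points(region)
  if (is.null(intrinsics)) {
    bc <- as.matrix(world_to_camera(bpts, ext))
    if (any(bc[, 3] <= 0)) abort("template region lies behind the camera")
    nx <- bc[, 1] / bc[, 3]; ny <- bc[, 2] / bc[, 3]
    wn <- diff(range(nx)); hn <- diff(range(ny))
    fx <- W * (1 - 2 * margin) / wn
    fy <- H * (1 - 2 * margin) / hn
    ox <- (W - 1) / 2 - fx * mean(range(nx))
    oy <- (H - 1) / 2 - fy * mean(range(ny))
    intrinsics <- camera_intrinsics(fx, fy, ox, oy)
  }
  stopifnot(inherits(intrinsics, "camera_intrinsics"))

  geom <- switch(su$kind,
    plane = list(),
    circular_cylinder = list(R = su$radius_cm / 100),
    elliptical_cylinder = list(h = region$semiaxes$h, v = region$semiaxes$v),
    sphere = list(R = su$radius_cm / 100))

  # visibility: every boundary point must itself be the nearest surface hit
  bd <- sweep(bpts, 2, Cw)
  zb <- (bpts %*% t(R))[, 3] + tt[3]       # camera-frame z of boundary points
  Dv <- bd / zb                            # direction scaled to unit cam-z
  sb <- ray_surface_depth(su$kind, geom, Cw[1], Cw[2], Cw[3],
                          Dv[, 1], Dv[, 2], Dv[, 3])
  if (any(!is.finite(sb)) || any(sb < zb * (1 - 1e-6))) {
    abort("template region wraps beyond the visible horizon for this camera pose")
  }

  # per-pixel rays: p_world = C + s * (R^T d_cam), s = z-depth
  u <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  v <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  dx <- (u - intrinsics$ox) / intrinsics$fx
  dy <- (v - intrinsics$oy) / intrinsics$fy
  Dx <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1]
  Dy <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2]
  Dz <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3]
  s <- ray_surface_depth(su$kind, geom, Cw[1], Cw[2], Cw[3], Dx, Dy, Dz)
  X <- Cw[1] + s * Dx; Y <- Cw[2] + s * Dy; Z <- Cw[3] + s * Dz
  mask <- !is.na(s) & region_member(region, X, Y, Z)
  if (!any(mask)) abort("template region not visible at this resolution")
  # the full wound must be captured: the mask may not touch the image border
  if (any(mask[1, ]) || any(mask[H, ]) || any(mask[, 1]) || any(mask[, W])) {
    abort("template region partially outside the field of view")
  }

  depth <- s
  if (noise_sd > 0) {
    if (is.null(seed)) abort("a seed is required when noise_sd > 0")
    noise <- withr_seed(seed, rnorm(sum(!is.na(s)), sd = noise_sd))
    depth[!is.na(s)] <- pmax(depth[!is.na(s)] + noise, 1e-6)
  }

  structure(list(depth = depth, mask = mask,
                 intrinsics = intrinsics, extrinsics = ext,
                 region = region, truth = ground_truth(region),
                 resolution = c(H, W), distance = distance,
                 camera_tilt = camera_tilt / 1, noise_sd = noise_sd,
                 seed = seed, margin = margin),
            class = "phantom_scene")
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %s, %d x %d px, %.0f cm, %d masked px%s\n",
              x$region$surface$kind, x$resolution[1], x$resolution[2],
              x$distance * 100, sum(x$mask),
              if (x$noise_sd > 0) sprintf(", noise sd %.2g m", x$noise_sd) else ""))
  invisible(x)
}

#' Run the measurement pipeline on a rendered phantom scene
#'
#' Convenience wrapper equivalent to calling [measure_wounds()] on the
#' scene's depth map, mask and camera parameters.
#'
#' @param scene A [render_phantom()] scene.
#' @param ... Passed to [measure_wounds()].
#' @return A `wound_measurement` tibble.
#' @export
measure_scene <- function(scene, ...) {
  stopifnot(inherits(scene, "phantom_scene"))
  measure_wounds(scene$depth, scene$mask, scene$intrinsics, scene$extrinsics, ...)
}

#' Representative anatomical cross-sections for cohort simulation
#'
#' Full long/short axis lengths (cm) of elliptical cross-sections for the
#' body sites used in the template study, with the template placed on the
#' flat or curved vertex. The axes are representative adult values chosen to
#' reproduce the study's span of diameter-convention curvatures (about
#' 0.023-0.183 per cm); they are synthetic stand-ins, not participant data.
#'
#' @return A tibble with columns `location`, `long_axis`, `short_axis`,
#'   `side`.
#' @export
body_sites <- function() {
  tibble::tribble(
    ~location,            ~long_axis, ~short_axis, ~side,
    "forearm_volar",      7.4,        7.0,         "flat",
    "forearm_radial",     7.4,        7.0,         "curved",
    "arm_anterior",       6.5,        6.5,         "curved",
    "hand_dorsal",        9.0,        3.0,         "flat",
    "leg_anterior",       7.2,        7.2,         "curved",
    "leg_lateral",        11.0,       9.3,         "flat",
    "thigh_anterior",     10.0,       9.9,         "flat",
    "foot_dorsal",        9.6,        9.6,         "curved",
    "neck_nape",          8.8,        8.8,         "curved",
    "abdomen",            30.0,       24.3,        "flat",
    "back_lower",         34.0,       31.2,        "flat"
  )
}

#' Simulate a template-measurement cohort on elliptical-cylinder phantoms
#'
#' The synthetic twin of the template study: for each simulated subject and
#' body site, the site's cross-section axes are jittered (a common
#' per-subject scale factor plus a small shape factor on the short axis,
#' both truncated at two standard deviations so extreme draws stay
#' renderable), an elliptical-cylinder phantom is built with the template on
#' the configured vertex, a depth map is rendered and the full measurement
#' pipeline is run.
#'
#' @param sites Site table as from [body_sites()].
#' @param n Subjects per site (default 10).
#' @param scale_sd SD of the common axis scale factor (default 0.08).
#' @param shape_sd SD of the short-axis shape factor (default 0.03).
#' @param area Template area in cm^2.
#' @param resolution,distance,noise_sd Render settings; see
#'   [render_phantom()].
#' @param seed Integer seed controlling all randomness.
#'
#' @return A tibble of class `cohort_records`, one row per subject x site:
#'   `location`, `subject`, `long_axis`, `short_axis`, `side`, `curvature`
#'   (diameter convention, 1/cm), `area2d_cm2`, `area3d_cm2`, `gt_area_cm2`,
#'   `ratio_3d_2d`, `ratio_3d_gt`. Summarize with [ratio_stats()].
#' @export
simulate_cohort <- function(sites = body_sites(), n = 10,
                            scale_sd = 0.08, shape_sd = 0.03,
                            area = template_area_default(),
                            resolution = c(192, 256), distance = 0.27,
                            noise_sd = 0, seed = 1) {
  stopifnot(is.data.frame(sites),
            all(c("location", "long_axis", "short_axis", "side") %in% names(sites)))
  if (n < 2) abort("need at least 2 subjects per site")
  rtrunc <- function(m, sdv) {  # truncated at +/- 2 sd
    x <- rnorm(m, 1, sdv)
    pmin(pmax(x, 1 - 2 * sdv), 1 + 2 * sdv)
  }
  withr_seed(seed, {
    out <- purrr::pmap_dfr(sites, function(location, long_axis, short_axis, side) {
      scale <- rtrunc(n, scale_sd)
      shape <- rtrunc(n, shape_sd)
      purrr::map_dfr(seq_len(n), function(i) {
        a <- long_axis * scale[i]
        b <- min(short_axis * scale[i] * shape[i], a)
        surf <- if (abs(a - b) < 1e-9) {
          phantom_cylinder(radius = a / 2)
        } else {
          phantom_elliptical_cylinder(a, b, side)
        }
        scn <- render_phantom(wrap_template(surf, area),
                              resolution = resolution, distance = distance,
                              noise_sd = noise_sd,
                              seed = if (noise_sd > 0) sample.int(2^31 - 1, 1) else NULL)
        mm <- glance(measure_scene(scn))
        tibble::tibble(
          location = location, subject = i,
          long_axis = a, short_axis = b, side = side,
          curvature = surf$curvature,
          area2d_cm2 = mm$area2d_cm2, area3d_cm2 = mm$area3d_cm2,
          gt_area_cm2 = area,
          ratio_3d_2d = mm$ratio, ratio_3d_gt = mm$area3d_cm2 / area
        )
      })
    })
    class(out) <- c("cohort_records", class(out))
    out
  })
}
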