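#' Triangle area by Heron's formula
#'
#' Computes triangle areas from the Euclidean side lengths using the
#' numerically stabilized (sorted-side) form of Heron's formula,
#' `A = 1/4 * sqrt((a+(b+c)) (c-(a-b)) (c+(a-b)) (a+(b-c)))` with
#' `a >= b >= c`, so near-degenerate triangles cannot produce a negative
#' radicand. Degenerate (collinear) triangles return 0.
#'
#' @param p1,p2,p3 Triangle vertices in meters: length-3 vectors or n x 3
#'   matrices (one triangle per row).
#' @return Numeric vector of areas in square meters.
#' @export
#' @examples
#' heron_area(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))  # 6
heron_area <- function(p1, p2, p3) {
  as_mat <- function(p) if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3)
  edge <- function(a, b) sqrt(rowSums((a - b)^2))
  heron_sides(edge(p1, p2), edge(p2, p3), edge(p3, p1))
}

# stabilized Heron on side lengths (vectorized); clamps tiny negative radicands
heron_sides <- function(d1, d2, d3) {
  a <- pmax(d1, d2, d3)
  c <- pmin(d1, d2, d3)
  b <- d1 + d2 + d3 - a - c
  rad <- (a + (b + c)) * (c - (a - b)) * (c + (a - b)) * (a + (b - c))
  0.25 * sqrt(pmax(rad, 0))
}

#' Best-fit plane of an ordered 3D contour (Newell's method)
#'
#' Applies Newell's summation over consecutive vertex pairs (cyclically) to
#' obtain the polygon normal, with the contour centroid as the plane's
#' reference point. The normal's sign follows the contour orientation.
#'
#' @param contour Ordered contour vertices: n x 3 matrix or data frame with
#'   columns `x`, `y`, `z` (meters), n >= 3, not all collinear.
#' @return An object of class `wound_plane`: list with unit `normal` and
#'   centroid reference point `center`.
#' @export
newell_plane <- function(contour) {
  P <- as_xyz_matrix(contour)
  if (nrow(P) < 3) abort("degenerate contour: need at least 3 points")
  if (any(!is.finite(P))) abort("contour contains non-finite coordinates")
  Q <- P[c(2:nrow(P), 1), , drop = FALSE]
  n <- c(
    sum((P[, 2] - Q[, 2]) * (P[, 3] + Q[, 3])),
    sum((P[, 3] - Q[, 3]) * (P[, 1] + Q[, 1])),
    sum((P[, 1] - Q[, 1]) * (P[, 2] + Q[, 2]))
  )
  center <- colMeans(P)
  scale <- sum(sweep(P, 2, center)^2)
  nrm <- sqrt(sum(n^2))
  if (scale == 0 || nrm <= 1e-12 * scale) {
    abort("degenerate contour: points are collinear or coincident")
  }
  structure(list(normal = n / nrm, center = center), class = "wound_plane")
}

#' @export
print.wound_plane <- function(x, ...) {
  cat(sprintf("<wound_plane> n = (%.6f, %.6f, %.6f), c = (%.4g, %.4g, %.4g)\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# deterministic in-plane orthonormal basis: first axis is the world x-axis
# projected into the plane (y-axis fallback when nearly parallel to n)
plane_basis <- function(normal) {
  ref <- c(1, 0, 0)
  if (abs(sum(ref * normal)) > 0.9) ref <- c(0, 1, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  rbind(e1, e2)
}

# O(n^2) simple-polygon test on 2D vertices; used only for short contours
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n > 1500) return(NA)
  a <- xy
  b <- xy[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ux, uy, vx, vy) ux * vy - uy * vx
  simple <- TRUE
  for (i in seq_len(n - 2)) {
    j <- seq.int(i + 2, n)
    j <- j[!(i == 1 & j == n)]  # skip edges sharing a vertex
    if (!length(j)) next
    d1 <- cross2(b[i, 1] - a[i, 1], b[i, 2] - a[i, 2],
                 a[j, 1] - a[i, 1], a[j, 2] - a[i, 2])
    d2 <- cross2(b[i, 1] - a[i, 1], b[i, 2] - a[i, 2],
                 b[j, 1] - a[i, 1], b[j, 2] - a[i, 2])
    d3 <- cross2(b[j, 1] - a[j, 1], b[j, 2] - a[j, 2],
                 a[i, 1] - a[j, 1], a[i, 2] - a[j, 2])
    d4 <- cross2(b[j, 1] - a[j, 1], b[j, 2] - a[j, 2],
                 b[i, 1] - a[j, 1], b[i, 2] - a[j, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) { simple <- FALSE; break }
  }
  simple
}

#' 2D projection area of a wound contour
#'
#' Projects an ordered 3D contour onto its Newell best-fit plane, expresses
#' the projected vertices in a fixed in-plane orthonormal basis, and returns
#' the absolute signed (shoelace) polygon area. The signed form is exact for
#' all simple polygons, including concave ones, and agrees with a Heron fan
#' on convex contours.
#'
#' @inheritParams newell_plane
#' @param check_simple If `TRUE` (default), warn when a short contour
#'   self-intersects; the signed-area value is still returned.
#' @return Projection area in cm^2 (square centimeters), with the fitted
#'   plane attached as attribute `plane` and a `self_intersecting` flag.
#' @export
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 5)
#' projection_area(sq)  # 10000 cm^2
projection_area <- function(contour, check_simple = TRUE) {
  P <- as_xyz_matrix(contour)
  plane <- newell_plane(P)
  B <- plane_basis(plane$normal)
  rel <- sweep(P, 2, plane$center)
  uv <- rel %*% t(B)  # projecting onto the plane == dropping the n-component
  n <- nrow(uv)
  nxt <- c(2:n, 1)
  signed <- 0.5 * sum(uv[, 1] * uv[nxt, 2] - uv[nxt, 1] * uv[, 2])
  simple <- if (check_simple) polygon_is_simple(uv) else NA
  if (isFALSE(simple)) warn("contour is self-intersecting; signed area returned")
  structure(abs(signed) * 1e4, plane = plane,
            self_intersecting = isFALSE(simple))
}

#' Label 4-connected components of a binary mask
#'
#' @param mask H x W logical (or 0/1) matrix.
#' @return Integer H x W matrix; 0 = background, 1..k = component labels in
#'   top-left-first scan order.
#' @export
label_components <- function(mask) {
  m <- as.matrix(mask) > 0
  m[is.na(m)] <- FALSE
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  idx <- which(m)
  if (!length(idx)) return(lab)
  nextlab <- 0L
  stack <- integer(length(idx))
  for (s in idx) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    top <- 1L
    stack[1L] <- s
    lab[s] <- nextlab
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- ((cur - 1L) %% H) + 1L
      cc <- ((cur - 1L) %/% H) + 1L
      if (r > 1L) { nb <- cur - 1L
        if (m[nb] && lab[nb] == 0L) { lab[nb] <- nextlab; top <- top + 1L; stack[top] <- nb } }
      if (r < H) { nb <- cur + 1L
        if (m[nb] && lab[nb] == 0L) { lab[nb] <- nextlab; top <- top + 1L; stack[top] <- nb } }
      if (cc > 1L) { nb <- cur - H
        if (m[nb] && lab[nb] == 0L) { lab[nb] <- nextlab; top <- top + 1L; stack[top] <- nb } }
      if (cc < W) { nb <- cur + H
        if (m[nb] && lab[nb] == 0L) { lab[nb] <- nextlab; top <- top + 1L; stack[top] <- nb } }
    }
  }
  lab
}

#' Trace the outer boundary of a mask component (Moore tracing)
#'
#' Moore-neighbor boundary tracing with Jacob's stopping criterion on the
#' first (top-left-most) 4-connected component of the mask, returning the
#' ordered closed boundary as pixel (row, col) pairs. Orientation is fixed:
#' the traced polygon is counter-clockwise in image coordinates (v axis
#' pointing down).
#'
#' @param mask H x W logical (or 0/1) matrix containing a single component
#'   (extra components are ignored).
#' @return Integer matrix with columns `row`, `col` (1-based).
#' @export
trace_boundary <- function(mask) {
  m <- as.matrix(mask) > 0
  m[is.na(m)] <- FALSE
  H <- nrow(m); W <- ncol(m)
  idx <- which(m)
  if (!length(idx)) abort("no wound: mask is empty")
  # start at the top-left-most masked pixel (row-major scan)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  ord <- order(rows, cols)
  r0 <- rows[ord[1L]]; c0 <- cols[ord[1L]]
  inside <- function(r, cc) r >= 1L && r <= H && cc >= 1L && cc <= W && m[r, cc]
  # 8-neighborhood, clockwise starting from West
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  boundary <- matrix(0L, nrow = 4L * (H + W) + 8L, ncol = 2L)
  nb <- 1L
  boundary[1L, ] <- c(r0, c0)
  if (sum(m) == 1L) return(boundary[1L, , drop = FALSE])
  # the scan around each boundary pixel starts at its backtrack: the last
  # background neighbour examined before the pixel was entered. The start
  # pixel's backtrack is its (background) West neighbour.
  scan_next <- function(r, cc, start_idx) {
    # first foreground neighbour clockwise from start_idx (0-based ring pos);
    # returns c(row, col, new_start_idx) or NULL
    for (k in 0:7) {
      d <- (start_idx + k) %% 8L + 1L
      rr <- r + dr[d]; ccn <- cc + dc[d]
      if (inside(rr, ccn)) {
        dprev <- (start_idx + k - 1L) %% 8L + 1L   # last background cell
        bg <- c(r + dr[dprev], cc + dc[dprev])
        delta_r <- bg[1] - rr; delta_c <- bg[2] - ccn
        j <- which(dr == delta_r & dc == delta_c)  # bg seen from new pixel
        return(c(rr, ccn, j - 1L))
      }
    }
    NULL
  }
  r <- r0; cc <- c0; start_idx <- 0L
  first_step <- NULL
  steps <- 0L
  repeat {
    nxt <- scan_next(r, cc, start_idx)
    if (is.null(nxt)) break  # isolated pixel (cannot happen when sum > 1)
    r <- nxt[1]; cc <- nxt[2]; start_idx <- nxt[3]
    if (nb >= nrow(boundary)) boundary <- rbind(boundary, boundary)
    nb <- nb + 1L
    boundary[nb, ] <- c(r, cc)
    if (is.null(first_step)) {
      first_step <- c(r, cc)
    } else if (r == r0 && cc == c0) {
      # Jacob's criterion: stop when the start is re-entered such that the
      # trace would repeat its first move
      peek <- scan_next(r, cc, start_idx)
      if (!is.null(peek) && all(peek[1:2] == first_step)) break
    }
    steps <- steps + 1L
    if (steps > 8L * H * W) break  # safety net
  }
  out <- boundary[seq_len(nb - 1L), , drop = FALSE]  # drop repeated start
  colnames(out) <- c("row", "col")
  # fix orientation: counter-clockwise with the v (row) axis pointing down
  if (nrow(out) >= 3) {
    u <- out[, "col"]; v <- out[, "row"]
    nxt <- c(2:nrow(out), 1)
    if (0.5 * sum(u * v[nxt] - u[nxt] * v) < 0) out <- out[nrow(out):1, , drop = FALSE]
  }
  out
}

#' Triangulated 3D surface area over a masked point grid
#'
#' Approximates the curved wound surface by scanning all 2 x 2 pixel quads
#' from the top-left to the bottom-right, splitting each along its
#' top-left-to-bottom-right diagonal into two triangles, and summing Heron
#' areas. A triangle contributes iff all three of its vertices are valid
#' masked cells, so no area is extrapolated outside the segmented wound; the
#' resulting boundary bias is surfaced through `coverage`.
#'
#' @param grid A `point_grid` from [unproject_depth_map()].
#' @param mask Optional H x W mask restricting the grid's valid cells
#'   further (e.g. one wound component).
#' @param diagonal Quad-splitting diagonal; the default `"tlbr"` follows the
#'   top-left-to-bottom-right scan. `"trbl"` exists to quantify that the
#'   choice is immaterial.
#' @return A list: `area_cm2` (triangle-area sum), `triangle_count`, and
#'   `coverage` = fully valid masked quads / fully masked quads.
#' @export
surface_area_3d <- function(grid, mask = NULL, diagonal = c("tlbr", "trbl")) {
  stopifnot(inherits(grid, "point_grid"))
  diagonal <- match.arg(diagonal)
  H <- grid$dim[1]; W <- grid$dim[2]
  if (is.null(mask)) {
    msk <- grid$mask  # the wound mask the grid was built with
    valid <- grid$valid
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == c(H, W))) abort("mask dimensions must match the grid")
    msk <- mask > 0 & !is.na(mask)
    valid <- grid$valid & msk
  }
  X <- grid$x; Y <- grid$y; Z <- grid$z
  i <- seq_len(H - 1); j <- seq_len(W - 1)
  TL <- outer(i, (j - 1L) * H, `+`)
  TR <- TL + H; BL <- TL + 1L; BR <- TR + 1L
  d3 <- function(a, b) sqrt((X[a] - X[b])^2 + (Y[a] - Y[b])^2 + (Z[a] - Z[b])^2)
  if (diagonal == "tlbr") {
    ok1 <- valid[TL] & valid[TR] & valid[BR]
    ok2 <- valid[TL] & valid[BL] & valid[BR]
    a1 <- heron_sides(d3(TL, TR), d3(TR, BR), d3(BR, TL))
    a2 <- heron_sides(d3(TL, BL), d3(BL, BR), d3(BR, TL))
  } else {
    ok1 <- valid[TR] & valid[TL] & valid[BL]
    ok2 <- valid[TR] & valid[BR] & valid[BL]
    a1 <- heron_sides(d3(TR, TL), d3(TL, BL), d3(BL, TR))
    a2 <- heron_sides(d3(TR, BR), d3(BR, BL), d3(BL, TR))
  }
  count <- sum(ok1) + sum(ok2)
  if (count < 1) abort("unmeasurable wound: no triangle has three valid masked vertices")
  quad_masked <- msk[TL] & msk[TR] & msk[BL] & msk[BR]
  quad_valid <- valid[TL] & valid[TR] & valid[BL] & valid[BR]
  coverage <- if (sum(quad_masked) > 0) sum(quad_valid & quad_masked) / sum(quad_masked) else NA_real_
  list(area_cm2 = (sum(a1[ok1]) + sum(a2[ok2])) * 1e4,
       triangle_count = as.integer(count),
       coverage = coverage)
}

#' Measure wound areas from a depth map and segmentation mask
#'
#' The full measurement pipeline: unprojects the depth map to world
#' coordinates, splits the mask into 4-connected wound components, and for
#' each component computes the 2D projection area of its traced outer
#' contour on the component's own best-fit plane together with the
#' triangulated 3D surface area. Components are measured independently and
#' the totals are the sums across components, mirroring how multi-wound
#' images are handled by summing 2D and 3D results separately.
#'
#' @inheritParams unproject_depth_map
#' @param min_coverage Wounds whose depth coverage falls below this fraction
#'   are flagged `low_coverage` (default 0.95).
#' @param min_pixels Components with fewer valid cells than this are dropped
#'   with a warning (default 3).
#'
#' @return A tibble of class `wound_measurement`, one row per wound:
#'   `wound`, `pixels`, `area2d_cm2`, `area3d_cm2`, `ratio` (3D/2D),
#'   `triangle_count`, `coverage`, `low_coverage`. Totals are available via
#'   [glance()].
#' @export
measure_wounds <- function(depth, mask, intrinsics, extrinsics = NULL,
                           min_coverage = 0.95, min_pixels = 3L) {
  grid <- unproject_depth_map(depth, mask, intrinsics, extrinsics)
  if (!any(grid$valid)) abort("no wound: mask selects no valid-depth pixels")
  # wounds are 4-connected components of the segmentation mask; depth
  # validity is applied inside each component (holes reduce coverage)
  lab <- label_components(grid$mask)
  k <- max(lab)
  rows <- vector("list", k)
  for (comp in seq_len(k)) {
    cm <- lab == comp
    cm_valid <- cm & grid$valid
    npix <- sum(cm_valid)
    if (npix < min_pixels) {
      warn(sprintf("dropping wound component %d: only %d valid pixels", comp, npix))
      next
    }
    bnd <- trace_boundary(cm_valid)
    pts <- cbind(grid$x[cbind(bnd[, 1], bnd[, 2])],
                 grid$y[cbind(bnd[, 1], bnd[, 2])],
                 grid$z[cbind(bnd[, 1], bnd[, 2])])
    a2 <- tryCatch(projection_area(pts, check_simple = FALSE),
                   error = function(e) {
                     warn(sprintf("wound component %d: %s", comp, conditionMessage(e)))
                     NA_real_
                   })
    a3 <- surface_area_3d(grid, cm)
    rows[[comp]] <- tibble::tibble(
      wound = comp,
      pixels = npix,
      area2d_cm2 = as.numeric(a2),
      area3d_cm2 = a3$area_cm2,
      ratio = a3$area_cm2 / as.numeric(a2),
      triangle_count = a3$triangle_count,
      coverage = a3$coverage,
      low_coverage = is.finite(a3$coverage) && a3$coverage < min_coverage
    )
  }
  res <- dplyr::bind_rows(rows)
  if (!nrow(res)) abort("no measurable wound component in mask")
  res$wound <- seq_len(nrow(res))
  if (any(res$low_coverage)) {
    warn(sprintf("%d wound(s) below the %.0f%% depth-coverage threshold",
                 sum(res$low_coverage), 100 * min_coverage))
  }
  class(res) <- c("wound_measurement", class(res))
  res
}

#' @exportS3Method
glance.wound_measurement <- function(x, ...) {
  a2 <- sum(x$area2d_cm2)
  a3 <- sum(x$area3d_cm2)
  tibble::tibble(
    n_wounds = nrow(x),
    area2d_cm2 = a2,
    area3d_cm2 = a3,
    ratio = a3 / a2,
    min_coverage = min(x$coverage)
  )
}

#' @exportS3Method
tidy.wound_measurement <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "wound_measurement")
  out
}
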