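DEPTH_MAGIC <- "BMDEPTH1"

#' Read and write depth maps in the package's binary dialect
#'
#' The vendor layout of mobile depth exports is undocumented, so this
#' package defines its own dialect: an 8-byte ASCII magic tag
#' (`"BMDEPTH1"`), two little-endian int32 giving height then width, and
#' `H * W` little-endian float32 depths in meters, row-major. Missing
#' returns are stored as the non-positive sentinel `-1` and surface as `NA`
#' in memory. Reading back a written file is bit-identical.
#'
#' @param path File path.
#' @param depth H x W numeric matrix of depths in meters (`NA` or
#'   non-positive = invalid).
#' @return `read_depth_bin()` returns the depth matrix; `write_depth_bin()`
#'   returns `path` invisibly.
#' @name depth_bin
#' @export
read_depth_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic, charToRaw(DEPTH_MAGIC))) {
    abort(sprintf("bad depth file magic in %s", path))
  }
  hw <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  H <- hw[1]; W <- hw[2]
  if (is.na(H) || is.na(W) || H < 2 || W < 2) {
    abort("corrupt depth file header: implausible dimensions")
  }
  expect <- 16 + 4 * H * W
  if (file.size(path) != expect) {
    abort(sprintf("truncated or oversized depth file: %d bytes, expected %d",
                  file.size(path), expect))
  }
  vals <- readBin(con, "numeric", H * W, size = 4L, endian = "little")
  d <- matrix(vals, H, W, byrow = TRUE)
  d[!is.finite(d) | d <= 0] <- NA_real_
  d
}

#' @rdname depth_bin
#' @export
write_depth_bin <- function(depth, path) {
  depth <- as.matrix(depth)
  H <- nrow(depth); W <- ncol(depth)
  vals <- as.vector(t(depth))  # row-major
  vals[!is.finite(vals) | vals <= 0] <- -1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(DEPTH_MAGIC), con)
  writeBin(as.integer(c(H, W)), con, size = 4L, endian = "little")
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read and write binary wound masks as PNG
#'
#' Masks are 8-bit grayscale PNGs with any nonzero pixel marking wound.
#'
#' @param path PNG file path.
#' @param mask H x W logical (or 0/1) matrix.
#' @return `read_mask_png()` returns a logical matrix; `write_mask_png()`
#'   returns `path` invisibly.
#' @name mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0
}

#' @rdname mask_png
#' @export
write_mask_png <- function(mask, path) {
  m <- (as.matrix(mask) > 0) * 1
  png::writePNG(m, path)
  invisible(path)
}

#' Read polygon wound annotations (Labelme JSON)
#'
#' Parses the polygon `shapes` of a Labelme-style annotation file. Shapes
#' with fewer than 3 vertices are skipped with a warning.
#'
#' @param path JSON file path.
#' @return A list of polygons, each a list with `label` and `points` (n x 2
#'   matrix of (u, v) pixel coordinates); the annotation's `imageHeight` /
#'   `imageWidth` are attached as the `image_size` attribute `c(H, W)` when
#'   present.
#' @export
read_labelme <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  shapes <- doc$shapes
  if (is.null(shapes)) abort("not a Labelme annotation: no 'shapes' entry")
  polys <- list()
  for (sh in shapes) {
    if (!is.null(sh$shape_type) && !identical(sh$shape_type, "polygon")) next
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(pts) < 3) {
      warn(sprintf("skipping shape '%s': fewer than 3 vertices",
                   if (is.null(sh$label)) "?" else sh$label))
      next
    }
    polys[[length(polys) + 1]] <- list(
      label = if (is.null(sh$label)) "wound" else sh$label,
      points = pts
    )
  }
  if (!is.null(doc$imageHeight) && !is.null(doc$imageWidth)) {
    attr(polys, "image_size") <- c(as.integer(doc$imageHeight),
                                   as.integer(doc$imageWidth))
  }
  polys
}

# even-odd point-in-polygon for pixel centers of one polygon (u, v 0-based)
rasterize_one <- function(pts, H, W) {
  m <- matrix(FALSE, H, W)
  u0 <- max(0L, floor(min(pts[, 1])))
  u1 <- min(W - 1L, ceiling(max(pts[, 1])))
  v0 <- max(0L, floor(min(pts[, 2])))
  v1 <- min(H - 1L, ceiling(max(pts[, 2])))
  if (u1 < u0 || v1 < v0) return(m)
  us <- u0:u1; vs <- v0:v1
  U <- matrix(rep(us, each = length(vs)), length(vs), length(us))
  V <- matrix(rep(vs, times = length(us)), length(vs), length(us))
  inside <- matrix(FALSE, length(vs), length(us))
  n <- nrow(pts)
  j <- n
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]
    xj <- pts[j, 1]; yj <- pts[j, 2]
    crosses <- ((yi > V) != (yj > V)) &
      (U < (xj - xi) * (V - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  m[cbind(as.vector(V) + 1L, as.vector(U) + 1L)] <- as.vector(inside)
  m
}

#' Rasterize wound polygons to a mask at depth-map resolution
#'
#' Uses the even-odd rule sampled at pixel centers. Polygons annotated at a
#' different (e.g. RGB) resolution are rescaled to the target grid by the
#' resolution ratio before rasterizing.
#'
#' @param polygons A list as returned by [read_labelme()], or a single n x 2
#'   matrix of (u, v) vertices.
#' @param height,width Target mask dimensions (the depth grid).
#' @param source_size Optional `c(H, W)` of the coordinate system the
#'   polygons were annotated in; default the `image_size` attribute, else
#'   the target size.
#' @return H x W logical mask (union of all polygons).
#' @export
rasterize_polygons <- function(polygons, height, width, source_size = NULL) {
  if (is.matrix(polygons)) polygons <- list(list(label = "wound", points = polygons))
  if (is.null(source_size)) source_size <- attr(polygons, "image_size")
  sx <- if (is.null(source_size)) 1 else width / source_size[2]
  sy <- if (is.null(source_size)) 1 else height / source_size[1]
  mask <- matrix(FALSE, height, width)
  for (poly in polygons) {
    pts <- poly$points
    pts <- cbind(pts[, 1] * sx, pts[, 2] * sy)
    mask <- mask | rasterize_one(pts, height, width)
  }
  mask
}

#' Read and write camera parameters as JSON
#'
#' Small explicit-field JSON documents: intrinsics as
#' `{"fx":..,"fy":..,"ox":..,"oy":..}` and extrinsics as
#' `{"rotation": [[..]x3], "translation": [..]}`.
#'
#' @param path JSON file path.
#' @param intrinsics,extrinsics Objects from [camera_intrinsics()] /
#'   [camera_extrinsics()].
#' @name camera_json
#' @export
read_intrinsics_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  camera_intrinsics(doc$fx, doc$fy, doc$ox, doc$oy)
}

#' @rdname camera_json
#' @export
write_intrinsics_json <- function(intrinsics, path) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  jsonlite::write_json(intrinsics[c("fx", "fy", "ox", "oy")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname camera_json
#' @export
read_extrinsics_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  R <- doc$rotation
  R <- if (is.list(R)) do.call(rbind, lapply(R, unlist)) else as.matrix(R)
  camera_extrinsics(R, unlist(doc$translation))
}

#' @rdname camera_json
#' @export
write_extrinsics_json <- function(extrinsics, path) {
  stopifnot(inherits(extrinsics, "camera_extrinsics"))
  jsonlite::write_json(
    list(rotation = apply(extrinsics$rotation, 1, identity, simplify = FALSE),
         translation = extrinsics$translation),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read and write measurement-record tables as CSV
#'
#' One row per measured image/wound set. Recognized columns: `location`,
#' `subject`, `area2d_cm2`, `area3d_cm2`, `gt_area_cm2`, `curvature`,
#' `n_wounds`, plus any ratio columns; extra columns pass through.
#'
#' @param path CSV file path.
#' @param records A data frame of measurement records.
#' @name records_csv
#' @export
read_records_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname records_csv
#' @export
write_records_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Save a rendered phantom scene as capture-style files
#'
#' Writes `depth.bin`, `mask.png`, `intrinsics.json`, `extrinsics.json` and
#' `truth.json` into a directory, so synthetic scenes flow through exactly
#' the same files as real captures.
#'
#' @param scene A [render_phantom()] scene.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "phantom_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_depth_bin(scene$depth, file.path(dir, "depth.bin"))
  write_mask_png(scene$mask, file.path(dir, "mask.png"))
  write_intrinsics_json(scene$intrinsics, file.path(dir, "intrinsics.json"))
  write_extrinsics_json(scene$extrinsics, file.path(dir, "extrinsics.json"))
  jsonlite::write_json(as.list(scene$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a capture directory and measure it
#'
#' Reads a directory written by [write_scene()] (or assembled from real
#' captures in the same dialect) and runs [measure_wounds()].
#'
#' @param dir Directory containing `depth.bin`, a `mask.png` or Labelme
#'   `annotation.json`, `intrinsics.json` and optionally `extrinsics.json`.
#' @param ... Passed to [measure_wounds()].
#' @return A `wound_measurement` tibble.
#' @export
measure_capture <- function(dir, ...) {
  depth <- read_depth_bin(file.path(dir, "depth.bin"))
  K <- read_intrinsics_json(file.path(dir, "intrinsics.json"))
  extp <- file.path(dir, "extrinsics.json")
  ext <- if (file.exists(extp)) read_extrinsics_json(extp) else NULL
  annp <- file.path(dir, "annotation.json")
  mask <- if (file.exists(annp)) {
    rasterize_polygons(read_labelme(annp), nrow(depth), ncol(depth))
  } else {
    read_mask_png(file.path(dir, "mask.png"))
  }
  measure_wounds(depth, mask, K, ext, ...)
}
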