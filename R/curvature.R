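#' Vertex curvatures of an elliptical body cross-section
#'
#' Limb and trunk cross-sections are modelled as ellipses gauged by their
#' full long and short axis lengths `a >= b` (caliper measurements, cm). The
#' flatter vertex (e.g. the volar forearm) has curvature `b / a^2` and the
#' sharper vertex (e.g. the radial forearm) has curvature `a / b^2`. In the
#' circular limit `a = b = r` both reduce to `1 / r`.
#'
#' Note the convention: curvatures are expressed on *full* axis lengths
#' (diameters), not semi-axes, so the circular value `1/r` uses the diameter.
#' Phantom builders in this package share the convention: a circular cylinder
#' with diameter-convention curvature `k` has radius `1 / (2 k)`.
#'
#' @param long_axis,short_axis Full axis lengths in cm; both positive, with
#'   `long_axis >= short_axis`. Vectorized.
#' @return A tibble with columns `long_axis`, `short_axis`, `flat_side`,
#'   `curved_side` (curvatures in 1/cm).
#' @seealso [curvature_report()] for the 3-decimal truncated display values,
#'   [predicted_ratio()] for the curvature-to-area-ratio model.
#' @export
#' @examples
#' ellipse_curvature(7.4, 7.0)        # flat 0.1278..., curved 0.1510...
#' curvature_report(ellipse_curvature(7.4, 7.0))  # 0.127 / 0.151
ellipse_curvature <- function(long_axis, short_axis) {
  n <- max(length(long_axis), length(short_axis))
  a <- rep_len(as.numeric(long_axis), n)
  b <- rep_len(as.numeric(short_axis), n)
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    abort("axis lengths must be positive finite numbers")
  }
  if (any(b > a)) abort("long_axis must be >= short_axis")
  tibble::tibble(
    long_axis = a,
    short_axis = b,
    flat_side = b / a^2,
    curved_side = a / b^2
  )
}

#' Truncate curvatures toward zero for reporting
#'
#' Reported curvatures are truncated (not rounded) to three decimals:
#' 7.0/7.4^2 = 0.12783... is displayed as 0.127.
#'
#' @param x A numeric vector, or a tibble from [ellipse_curvature()] whose
#'   `flat_side`/`curved_side` columns are to be truncated.
#' @param digits Decimal places kept (default 3).
#' @return Same shape as `x`, truncated toward zero.
#' @export
curvature_report <- function(x, digits = 3) {
  tr <- function(v) trunc(v * 10^digits) / 10^digits
  if (is.data.frame(x)) {
    for (cn in intersect(c("flat_side", "curved_side"), names(x))) x[[cn]] <- tr(x[[cn]])
    x
  } else {
    tr(x)
  }
}

#' Predicted 3D/2D area ratio of a circular template on a curved surface
#'
#' Models the wound template as a geodesic disc of the given area wrapped
#' onto a circular cylinder whose diameter-convention curvature is `curvature`
#' (radius `1 / (2 * curvature)` cm, diameter convention). The predicted
#' ratio is the disc's surface area divided by the area of its orthogonal
#' projection onto the tangent plane at the disc center. The projection area
#' is obtained by deterministic numerical integration of the foreshortening
#' factor `cos(s / R)` over the disc (`s` = arc distance in the wrap
#' direction), which for small curvature reduces to the closed form
#' `1 / (1 - r^2 / (8 R^2))`.
#'
#' @param curvature Diameter-convention curvature in 1/cm (`>= 0`). Vectorized.
#' @param template_area Template surface area in cm^2 (default the standard
#'   template, [template_area_default()]).
#' @return Numeric vector of predicted 3D/2D ratios (`1` at zero curvature).
#' @export
#' @examples
#' predicted_ratio(0)              # exactly 1
#' predicted_ratio(0.027)          # about 1.005
predicted_ratio <- function(curvature, template_area = template_area_default()) {
  if (any(!is.finite(curvature)) || any(curvature < 0)) {
    abort("curvature must be finite and >= 0")
  }
  if (length(template_area) != 1 || !is.finite(template_area) || template_area <= 0) {
    abort("template_area must be a positive scalar")
  }
  r <- sqrt(template_area / pi)
  vapply(curvature, function(k) {
    if (k == 0) return(1)
    R <- 1 / (2 * k)
    if (r >= pi * R / 2) {
      abort(sprintf(
        "out of model: disc radius %.3g cm wraps beyond a quarter turn of a cylinder with radius %.3g cm",
        r, R))
    }
    proj <- integrate(function(s) 2 * sqrt(pmax(r^2 - s^2, 0)) * cos(s / R),
                      lower = -r, upper = r,
                      rel.tol = 1e-12, abs.tol = 0)$value
    (pi * r^2) / proj
  }, numeric(1))
}

#' Standard circular template area
#'
#' The template is sized at 1/400 of the average adult total body surface
#' area; with the 17,000 cm^2 adult reference this gives 42.5, reported
#' rounded (half away from zero) as 43 cm^2.
#'
#' @param adult_bsa_cm2 Adult total body surface area reference (cm^2).
#' @param fraction Template fraction of the body surface (default 1/400).
#' @return Template area in cm^2 (integer-valued; 43 for the defaults).
#' @export
template_area_default <- function(adult_bsa_cm2 = 17000, fraction = 1 / 400) {
  x <- adult_bsa_cm2 * fraction
  floor(x + 0.5)  # half away from zero for positive areas
}
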