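#' Per-location summary of measurement ratios
#'
#' Summarizes a measurement cohort per location: sample mean and sample
#' standard deviation (n - 1 denominator) of the 3D/ground-truth ratio, the
#' 3D/2D ratio and the cross-section curvature, for whichever of those
#' columns are present. Record order is irrelevant.
#'
#' @param records A data frame with a `location` column and some of
#'   `ratio_3d_gt`, `ratio_3d_2d`, `curvature` (the latter two are derived
#'   from `area3d_cm2`/`area2d_cm2`/`gt_area_cm2` when absent but
#'   derivable), e.g. from [simulate_cohort()] or [read_records_csv()].
#' @return A tibble of class `cohort_summary`, one row per location with
#'   `n` and `<quantity>_mean` / `<quantity>_sd` columns.
#' @export
#' @examples
#' rec <- tibble::tibble(location = "site", area2d_cm2 = c(40, 41),
#'                       area3d_cm2 = c(44, 45.1))
#' ratio_stats(rec)
ratio_stats <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"location" %in% names(records)) {
    records$location <- "all"
  }
  if (!"ratio_3d_2d" %in% names(records) &&
      all(c("area2d_cm2", "area3d_cm2") %in% names(records))) {
    records$ratio_3d_2d <- records$area3d_cm2 / records$area2d_cm2
  }
  if (!"ratio_3d_gt" %in% names(records) &&
      all(c("gt_area_cm2", "area3d_cm2") %in% names(records))) {
    records$ratio_3d_gt <- records$area3d_cm2 / records$gt_area_cm2
  }
  qty <- intersect(c("ratio_3d_gt", "ratio_3d_2d", "curvature"), names(records))
  if (!length(qty)) abort("no summarizable ratio/curvature columns in records")
  empty <- is.na(records$location)
  if (any(empty)) {
    warn(sprintf("omitting %d record(s) with missing location", sum(empty)))
    records <- records[!empty, , drop = FALSE]
  }
  out <- records |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(qty),
                    list(mean = ~mean(.x), sd = ~sd(.x))),
      .groups = "drop"
    )
  class(out) <- c("cohort_summary", class(out))
  out
}

new_area_fit <- function(fit, records, response, predictor) {
  sm <- summary(fit)
  structure(list(fit = fit, records = records,
                 response = response, predictor = predictor,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 n = length(fit$residuals)),
            class = "area_fit")
}

check_fit_input <- function(records, xcol, ycol) {
  stopifnot(is.data.frame(records))
  if (!all(c(xcol, ycol) %in% names(records))) {
    abort(sprintf("records must contain columns %s and %s", xcol, ycol))
  }
  x <- records[[xcol]]
  if (sum(stats::complete.cases(records[, c(xcol, ycol)])) < 3) {
    abort("need at least 3 complete records for a regression")
  }
  if (sd(x, na.rm = TRUE) == 0) abort("degenerate fit: predictor is constant")
  invisible(TRUE)
}

#' Linear fit of 3D surface area against 2D projection area
#'
#' Ordinary least squares of `area3d_cm2` on `area2d_cm2` with intercept.
#' The slope estimates how many times larger the 3D surface area is than
#' the 2D projection area on average; R-squared measures how well the
#' linear relation explains the data.
#'
#' @param records Data frame with columns `area2d_cm2` and `area3d_cm2`.
#' @return An object of class `area_fit` with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
fit_3d_vs_2d <- function(records) {
  check_fit_input(records, "area2d_cm2", "area3d_cm2")
  fit <- lm(area3d_cm2 ~ area2d_cm2, data = records)
  new_area_fit(fit, records, "area3d_cm2", "area2d_cm2")
}

#' Linear fit of the 3D/2D ratio against wound size
#'
#' Ordinary least squares of the per-record 3D/2D area ratio on the 3D
#' surface area, probing whether larger wounds show a larger 2D
#' underestimate (a positive slope).
#'
#' @inheritParams fit_3d_vs_2d
#' @return An object of class `area_fit`.
#' @export
ratio_vs_size <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"ratio_3d_2d" %in% names(records)) {
    if (!all(c("area2d_cm2", "area3d_cm2") %in% names(records))) {
      abort("records must contain ratio_3d_2d or both area columns")
    }
    records$ratio_3d_2d <- records$area3d_cm2 / records$area2d_cm2
  }
  check_fit_input(records, "area3d_cm2", "ratio_3d_2d")
  fit <- lm(ratio_3d_2d ~ area3d_cm2, data = records)
  new_area_fit(fit, records, "ratio_3d_2d", "area3d_cm2")
}

#' @export
print.area_fit <- function(x, ...) {
  cat(sprintf("<area_fit> %s ~ %s: y = %.4f x + %.4f, R^2 = %.4f (n = %d)\n",
              x$response, x$predictor, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @exportS3Method
tidy.area_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @exportS3Method
glance.area_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}
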