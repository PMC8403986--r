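#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Michaelis--Menten fit
#'
#' One row per kinetic parameter with estimate and standard error; in
#' linear-only mode only the catalytic efficiency is determined.
#'
#' @param x A [fit_michaelis_menten()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.dc_mm_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = c("Vmax", "KM", "kcat", "kcat/KM"),
    estimate = c(x$vmax, x$km, x$kcat, x$efficiency),
    std.error = c(x$vmax_se, x$km_se, x$kcat_se, x$efficiency_se)
  )
  if (x$mode == "linear-only") out <- out[out$term == "kcat/KM", ]
  out
}

#' @rdname tidy.dc_mm_fit
#' @export
glance.dc_mm_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n = nrow(x$rates),
    ET_pmol = x$et_pmol,
    sigma = tryCatch(suppressWarnings(summary(x$fit)$sigma),
                     error = function(e) NA_real_)
  )
}

#' Tidy a contrast-to-mass calibration
#'
#' @param x A [fit_c2m()] object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.dc_c2m <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std.error = c(x$slope_se, x$intercept_se)
  )
}

#' @rdname tidy.dc_c2m
#' @export
glance.dc_c2m <- function(x, ...) {
  tibble::tibble(
    n = length(x$residuals),
    sigma = suppressWarnings(summary(x$fit))$sigma,
    r.squared = suppressWarnings(summary(x$fit))$r.squared,
    through_origin = x$through_origin
  )
}

#' Tidy a standard curve
#'
#' @param x A [fit_standard_curve()] object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.dc_standard_curve <- function(x, ...) {
  tibble::tibble(
    term = "slope",
    estimate = x$slope,
    std.error = x$slope_se
  )
}
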