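#' Contrast-to-mass calibration from standard proteins
#'
#' Least-squares line mapping image contrast to molecular mass, fitted on
#' calibration standards (the NativeMark set: 66, 146, 480 and 1048 kDa).
#' The intercept is free by default; set `through_origin = TRUE` for a
#' proportional calibration.
#'
#' @param standards Data frame with columns `contrast` and `mass_kda`.
#' @param through_origin Force the line through (0, 0)?
#' @return Object of class `dc_c2m`: `slope` (kDa per contrast unit),
#'   `intercept` (kDa), their SEs, `residuals` and the underlying `lm`.
#' @export
#' @examples
#' cal <- fit_c2m(data.frame(contrast = c(1, 2), mass_kda = c(100, 200)))
#' contrast_to_mass(cal, 1.5)  # 150
fit_c2m <- function(standards, through_origin = FALSE) {
  stopifnot(is.data.frame(standards),
            all(c("contrast", "mass_kda") %in% names(standards)))
  if (nrow(standards) < 2) rlang::abort("need at least 2 calibration standards")
  if (stats::var(standards$contrast) == 0) {
    rlang::abort("calibration contrasts are degenerate (no spread)")
  }
  fit <- if (through_origin) {
    stats::lm(mass_kda ~ 0 + contrast, data = standards)
  } else {
    stats::lm(mass_kda ~ contrast, data = standards)
  }
  sm <- suppressWarnings(summary(fit))  # exact calibrations trip summary.lm
  co <- sm$coefficients
  slope <- co["contrast", "Estimate"]
  if (slope == 0) rlang::abort("calibration slope is zero")
  structure(
    list(slope = slope,
         slope_se = co["contrast", "Std. Error"],
         intercept = if (through_origin) 0 else co["(Intercept)", "Estimate"],
         intercept_se = if (through_origin) 0 else co["(Intercept)", "Std. Error"],
         residuals = stats::residuals(fit),
         fit = fit,
         through_origin = through_origin),
    class = "dc_c2m"
  )
}

#' Apply a contrast-to-mass calibration
#'
#' @param calibration A [fit_c2m()] object.
#' @param contrast Event contrasts (vectorised).
#' @return Event masses, kDa.
#' @export
contrast_to_mass <- function(calibration, contrast) {
  stopifnot(inherits(calibration, "dc_c2m"))
  calibration$slope * contrast + calibration$intercept
}

#' Fixed-bandwidth Gaussian kernel density estimate of an event-mass sample
#'
#' Places a Gaussian kernel of fixed SD `bandwidth` (default 25 kDa; no
#' rule-of-thumb selection) on every event and averages. The default grid
#' spans 0 to max(mass) + 4 bandwidths at 1 kDa resolution, wide enough for
#' the multi-MDa complexes of interest; the density is the exact kernel
#' mixture evaluated on that grid, so it integrates to 1 up to the grid
#' truncation.
#'
#' @param masses Event masses, kDa (from [contrast_to_mass()]).
#' @param bandwidth Kernel SD, kDa.
#' @param grid Optional evaluation grid, kDa; default as described.
#' @return Tibble of class `dc_mass_kde` with columns `mass_kda`, `density`;
#'   the events and bandwidth travel as attributes.
#' @export
mass_kde <- function(masses, bandwidth = 25, grid = NULL) {
  masses <- masses[!is.na(masses)]
  if (length(masses) == 0) rlang::abort("no events supplied")
  if (bandwidth <= 0) rlang::abort("bandwidth must be > 0")
  if (is.null(grid)) {
    grid <- seq(0, max(masses) + 4 * bandwidth, by = 1)
  }
  # exact Gaussian mixture; grids here are a few thousand points
  dens <- vapply(grid, function(g) {
    mean(stats::dnorm(g, mean = masses, sd = bandwidth))
  }, numeric(1))
  out <- tibble::tibble(mass_kda = grid, density = dens)
  attr(out, "bandwidth") <- bandwidth
  attr(out, "events") <- masses
  class(out) <- c("dc_mass_kde", class(out))
  out
}

#' Modes of a mass distribution
#'
#' Local maxima of the KDE above a density floor, for locating species peaks.
#'
#' @param kde A [mass_kde()] result.
#' @param min_density_frac Ignore maxima below this fraction of the global
#'   maximum density.
#' @return Tibble with `mass_kda` and `density` of each mode, ordered by mass.
#' @export
kde_modes <- function(kde, min_density_frac = 0.05) {
  d <- kde$density
  n <- length(d)
  is_max <- c(FALSE, d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n], FALSE)
  is_max <- is_max & d >= min_density_frac * max(d)
  tibble::tibble(mass_kda = kde$mass_kda[is_max], density = d[is_max])
}
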