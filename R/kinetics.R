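#' Fit a radiolabel standard curve
#'
#' Least-squares line relating spot signal intensity (linear scale, already
#' background-corrected) to the known radiolabel amount per spot. By default
#' the line is forced through the origin: zero label gives zero signal after
#' background correction. Set `through_origin = FALSE` for a free intercept.
#'
#' @param standards Data frame with columns `amount_pmol` and `signal`.
#' @param through_origin Force the fit through (0, 0)? Default `TRUE`.
#' @return Object of class `dc_standard_curve`: list with `slope` (a.u. per
#'   pmol), `slope_se`, `intercept`, `sigma` and the underlying `lm` fit.
#' @export
#' @examples
#' sc <- fit_standard_curve(data.frame(amount_pmol = c(1, 2, 4),
#'                                     signal = c(1000, 2000, 4000)))
#' sc$slope  # 1000
fit_standard_curve <- function(standards, through_origin = TRUE) {
  stopifnot(is.data.frame(standards),
            all(c("amount_pmol", "signal") %in% names(standards)))
  if (nrow(standards) < 3) rlang::abort("need at least 3 standard spots")
  if (any(standards$amount_pmol <= 0)) rlang::abort("spot amounts must be > 0")
  fit <- if (through_origin) {
    stats::lm(signal ~ 0 + amount_pmol, data = standards)
  } else {
    stats::lm(signal ~ amount_pmol, data = standards)
  }
  sm <- suppressWarnings(summary(fit))  # noiseless standards trip summary.lm
  co <- sm$coefficients
  slope <- co["amount_pmol", "Estimate"]
  if (slope <= 0) rlang::abort("standard-curve slope is not positive; signals inconsistent")
  structure(
    list(slope = slope,
         slope_se = co["amount_pmol", "Std. Error"],
         intercept = if (through_origin) 0 else co["(Intercept)", "Estimate"],
         sigma = sm$sigma,
         fit = fit,
         through_origin = through_origin),
    class = "dc_standard_curve"
  )
}

#' Convert signal intensities to picomoles via a standard curve
#'
#' @param curve A [fit_standard_curve()] object.
#' @param signal Linear-scale signal intensities (vectorised).
#' @return Product amounts, pmol.
#' @export
signal_to_pmol <- function(curve, signal) {
  stopifnot(inherits(curve, "dc_standard_curve"))
  (signal - curve$intercept) / curve$slope
}

#' Initial rate from a product time course
#'
#' Slope of the ordinary least-squares line of product amount against time
#' (free intercept; time zero is not a sampled point in the assay design).
#'
#' @param time_min Sampling times, min.
#' @param product_pmol Product amounts, pmol.
#' @return Initial rate, pmol/min.
#' @export
#' @examples
#' initial_rate(c(0.5, 1, 2, 5), 2 * c(0.5, 1, 2, 5))  # 2
initial_rate <- function(time_min, product_pmol) {
  stopifnot(length(time_min) == length(product_pmol))
  if (length(time_min) < 2) rlang::abort("need at least 2 time points")
  if (stats::var(time_min) == 0) rlang::abort("all time points identical")
  unname(stats::coef(stats::lm(product_pmol ~ time_min))["time_min"])
}

#' Initial rates for every substrate concentration in a time-course table
#'
#' @param timecourse Data frame with columns `substrate_uM`, `time_min` and
#'   `product_pmol` (one row per sampled time point), e.g. the `timecourse`
#'   element of [simulate_kinase_assay()].
#' @return Tibble with one row per substrate concentration: `substrate_uM`,
#'   `v0_pmol_min`.
#' @export
initial_rates <- function(timecourse) {
  stopifnot(all(c("substrate_uM", "time_min", "product_pmol") %in% names(timecourse)))
  timecourse |>
    dplyr::group_by(.data$substrate_uM) |>
    dplyr::summarise(
      v0_pmol_min = initial_rate(.data$time_min, .data$product_pmol),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$substrate_uM)
}

#' Fit Michaelis--Menten kinetics to initial rates
#'
#' Nonlinear least squares for v0 = Vmax * S / (KM + S); the turnover number
#' is kcat = Vmax / E_T with E_T entered as an amount (the assay convention:
#' 0.9 pmol for 6 uL of 150 nM enzyme complex), and the catalytic efficiency
#' kcat / KM carries a standard error propagated in quadrature
#' ([propagate_ratio_error()]).
#'
#' When the rate response shows no saturation -- the observed rate at the
#' largest substrate concentration is still close to twice the rate at half
#' that concentration (ratio >= `saturation_ratio`, default 1.8; a doubling
#' means the response is linear, while Michaelis--Menten curvature pulls the
#' ratio below 2) -- Vmax, KM and kcat are not determined. The fit then
#' returns `mode = "linear-only"` with the efficiency taken from a
#' through-origin straight-line fit of rate against concentration, divided
#' by E_T.
#'
#' @param rates Data frame with columns `substrate_uM` and `v0_pmol_min`
#'   (e.g. from [initial_rates()]).
#' @param et_pmol Total enzyme amount E_T, pmol.
#' @param saturation_ratio Threshold on v(S_max) / v(~S_max/2) above which
#'   the series is declared non-saturating.
#' @return Object of class `dc_mm_fit`; use [tidy()] / [glance()] or access
#'   fields directly (`vmax`, `vmax_se`, `km`, `km_se`, `kcat`, `kcat_se`,
#'   `efficiency`, `efficiency_se`, `mode`).
#' @export
fit_michaelis_menten <- function(rates, et_pmol, saturation_ratio = 1.8) {
  stopifnot(is.data.frame(rates),
            all(c("substrate_uM", "v0_pmol_min") %in% names(rates)))
  if (et_pmol <= 0) rlang::abort("et_pmol must be > 0")
  if (nrow(rates) < 4) rlang::abort("need at least 4 substrate concentrations")
  if (anyDuplicated(rates$substrate_uM) > 0) {
    rlang::abort("substrate concentrations must be distinct")
  }
  rates <- dplyr::arrange(rates, .data$substrate_uM)
  s <- rates$substrate_uM
  v <- rates$v0_pmol_min

  s_max <- s[length(s)]
  i_half <- which.min(abs(s - s_max / 2))
  ratio <- v[length(v)] / v[i_half]
  saturating <- is.finite(ratio) && ratio < saturation_ratio

  if (!saturating) {
    lf <- stats::lm(v0_pmol_min ~ 0 + substrate_uM, data = rates)
    co <- summary(lf)$coefficients
    out <- list(
      mode = "linear-only",
      vmax = NA_real_, vmax_se = NA_real_,
      km = NA_real_, km_se = NA_real_,
      kcat = NA_real_, kcat_se = NA_real_,
      efficiency = unname(co[1, "Estimate"]) / et_pmol,
      efficiency_se = unname(co[1, "Std. Error"]) / et_pmol,
      et_pmol = et_pmol, rates = rates, fit = lf
    )
    class(out) <- "dc_mm_fit"
    return(out)
  }

  start <- list(vmax = max(v), km = s[which.min(abs(v - max(v) / 2))])
  fit <- tryCatch(
    stats::nls(v0_pmol_min ~ vmax * substrate_uM / (km + substrate_uM),
               data = rates, start = start),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v0_pmol_min ~ vmax * substrate_uM / (km + substrate_uM),
                        data = rates, start = start),
      error = function(e) rlang::abort(paste0(
        "Michaelis-Menten fit did not converge: ", conditionMessage(e)))
    )
  }
  co <- suppressWarnings(summary(fit))$coefficients
  vmax <- co["vmax", "Estimate"]; vmax_se <- co["vmax", "Std. Error"]
  km <- co["km", "Estimate"]; km_se <- co["km", "Std. Error"]
  kcat <- vmax / et_pmol
  kcat_se <- vmax_se / et_pmol
  out <- list(
    mode = "saturating",
    vmax = vmax, vmax_se = vmax_se,
    km = km, km_se = km_se,
    kcat = kcat, kcat_se = kcat_se,
    efficiency = kcat / km,
    efficiency_se = propagate_ratio_error(kcat, kcat_se, km, km_se),
    et_pmol = et_pmol, rates = rates, fit = fit
  )
  class(out) <- "dc_mm_fit"
  out
}

#' Standard error of a ratio by quadrature propagation
#'
#' For z = x / y with independent uncertainties,
#' dz = |z| * sqrt((dx/x)^2 + (dy/y)^2). Used for the kcat/KM efficiency.
#'
#' @param x,dx Numerator and its standard error.
#' @param y,dy Denominator and its standard error.
#' @return Standard error of x / y.
#' @export
#' @examples
#' propagate_ratio_error(10, 1, 5, 0.5)  # ~0.2828
propagate_ratio_error <- function(x, dx, y, dy) {
  if (any(x == 0) || any(y == 0)) rlang::abort("x and y must be non-zero")
  if (any(dx < 0) || any(dy < 0)) rlang::abort("standard errors must be >= 0")
  abs(x / y) * sqrt((dx / x)^2 + (dy / y)^2)
}

#' Poly-ubiquitylated fraction of a substrate lane
#'
#' Ratio of the poly-ubiquitylated substrate signal to the total substrate
#' signal in the same lane (both linear-scale, background-corrected).
#'
#' @param polyub_signal Poly-ubiquitylated-species signal, a.u.
#' @param total_signal Total substrate signal in the lane, a.u.
#' @return Fraction in \[0, 1\].
#' @export
polyubiquitylated_fraction <- function(polyub_signal, total_signal) {
  if (any(total_signal <= 0)) rlang::abort("total signal must be > 0")
  if (any(polyub_signal < 0)) rlang::abort("poly-ub signal must be >= 0")
  if (any(polyub_signal > total_signal)) {
    rlang::abort("poly-ub signal exceeds total signal")
  }
  polyub_signal / total_signal
}

#' @export
print.dc_mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (", x$mode, ")\n", sep = "")
  if (x$mode == "saturating") {
    cat(sprintf("  Vmax = %.4g +- %.2g pmol/min\n", x$vmax, x$vmax_se))
    cat(sprintf("  KM   = %.4g +- %.2g uM\n", x$km, x$km_se))
    cat(sprintf("  kcat = %.4g +- %.2g min^-1 (E_T = %.3g pmol)\n",
                x$kcat, x$kcat_se, x$et_pmol))
  }
  cat(sprintf("  kcat/KM = %.4g +- %.2g uM^-1 min^-1\n",
              x$efficiency, x$efficiency_se))
  invisible(x)
}
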