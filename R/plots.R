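#' Plot a SEC-MALS chromatogram with per-slice molar masses
#'
#' Scattering trace over elution volume with the recovered per-slice molar
#' mass overlaid on a secondary axis, the conventional SEC-MALS display.
#'
#' @param object A slice table (e.g. from [simulate_chromatogram()]).
#' @param config Instrument config; defaults to the attached one.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dc_slices <- function(object, config = NULL, ...) {
  ps <- secmals_slices(object, config = config)
  sc <- max(ps$LS, na.rm = TRUE) / max(ps$M_Da, na.rm = TRUE)
  ggplot2::ggplot(ps, ggplot2::aes(x = .data$volume_mL)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$LS)) +
    ggplot2::geom_point(
      data = ps[ps$included, ],
      ggplot2::aes(y = .data$M_Da * sc), colour = "firebrick", size = 0.6
    ) +
    ggplot2::scale_y_continuous(
      "light scattering (a.u.)",
      sec.axis = ggplot2::sec_axis(~ . / sc, name = "molar mass (g/mol)")
    ) +
    ggplot2::labs(x = "elution volume (mL)") +
    ggplot2::theme_minimal()
}

#' Plot a mass-photometry KDE
#'
#' @param object A [mass_kde()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dc_mass_kde <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mass_kda, .data$density)) +
    ggplot2::geom_area(fill = "grey80", colour = "grey20") +
    ggplot2::labs(x = "mass (kDa)", y = "density",
                  subtitle = sprintf("Gaussian KDE, bandwidth %g kDa",
                                     attr(object, "bandwidth"))) +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis--Menten fit over its rate data
#'
#' @param object A [fit_michaelis_menten()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dc_mm_fit <- function(object, ...) {
  r <- object$rates
  grid <- tibble::tibble(substrate_uM = seq(0, max(r$substrate_uM), length.out = 200))
  grid$v <- if (object$mode == "saturating") {
    object$vmax * grid$substrate_uM / (object$km + grid$substrate_uM)
  } else {
    object$efficiency * object$et_pmol * grid$substrate_uM
  }
  ggplot2::ggplot(r, ggplot2::aes(.data$substrate_uM, .data$v0_pmol_min)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$v), colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[S] (uM)", y = "v0 (pmol/min)",
                  subtitle = paste0("fit mode: ", object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot a feasible stoichiometry set
#'
#' Component copy numbers of every feasible stoichiometry against its
#' complex mass, one line per component.
#'
#' @param object An [enumerate_stoichiometries()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dc_feasible <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    dplyr::starts_with("n_"), names_to = "component", values_to = "copies",
    names_prefix = "n_"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$mass_da / 1000, .data$copies,
                                     colour = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "complex mass (kDa)", y = "copy number") +
    ggplot2::theme_minimal()
}
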