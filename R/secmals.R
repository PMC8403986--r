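#' Mass concentration from differential refractive index
#'
#' The dRI of a protein solution relative to solvent is proportional to its
#' mass concentration: c = dRI / (dn/dc).
#'
#' @param dri Differential refractive index (dimensionless), vectorised.
#' @param dn_dc Refractive-index increment, mL/g (protein convention 0.185).
#' @return Mass concentration, g/mL.
#' @export
#' @examples
#' slice_concentration(1.85e-5, 0.185)  # 1e-4 g/mL
slice_concentration <- function(dri, dn_dc = 0.185) {
  if (dn_dc <= 0) rlang::abort("dn_dc must be > 0")
  dri / dn_dc
}

#' Molar mass of a slice from its scattering signal
#'
#' Zero-angle, zero-virial light-scattering relation: the excess scattering
#' signal is K * c * M, so M = LS / (K * c). Slices whose concentration is
#' at or below `c_floor` are excluded (returned as `NA`) because the division
#' is unstable at peak edges.
#'
#' @param ls Scattering signal, arbitrary units (vectorised).
#' @param c_mass Mass concentration, g/mL.
#' @param k Optical constant matching the one used to record `ls`.
#' @param c_floor Concentration floor, g/mL, below which a slice is excluded.
#' @return Molar mass, g/mol; `NA` for excluded slices.
#' @export
slice_molar_mass <- function(ls, c_mass, k, c_floor = 1e-9) {
  if (k <= 0) rlang::abort("optical constant must be > 0")
  ifelse(c_mass > c_floor, ls / (k * c_mass), NA_real_)
}

#' Molar extinction coefficient of a slice
#'
#' Beer--Lambert: the specific extinction coefficient A / (l * c) in
#' L g^-1 cm^-1 is converted to molar units by multiplying with the slice
#' molar mass: eps = A280 / (path * c_gL) * M.
#'
#' @param a280 Absorbance at 280 nm, AU.
#' @param c_mass_gl Mass concentration, g/L.
#' @param m_da Slice molar mass, g/mol.
#' @param path Path length, cm.
#' @return Molar extinction coefficient, M^-1 cm^-1.
#' @export
#' @examples
#' slice_molar_extinction(0.5, 1.0, 1e6)  # 5e5
slice_molar_extinction <- function(a280, c_mass_gl, m_da, path = 1) {
  if (path <= 0) rlang::abort("path length must be > 0")
  ifelse(c_mass_gl > 0, a280 / (path * c_mass_gl) * m_da, NA_real_)
}

#' Per-slice SEC-MALS analysis of a chromatogram table
#'
#' Applies the slice-level relations to every row: concentration from dRI,
#' molar mass from the scattering channel, molar extinction coefficient from
#' A280, and the molar complex concentration c/M. Slices below the
#' concentration floor are flagged `included = FALSE` and carry `NA` derived
#' values.
#'
#' @param slices Data frame with columns `volume_mL`, `dRI`, `A280`, `LS`
#'   (extra columns pass through), e.g. from [simulate_chromatogram()] or
#'   [read_slice_csv()].
#' @param config A [generator_config()] carrying dn/dc, the optical constant
#'   and the path length; defaults to the config attached to `slices` if
#'   present.
#' @param c_floor Exclusion floor for slice concentration, g/mL.
#' @return The input tibble with added columns `c_g_mL`, `M_Da`, `eps`,
#'   `c_M`, `included`.
#' @export
secmals_slices <- function(slices, config = NULL, c_floor = 1e-9) {
  if (is.null(config)) config <- attr(slices, "config")
  if (is.null(config)) rlang::abort("no generator/instrument config supplied")
  req <- c("volume_mL", "dRI", "A280", "LS")
  if (!all(req %in% names(slices))) {
    rlang::abort(paste0("slice table needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(diff(slices$volume_mL) <= 0)) rlang::abort("volumes must be strictly increasing")
  out <- dplyr::mutate(
    tibble::as_tibble(slices),
    c_g_mL = slice_concentration(.data$dRI, config$dn_dc),
    M_Da = slice_molar_mass(.data$LS, .data$c_g_mL, config$optical_constant, c_floor),
    eps = slice_molar_extinction(.data$A280, .data$c_g_mL * 1000, .data$M_Da,
                                 config$path_length),
    c_M = ifelse(is.na(.data$M_Da), NA_real_, .data$c_g_mL * 1000 / .data$M_Da),
    included = !is.na(.data$M_Da)
  )
  attr(out, "config") <- config
  out
}

#' Weight- and number-average molar mass and dispersity
#'
#' Over the supplied slices: Mw = sum(c_i M_i) / sum(c_i),
#' Mn = sum(c_i) / sum(c_i / M_i), dispersity = Mw / Mn (>= 1 by the
#' Cauchy--Schwarz inequality, with equality only for monodisperse input).
#' Both averages are invariant under uniform rescaling of the concentrations.
#'
#' @param c_mass Slice mass concentrations (any consistent unit).
#' @param m_da Slice molar masses, g/mol.
#' @return Tibble with `Mw_Da`, `Mn_Da`, `dispersity`.
#' @export
#' @examples
#' average_molar_masses(c(1, 1), c(1e6, 2e6))  # Mw 1.5e6, Mn 4/3e6
average_molar_masses <- function(c_mass, m_da) {
  keep <- !is.na(c_mass) & !is.na(m_da) & c_mass > 0
  if (!any(keep)) rlang::abort("no valid slices to average")
  c_mass <- c_mass[keep]; m_da <- m_da[keep]
  mw <- sum(c_mass * m_da) / sum(c_mass)
  mn <- sum(c_mass) / sum(c_mass / m_da)
  tibble::tibble(Mw_Da = mw, Mn_Da = mn, dispersity = mw / mn)
}

#' Summarise a SEC-MALS run over its elution-peak window
#'
#' Restricts the per-slice analysis to `peak_window` (inclusive volume
#' range), then reports Mw, Mn, dispersity, the mean and SD of the per-slice
#' molar extinction coefficients, the maximum molar complex concentration
#' seen at the detector, and the number of slices used. The +-1 SD on eps is
#' the building block for the 95% windows the stoichiometry enumerator uses
#' (the 1.96 multiplier is applied there, not here).
#'
#' @param slices Chromatogram table (see [secmals_slices()]).
#' @param peak_window Length-2 numeric, inclusive volume range in mL
#'   (e.g. `c(2.3, 3.0)`).
#' @inheritParams secmals_slices
#' @return One-row tibble of class `dc_mass_summary` with columns `Mw_Da`,
#'   `Mn_Da`, `dispersity`, `eps_mean`, `eps_sd`, `c_max_M`, `n_slices`.
#' @export
summarize_run <- function(slices, peak_window, config = NULL, c_floor = 1e-9) {
  stopifnot(length(peak_window) == 2, peak_window[1] < peak_window[2])
  ps <- secmals_slices(slices, config = config, c_floor = c_floor)
  win <- ps$volume_mL >= peak_window[1] & ps$volume_mL <= peak_window[2]
  ps <- ps[win & ps$included, ]
  if (nrow(ps) == 0) rlang::abort("no valid slices inside the peak window")
  avg <- average_molar_masses(ps$c_g_mL, ps$M_Da)
  out <- dplyr::bind_cols(
    avg,
    tibble::tibble(
      eps_mean = mean(ps$eps),
      eps_sd = if (nrow(ps) > 1) stats::sd(ps$eps) else 0,
      c_max_M = max(ps$c_M),
      n_slices = nrow(ps)
    )
  )
  attr(out, "peak_window") <- peak_window
  class(out) <- c("dc_mass_summary", class(out))
  out
}

#' Molar concentration of an input sample from its A280
#'
#' Beer--Lambert with the complex-level mean molar extinction coefficient
#' from the SEC-MALS peak: c = A280 / (eps * path). With the wild-type DC
#' values (A280 = 0.84, eps = 2,024,161 M^-1 cm^-1) this gives 415 nM, and
#' 877 nM for the M3 variant (0.86, 980,087).
#'
#' @param a280 Absorbance of the input sample at 280 nm, AU.
#' @param eps_mean Mean molar extinction coefficient, M^-1 cm^-1.
#' @param path Path length, cm.
#' @return Molar concentration, M.
#' @export
#' @examples
#' estimate_input_concentration(0.84, 2024161) * 1e9  # ~415 nM
estimate_input_concentration <- function(a280, eps_mean, path = 1) {
  if (any(eps_mean <= 0)) rlang::abort("eps_mean must be > 0")
  if (path <= 0) rlang::abort("path length must be > 0")
  a280 / (eps_mean * path)
}
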