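#' Generator configuration for synthetic instrument data
#'
#' Houses the constants shared between the synthetic-data generators and the
#' SEC-MALS analyser: the protein refractive-index increment dn/dc
#' (0.185 mL/g), the instrument optical constant K linking the scattering
#' signal to the product c*M (left implicit inside vendor software on real
#' instruments; here a single user-set scalar), the cuvette path length and
#' the relative noise level.
#'
#' @param dn_dc Refractive-index increment, mL/g.
#' @param optical_constant Scattering proportionality constant K
#'   (arbitrary units); only the product K*c*M is observable.
#' @param path_length Optical path length, cm.
#' @param noise_sd_rel Relative SD of the multiplicative Gaussian noise
#'   applied per detector channel (0 = noiseless).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list with class `dc_generator_config`.
#' @export
generator_config <- function(dn_dc = 0.185, optical_constant = 1e-5,
                             path_length = 1, noise_sd_rel = 0, seed = NULL) {
  stopifnot(dn_dc > 0, optical_constant > 0, path_length > 0, noise_sd_rel >= 0)
  structure(
    list(dn_dc = dn_dc, optical_constant = optical_constant,
         path_length = path_length, noise_sd_rel = noise_sd_rel, seed = seed),
    class = "dc_generator_config"
  )
}

#' Describe one eluting species for the chromatogram simulator
#'
#' @param stoich Named integer copy-number vector over the component table.
#' @param peak_center_ml Elution-peak centre, mL.
#' @param peak_width_ml SD of the Gaussian elution profile, mL; must be > 0.
#' @param mass_loaded_g Total protein mass of this species injected, g.
#' @return A one-row tibble with a list-column `stoich`.
#' @export
dc_species <- function(stoich, peak_center_ml, peak_width_ml, mass_loaded_g) {
  stopifnot(peak_width_ml > 0, mass_loaded_g >= 0)
  tibble::tibble(
    stoich = list(stoich),
    peak_center_ml = peak_center_ml,
    peak_width_ml = peak_width_ml,
    mass_loaded_g = mass_loaded_g
  )
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

mult_noise <- function(x, sd_rel) {
  if (sd_rel == 0) return(x)
  x * (1 + stats::rnorm(length(x), 0, sd_rel))
}

#' Simulate a SEC-MALS chromatogram with known ground truth
#'
#' Each species elutes as a Gaussian profile in volume; per slice the
#' generator produces the three detector channels the analyser consumes:
#' dRI = c * dn/dc, A280 = sum over species of eps * c_molar * path, and
#' LS = K * sum of c * M, then applies independent multiplicative Gaussian
#' noise per channel. Ground-truth per-slice mass concentration, (weight
#' average) molar mass and molar complex concentration are kept alongside
#' the observations so that downstream recovery can be checked exactly.
#'
#' @param species Tibble of species rows from [dc_species()] (row-bind for
#'   mixtures).
#' @param grid Strictly increasing elution-volume grid, mL.
#' @param config A [generator_config()].
#' @param components Component table used to derive each species' complex
#'   mass and extinction coefficient.
#' @return A tibble of class `dc_slices` with observed columns `volume_mL`,
#'   `dRI`, `A280`, `LS` and truth columns `true_c_g_mL`, `true_M_Da`,
#'   `true_c_M`. The generator config travels as attribute `config`.
#' @export
simulate_chromatogram <- function(species, grid, config = generator_config(),
                                  components = dc_components()) {
  if (!is.data.frame(species) || nrow(species) == 0) {
    rlang::abort("at least one species is required")
  }
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    rlang::abort("elution-volume grid must be strictly increasing")
  }
  sp <- species
  sp$mass_da <- purrr::map_dbl(sp$stoich, complex_mass, components = components)
  sp$eps     <- purrr::map_dbl(sp$stoich, complex_extinction, components = components)

  # per-slice mass concentration of each species, g/mL
  cmat <- vapply(seq_len(nrow(sp)), function(i) {
    sp$mass_loaded_g[i] * stats::dnorm(grid, sp$peak_center_ml[i], sp$peak_width_ml[i])
  }, numeric(length(grid)))
  cmat <- matrix(cmat, nrow = length(grid))

  c_tot <- rowSums(cmat)
  cm_tot <- as.numeric(cmat %*% sp$mass_da)              # sum c*M
  true_m <- ifelse(c_tot > 0, cm_tot / c_tot, NA_real_)  # slice weight-average M
  # molar complex concentration, mol/L: sum over species of c/M * 1000
  true_c_molar <- as.numeric(cmat %*% (1 / sp$mass_da)) * 1000
  a280 <- as.numeric(cmat %*% (sp$eps / sp$mass_da)) * 1000 * config$path_length

  out <- with_seed_if(config$seed, tibble::tibble(
    volume_mL = grid,
    dRI  = mult_noise(c_tot * config$dn_dc, config$noise_sd_rel),
    A280 = mult_noise(a280, config$noise_sd_rel),
    LS   = mult_noise(config$optical_constant * cm_tot, config$noise_sd_rel),
    true_c_g_mL = c_tot,
    true_M_Da = true_m,
    true_c_M = true_c_molar
  ))
  attr(out, "config") <- config
  class(out) <- c("dc_slices", class(out))
  out
}

#' Simulate mass-photometry landing events
#'
#' Draws event masses from a categorical mixture, perturbs them with
#' Gaussian noise, and converts them to image contrasts by inverting the
#' contrast-to-mass calibration line `mass = slope * contrast + intercept`.
#'
#' @param masses Species masses, kDa.
#' @param weights Mixture weights; must sum to 1.
#' @param n_events Number of landing events to draw.
#' @param noise_sd Gaussian mass noise SD, kDa.
#' @param slope,intercept Calibration line (kDa per contrast unit, kDa).
#' @param seed Integer seed or `NULL`.
#' @return Tibble with columns `contrast`, `true_mass_kda` (the mixture
#'   component each event came from) and `noisy_mass_kda` (truth + noise,
#'   i.e. the mass an exact calibration would recover).
#' @export
simulate_mp_events <- function(masses, weights, n_events, noise_sd = 0,
                               slope = 2000, intercept = 0, seed = NULL) {
  stopifnot(length(masses) == length(weights), n_events > 0, noise_sd >= 0,
            slope != 0)
  if (abs(sum(weights) - 1) > 1e-8) {
    rlang::abort("mixture weights must sum to 1")
  }
  with_seed_if(seed, {
    idx <- sample.int(length(masses), n_events, replace = TRUE, prob = weights)
    true_mass <- masses[idx]
    noisy <- true_mass + stats::rnorm(n_events, 0, noise_sd)
    tibble::tibble(
      contrast = (noisy - intercept) / slope,
      true_mass_kda = true_mass,
      noisy_mass_kda = noisy
    )
  })
}

#' Paper-style radiolabel standard-curve spot amounts (pmol)
#' @keywords internal
standard_spot_amounts <- function() {
  c(12.5, 6.25, 3.125, 1.563, 0.781, 0.390, 0.195)
}

#' Simulate a radiometric kinase assay
#'
#' For each substrate concentration the initial rate follows the
#' Michaelis--Menten equation v0 = kcat * E_T * S / (KM + S); product grows
#' linearly as v0 * t over the sampled time points (the initial-rate regime),
#' with multiplicative Gaussian noise. A standard-curve spot table over the
#' conventional two-fold radiolabel dilutions (12.5 down to 0.195 pmol) is
#' emitted alongside so the downstream signal-to-pmol conversion can be
#' exercised.
#'
#' @param kcat Turnover number, min^-1.
#' @param km Michaelis constant, uM.
#' @param et_pmol Total enzyme amount, pmol (0.9 pmol corresponds to 6 uL of
#'   150 nM enzyme complex).
#' @param substrate_um Substrate concentrations, uM.
#' @param timepoints_min Sampling times, min (default 0.5, 1, 2, 5).
#' @param noise_sd_rel Relative SD of multiplicative noise on product amounts
#'   and spot signals.
#' @param sc_slope True signal per pmol for the standard-curve spots.
#' @param seed Integer seed or `NULL`.
#' @return List with `timecourse` (tibble: `substrate_uM`, `time_min`,
#'   `product_pmol`, `true_v0`), `standards` (tibble: `amount_pmol`,
#'   `signal`) and `truth` (the generating parameters).
#' @export
simulate_kinase_assay <- function(kcat, km, et_pmol,
                                  substrate_um,
                                  timepoints_min = c(0.5, 1, 2, 5),
                                  noise_sd_rel = 0, sc_slope = 1000,
                                  seed = NULL) {
  stopifnot(kcat > 0, km > 0, et_pmol > 0, all(substrate_um > 0),
            all(timepoints_min > 0), noise_sd_rel >= 0, sc_slope > 0)
  with_seed_if(seed, {
    tc <- tidyr::expand_grid(substrate_uM = substrate_um,
                             time_min = timepoints_min)
    tc$true_v0 <- kcat * et_pmol * tc$substrate_uM / (km + tc$substrate_uM)
    tc$product_pmol <- mult_noise(tc$true_v0 * tc$time_min, noise_sd_rel)
    amounts <- standard_spot_amounts()
    sc <- tibble::tibble(
      amount_pmol = amounts,
      signal = mult_noise(sc_slope * amounts, noise_sd_rel)
    )
    list(
      timecourse = tc[, c("substrate_uM", "time_min", "product_pmol", "true_v0")],
      standards = sc,
      truth = list(kcat = kcat, km = km, et_pmol = et_pmol, sc_slope = sc_slope)
    )
  })
}
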