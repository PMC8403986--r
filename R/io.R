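#' Read and write SEC-MALS slice tables
#'
#' Plain CSV with header columns `volume_mL`, `dRI`, `A280`, `LS`; truth
#' columns written by the simulator round-trip unchanged.
#'
#' @param path File path.
#' @return `read_slice_csv()`: a tibble.
#' @export
read_slice_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_slice_csv
#' @param slices Slice table to write.
#' @export
write_slice_csv <- function(slices, path) {
  readr::write_csv(tibble::as_tibble(slices), path)
  invisible(path)
}

#' Read and write component tables
#'
#' CSV with columns `component`, `mass_da`, `eps`, `role`.
#'
#' @param path File path.
#' @export
read_components_csv <- function(path) {
  validate_components(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_components_csv
#' @param components Component table to write.
#' @export
write_components_csv <- function(components, path) {
  readr::write_csv(validate_components(components), path)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Keys: `seed`, `output_dir`, `generator` (dn_dc, optical_constant,
#' path_length, noise_sd_rel), `enumeration` (ci_multiplier, bcat_lower_rule),
#' per-variant blocks `wt` / `m3` (species: stoichiometry counts,
#' peak_center_ml, peak_width_ml, mass_loaded_g; peak_window), and `kinetics`
#' (kcat, km, et_pmol, substrate_um, noise_sd_rel).
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config Configuration list to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
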