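#' Default destruction-complex component table
#'
#' The five subunits of the beta-catenin destruction complex (DC) with the
#' molecular weights used throughout: APC 312 kDa, AXIN1 92 kDa, CK1alpha
#' 39 kDa, GSK3beta 47 kDa, beta-catenin 85 kDa. Roles drive the
#' stoichiometry constraints: `scaffold_a` (APC) carries the beta-catenin
#' 15R/20R repeats and the SAMP repeats, `scaffold_b` (AXIN1) carries one
#' kinase site per kinase and one beta-catenin site, `kinase` components
#' occupy AXIN1 kinase sites and `substrate` is beta-catenin.
#'
#' The bundled molar extinction coefficients are synthetic illustrative
#' values (mass scaled by a typical specific absorptivity of about
#' 1.1 (mg/mL)^-1 cm^-1, rounded); real analyses should replace them with
#' sequence-derived values, e.g. from [gill_von_hippel()] applied to the
#' canonical sequences.
#'
#' @return A tibble with columns `component`, `mass_da`, `eps` (M^-1 cm^-1)
#'   and `role`.
#' @export
#' @examples
#' dc_components()
dc_components <- function() {
  tibble::tibble(
    component = c("APC", "AXIN1", "CK1a", "GSK3b", "bcat"),
    mass_da   = c(312000, 92000, 39000, 47000, 85000),
    # synthetic illustrative epsilons (see description)
    eps       = c(343000, 101000, 43000, 52000, 94000),
    role      = c("scaffold_a", "scaffold_b", "kinase", "kinase", "substrate")
  )
}

validate_components <- function(components) {
  stopifnot(is.data.frame(components))
  req <- c("component", "mass_da", "eps", "role")
  missing <- setdiff(req, names(components))
  if (length(missing) > 0) {
    rlang::abort(paste0("component table lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(components$component) > 0) {
    rlang::abort("component names must be unique")
  }
  if (any(components$mass_da <= 0)) rlang::abort("component masses must be > 0")
  if (any(components$eps < 0)) rlang::abort("component extinction coefficients must be >= 0")
  invisible(components)
}

#' Molar extinction coefficient of a protein from its sequence
#'
#' Gill--von Hippel estimate at 280 nm: 5500 per tryptophan, 1490 per
#' tyrosine and, for oxidised proteins, 125 per cystine (half-cystine pairs).
#'
#' @param sequence One-letter amino-acid sequence (character scalar).
#' @param reduced If `TRUE` (default) cysteines contribute nothing; if
#'   `FALSE` every Cys pair is counted as a cystine.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
#' @examples
#' gill_von_hippel("WWYC")           # 2 Trp + 1 Tyr, reduced
#' gill_von_hippel("WWYCC", reduced = FALSE)
gill_von_hippel <- function(sequence, reduced = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(toupper(sequence), "")[[1]]
  n_w <- sum(aa == "W")
  n_y <- sum(aa == "Y")
  n_c <- sum(aa == "C")
  eps <- 5500 * n_w + 1490 * n_y
  if (!reduced) eps <- eps + 125 * (n_c %/% 2)
  eps
}

# Normalise a stoichiometry given as named vector/list or data frame of
# count columns into an n x k count matrix aligned with `components`.
stoich_count_matrix <- function(stoich, components) {
  validate_components(components)
  if (is.data.frame(stoich)) {
    cols <- intersect(components$component, names(stoich))
    extra <- setdiff(names(stoich), c(components$component,
                                      paste0("n_", components$component)))
    if (length(cols) == 0) {
      # allow n_<name> column convention
      ncols <- paste0("n_", components$component)
      cols2 <- intersect(ncols, names(stoich))
      if (length(cols2) == 0) rlang::abort("no count columns match the component table")
      m <- matrix(0, nrow(stoich), nrow(components),
                  dimnames = list(NULL, components$component))
      m[, sub("^n_", "", cols2)] <- as.matrix(stoich[cols2])
      return(m)
    }
    m <- matrix(0, nrow(stoich), nrow(components),
                dimnames = list(NULL, components$component))
    m[, cols] <- as.matrix(stoich[cols])
    return(m)
  }
  counts <- unlist(stoich)
  if (is.null(names(counts)) || any(names(counts) == "")) {
    rlang::abort("stoichiometry must be a named vector/list or a data frame")
  }
  unknown <- setdiff(names(counts), components$component)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown component(s): ", paste(unknown, collapse = ", ")))
  }
  m <- matrix(0, 1L, nrow(components), dimnames = list(NULL, components$component))
  m[1L, names(counts)] <- counts
  m
}

#' Mass of a complex at a given stoichiometry
#'
#' Count-weighted sum of the component molecular weights. The theoretical
#' fully loaded DC (1 APC, 3 AXIN1, 3 CK1alpha, 3 GSK3beta, 13 beta-catenin)
#' comes to 1,951 kDa with the default component table.
#'
#' @param stoich Named vector/list of integer copy numbers, or a data frame
#'   with one column per component (optionally prefixed `n_`); data frames
#'   are handled row-wise.
#' @param components Component table, see [dc_components()].
#' @return Numeric vector of complex masses in g/mol (Da).
#' @export
#' @examples
#' complex_mass(c(APC = 1, AXIN1 = 3, CK1a = 3, GSK3b = 3, bcat = 13)) / 1000
complex_mass <- function(stoich, components = dc_components()) {
  m <- stoich_count_matrix(stoich, components)
  if (any(rowSums(m) == 0)) rlang::abort("stoichiometry has all counts zero")
  as.numeric(m %*% components$mass_da)
}

#' Extinction coefficient of a complex at a given stoichiometry
#'
#' Count-weighted sum of the component molar extinction coefficients
#' (additivity of chromophores at 280 nm).
#'
#' @inheritParams complex_mass
#' @return Numeric vector, M^-1 cm^-1.
#' @export
complex_extinction <- function(stoich, components = dc_components()) {
  m <- stoich_count_matrix(stoich, components)
  if (any(rowSums(m) == 0)) rlang::abort("stoichiometry has all counts zero")
  as.numeric(m %*% components$eps)
}
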