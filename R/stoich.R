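#' Constraints for destruction-complex stoichiometry enumeration
#'
#' Bundles the measured windows and the biological site capacities that the
#' feasibility conditions use. A candidate stoichiometry is feasible when its
#' summed mass and extinction coefficient fall inside
#' mean +- ci_multiplier * SD and all occupancy rules hold.
#'
#' @param mn_mean,mn_sd Number-average molar mass window centre and SD, g/mol.
#' @param eps_mean,eps_sd Molar extinction window centre and SD, M^-1 cm^-1;
#'   set `eps_mean = NULL` to leave the extinction coefficient unconstrained.
#' @param ci_multiplier Window half-width in SDs (1.96 for a 95% CI).
#' @param variant `"wt"` (polymerising AXIN1; at least two copies, and no
#'   direct cap from APC's SAMP repeats because polymers chain beyond them)
#'   or `"m3"` (polymerisation-deficient; at least one copy, at most three
#'   per APC via the three SAMP repeats).
#' @param bcat_per_apc beta-catenin sites per APC (ten: four 15R plus six
#'   usable 20R repeats, 20R2 being non-binding).
#' @param axin_per_apc AXIN1 sites per APC (three SAMP repeats).
#' @param bcat_lower_rule How the "at least one beta-catenin per AXIN1 or
#'   APC" requirement counts: `"max"` (default; one beta-catenin can bridge
#'   an AXIN1 site and an APC 20R simultaneously, so the bound is
#'   max(n_AXIN1, n_APC)) or `"sum"` (each scaffold copy needs its own).
#' @return A list of class `dc_constraints`.
#' @export
dc_constraints <- function(mn_mean, mn_sd, eps_mean = NULL, eps_sd = 0,
                           ci_multiplier = 1.96,
                           variant = c("wt", "m3"),
                           bcat_per_apc = 10, axin_per_apc = 3,
                           bcat_lower_rule = c("max", "sum")) {
  variant <- match.arg(variant)
  bcat_lower_rule <- match.arg(bcat_lower_rule)
  stopifnot(mn_mean > 0, mn_sd >= 0, ci_multiplier > 0,
            bcat_per_apc >= 1, axin_per_apc >= 1)
  if (!is.null(eps_mean)) stopifnot(eps_mean > 0, eps_sd >= 0)
  structure(
    list(mn_mean = mn_mean, mn_sd = mn_sd,
         eps_mean = eps_mean, eps_sd = eps_sd,
         ci_multiplier = ci_multiplier, variant = variant,
         bcat_per_apc = bcat_per_apc, axin_per_apc = axin_per_apc,
         bcat_lower_rule = bcat_lower_rule),
    class = "dc_constraints"
  )
}

constraint_windows <- function(constraints) {
  ci <- constraints$ci_multiplier
  list(
    mass_lo = constraints$mn_mean - ci * constraints$mn_sd,
    mass_hi = constraints$mn_mean + ci * constraints$mn_sd,
    eps_lo = if (is.null(constraints$eps_mean)) -Inf else
      constraints$eps_mean - ci * constraints$eps_sd,
    eps_hi = if (is.null(constraints$eps_mean)) Inf else
      constraints$eps_mean + ci * constraints$eps_sd
  )
}

# Map the component table's roles onto the canonical count columns the
# conditions are written in: APC-like scaffold, AXIN1-like scaffold, the two
# kinases and the substrate.
role_slots <- function(components) {
  validate_components(components)
  apc <- which(components$role == "scaffold_a")
  axn <- which(components$role == "scaffold_b")
  kin <- which(components$role == "kinase")
  sub <- which(components$role == "substrate")
  if (length(apc) != 1 || length(axn) != 1 || length(kin) != 2 || length(sub) != 1) {
    rlang::abort("component table must have one scaffold_a, one scaffold_b, two kinases and one substrate")
  }
  list(apc = apc, axn = axn, k1 = kin[1], k2 = kin[2], sub = sub)
}

# Vectorised condition evaluation on a count matrix (rows = candidates,
# columns ordered as the component table). Returns a tibble of logicals,
# one column per condition, plus derived mass/eps.
eval_conditions <- function(counts, constraints, components) {
  sl <- role_slots(components)
  w <- constraint_windows(constraints)
  apc <- counts[, sl$apc]; axn <- counts[, sl$axn]
  k1 <- counts[, sl$k1]; k2 <- counts[, sl$k2]; sub <- counts[, sl$sub]

  mass <- as.numeric(counts %*% components$mass_da)
  eps <- as.numeric(counts %*% components$eps)

  min_axin <- if (constraints$variant == "wt") 2 else 1
  bcat_lower <- switch(constraints$bcat_lower_rule,
                       max = pmax(axn, apc),
                       sum = axn + apc)
  # vacant kinase sites on AXIN1 free up one beta-catenin slot each
  bcat_upper <- axn + constraints$bcat_per_apc * apc + (2 * axn - k1 - k2)

  tibble::tibble(
    c4_mass = mass >= w$mass_lo & mass <= w$mass_hi,
    c4_eps = eps >= w$eps_lo & eps <= w$eps_hi,
    c5_all_present = rowSums(counts >= 1) == ncol(counts),
    c6_integer = apply(counts, 1, function(r) all(r >= 0 & r == round(r))),
    c8_min_axin = axn >= min_axin,
    c9_kinase_occupancy = k1 >= ceiling(axn / 2) & k1 <= axn &
      k2 >= ceiling(axn / 2) & k2 <= axn,
    c10_bcat_upper = sub <= bcat_upper,
    c11_axin_per_apc = axn >= apc &
      (constraints$variant != "m3" | axn <= constraints$axin_per_apc * apc),
    c12_bcat_lower = sub >= bcat_lower,
    mass_da = mass,
    eps = eps
  )
}

#' Check one stoichiometry against the feasibility conditions
#'
#' Evaluates every condition the enumerator enforces and reports each pass /
#' fail separately: the mass and extinction windows, presence of every
#' component, integrality, the variant-dependent minimum AXIN1 count, at
#' least 50% kinase occupancy of AXIN1 (ceiling for odd counts) with at most
#' full occupancy, the beta-catenin bounds (lower: one per scaffold by the
#' chosen rule; upper: one site per AXIN1, ten per APC, plus one per vacant
#' kinase site), and the AXIN1-per-APC rule.
#'
#' @param stoich Named counts (vector/list) or a one-row data frame.
#' @param constraints A [dc_constraints()].
#' @param components Component table.
#' @return Tibble with columns `condition`, `pass`. Always returned; never
#'   errors on a failing candidate.
#' @export
check_conditions <- function(stoich, constraints, components = dc_components()) {
  m <- stoich_count_matrix(stoich, components)
  rep <- eval_conditions(m, constraints, components)
  conds <- setdiff(names(rep), c("mass_da", "eps"))
  tibble::tibble(
    condition = conds,
    pass = as.logical(unlist(rep[1, conds]))
  )
}

#' Enumerate all feasible complex stoichiometries
#'
#' Exhaustively visits integer count vectors up to the per-component bound
#' floor(mass_hi / component mass) and returns exactly those passing every
#' condition in [check_conditions()], sorted lexicographically by
#' (APC, AXIN1, kinase 1, kinase 2, substrate) counts so the output is
#' independent of traversal order. The search itself iterates scaffold and
#' kinase counts inside their structural ranges and intersects the substrate
#' range with the mass window analytically, which keeps the visit count small
#' without changing the result (a brute-force filter of the full bounded grid
#' gives the identical set).
#'
#' @param components Component table (one `scaffold_a`, one `scaffold_b`,
#'   two `kinase`, one `substrate` row).
#' @param constraints A [dc_constraints()]; the mass window must be finite.
#' @return Tibble of class `dc_feasible` with one count column per component
#'   (`n_<name>`) plus `mass_da` and `eps`; zero rows when nothing fits.
#' @export
#' @examples
#' comps <- dc_components()
#' cons <- dc_constraints(mn_mean = 660000, mn_sd = 2551, variant = "m3")
#' enumerate_stoichiometries(comps, cons)  # 1 APC, 1 AXIN1, 1+1 kinases, 2 bcat
enumerate_stoichiometries <- function(components, constraints) {
  validate_components(components)
  sl <- role_slots(components)
  w <- constraint_windows(constraints)
  if (!is.finite(w$mass_lo) || !is.finite(w$mass_hi)) {
    rlang::abort("mass window must be finite")
  }
  m <- components$mass_da
  empty <- tibble::tibble()
  if (w$mass_hi < sum(m)) {
    res <- feasible_tibble(matrix(numeric(0), 0, nrow(components)),
                           components, constraints)
    return(res)
  }
  bound <- function(i) floor(w$mass_hi / m[i])
  min_axin <- if (constraints$variant == "wt") 2 else 1

  rows <- list(); nr <- 0L
  for (apc in seq_len(bound(sl$apc))) {
    axn_hi <- bound(sl$axn)
    if (constraints$variant == "m3") {
      axn_hi <- min(axn_hi, constraints$axin_per_apc * apc)
    }
    axn_lo <- max(min_axin, apc)
    if (axn_lo > axn_hi) next
    for (axn in axn_lo:axn_hi) {
      k_lo <- ceiling(axn / 2)
      if (k_lo > bound(sl$k1) || k_lo > bound(sl$k2)) next
      for (k1 in k_lo:min(axn, bound(sl$k1))) {
        for (k2 in k_lo:min(axn, bound(sl$k2))) {
          base <- apc * m[sl$apc] + axn * m[sl$axn] +
            k1 * m[sl$k1] + k2 * m[sl$k2]
          s_lo <- switch(constraints$bcat_lower_rule,
                         max = max(axn, apc), sum = axn + apc)
          s_hi <- min(axn + constraints$bcat_per_apc * apc + (2 * axn - k1 - k2),
                      bound(sl$sub))
          # intersect with the mass window analytically
          s_lo <- max(s_lo, ceiling((w$mass_lo - base) / m[sl$sub]))
          s_hi <- min(s_hi, floor((w$mass_hi - base) / m[sl$sub]))
          if (s_lo > s_hi) next
          for (s in s_lo:s_hi) {
            cand <- numeric(nrow(components))
            cand[c(sl$apc, sl$axn, sl$k1, sl$k2, sl$sub)] <-
              c(apc, axn, k1, k2, s)
            nr <- nr + 1L
            rows[[nr]] <- cand
          }
        }
      }
    }
  }
  counts <- if (nr == 0) matrix(numeric(0), 0, nrow(components)) else
    do.call(rbind, rows)
  if (nr > 0) {
    rep <- eval_conditions(counts, constraints, components)
    keep <- Reduce(`&`, rep[setdiff(names(rep), c("mass_da", "eps"))])
    counts <- counts[keep, , drop = FALSE]
  }
  feasible_tibble(counts, components, constraints)
}

feasible_tibble <- function(counts, components, constraints) {
  sl <- role_slots(components)
  ord_cols <- c(sl$apc, sl$axn, sl$k1, sl$k2, sl$sub)
  out <- tibble::as_tibble(as.data.frame(counts))
  names(out) <- paste0("n_", components$component)
  if (nrow(out) > 0) {
    out$mass_da <- as.numeric(counts %*% components$mass_da)
    out$eps <- as.numeric(counts %*% components$eps)
    out <- out[do.call(order, as.data.frame(counts[, ord_cols, drop = FALSE])), ]
    out <- dplyr::distinct(out)
  } else {
    out$mass_da <- numeric(0)
    out$eps <- numeric(0)
  }
  attr(out, "constraints") <- constraints
  attr(out, "components") <- components
  class(out) <- c("dc_feasible", class(out))
  out
}

#' Couple wild-type and M3 feasible sets through their beta-catenin counts
#'
#' The polymerising (wild-type) complex recovers visibly more beta-catenin
#' than the M3 complex, so for every (APC, AXIN1) count pair present in both
#' sets, an M3 stoichiometry may carry at most one beta-catenin fewer than
#' the largest wild-type count at that pair. M3 entries whose (APC, AXIN1)
#' pair has no wild-type counterpart are retained unchanged; the wild-type
#' set is never filtered.
#'
#' @param wt,m3 Feasible sets from [enumerate_stoichiometries()] built on the
#'   same component table.
#' @return List with elements `wt` (unchanged) and `m3` (filtered).
#' @export
pair_wt_m3 <- function(wt, m3) {
  comps <- attr(wt, "components")
  if (is.null(comps)) comps <- attr(m3, "components")
  if (is.null(comps)) rlang::abort("feasible sets lack their component table attribute")
  sl <- role_slots(comps)
  nm <- paste0("n_", comps$component)
  apc_col <- nm[sl$apc]; axn_col <- nm[sl$axn]; sub_col <- nm[sl$sub]
  if (nrow(m3) == 0 || nrow(wt) == 0) return(list(wt = wt, m3 = m3))

  wt_max <- wt |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(apc_col, axn_col)))) |>
    dplyr::summarise(.wt_max_bcat = max(.data[[sub_col]]), .groups = "drop")

  m3f <- dplyr::left_join(m3, wt_max, by = c(apc_col, axn_col))
  keep <- is.na(m3f$.wt_max_bcat) | m3f[[sub_col]] <= m3f$.wt_max_bcat - 1
  m3f <- m3f[keep, setdiff(names(m3f), ".wt_max_bcat")]
  attr(m3f, "constraints") <- attr(m3, "constraints")
  attr(m3f, "components") <- comps
  class(m3f) <- class(m3)
  list(wt = wt, m3 = m3f)
}
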