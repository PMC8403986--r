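# Shared fixtures: random component tables and an independent brute-force
# enumeration oracle written directly from the feasibility rules, used to
# cross-check the pruned enumerator. Component masses and window widths are
# kept in a range where the full bounded grid stays small enough to
# enumerate naively (a few hundred thousand candidates per case).

random_components <- function(seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      component = c("SA", "SB", "K1", "K2", "SU"),
      mass_da = round(stats::runif(5, 200000, 300000)),
      eps = round(stats::runif(5, 20000, 400000)),
      role = c("scaffold_a", "scaffold_b", "kinase", "kinase", "substrate")
    )
  })
}

random_constraints <- function(components, seed) {
  withr::with_seed(seed, {
    variant <- sample(c("wt", "m3"), 1)
    rule <- sample(c("max", "sum"), 1)
    # centre the mass window on a random structurally plausible stoichiometry
    apc <- 1
    axn <- sample(max(if (variant == "wt") 2 else 1, apc):2, 1)
    k1 <- sample(ceiling(axn / 2):axn, 1)
    k2 <- sample(ceiling(axn / 2):axn, 1)
    lo <- if (rule == "max") max(axn, apc) else axn + apc
    hi <- min(axn + 10 * apc + (2 * axn - k1 - k2), lo + 2)
    sub <- sample(lo:hi, 1)
    counts <- c(apc, axn, k1, k2, sub)
    mass <- sum(counts * components$mass_da)
    eps <- sum(counts * components$eps)
    half_width <- stats::runif(1, 0.02, 0.1) * mass
    use_eps <- sample(c(TRUE, FALSE), 1)
    dc_constraints(
      mn_mean = mass + stats::runif(1, -0.5, 0.5) * half_width,
      mn_sd = half_width / 1.96,
      eps_mean = if (use_eps) eps else NULL,
      eps_sd = if (use_eps) 0.3 * eps / 1.96 else 0,
      ci_multiplier = 1.96,
      variant = variant,
      bcat_lower_rule = rule
    )
  })
}

# Naive quintuple-loop filter over the full bounded grid, conditions coded
# independently of the package internals.
oracle_enumerate <- function(components, constraints) {
  m <- components$mass_da
  e <- components$eps
  ci <- constraints$ci_multiplier
  mass_lo <- constraints$mn_mean - ci * constraints$mn_sd
  mass_hi <- constraints$mn_mean + ci * constraints$mn_sd
  eps_lo <- if (is.null(constraints$eps_mean)) -Inf else
    constraints$eps_mean - ci * constraints$eps_sd
  eps_hi <- if (is.null(constraints$eps_mean)) Inf else
    constraints$eps_mean + ci * constraints$eps_sd
  bounds <- pmax(floor(mass_hi / m), 0)
  g <- expand.grid(apc = 0:bounds[1], axn = 0:bounds[2], k1 = 0:bounds[3],
                   k2 = 0:bounds[4], sub = 0:bounds[5])
  mass <- with(g, apc * m[1] + axn * m[2] + k1 * m[3] + k2 * m[4] + sub * m[5])
  eps <- with(g, apc * e[1] + axn * e[2] + k1 * e[3] + k2 * e[4] + sub * e[5])
  min_axin <- if (constraints$variant == "wt") 2 else 1
  lower <- if (constraints$bcat_lower_rule == "max") pmax(g$axn, g$apc) else g$axn + g$apc
  ok <- mass >= mass_lo & mass <= mass_hi &
    eps >= eps_lo & eps <= eps_hi &
    g$apc >= 1 & g$axn >= 1 & g$k1 >= 1 & g$k2 >= 1 & g$sub >= 1 &
    g$axn >= min_axin &
    g$k1 >= ceiling(g$axn / 2) & g$k1 <= g$axn &
    g$k2 >= ceiling(g$axn / 2) & g$k2 <= g$axn &
    g$sub >= lower &
    g$sub <= g$axn + constraints$bcat_per_apc * g$apc + (2 * g$axn - g$k1 - g$k2) &
    g$axn >= g$apc &
    (constraints$variant != "m3" | g$axn <= constraints$axin_per_apc * g$apc)
  out <- g[ok, , drop = FALSE]
  attr(out, "out.attrs") <- NULL
  out[] <- lapply(out, as.integer)
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

feasible_as_plain <- function(feasible, components) {
  nm <- paste0("n_", components$component)
  out <- as.data.frame(feasible)[, nm, drop = FALSE]
  names(out) <- c("apc", "axn", "k1", "k2", "sub")
  out[] <- lapply(out, as.integer)
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# a feasible-set tibble with the attributes pair_wt_m3() expects
make_feasible <- function(df, components, constraints = NULL) {
  out <- tibble::as_tibble(df)
  names(out) <- paste0("n_", names(df))
  out$mass_da <- complex_mass(df, components)
  out$eps <- complex_extinction(df, components)
  attr(out, "components") <- components
  attr(out, "constraints") <- constraints
  class(out) <- c("dc_feasible", class(out))
  out
}

dc_1951 <- c(APC = 1, AXIN1 = 3, CK1a = 3, GSK3b = 3, bcat = 13)
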