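wide <- function(variant = "m3", rule = "max") {
  dc_constraints(mn_mean = 2e6, mn_sd = 1e6, eps_mean = NULL,
                 ci_multiplier = 1.96, variant = variant,
                 bcat_lower_rule = rule)
}

test_that("condition report walks the feasibility rules", {
  comps <- dc_components()

  # minimal M3 complex passes everything under wide windows
  rep <- check_conditions(c(APC = 1, AXIN1 = 1, CK1a = 1, GSK3b = 1, bcat = 2),
                          wide("m3"), comps)
  expect_true(all(rep$pass))

  # wild-type requires at least two AXIN1
  rep <- check_conditions(c(APC = 1, AXIN1 = 1, CK1a = 1, GSK3b = 1, bcat = 2),
                          wide("wt"), comps)
  expect_false(rep$pass[rep$condition == "c8_min_axin"])
  expect_true(all(rep$pass[!rep$condition %in% "c8_min_axin"]))

  # missing kinase breaks presence and occupancy, nothing errors
  rep <- check_conditions(c(APC = 1, AXIN1 = 2, CK1a = 0, GSK3b = 2, bcat = 3),
                          wide("wt"), comps)
  expect_false(rep$pass[rep$condition == "c5_all_present"])
  expect_false(rep$pass[rep$condition == "c9_kinase_occupancy"])

  # mass window violation is reported, not thrown
  tight <- dc_constraints(mn_mean = 1e5, mn_sd = 1, variant = "m3")
  rep <- check_conditions(c(APC = 1, AXIN1 = 1, CK1a = 1, GSK3b = 1, bcat = 2),
                          tight, comps)
  expect_false(rep$pass[rep$condition == "c4_mass"])

  # non-integer counts fail integrality
  rep <- check_conditions(c(APC = 1, AXIN1 = 1.5, CK1a = 1, GSK3b = 1, bcat = 2),
                          wide("m3"), comps)
  expect_false(rep$pass[rep$condition == "c6_integer"])
})

test_that("kinase occupancy uses the ceiling for odd AXIN1 counts", {
  comps <- dc_components()
  # 3 AXIN1 -> at least 2 of each kinase
  rep <- check_conditions(c(APC = 1, AXIN1 = 3, CK1a = 1, GSK3b = 2, bcat = 3),
                          wide("m3"), comps)
  expect_false(rep$pass[rep$condition == "c9_kinase_occupancy"])
  rep <- check_conditions(c(APC = 1, AXIN1 = 3, CK1a = 2, GSK3b = 2, bcat = 3),
                          wide("m3"), comps)
  expect_true(rep$pass[rep$condition == "c9_kinase_occupancy"])
})

test_that("vacant kinase sites extend the beta-catenin upper bound", {
  comps <- dc_components()
  # 1 APC, 2 AXIN1, fully kinase-loaded: cap = 2 + 10 + 0 = 12
  full <- c(APC = 1, AXIN1 = 2, CK1a = 2, GSK3b = 2, bcat = 13)
  rep <- check_conditions(full, wide("m3"), comps)
  expect_false(rep$pass[rep$condition == "c10_bcat_upper"])
  # one vacancy per kinase: cap = 2 + 10 + 2 = 14
  vac <- c(APC = 1, AXIN1 = 2, CK1a = 1, GSK3b = 1, bcat = 13)
  rep <- check_conditions(vac, wide("m3"), comps)
  expect_true(rep$pass[rep$condition == "c10_bcat_upper"])
})

test_that("narrow M3 window isolates the single 660 kDa stoichiometry", {
  comps <- dc_components()
  cons <- dc_constraints(mn_mean = 660000, mn_sd = 5000 / 1.96,
                         variant = "m3")  # window 655-665 kDa
  fs <- enumerate_stoichiometries(comps, cons)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$n_APC, 1)
  expect_equal(fs$n_AXIN1, 1)
  expect_equal(fs$n_CK1a, 1)
  expect_equal(fs$n_GSK3b, 1)
  expect_equal(fs$n_bcat, 2)
  expect_equal(fs$mass_da, 660000)
})

test_that("a window below the one-of-each minimum yields an empty set", {
  comps <- dc_components()
  for (v in c("wt", "m3")) {
    fs <- enumerate_stoichiometries(
      comps, dc_constraints(mn_mean = 50000, mn_sd = 50000 / 1.96, variant = v))
    expect_equal(nrow(fs), 0)
  }
})

test_that("enumerator equals the brute-force oracle on random tables", {
  for (case in 1:100) {
    comps <- random_components(1000 + case)
    cons <- random_constraints(comps, 2000 + case)
    fs <- enumerate_stoichiometries(comps, cons)
    expect_equal(feasible_as_plain(fs, comps), oracle_enumerate(comps, cons),
                 info = paste("case", case))
  }
})

test_that("widening the confidence multiplier never shrinks the feasible set", {
  key <- function(fs) do.call(paste, as.data.frame(fs)[, 1:5])
  for (case in 1:20) {
    comps <- random_components(3000 + case)
    cons <- random_constraints(comps, 4000 + case)
    narrow <- enumerate_stoichiometries(comps, cons)
    cons_wide <- cons
    cons_wide$ci_multiplier <- cons$ci_multiplier * 2
    wide_fs <- enumerate_stoichiometries(comps, cons_wide)
    expect_true(all(key(narrow) %in% key(wide_fs)), info = paste("case", case))
  }
})

test_that("returned stoichiometries lie inside their windows when recomputed", {
  comps <- dc_components()
  cons <- dc_constraints(mn_mean = 1072000, mn_sd = 68000,
                         eps_mean = 980087, eps_sd = 275179,
                         variant = "m3")
  fs <- enumerate_stoichiometries(comps, cons)
  expect_gt(nrow(fs), 0)
  counts <- as.data.frame(fs)[, paste0("n_", comps$component)]
  names(counts) <- comps$component
  mass <- complex_mass(counts, comps)
  eps <- complex_extinction(counts, comps)
  expect_true(all(mass >= 1072000 - 1.96 * 68000 & mass <= 1072000 + 1.96 * 68000))
  expect_true(all(eps >= 980087 - 1.96 * 275179 & eps <= 980087 + 1.96 * 275179))
  # deterministic and sorted
  fs2 <- enumerate_stoichiometries(comps, cons)
  expect_identical(tibble::as_tibble(fs), tibble::as_tibble(fs2))
  expect_false(is.unsorted(fs$n_APC))
})

test_that("wt/m3 pairing drops only over-occupied M3 entries at shared pairs", {
  comps <- dc_components()
  wt <- make_feasible(
    tibble::tibble(APC = 1, AXIN1 = 2, CK1a = 2, GSK3b = 2, bcat = 4), comps)
  m3_keep <- tibble::tibble(APC = 1, AXIN1 = 2, CK1a = 2, GSK3b = 2, bcat = 3)
  m3_drop <- tibble::tibble(APC = 1, AXIN1 = 2, CK1a = 2, GSK3b = 2, bcat = 5)
  m3_only <- tibble::tibble(APC = 1, AXIN1 = 1, CK1a = 1, GSK3b = 1, bcat = 2)
  m3 <- make_feasible(dplyr::bind_rows(m3_keep, m3_drop, m3_only), comps)

  res <- pair_wt_m3(wt, m3)
  expect_equal(nrow(res$wt), 1)           # wild-type set untouched
  expect_equal(nrow(res$m3), 2)
  expect_true(all(res$m3$n_bcat %in% c(3, 2)))
  # the M3-only (1 APC, 1 AXIN1) pair has no wild-type counterpart: retained
  expect_true(any(res$m3$n_AXIN1 == 1))
})
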