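test_that("standard curve is a through-origin line and converts signals", {
  sc <- fit_standard_curve(tibble::tibble(amount_pmol = c(1, 2, 4, 8),
                                          signal = 1000 * c(1, 2, 4, 8)))
  expect_equal(sc$slope, 1000)
  expect_equal(signal_to_pmol(sc, 500), 0.5)
  expect_error(fit_standard_curve(tibble::tibble(amount_pmol = c(1, 2),
                                                 signal = c(1, 2))), "3")
  expect_error(fit_standard_curve(tibble::tibble(amount_pmol = c(1, 2, 3),
                                                 signal = c(3, 2, -10))),
               "not positive")
})

test_that("standard-curve slope is unbiased at 2% noise", {
  slopes <- vapply(1:100, function(s) {
    ds <- simulate_kinase_assay(10, 50, 0.9, 50, noise_sd_rel = 0.02,
                                sc_slope = 1000, seed = s)
    fit_standard_curve(ds$standards)$slope
  }, numeric(1))
  # the origin-forced fit weights spots by amount^2, so per-run SD is
  # ~0.016 * slope; the MC standard error of the mean over 100 runs is
  # ~1.6 a.u. -- allow 3 SE
  expect_equal(mean(slopes), 1000, tolerance = 0.005)
})

test_that("initial rate is the OLS slope of product over time", {
  t <- c(0.5, 1, 2, 5)
  expect_equal(initial_rate(t, 2 * t), 2)
  expect_equal(initial_rate(t, rep(3, 4)), 0)
  expect_error(initial_rate(c(1, 1), c(1, 2)), "identical")

  ds <- simulate_kinase_assay(10, 50, 0.9, c(10, 50, 200))
  r <- initial_rates(ds$timecourse)
  expect_equal(r$v0_pmol_min, 10 * 0.9 * r$substrate_uM / (50 + r$substrate_uM))
})

test_that("Michaelis-Menten fit recovers parameters and applies the E_T convention", {
  s_grid <- c(5, 10, 25, 50, 100, 200, 400)
  v <- 9 * s_grid / (50 + s_grid)  # Vmax = kcat * ET = 10 * 0.9
  fit <- fit_michaelis_menten(tibble::tibble(substrate_uM = s_grid,
                                             v0_pmol_min = v), et_pmol = 0.9)
  expect_equal(fit$mode, "saturating")
  expect_equal(fit$vmax, 9, tolerance = 1e-6)
  expect_equal(fit$km, 50, tolerance = 1e-6)
  # E_T from 6 uL of 150 nM: 0.9 pmol, and kcat = Vmax / E_T
  et <- 6e-6 * 150e-9 * 1e12
  expect_equal(et, 0.9)
  expect_equal(fit$kcat, fit$vmax / et, tolerance = 1e-9)
  expect_equal(fit$kcat, 10, tolerance = 1e-6)
  # analytic identity: v0 at [S] = KM is Vmax / 2
  expect_equal(9 * 50 / (50 + 50), fit$vmax / 2, tolerance = 1e-6)

  expect_error(fit_michaelis_menten(
    tibble::tibble(substrate_uM = c(1, 2, 3), v0_pmol_min = c(1, 2, 3)), 0.9),
    "4")
})

test_that("parameter recovery holds at 2% noise over 200 seeds", {
  s_grid <- c(5, 10, 25, 50, 100, 200, 400)
  rel_err <- vapply(1:200, function(s) {
    ds <- simulate_kinase_assay(10, 50, 0.9, s_grid, noise_sd_rel = 0.02,
                                seed = s)
    fit <- fit_michaelis_menten(initial_rates(ds$timecourse), 0.9)
    c(abs(fit$kcat - 10) / 10, abs(fit$km - 50) / 50)
  }, numeric(2))
  expect_lt(median(rel_err[1, ]), 0.05)
  expect_lt(median(rel_err[2, ]), 0.05)
})

test_that("non-saturating titrations fall back to a linear efficiency", {
  # all concentrations far below KM: response is linear, Vmax/KM undetermined
  s_grid <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  v <- 9 * s_grid / (50 + s_grid)
  fit <- fit_michaelis_menten(tibble::tibble(substrate_uM = s_grid,
                                             v0_pmol_min = v), et_pmol = 0.9)
  expect_equal(fit$mode, "linear-only")
  expect_true(is.na(fit$kcat) && is.na(fit$km) && is.na(fit$vmax))
  # fitted efficiency matches kcat/KM of the generating model within 2%
  expect_equal(fit$efficiency, 10 / 50, tolerance = 0.02)
  td <- tidy(fit)
  expect_equal(td$term, "kcat/KM")
  expect_equal(glance(fit)$mode, "linear-only")
})

test_that("ratio error propagation matches the quadrature formula and Monte Carlo", {
  expect_equal(propagate_ratio_error(10, 1, 5, 0.5), 2 * sqrt(0.01 + 0.01))
  expect_equal(propagate_ratio_error(10, 0, 5, 0), 0)
  expect_error(propagate_ratio_error(0, 1, 5, 0.5), "non-zero")

  # symmetry in the relative errors
  a <- propagate_ratio_error(10, 0.3, 5, 0.1) / 2
  b <- propagate_ratio_error(5, 0.1, 10, 0.3) * 2
  expect_equal(a, b)

  # sampling oracle: small relative errors, 1e6 draws
  withr::with_seed(99, {
    x <- rnorm(1e6, 10, 0.1)
    y <- rnorm(1e6, 5, 0.05)
    mc <- sd(x / y)
  })
  expect_equal(propagate_ratio_error(10, 0.1, 5, 0.05), mc, tolerance = 0.05)
})

test_that("poly-ubiquitylated fractions are ratios in [0, 1]", {
  expect_equal(polyubiquitylated_fraction(750, 1000), 0.75)
  expect_equal(polyubiquitylated_fraction(0, 123), 0)
  expect_equal(polyubiquitylated_fraction(55, 55), 1)
  expect_error(polyubiquitylated_fraction(2, 1), "exceeds")
  expect_error(polyubiquitylated_fraction(1, 0), "total")
  f <- polyubiquitylated_fraction(runif(50, 0, 1), 1)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("tidy and glance summarise a saturating fit", {
  ds <- simulate_kinase_assay(10, 50, 0.9, c(5, 10, 25, 50, 100, 200, 400))
  fit <- fit_michaelis_menten(initial_rates(ds$timecourse), 0.9)
  td <- tidy(fit)
  expect_equal(td$term, c("Vmax", "KM", "kcat", "kcat/KM"))
  expect_equal(td$estimate[td$term == "kcat/KM"], fit$efficiency)
  gl <- glance(fit)
  expect_equal(gl$mode, "saturating")
  expect_equal(gl$ET_pmol, 0.9)
})
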