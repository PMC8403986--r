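# dcstoich

Quantitative analysis of reconstituted β-catenin destruction complexes
(DCs) — the AXIN1 / APC / CK1α / GSK3β / β-catenin assemblies that mark
β-catenin for degradation in the Wnt pathway. The package is aimed at
biochemists characterising such multi-protein complexes by SEC-MALS, mass
photometry and radiometric kinase assays, and covers four pieces of
analysis plus seeded synthetic-data generators with known ground truth for
every stage.

## What it computes

**SEC-MALS slice analysis.** Per elution slice, the mass concentration
follows from the differential refractive index, *c* = dRI / (d*n*/d*c*)
with d*n*/d*c* = 0.185 mL/g; the molar mass from the zero-angle
light-scattering relation *M* = LS / (*K·c*); and the molar extinction
coefficient from Beer–Lambert, ε = *A*₂₈₀ / (*l·c*) · *M*. Over a peak
window these aggregate into the weight- and number-average molar masses
and the dispersity,

  *M*w = Σ*cᵢMᵢ* / Σ*cᵢ*,  *M*n = Σ*cᵢ* / Σ(*cᵢ*/*Mᵢ*),  Đ = *M*w/*M*n ≥ 1,

plus the mean ± SD of the per-slice ε and the maximum molar complex
concentration at the detector. The complex-level ε converts an input A₂₈₀
into a molar concentration.

**Stoichiometry enumeration.** Integer copy-number vectors
(APC, AXIN1, CK1α, GSK3β, β-catenin) are enumerated exhaustively and kept
when (i) their summed mass and ε fall inside the measured
mean ± 1.96 SD windows and (ii) occupancy rules hold: at least one of each
component; at least two AXIN1 for the polymerising wild type (one for the
polymerisation-deficient M3 mutant); each kinase occupies between 50% and
100% of AXIN1 copies; each APC carries 1–10 β-catenin (four 15R + six
usable 20R repeats) and 1–3 AXIN1 (three SAMP repeats, a hard cap only
for non-polymerising AXIN1); at least one β-catenin per scaffold copy;
and vacant kinase sites on AXIN1 free up additional β-catenin slots. A
pairing step couples the two variants: at a shared (APC, AXIN1) count
pair, an M3 complex must carry at least one β-catenin fewer than the
largest wild-type count.

**Kinase kinetics.** Radiolabel standard curves (through the origin),
initial rates as OLS slopes of product vs. time, Michaelis–Menten fits
*v*₀ = *k*cat·[*E*T]·[S]/(*K*M + [S]) with [*E*T] entered as an amount
(0.9 pmol for 6 µL of 150 nM complex), quadrature error propagation for
*k*cat/*K*M, a linear-efficiency fallback when the titration does not
saturate, and poly-ubiquitylated-fraction ratios.

**Mass photometry.** Contrast-to-mass calibration on the NativeMark
standards (66, 146, 480, 1048 kDa) and fixed-bandwidth (25 kDa) Gaussian
KDEs of single-particle mass distributions.

## Worked example

```r
library(dcstoich)

# Which stoichiometries are consistent with a 655-665 kDa mass window for
# the non-polymerising (M3) variant?
cons <- dc_constraints(mn_mean = 660000, mn_sd = 5000 / 1.96, variant = "m3")
enumerate_stoichiometries(dc_components(), cons)
#> # A tibble: 1 × 7
#>   n_APC n_AXIN1 n_CK1a n_GSK3b n_bcat mass_da    eps
#>   <dbl>   <dbl>  <dbl>   <dbl>  <dbl>   <dbl>  <dbl>
#> 1     1       1      1       1      2  660000 727000
```

Exactly one composition fits: one APC, one AXIN1, one copy of each kinase
and two β-catenin, summing to 660 kDa.

```r
# A simulated radiometric titration (true kcat 10 /min, KM 50 uM, 2% noise)
# analysed back through initial rates and a Michaelis-Menten fit:
ds <- simulate_kinase_assay(kcat = 10, km = 50, et_pmol = 0.9,
                            substrate_um = c(5, 10, 25, 50, 100, 200, 400),
                            noise_sd_rel = 0.02, seed = 1)
fit_michaelis_menten(initial_rates(ds$timecourse), et_pmol = 0.9)
#> Michaelis-Menten fit (saturating)
#>   Vmax = 8.545 +- 0.12 pmol/min
#>   KM   = 44.63 +- 2 uM
#>   kcat = 9.494 +- 0.13 min^-1 (E_T = 0.9 pmol)
#>   kcat/KM = 0.2127 +- 0.0099 uM^-1 min^-1
```

The fit recovers the generating parameters within a few percent at this
noise level; `tidy()` and `glance()` return the same numbers as tibbles,
and `autoplot()` draws the rate curve. An input-sample concentration from
Beer–Lambert:

```r
round(estimate_input_concentration(0.86, eps_mean = 980087) * 1e9)  # nM
#> [1] 877
```

The bundled `dc_components()` table carries the subunit masses used above
together with *synthetic illustrative* extinction coefficients; replace
the ε column with sequence-derived values (see `gill_von_hippel()`) for
real analyses.

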