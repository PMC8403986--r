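---
title: "Models and methods behind dcstoich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dcstoich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcstoich)
```

dcstoich analyses reconstituted β-catenin destruction complexes (DCs):
assemblies of the scaffolds AXIN1 and APC, the kinases CK1α and GSK3β, and
their substrate β-catenin. Because AXIN1 polymerises and APC carries
multiple binding repeats, the complex has no single defined stoichiometry;
the package's central question is which integer subunit compositions are
compatible with what the instruments actually measure.

## SEC-MALS slice model

Size-exclusion chromatography with in-line multi-angle light scattering
yields, per elution slice, a differential refractive index (dRI), an
absorbance at 280 nm and a scattering signal. The analysis chain is:

* concentration: $c_i = \mathrm{dRI}_i / (dn/dc)$, with the protein
  refractive-index increment $dn/dc = 0.185$ mL/g. Units are g/mL
  internally; molar outputs convert explicitly via the slice molar mass.
* molar mass: $M_i = \mathrm{LS}_i / (K c_i)$. This is the zero-angle,
  zero-virial limit of the light-scattering equation — complexes are
  treated as point scatterers and only the product $K c M$ is observable.
  The full angle-dependent Zimm fit that instrument software performs is
  deliberately out of scope; the single scalar $K$ is shared between the
  simulator and the analyser, mirroring how real instruments bury it in
  their calibration.
* extinction coefficient: $\varepsilon_i = A_{280,i} / (l \, c_i) \cdot
  M_i$ in M$^{-1}$cm$^{-1}$ (Beer–Lambert, path $l$ in cm, $c$ in g/L).

Over an inclusive peak window the package reports
$M_w = \sum c_i M_i / \sum c_i$, $M_n = \sum c_i / \sum (c_i/M_i)$,
dispersity $Đ = M_w/M_n$, the mean and SD of the per-slice $\varepsilon_i$,
and the maximum molar complex concentration $c_i/M_i$ at the detector.
$Đ \ge 1$ always (Cauchy–Schwarz), with equality only for monodisperse
peaks, and both averages are invariant under uniform rescaling of the
concentrations — both properties are enforced as tests.

Numerical choices: slices with $c_i$ at or below a configurable floor
(default $10^{-9}$ g/mL) are excluded from all averages, because $M_i$
divides by $c_i$ and peak edges otherwise contribute pure noise; this
mirrors the practice of summarising only over a trimmed peak window. The
ε spread is reported as ±1 SD across slices; the 1.96 multiplier for a 95%
window is applied downstream by the enumerator, keeping the two choices
independent. The ε mean and SD are computed over the same peak window as
$M_n$ — whether the two windows should ever differ is a judgement call we
resolve by using one window for everything. Proprietary instrument-software
uncertainty models for $M_w$/$M_n$ are not reproduced; the slice SD plays
that role here.

The complex-level mean ε converts an input-sample A280 into a molar
concentration, $c = A_{280} / (\varepsilon l)$. Because the DC's
composition is concentration dependent, so is its ε; these estimates are
therefore tied to the concentration at which the window was measured.

## Stoichiometry enumeration

A stoichiometry is a vector of non-negative integer copy numbers
$(n_{APC}, n_{AXIN1}, n_{CK1\alpha}, n_{GSK3\beta}, n_{\beta cat})$, with
derived mass and ε the count-weighted sums over the component table. A
candidate is feasible when:

1. mass and ε lie inside mean ± `ci_multiplier` · SD of the measured
   windows (default 1.96, i.e. 95%);
2. at least one copy of every component is present;
3. counts are integers;
4. $n_{AXIN1} \ge 2$ for wild-type AXIN1 (polymerisation is what builds
   large complexes, and a polymer implies at least a dimer); $\ge 1$ for
   the polymerisation-deficient M3 mutant;
5. each kinase occupies at least 50% and at most 100% of AXIN1 copies:
   $\lceil n_{AXIN1}/2 \rceil \le n_{kinase} \le n_{AXIN1}$. The ceiling
   implements "at least 50%" with indivisible molecules;
6. $n_{\beta cat} \le n_{AXIN1} + 10\,n_{APC} + (2 n_{AXIN1} -
   n_{CK1\alpha} - n_{GSK3\beta})$: one β-catenin site per AXIN1, ten per
   APC (four 15R and six usable 20R repeats; 20R2 does not bind), and one
   extra slot per vacant kinase site on AXIN1 — the reading under which
   incomplete kinase occupancy changes the count bound at all;
7. $n_{AXIN1} \ge n_{APC}$, and for M3 additionally
   $n_{AXIN1} \le 3 n_{APC}$ (three SAMP repeats per APC). The cap is not
   applied to wild-type AXIN1 because polymers chain beyond direct SAMP
   attachment — the same biology that motivates rule 4;
8. $n_{\beta cat} \ge \max(n_{AXIN1}, n_{APC})$ by default: a β-catenin
   can bridge an AXIN1 site and an APC repeat simultaneously, so one copy
   can satisfy one site on each scaffold. The stricter additive reading is
   available as `bcat_lower_rule = "sum"`.

Enumeration is exhaustive over the bounded grid
$n_X \le \lfloor \text{mass}_{hi} / \text{mass}_X \rfloor$, which
guarantees termination and cannot exclude a feasible vector (rule 1 caps
the total mass). The implementation iterates the scaffold and kinase
counts inside their structural ranges and intersects the substrate range
with the mass window analytically; a naive quintuple-loop filter over the
full grid is kept in the test suite as an independent oracle and the two
agree on 100 randomised component tables per run. Output is sorted
lexicographically by (APC, AXIN1, kinase, kinase, substrate) counts so
results do not depend on traversal order.

The cross-variant pairing applies two coupled observations — wild-type
complexes carry visibly more β-catenin, and M3 complexes never more than
wild-type — as: at each (APC, AXIN1) count pair present in both feasible
sets, M3 entries keep at most (max wild-type β-catenin at that pair) − 1
copies. We interpret "a given AXIN1:APC stoichiometry" as the exact count
pair, not the ratio; entries whose pair is absent from the other set are
retained, since the data constrain only compositions both variants can
form. The wild-type set is never filtered.

The bundled component table ships masses of 312 / 92 / 39 / 47 / 85 kDa
for APC / AXIN1 / CK1α / GSK3β / β-catenin and *synthetic illustrative*
extinction coefficients scaled to a typical specific absorptivity of
roughly 1.1 (mg/mL)⁻¹cm⁻¹. For real work, compute sequence-based values
with `gill_von_hippel()` (5500 per Trp, 1490 per Tyr, optionally 125 per
cystine) and pass your own table; no shipped analysis depends on the
placeholder ε values.

## Kinase kinetics

Radiometric assays quantify phosphorylated substrate via a standard curve
of known radiolabel amounts (the conventional two-fold dilution series
12.5 … 0.195 pmol). The curve is fitted through the origin by default —
zero label should give zero background-corrected signal — with a free
intercept available as a switch since instrument conventions vary.
Initial rates are OLS slopes of product against time with a free
intercept; time zero is not a fitted point because the assay's first
sample is at 0.5 min.

Rates against substrate concentration are fitted by nonlinear least
squares to $v_0 = k_{cat} [E_T] [S] / (K_M + [S])$ (plain Gauss–Newton
first, Levenberg–Marquardt as fallback; non-convergence is an error, not
a silent result). $[E_T]$ follows the assay convention of an *amount*:
0.9 pmol for 6 µL of 150 nM kinase complex, so
$k_{cat} = V_{max}/E_T$ in min⁻¹. The efficiency $k_{cat}/K_M$ carries a
standard error propagated in quadrature,
$\delta z = |z| \sqrt{(\delta x/x)^2 + (\delta y/y)^2}$, which the tests
check against a 10⁶-draw Monte-Carlo oracle.

When a titration does not saturate, $V_{max}$, $K_M$ and $k_{cat}$ are
not identifiable and the fit reports them as not determined. The
detection heuristic is a package convention: under Michaelis–Menten
curvature the rate at the largest [S] is strictly less than twice the
rate at half that concentration, approaching exactly twice as the
response becomes linear; we declare `linear-only` mode when the observed
ratio is ≥ 1.8. In that mode the efficiency comes from a through-origin
linear fit divided by $E_T$, which converges to the true $k_{cat}/K_M$
as $[S] \ll K_M$ (tested at $[S] \le K_M/100$, agreement within 2%).
Replicates are pooled, not weighted, in all fits.

## Mass photometry

Contrast-to-mass calibration is a least-squares line through the
standard-protein points (66, 146, 480, 1048 kDa). The intercept is free
by default — whether instrument software forces the line through the
origin is unknown, and a free intercept is the safer assumption; a
through-origin switch exists. Event masses are then kernel-density
estimated with a Gaussian kernel of *fixed* 25 kDa bandwidth (no
rule-of-thumb selection: fixed bandwidth keeps distributions comparable
across samples). The KDE is the exact kernel mixture evaluated on a grid
from 0 to max(mass) + 4 bandwidths at 1 kDa steps — wide enough for the
multi-MDa complexes of interest — so it integrates to 1 up to grid
truncation, and its mean equals the sample mean of the events; both are
test invariants.

## Synthetic data and what passing tests mean

The generators exist so that every analysis stage can be tested against
known ground truth:

* chromatograms: each species elutes as a Gaussian profile in volume
  (the simplest shape consistent with single-peak elution), channels are
  computed exactly from the species' mass, ε and the shared constants,
  and multiplicative Gaussian noise is applied per channel — detector
  noise scales with signal, and the multiplicative form keeps noiseless
  round trips exact. Ground truth (per-slice true concentration, molar
  mass, molar complex concentration) is stored beside the observations.
* photometry events: categorical mixture draws plus Gaussian mass noise,
  converted to contrasts by inverting a known calibration line.
* kinase assays: product grows as $v_0 t$ with $v_0$ from the
  Michaelis–Menten equation over the sampled time points, i.e. the
  simulation lives entirely in the initial-rate regime.

All generators are seed-reproducible bit for bit. No instrument noise
magnitudes are published for the study system, so the defaults (2%
relative noise where tests need a noisy regime) are free parameters
chosen as a realistic detector-class figure, not calibrated values.

The generators deliberately omit band broadening and inter-detector
delays, the second virial coefficient, substrate depletion and product
inhibition in time courses, and photometry shot-noise physics. Passing
round-trip tests therefore demonstrates that the analysis inverts the
stated measurement model exactly and degrades gracefully under
multiplicative noise — not that real chromatograms or movies satisfy
that model.

Test problem sizes are chosen to keep the full suite in the tens of
seconds while leaving Monte-Carlo error well below the asserted bounds:
~70-slice chromatograms, 200-seed recovery ensembles at 2% noise,
100 randomised enumeration tables per property, 10⁶-draw propagation
oracles and 5,000-event photometry samples.

## Pipelines

`run_stoichiometry_pipeline()` chains simulate → per-slice analysis →
peak summary → enumeration for both AXIN1 variants and then the pairing
step, writing every intermediate table as CSV plus a provenance log
(package version, seed, config hash) sufficient to re-run any stage in
isolation; `run_kinetics_pipeline()` does the same for the kinase chain.
Both take a single YAML-serialisable config (`read_run_config()` /
`write_run_config()`); per-variant seeds are derived from the one config
seed so the two simulated runs differ but the whole pipeline stays
deterministic. These functions, rather than a shell wrapper, are the
orchestration interface: the intended users work in R.

## Known limitations

* The zero-angle scattering model ignores angular dependence; for very
  large complexes real instruments fit it, and $K$ here is arbitrary
  rather than calibrated.
* Feasibility windows inherit the ±1.96 SD convention; with few slices
  the slice SD is itself noisy, and the window is only as good as it.
* The enumeration conditions encode specific biological readings
  (bridging β-catenin, vacancy bonus, WT exempt from the SAMP cap);
  where a stricter reading exists it is exposed as a switch rather than
  silently chosen.
* Kinetics fits assume initial-rate linearity over the sampled times;
  the simulator enforces it, real data may not.
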