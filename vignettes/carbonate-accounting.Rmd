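---
title: "Methods: inorganic carbon burial accounting in Blue Carbon sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inorganic carbon burial accounting in Blue Carbon sediments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blueCinorg)
```

## The problem

Seagrass meadows, mangrove forests and saltmarshes bury organic carbon, the
basis of "Blue Carbon" climate strategies. The same sediments often hold
large stocks of calcium carbonate deposited by associated calcifiers and,
frequently, imported from adjacent coral reefs or karstic catchments.
Calcification is a CO₂ *source* — roughly ψ = 0.6 mol CO₂ is released to
the atmosphere–seawater system per mol CaCO₃ precipitated — so a naïve
comparison of C_inorg and C_org burial rates can make a carbonate-rich
meadow look like a net CO₂ emitter. The accounting implemented here keeps
the two questions separate: *how much* carbonate is buried (a chronology and
concentration problem) and *where it was produced* (a mass-balance problem).
Only locally produced CaCO₃ carries the ψ-fold CO₂ penalty.

## The CF:CS chronology

Under the constant flux–constant sedimentation model, the flux of excess
²¹⁰Pb to the sediment surface and the mass accumulation rate (MAR) are both
constant, so the excess activity at cumulative dry mass $m$ (g cm⁻²) is

$$A_{xs}(m) = A_0\, e^{-\lambda m / \mathrm{MAR}},$$

with $\lambda = \ln 2 / 22.3$ yr⁻¹. `fit_cfcs()` regresses
$\ln A_{xs}$ on $m$ and takes $\mathrm{MAR} = \lambda/|\text{slope}|$, the
sediment accretion rate $\mathrm{SAR} = \mathrm{MAR}/\overline{\mathrm{DBD}}$
(mass-weighted mean dry bulk density of the fitted slices), and slice ages
$m_i/\mathrm{MAR}$.

Design choices that were genuinely open:

* **Mass versus depth coordinate.** CF:CS is defined on mass flux, so the
  default regression uses cumulative mass at slice midpoints; compaction
  then does not bias the rate. A `coordinate = "depth"` variant (slope
  $-\lambda/\mathrm{SAR}$) is provided for sensitivity analyses, since many
  published chronologies used linear depth. On uniform-density cores the two
  are identical (tested).
* **Supported ²¹⁰Pb.** When a ²²⁶Ra (or other supported) column exists its
  mean is used; otherwise the default is the mean total activity of the 3
  deepest slices (`estimate_supported()`, method `deep_plateau`). A warning
  flags profiles whose plateau estimate exceeds the shallow minimum — the
  plateau has likely not been reached and the chronology should be treated
  with caution. The choice is recorded in the returned object.
* **Weighting.** Ordinary least squares by default, the common CF:CS
  practice; inverse-variance weighting by activity errors is available
  (`weighting = "activity_err"`).
* **Non-positive excess.** Slices at or below the supported level are
  excluded from the regression rather than clamped into the log domain
  (clamping biases the slope); they still receive ages by extrapolation.
  At least three positive-excess slices are required, and a non-negative
  slope is an error ("no decay trend"), never a silent result.

## Carbonate accounting

Contemporary accounting uses slices younger than calendar year 1900
(midpoint convention, `post1900_mask()`). Over that window,

$$\mathrm{CaCO_3\%} = \text{unweighted mean of slice percentages}, \qquad
  C_{inorg} = \overline{\mathrm{DBD}} \cdot \frac{\mathrm{CaCO_3\%}}{100}
  \cdot f_c,$$

with $f_c = 0.12$, the rounded carbon mass ratio of CaCO₃ (the molar-exact
12.011/100.087 is available through the configuration; the rounded value is
the accounting convention and keeps published rate pairs exactly
consistent). The burial rate is $\mathrm{SAR} \times C_{inorg} \times 10^4$
gC m⁻² yr⁻¹. The dry bulk density entering the concentration is averaged
over the same post-1900 window as the CaCO₃ percentage — the one reading
consistent with the averaging of the percentages. Cores with negligible
CaCO₃ legitimately yield zero burial and are *retained* in all statistics;
undated cores (no usable ²¹⁰Pb profile) contribute concentrations but no
rates (`core_carbonate(core, chron = NULL)`).

## Aggregation and global upscaling

Cores from the same site or area with the same allochthonous-source state
are replicates of one *location* (`group_locations()`); cores sharing a site
but differing in source presence are split, since they sample different
carbonate regimes. Location-level values feed `summarize_distribution()`,
which always reports both median (IQR) and mean (SE): burial-rate and CaCO₃
distributions are strongly right-skewed and bimodal, so the median is the
preferred central tendency, and a Shapiro–Wilk screen (α = 0.05, advisory
only, never gating) documents the non-normality. Quantiles use linear
interpolation between order statistics (the type-7 convention interpolating
at index $p(n-1)$); IQR values depend on this choice, hence it is fixed and
documented. No standard error of the median is attempted.

Global estimates are the product rate × area: Tg yr⁻¹ = (gC m⁻² yr⁻¹) ×
km² × 10⁻⁶, over an areal range (seagrass 150,000–600,000 km²; mangrove
137,760 km²). `partitioned_global()` splits the extent 2/3 tropical : 1/3
higher-latitude with zone-specific rates; with equal rates the partition
reproduces the unpartitioned product exactly (a conservation property that
is tested). Presentation rounding (whole Tg at ≥ 10, one decimal below)
is applied only to the `presented` strings; unrounded values are always
returned.

## The carbon budget and the allochthonous mass balance

For a site with net CO₂ uptake by primary production $U$ and net community
calcification $C$ (calcification minus dissolution, in C_inorg units):

* emission $E = \psi C$ (signed: net dissolution, $C < 0$, is a CO₂ uptake
  and is never clamped);
* net sequestration $S = U - E$, classifying the site as net sink, net
  source, or neutral;
* allochthonous fraction of burial $= 1 - \max(C, 0)/B$ for burial rate
  $B > 0$, clamped to $[0,1]$ with an explicit flag when local production
  exceeds burial.

`global_offset()` applies the same logic to global ranges under the
worst-case assumption that all buried CaCO₃ is autochthonous: emissions are
ψ-fold the burial bounds and offsets divide them by the C_org burial bounds,
paired index-wise (low/low, high/high). Presented values follow the printed
convention for ranges — integer bounds once the range reaches 10 Tg, with
presented offsets recomputed from those integer emissions (so 7.8–37.2 Tg
prints as 8–37, and against 48–112 Tg of C_org burial gives 17–33%); the
unrounded values are always in the returned object. An envelope pairing
(min/max over cross pairings) is available behind `pairing = "envelope"`.

## Effect-size statistics

The vegetated-versus-unvegetated carbonate comparison uses Hedges' g:

$$g = \frac{(\bar X_E - \bar X_C)\,J}{SD_{pooled}},\quad
  SD_{pooled} = \sqrt{\tfrac{(n_E-1)SD_E^2 + (n_C-1)SD_C^2}{n_E+n_C-2}},\quad
  J = 1 - \tfrac{3}{4(n_E+n_C-2)-1},$$
$$V_g = \frac{n_E+n_C}{n_E n_C} + \frac{g^2}{2(n_E+n_C)}.$$

Per-study effects are pooled with one-level DerSimonian–Laird
random-effects weighting ($1/(V_g + \tau^2)$) and a normal z-test. This is
a deliberate simplification of multilevel pooling with study and
marine-province random terms: a multilevel variance structure cannot be
reproduced without its full specification, whereas DL is a standard,
fully-determined estimator (cross-checked against `metafor::rma(method =
"DL")` in the tests). The scientific conclusion it supports — no detectable
vegetated/unvegetated difference in carbonate content under the null — is
the same, but exact z and p values from a multilevel fit are not a target.
Studies with a single core in either habitat are excluded (no SD), and the
number of pooled comparisons is reported.

`mann_whitney()` reports U for its first argument and uses exact
enumeration of the permutation null whenever $n_a + n_b \le 12$ with no
ties, falling back to the tie- and continuity-corrected normal
approximation otherwise. The exact path exists because the normal
approximation is genuinely poor at these sizes: full enumeration shows
worst-case two-sided p discrepancies of ~0.13 at $n_a = 1$, ~0.09 at
$n_a = n_b = 2$ and ~0.04 at $n_a = n_b = 3$ (concentrated at mid-range p;
tail agreement is much better). No approximation choice removes this, so
the package defaults to exact where it matters.

## The synthetic-core generator

`generate_core()` simulates what the accounting assumes: activities
$A_i = A_{sup} + A_0 e^{-\lambda m_i/\mathrm{MAR}} \varepsilon_i$ with
multiplicative lognormal noise $\varepsilon_i$ (mean 1, CV `noise_cv`;
counting errors scale with activity — an additive variant is deliberately
not the default), and CaCO₃ %DW drawn logit-normal in $[0, 100]$.
Logit-normal was chosen over Beta because its two parameters map directly
onto a median percentage and a spread, making regimes easy to state: cores
near allochthonous sources centre at 60 %DW, cores without at 3 %DW —
reproducing the strong bimodality of real compilations, where ~40% of
locations sit under 10 %DW and over a quarter above 80 %DW.

Generator defaults are the study conditions the package mirrors, chosen
once: true SAR 0.22 cm yr⁻¹ (the compiled seagrass median), DBD 1 g cm⁻³,
surface excess 500 Bq kg⁻¹ over a supported level of 25 Bq kg⁻¹, 10%
activity noise, 20 one-cm slices. `generate_dataset()` arranges cores into
locations sharing a source state and a location-level carbonate centre
(17 locations × 3 cores = 51 cores by default, 60% of locations with
sources, between-core SAR lognormal with σ_log = 0.4), optionally adding a
matched set of unvegetated cores per location drawn from the *same* regime —
the null hypothesis of equal carbonate content inside and outside the canopy.
All generators are pure functions of their scenario and seed, restoring the
caller's RNG state.

What the generator does **not** emulate: sediment mixing and bioturbation,
compaction, ²¹⁰Pb flux variability (the CF:CS assumptions are imposed, not
violated), spatial correlation between locations, and the messy reality of
multi-study compilations (different counting geometries, inconsistent
supported-activity conventions). Passing recovery tests therefore
demonstrate that the estimators invert the model they assume — they say
nothing about robustness to violations of that model on real cores.

## Numerical conventions and problem sizes

* Noiseless profiles are recovered to 10⁻⁶ relative (tested across MAR
  0.03–0.8 g cm⁻² yr⁻¹); with 10% activity noise the median fitted SAR over
  200 replicates stays within 5% of truth.
* The Hedges' g implementation agrees with a brute-force re-evaluation of
  the printed formulas to 10⁻¹² relative over 1000 random inputs.
* Monte-Carlo calibration in the test suite uses 1000 replicates for the
  pooled z-test type-I error (k = 5 studies, n = 20 per arm) and 100
  replicates for the paired-contrast null; the recovery harness uses 50–200
  replicates per scenario. These sizes give stable checks at sub-minute
  runtimes and are stated here as the package's chosen validation sizes.
* CSV round trips serialize numerics with `%.17g`, so write/read reproduces
  every double bit-identically.
* Ties in `mann_whitney()` force the normal path; a fully tied sample
  returns U at its null mean with p = 1.

## Known limitations

* CF:CS only: no constant-rate-of-supply (CRS) or constant-initial-
  concentration model, no ¹³⁷Cs validation, no compaction correction.
  Cores whose excess profile is non-monotone for physical reasons (mixing,
  flux changes) will either fail the fit or silently average through the
  structure, as CF:CS always does.
* The ψ = 0.6 emission factor is a fixed scalar; the true released-CO₂
  ratio varies with temperature, salinity and pCO₂, and no
  carbonate-chemistry dependence is modelled.
* The effective density converting CaCO₃ mass flux to vertical accretion
  (`caco3_accretion()`) is a user parameter — bulk sediment versus mineral
  density differ by a factor of ~2 and published order-of-magnitude
  accretion figures do not state their choice.
* Reproduction of compiled-dataset statistics (global medians, ecosystem
  SAR medians) requires the underlying multi-study core compilation, which
  is third-party data not shipped with the package; the end-to-end test
  instead validates the pipeline on the synthetic compilation described
  above.
* Allochthonous-source flags are inputs; the package does not derive them
  from reef or lithology maps.
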