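---
title: "Chamber flux estimation and trait quality control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chamber flux estimation and trait quality control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxtraits)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the parameters that matter, and the numerical
choices made where the design was genuinely open. The companion README
shows a worked end-to-end example.

## The chamber flux model

A closed transparent or darkened chamber is sealed over a vegetation plot
and CO~2~ concentration is logged at 1 Hz for about three minutes. As CO~2~
is taken up or released, the concentration inside the chamber relaxes
towards a new equilibrium. The package models one closure as

$$C(t) = C_m + a\,(t - t_z) + (C_z - C_m)\,e^{-b (t - t_z)}$$

where $C_m$ (ppm) is the concentration once equilibrium is established,
$a$ (ppm s$^{-1}$) is a residual linear drift, $b$ (s$^{-1}$) is the
equilibration rate, $C_z$ (ppm) is the concentration at the start of the
usable record and $t_z$ (s) is the time at which the model crosses $C_z$.
The instantaneous flux the plot imposed on the chamber air at $t_z$ is the
derivative

$$C'(t_z) = a + b\,(C_m - C_z),$$

which the ideal-gas law converts to an areal flux:

$$F = C'(t_z)\,\frac{P V}{R\,T\,A}$$

with $P$ the pressure (atm), $V$ the chamber-plus-tubing volume (L), $R =
0.082057$ L atm K$^{-1}$ mol$^{-1}$, $T$ the mean chamber air temperature
(K) and $A$ the chamber base area (m$^2$). With the slope in ppm
s$^{-1}$ (µmol mol$^{-1}$ s$^{-1}$) this yields µmol m$^{-2}$ s$^{-1}$ and
is rescaled by $3600/1000$ to mmol m$^{-2}$ h$^{-1}$, the unit of the
output tables. The default geometry (25 L, 0.0625 m$^2$, 1 atm) describes
a 25 × 25 × 40 cm chamber on a 25 × 25 cm frame.

### Fitting procedure

1. The first and last 10 s of each closure are discarded (sealing and
   venting transients).
2. $C_z$ is the intercept, at the start of the retained window, of an
   ordinary least-squares line through the first 15 s of retained data.
3. With $C_z$ held fixed, $(C_m, a, b, t_z)$ minimise the RMSE of the
   model residuals under a derivative-free Nelder–Mead simplex.

Two numerical choices support step 3. First, with $(b, t_z)$ fixed the
model is linear in $(C_m, a)$, so those are profiled out by least squares
on a 24-point log-spaced grid of $b \in [10^{-4}, 2]$; the best few grid
points seed the simplex. This matters because nearly linear closures
(small $b$) make $b$ and $C_m$ almost unidentifiable jointly, and a single
simplex start can stall in a local minimum with $b$ slightly negative —
which the QC tree would misread as an artefact. Second, the simplex is
restarted until the objective stabilises; on noiseless series the RMSE
approaches zero, where the relative-tolerance stopping rule alone never
triggers. The multi-start and restarts are deterministic, so a fixed input
always yields the same fit.

### A known limitation: the $C_z$ anchor

On an exactly exponential series the fitted curve interpolates the data
(RMSE $\approx$ 0), yet the reported slope is not exactly
$a + b(C_m - C_z)$ evaluated at the generating parameters. The reason is
geometric: the least-squares line through the first 15 s of a convex or
concave curve has an intercept bias of roughly $17.5\,b^2 (C_m - C_z)$
ppm, so the fit re-anchors at a slightly shifted $t_z$ where the curve
equals the estimated $C_z$, and reports the derivative there. The
relative slope deviation is about $14\,b^2$ — negligible for slowly
equilibrating closures ($b \lesssim 0.01$ s$^{-1}$), around 3% at
$b = 0.05$ s$^{-1}$, and the dominant error term for fast-equilibrating
chambers. Users comparing against simulated ground truth should expect
this floor; it is a property of the $C_z$ definition, not of the
optimiser.

## The flux QC decision tree

Each fitted closure receives exactly one flag:

1. `start_error` — the first retained reading lies outside
   421 ± 100 ppm (ambient plus a generous band); the chamber was not
   properly vented or sealed. Checked first, before fit quality.
2. A fit is *bad* when $b \geq 1$ or $b < 0$ (both exits of $[0, 1]$ are
   optimiser artefacts), when a darkened-chamber (ER) closure shows a
   negative slope (ecosystem respiration cannot be uptake), or when the
   optimiser did not converge.
3. A bad fit with $|r| > 0.5$ (Pearson correlation of time and
   concentration over the fitting window) is `discard`ed: there is a real
   trend the model failed to capture. A bad fit with $|r| \leq 0.5$ is
   replaced by `zero`: the variation is mostly noise.
4. Everything else is `okflux` with the converted flux value.

Boundary conventions are strict as documented: $b = 1$ is bad, $|r| = 0.5$
falls on the `zero` branch, a start concentration exactly on the band edge
passes. Analyst-rejected measurements (`weird_flux`) are a manual override
that blanks the value; rounds never measured become `missing_round`
placeholders so that flag counts always partition the full slot grid.

## GPP and the diurnal baseline correction

Gross primary production is computed per plot and round as
$\mathrm{GPP} = \mathrm{NEE} - \mathrm{ER}$ (negative = CO~2~ removal).
When one member was zeroed the GPP is flagged `zeroNEE`/`zeroER`; when one
member has no value the GPP inherits the blocking flag.

CO~2~ accumulates in the vegetation layer before a transparent-chamber
measurement and is disturbed before the darkened one, biasing night-time
GPP positive. The correction shifts all valued GPP records within each
site × 24 h measurement cycle so that the most positive GPP equals zero.
Cycle boundaries are anchored at each site's first measurement, not at
calendar midnight, because campaigns start mid-day. Only GPP is shifted —
NEE and ER stay as measured — and the applied offset is stored in a
`gpp_offset` column. The correction is a switch
(`night_correction = FALSE` leaves GPP = NEE − ER bit-exact) for users who
prefer uncorrected data.

## Leaf trait derivation and validation

Composite samples (several leaves per envelope) are averaged to per-leaf
values: wet mass and leaf area divide by the number of leaves collected,
dry mass divides by the number of leaves present at drying (leaves are
occasionally lost between stations), and the five tightly folded-leaf
graminoids (*Festuca rubra*, *F. ovina*, *F. vivipara*, *Avenella
flexuosa*, *Nardus stricta*) are scanned folded, so their scanned area is
doubled first. Thickness is the mean of up to three micrometer readings.
Then SLA = area/dry mass (cm$^2$ g$^{-1}$) and LDMC = dry/wet mass
(g g$^{-1}$), each computed from internally consistent leaf sets, plus
C:N and N:P where chemistry exists. Pooled chemistry assays are expanded
back to every contributing leaf with a `merged` marker and the pool
membership in `ID_merged`.

Validation removes individual values (not whole leaves) outside
plausibility limits: LDMC > 1 g g$^{-1}$ (physically impossible), SLA
outside (5, 500) cm$^2$ g$^{-1}$, and leaf N > 6.4% — a cutoff taken from
the highest published values for these genera and treated as
configuration, not recomputed. All thresholds are strict inequalities, so
boundary-equal values are retained. The raw view keeps every row with its
flags; the clean view drops flagged and duplicated rows, and the row
counts balance exactly.

## Assimilation–temperature curve QC

Thermal response curves measured on a continuous leaf-temperature ramp
are screened in two stages.

**Modality.** A cubic smoothing spline is fitted with smoothness chosen by
generalised cross-validation, then evaluated on a 512-point grid; curves
whose spline has more than one maximum are excluded (stomatal
oscillations and similar confounders produce secondary bumps). Two
guards make the count stable under measurement noise, where plain GCV
visibly undersmooths 1–2 s gas-exchange data and fragments a single
physiological peak into micro-ripples: the spline's equivalent degrees of
freedom are capped (default 10), and a maximum only counts if its
prominence — height above the deeper adjacent saddle — exceeds 5% of the
fitted range. Plateaus collapse to a single maximum; monotone curves
count one boundary maximum.

**Optimum temperature.** Unimodal curves are fitted with the
Sharpe–Schoolfield model with high-temperature deactivation in its
explicit-$T_{opt}$ form (reference temperature 20 °C, Boltzmann constant
in eV K$^{-1}$), by Levenberg–Marquardt least squares multi-started over
a deterministic grid of candidate optima from 0 to 60 °C — deliberately
extending beyond any measured range so that out-of-range optima are
recovered rather than clipped. A curve whose fitted $T_{opt}$ falls
strictly outside the measured leaf-temperature range is excluded: such
data cannot constrain the optimum. The deactivation energy is bounded at
8 eV; published deactivation energies for photosynthesis are a few eV,
and without the ceiling the optimiser can manufacture an arbitrarily
sharp deactivation cliff at the edge of the data, pulling a truly
out-of-range optimum just inside the measured range and defeating the
range criterion.

## Microclimate QC

Logger series are first trimmed to the deployment window (closed
interval), then range-filtered: air temperature within [−40, 30] °C,
ground within [−40, 35] °C, soil within [5, 20] °C, and soil moisture not
below 0%. Comparisons are strict; boundary values are retained. Flagged
values are nulled in the clean view but kept, with their flag
(`cut_Tmax_air`, `cut_Tmin_soil`, `cut_min_moist`, ...), in the raw view,
and the filter is idempotent. Raw moisture counts are converted by a
user-supplied polynomial calibration for the configured soil class
(default label `silt_loam`); the coefficients are accepted as opaque
configuration because their derivation needs laboratory soil data.

## The synthetic-data module

Every pipeline input can be generated with known ground truth, which is
how the package tests itself without field data.

* **Flux closures** follow the exponential model exactly at zero noise,
  with additive i.i.d. Gaussian concentration noise (the simplest model
  consistent with analyser noise; the default 1 ppm is a free parameter
  since no analyser noise figure is available). Scenario defaults were
  fixed once at field-realistic values: 180 s closures at 1 Hz, starting
  concentrations U(400, 440) ppm, drift U(−0.02, 0.02) ppm s$^{-1}$,
  equilibration rate log-uniform on [0.005, 0.1] s$^{-1}$ (time constants
  of 10–200 s for a fan-mixed 25 L chamber), and slope magnitudes
  U(0.1, 2) ppm s$^{-1}$, i.e. flux magnitudes of roughly 6–120 mmol
  m$^{-2}$ h$^{-1}$.
* **Failure modes** map one-to-one onto QC flags: shifted start
  concentrations (`start_error`); a fast transient with $b$ far above 1
  followed by trendless signal (`zero`); a steadily declining darkened-
  chamber closure (`discard`). The mode library is closed so that QC
  recall can be computed exactly against labels.
* **Campaigns** emit hourly paired NEE/ER closures per plot over a 24 h
  cycle with shared covariates and a schedule attribute, so
  missing-round detection can be tested by construction.
* **Trait tables** draw true per-leaf SLA, LDMC and dry mass and invert
  every processing rule (per-leaf averaging, folded-area halving) to
  produce the raw envelope columns; injected violations each trip exactly
  one validation rule.
* **AT curves** are drawn from the Sharpe–Schoolfield model itself
  (unimodal), with a second well-separated bump added (bimodal; the
  primary peak is kept in the lower 35% of the range so the two modes do
  not merge under smoothing), or with the optimum placed 10 °C above the
  measured range (monotone). Battery noise is expressed as a fraction of
  each curve's peak.
* **Microclimate series** are smooth diurnal cycles inside the
  plausibility ranges with out-of-range values injected per variable.

All generators are pure functions of (scenario, seed): they restore the
caller's RNG state and reproduce byte-identical output for equal seeds.

What passing these tests shows — and does not show — about real data: the
synthetic closures have no water-vapour dilution, pressure fluctuation,
chamber leakage or autocorrelated analyser drift; trait tables have no
recorder errors beyond the modelled ones; AT curves have no nonequilibrium
lag. The tests therefore certify the *processing* (formulas, decision
trees, bookkeeping, determinism), not instrument physics.

## Problem sizes used by the shipped batteries

The test-suite and acceptance batteries use 200 flux scenarios per noise
level, one labelled campaign of 3 plots × 12 rounds, 10,000 synthetic
leaf samples, and 100 labelled AT curves — sizes at which every
stochastic summary (medians, agreement rates) is stable across seeds
while the whole suite runs in well under a minute per battery.

## Known limitations

* The $C_z$ anchoring bias described above sets a floor of order
  $14\,b^2$ on relative slope recovery; a closure with $b = 0.1$
  s$^{-1}$ carries a deterministic ≈ 14% slope deviation from the
  generating parameters even at zero noise.
* The flux model assumes a single gas, constant temperature within a
  closure, and no dilution correction.
* Trait validation checks ranges only; it cannot detect internally
  consistent but wrong measurements (e.g. a mislabelled species).
* The AT screening decides keep/exclude only; it does not attempt to
  correct curves, and its $T_{opt}$ is conditional on the assumed model
  form.
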