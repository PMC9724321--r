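---
title: "Mass-balance yields, growth rates and cell morphometry for high-solids SSF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-balance yields, growth rates and cell morphometry for high-solids SSF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssfyield)
```

## The problem

In simultaneous saccharification and fermentation (SSF) of pretreated
lignocellulose, enzymes hydrolyze glucan to glucose in the same vessel where
a yeast ferments that glucose to ethanol. At high insoluble-solids loadings
(13–20 wt%) the naive yield calculation — concentration times a fixed broth
volume — is wrong, because the liquid phase is not constant: as solids
dissolve, mass moves from the insoluble to the liquid phase, and the liquid's
density changes with its sugar content. `ssfyield` implements the
mass-balance-corrected yield chain for such experiments, together with two
companion analyses that the same experiments need: exponential growth-rate
estimation from OD600 series, and prolate-spheroid cell morphometry from
microscopy axis measurements (yeast cells swell under hyperosmotic glucose
stress and shrink under combined ethanol/temperature stress, and the volume
change is the quantitative readout).

## The mass-balance model

All concentrations are carried internally in g/mL (external tables are g/L
and converted on read). Per timepoint $t$, with $C_j$ the concentration of
species $j$ and $\Delta C_j = C_j(t) - C_j(0)$:

1. **Liquid density** (g/cc) from the dissolved sugars:
   $\rho_l = 0.456\,(C_g + C_{cb} + C_x) + 0.97$.
2. **Insoluble solids fraction**: each $\Delta C_j$ is mapped back to the
   insoluble polymer mass it came from by its anhydro correction factor
   (glucose 1.11, cellobiose 1.056, xylose 1.36, glycerol 1.135, acetic acid
   1.11, ethanol 0.567 — g of product per g of polymer, water gain and CO2
   loss included), giving the solubilized mass fraction
   $D = \sum_j (\Delta C_j / f_j) / \rho_l$ and
   $S_i = (S_{i0} - D) / (1 - D)$.
3. **Liquid volume**: $V_l = M (1 - S_i) / \rho_l$, with $M$ the initial
   total charge mass.
4. **Yields**: glucose yield $(C_g V_l / 1.11)/M_g \times 100$; glucan
   conversion sums all glucan-derived products
   $(C_g/1.11 + C_{cb}/1.056 + C_{Gly}/1.135 + C_{Ac}/1.111 +
   C_{Eth}/0.567)\,V_l/M_g \times 100$; theoretical ethanol yield
   $(C_{Eth} V_l \times 0.9)/(0.51\,M_g) \times 100$, where 0.51 is the mass
   yield of ethanol from glucose and 0.9 the glucose-to-glucan back-
   conversion as printed in the source correlations.

Three bookkeeping quirks are preserved deliberately rather than silently
"fixed", because the chain is only reproducible if the constants are used as
published: acetic acid carries 1.111 in the conversion sum but 1.11 in the
solids balance; the xylose divisor is 1.36 (not the conventional xylan
anhydro factor ~1.136); and the ethanol divisor 0.567 differs in the fourth
digit from 0.51/0.9 = 0.5667, so for an ethanol-only broth the glucan
conversion and the theoretical ethanol yield agree only to ~0.06% relative
(the tests allow 0.3%). The liquid volume in the theoretical-yield formula
is taken to be the same $V_l$ as everywhere else.

Negative $\Delta C_j$ (assay scatter) pass through unclamped — clamping
would hide assay problems — but a drop larger than 0.002 g/mL attaches a
warning. If the estimator drives $S_i$ below zero the reported value is
clamped to 0 with a warning and the raw value kept in `s_i_raw`. A
solubilized fraction $D \ge 1$ is a hard error (more mass dissolved than the
system holds). The low-solids simplification "liquid density = solvent
density" is available as `water_density = TRUE`, using 0.97 g/cc — the
correlation's own zero-solute limit — so that the mode is internally
consistent with the density model rather than introducing a second constant.

**Productivity conventions.** Pure-sugar fermentations report g ethanol per
g glucose fed per hour. SSF reports g ethanol per g *glucose equivalent of
the initial glucan* per day; the glucose equivalent of glucan is defined
here as $1.11 \times M_g$, reusing the hydrolysis hydration factor, since
the denominator is not defined more precisely in the published convention.

**Arrest flag.** High-temperature, high-ethanol SSF can stop fermenting
while hydrolysis continues, so glucose accumulates under a flat ethanol
curve. `analyze_timecourse()` flags arrest when, between consecutive
samples, ethanol rises by less than 0.5 g/L while glucose rises by more than
1 g/L. The thresholds are deliberately coarse — they encode "virtually
stopped" versus "building up", not a kinetic fit — and are tunable
arguments.

## Growth-rate estimation

The growth rate $\alpha$ (h$^{-1}$) is the slope of $\ln(\mathrm{OD}_{600})$
versus time over the exponential phase. Real curves have lag and stationary
phases, so the window must be chosen. The selection contract: every window
of at least `min_points` (default 4) consecutive points is fit by least
squares on the log scale; windows with non-positive slope or $R^2$ below
`r2_min` (default 0.98) are discarded; among the survivors the window whose
slope has the largest *t-statistic* ($\hat\alpha \sqrt{S_{xx}} / \hat\sigma$)
is selected, ties going to the longer window and then the earlier start.

This criterion was chosen after measuring two simpler rules on simulated
curves (200 curves, $\alpha \in [0.1, 0.9]$ h$^{-1}$, 5% multiplicative
noise, 1-h sampling over 24 h — the same conditions the test suite uses).
Picking the maximum slope among qualifying windows is biased upward —
badly so for slow growers — because short windows whose noise happens to
align steeply can sneak past the $R^2$ filter. Picking the longest
qualifying window is biased downward, because windows that swallow a lag or
stationary boundary point can still clear $R^2 = 0.98$ when the exponential
stretch dominates the variance. The t-statistic rewards windows that are
simultaneously steep, long and clean: under the same conditions it is
essentially unbiased, with median relative error well inside the 5% bound
the test suite asserts, and on noiseless data every pure log-linear window is exact
($\hat\sigma = 0$), so the tie-break returns the full exponential phase and
the recovered slope equals the true rate to machine precision. Points with
OD $\le 0$ are excluded with a warning before fitting; fewer than
`min_points` usable points, or no qualifying window, raise the documented
errors. Replicates are fit individually and their rates averaged, rather
than averaging curves before fitting, so replicate-to-replicate variation in
lag does not smear the exponential phase.

Between-strain comparisons report the rate ratio both exactly and rounded
to two significant figures, the conventional "grew 1.7 times faster" style.

## Cell morphometry

Cells are modelled as prolate spheroids with equatorial (horizontal)
semi-axis $a$ and polar (vertical) semi-axis $b \ge a$. Measurement exports
give full axis lengths; they are halved and sorted per cell so the arccos in
the angular eccentricity $\alpha = \arccos(a/b)$ is always in domain
(sorting can be disabled for strict as-measured processing, in which case
$a > b$ is an error). Surface area is
$2\pi(a^2 + ab\,\alpha/\sin\alpha)$, with the removable singularity at
$\alpha = 0$ evaluated as its limit ($\alpha/\sin\alpha \to 1$ for
$\alpha < 10^{-8}$), which reduces to $4\pi a^2$ for spheres and is
algebraically identical to the classical closed form
$2\pi a^2 + 2\pi ab \arcsin(e)/e$ — the tests verify this to $10^{-9}$ on
random axes.

Volume defaults to $(4/3)\pi a b^2$ for comparability with analyses that
used that form, although the textbook prolate volume is $(4/3)\pi a^2 b$;
both modes are exposed (`mode = "ab2"` / `"a2b"`) and differ by the factor
$b/a$ for elongated cells, so condition-to-condition *percent changes* of
mean volume — the actual readout — are much less sensitive to the choice
than absolute volumes are. Population summaries report per-condition mean,
sample SD ($n-1$; absent for $n = 1$) and count, and percent change of mean
volume against a named reference condition.

## The synthetic-data generator

No raw HPLC, OD or ImageJ tables are published for the motivating
experiments, so the package carries a generator whose outputs have exact
known ground truth; every analysis stage is validated against it.

**SSF time courses.** The generator keeps its ledger in *glucan-equivalent*
units: first-order hydrolysis moves $dX = H(1 - e^{-k\,dt})$ g of glucan
equivalents from the remaining hydrolyzable pool $H$ into a dissolved
glucose pool; microbial uptake moves glucan equivalents from the glucose
pool into ethanol and glycerol pools at fractions $y_e$ and $y_{gly}$,
capped by a volumetric uptake capacity, until the broth ethanol
concentration reaches the arrest threshold, after which uptake stops
permanently and glucose accumulates. Masses are recovered from the pools by
the *same* anhydro factors the analyzer divides by (glucose $1.11$, ethanol
$0.567$, glycerol $1.135$), and concentrations by the same density/volume
chain ($\rho = 0.97/(1 - 0.456\,m_{sugar}/L)$ solves the density
correlation self-consistently for liquid mass $L = M(1 - S_i)$). Under this
bookkeeping the analyzer's solids estimate is algebraically exact: with all
products starting at zero, $D = A/L$ where $A$ is the glucan equivalents in
the liquid, and substituting $L = M - M_{s0} + A$ into
$(S_{i0} - D)/(1 - D)$ collapses to $(M_{s0} - A)/M$, the generator's true
solids fraction. The analyzer-vs-generator closure test (conversion
recovered to $10^{-6}$ relative at every timepoint) is therefore a strict
check of both codes' arithmetic, not a tautology of shared code — the two
sides share no functions, and the tests additionally compare the analyzer
against a straight-line oracle reimplementation to $10^{-12}$.

Two modelling simplifications follow from that design. CO2 leaving the
broth is not subtracted from the system mass, because the analyzer's volume
equation assumes constant $M$; the 0.567 ethanol factor already accounts
for the CO2 carbon. And the generator emits only glucose, glycerol and
ethanol (cellobiose, xylose and acetic acid stay at zero): these are the
dominant analytes in glucan-rich SSF broths, and it keeps the
acetic-acid factor discrepancy (1.111 vs 1.11) out of the closure path.
Noise, when requested, is multiplicative log-normal applied to the emitted
concentrations only — never to the internal ledger — so ground truth stays
exact under noisy emissions.

Defaults are fixed once as the study conditions: a 25 g charge (25 mL
working volume) at 20 wt% insoluble solids of an 88.5% glucan / 3.0% xylan /
2.3% lignin substrate (glucan 4.425 g), 15 mg enzyme protein per g glucan,
37 °C, 7 days sampled every 6 h. The kinetic constants are round values in
the physiological range for fast enzymatic hydrolysis of highly digestible
cellulose-enriched solids: $k = 0.8$/day first-order hydrolysis with 90% of
the glucan reachable, a 50 g glucose/L/day uptake capacity, a 75 g/L
ethanol arrest threshold, and a 0.95/0.05 ethanol/glycerol split of
consumed glucan equivalents (ethanol mass yield ≈ 0.49 g per g glucose,
below the 0.511 stoichiometric ceiling; the split must not exceed 1, and
any shortfall is tracked as diverted biomass/CO2 carbon in the truth
ledger). These defaults produce peak ethanol titres of ~55–79 g/L across
the 13–20 wt% loadings, final conversions near 90%, early productivities of
~0.11–0.17 g/g glucose-equivalent/day, and an ethanol-triggered arrest with
subsequent glucose build-up at the highest loading — the qualitative
phenomenology of high-solids SSF.

**What the generator does not emulate.** It is not a predictive kinetic
model of *K. marxianus* or *S. cerevisiae* physiology: no temperature
dependence beyond the arrest threshold, no enzyme deactivation or product
inhibition of hydrolysis, no cell growth coupling, no assay drift or
carry-over, and noise is independent across species and timepoints whereas
HPLC errors correlate within an injection. Passing tests therefore
demonstrate that the analysis chain is arithmetically correct and robust to
multiplicative scatter — not that it compensates for structured assay error
in real chromatograms.

**Growth curves and cell samples.** OD curves are flat at `od0` through the
lag, exponential at the true rate, capped at `od_max`, with optional
multiplicative log-normal noise. Cell samples draw both semi-axes as
independent log-normals around the target means (a noisy draw can invert
the major/minor order, as a real line-tool export can; readers canonicalize
per cell) and emit the measurement dialect.

## Numerical and interface choices

* Sampling grids, not ODE solvers: the generator uses exact first-order
  decay per step, so step size affects only uptake discretization.
* Deterministic emissions: all writers format numbers at 6 significant
  digits with fixed column order, so written reports are byte-identical
  across runs and platforms.
* Internal sanity bound: concentrations above 0.3 g/mL are rejected on
  ingest — almost always a g/L table fed in without conversion.
* Seeds are single integers; a fixed seed reproduces every generator output
  byte-for-byte.
* Problem sizes in the test suite — 1,000 random mass-balance states
  against the oracle, 1,000 random axes for the surface-area identity, 200
  simulated growth curves, 100-to-1,000-cell populations — were chosen as
  the smallest sizes at which the law-of-large-numbers assertions are
  stable.

## Known limitations

* The insoluble-solids estimator inherits the published correlations'
  constants; it is only as good as the density correlation for broths whose
  dissolved solutes are dominated by the three sugars.
* The arrest flag is a difference heuristic on consecutive samples; sparse
  sampling around the arrest time will locate it to within one interval at
  best.
* Growth-rate fitting assumes a single exponential phase; diauxic curves
  will have their steeper phase reported (by design) without any flag that a
  second phase exists.
* Morphometry treats every cell as an ideal prolate spheroid; surface
  wrinkling and collapse, which accompany severe ethanol stress, violate
  the model in the direction of underestimating true surface area.
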