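# ssfyield

Mass-balance-corrected yield analysis for high-solids simultaneous
saccharification and fermentation (SSF), with companion growth-rate
estimation and cell morphometry. Written for fermentation scientists who
run SSF of pretreated lignocellulose at 13–20 wt% insoluble solids and need
yields that account for the shrinking solids phase and the sugar-dependent
broth density, rather than concentration × a fixed volume.

## What it computes

Per timepoint of an HPLC broth time course (concentrations internally in
g/mL), the mass-balance chain is

- liquid density: ρ_l = 0.456 (C_g + C_cb + C_x) + 0.97 (g/cc)
- insoluble solids fraction: S_i = (S_i0 − D)/(1 − D), where
  D = (ΔC_g/1.11 + ΔC_cb/1.056 + ΔC_x/1.36 + ΔC_Gly/1.135 + ΔC_Ac/1.11 +
  ΔC_Eth/0.567)/ρ_l maps each concentration change back to dissolved
  polymer mass via its anhydro correction factor
- liquid volume: V_l = M (1 − S_i)/ρ_l (mL)
- glucose yield = (C_g V_l/1.11)/M_g × 100 (%)
- glucan conversion = (C_g/1.11 + C_cb/1.056 + C_Gly/1.135 + C_Ac/1.111 +
  C_Eth/0.567) V_l/M_g × 100 (%)
- theoretical ethanol yield = (C_Eth V_l × 0.9)/(0.51 M_g) × 100 (%)

plus ethanol productivities (g/g glucose fed/h for sugar fermentations;
g/g glucose equivalent of initial glucan/day for SSF, with the glucose
equivalent defined as 1.11 M_g) and a fermentation-arrest flag (ethanol
stalls while glucose accumulates). The growth module fits α (h⁻¹) as the
slope of ln(OD600) vs time over an automatically selected exponential
window. The morphometry module converts measured cell axes to
prolate-spheroid surface area 2π(a² + abα/sin α), α = arccos(a/b), and
volume (4/3)πab² (the textbook (4/3)πa²b is available as a mode), with
per-condition summaries and percent volume changes.

Because no raw broth/OD/imaging tables are published for the motivating
experiments, the package includes a synthetic-data generator with exact
stoichiometric ground truth (ledger kept in glucan equivalents using the
same anhydro factors); the analyzer provably recovers the generator's true
conversion exactly on noise-free output, and the test suite holds it to
1e−6 (plus 1e−12 against an independent oracle). See the methods vignette
(`vignettes/ssf-mass-balance.Rmd`) for the model, assumptions and design
choices.

## Worked example

```r
library(ssfyield)

# 20 wt% insoluble solids of an 88.5% glucan substrate in a 25 g charge
cfg <- ssf_config(total_mass_g = 25, glucan_mass_g = 4.425,
                  insoluble_solids_frac = 0.20)
sim <- simulate_ssf_timecourse(sim_params(config = cfg, seed = 7))
report <- analyze_timecourse(sim$samples, cfg)
report
#> SSF yield report: 29 timepoints over 168 h
#>   peak ethanol:      79.16 g/L at 84 h
#>   final yields:      glucose 8.651%, glucan conversion 89.67%, ethanol 77.01% of theoretical
#>   fermentation arrest flagged at 90 h (ethanol stalled while glucose rose)
```

The report says: ethanol peaked at 79.2 g/L 84 h in; by day 7 almost 90% of
the glucan had been solubilized but only 77% of the theoretical ethanol was
made, because uptake arrested at the 75 g/L ethanol threshold — after which
hydrolysis kept releasing glucose (the arrest flag fires at the next
sample, 90 h). The per-timepoint states carry the corrected volumes:

```r
tail(report$states[, c("time_h", "s_i", "v_liquid_mL",
                       "glucan_conversion_pct", "ethanol_yield_pct")], 3)
#>  time_h     s_i v_liquid_mL glucan_conversion_pct ethanol_yield_pct
#>     156 0.04158       24.51                 89.50             77.01
#>     162 0.04142       24.51                 89.59             77.01
#>     168 0.04129       24.51                 89.67             77.01
```

Growth rates and strain comparisons:

```r
curve <- simulate_growth_curve(alpha = 0.7938, od0 = 0.05, lag_h = 2,
                               od_max = 10, duration_h = 24,
                               noise_cv = 0.03, seed = 1)
fit_growth_rate(curve)
#> Exponential growth fit: alpha = 0.7967 h^-1 (R^2 = 0.9998, 7 points, window 3-9)

growth_rate_ratio(0.7938, 0.4759)$reported
#> [1] 1.7
```

The fitted α recovers the simulated 0.7938 h⁻¹ within 0.4% despite 3%
multiplicative noise, and the thermotolerant strain's rate is 1.7× the
reference strain's — the conventional two-significant-figure fold report.

## Analysis workflow

`analysis/` holds the numbered drivers that reproduce the package's study:

```sh
Rscript analysis/01_simulate_ssf.R    # synthetic broth courses at 13/17/20 wt% solids
Rscript analysis/02_mass_balance.R    # yields, conversions, arrest flags -> results/
Rscript analysis/03_growth_rates.R    # OD fitting and strain rate ratios
Rscript analysis/04_morphometry.R     # cell volume changes vs seed culture
```

Each writes its tables under `results/` and prints a one-paragraph
narrative of what it found.

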