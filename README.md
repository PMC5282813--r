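# vfaferm

Analytics for mixed-culture **carboxylate-platform fermentation** of
sugar-rich, saline substrates (molasses-type feeds): reaction
bioenergetics at fermentation conditions, COD-based yield and
mass-balance accounting for batch and continuously fed reactors,
acid–base speciation with conductivity/salinity classification, and a
synthetic-data generator with exact COD closure for testing the whole
pipeline at desk scale.

It is written for bioprocess engineers and environmental
biotechnologists who work with volatile fatty acid (VFA) fermentations
and need the standard calculations of that field in one tested,
scriptable place.

## What it computes

**Bioenergetics.** For any balanced reaction over the packaged
compound table (Thauer-style standard formation values; acids as
anion + H⁺, CO₂ as gas),

ΔG°′(T) = [Σᵢ νᵢ ΔGf°ᵢ]·T/T₀ + [Σᵢ νᵢ ΔHf°ᵢ]·(1 − T/T₀) + n_H⁺·R·T_c·ln 10·(−pH)

with T₀ = 298.15 K, the working temperature T (default 308.15 K) and
the proton-correction temperature T_c (default 298.15 K, where one
proton per pH unit is 5.708 kJ mol⁻¹). Four hexose fermentation routes
(ethanol, acetate+H₂ via ethanol, butyrate+H₂, homoacetogenesis) are
built in.

**COD accounting.** Theoretical oxygen demand from combustion
stoichiometry (CxHyOzNn ↦ x + y/4 − z/2 − 3n/4 mol O₂, N → NH₃) drives
every conversion: CH₄ at 64 g_COD mol⁻¹ (0.35 L per g_COD at
22.4 L mol⁻¹), H₂ at 16, VSS biomass at 1.2 g_COD g⁻¹. Reactor periods
are summarised into the field's standard quantities:

- degree of acidification DA = 100·(VFA_out − VFA_in)/(COD_in − VFA_in)
- Y_VFA = 100·(VFA_out − VFA_in)/((COD_in − VFA_in) − (COD_out − VFA_out))
- Y_CH4 = CH₄ rate / COD removal rate (L g_COD⁻¹)
- COD tracked = net VFA + CH₄ + VSS (as COD), absolute and % of fed

**Salinity.** Henderson–Hasselbalch speciation (effective pKa 4.8),
the NaCl↔conductivity anchor ladder with fresh/brackish/saline/brine
classes (brine > 47 mS cm⁻¹), and a Kohlrausch estimate of the VFA
contribution to conductivity.

**Simulation.** Serial-batch enrichments (7-day batches, sampling days
0/1/2/4/7, three transfers) and continuous packed-bed runs (HRT 10 d,
OLR 5 → 10 step) with first-order uptake routed through the pathway
stoichiometries. Every simulated interval closes its COD balance to
machine precision, and identical seeds give byte-identical output
files. `fit_pathway_weights()` recovers the generating pathway split
from a simulated series by non-negative least squares on the product/gas
signatures.

## Worked example

```r
library(vfaferm)

pathway_energy_table()[, c("pathway", "pH", "dG0prime_T")]
#>       pathway pH dG0prime_T
#> 1     ethanol  7   -239.548
#> 2     ethanol  6   -239.548
#> 3  acetate_h2  7      8.269
#> 4  acetate_h2  6     13.977
#> 5    butyrate  7   -269.646
#> 6    butyrate  6   -263.938
#> 7 homoacetate  7   -310.784
#> 8 homoacetate  6   -293.660
```

Ethanol oxidation to acetate (row 3) is endergonic under standard
biological conditions (+8.3 kJ mol⁻¹ at pH 7) and 5.7 kJ mol⁻¹ worse
per pH unit downward — it only proceeds when H₂ is kept low. The
glucose routes are strongly exergonic, homoacetogenesis most of all at
pH 7; proton-free route 1 is pH-invariant.

```r
sim <- simulate_pbbr(pbbr_preset("terrestrial", seed = 1))
summarize_period(as_reactor_period(sim))
#> Reactor period summary (window 67.0-77.0 d, HRT 10.0 d, ratio averaging, n = 11)
#>   metric                               mean         sd
#>   COD to VFAs (DA)        [%]          72.5        2.7
#>   Y_VFA                   [%]          82.3        4.8
#>   VFA productivity  [gCOD/L/d]         7.25       0.27
#>   CH4 production     [mL/L/d]         419.7       21.8
#>   CH4 as COD       [gCOD/L/d]          1.20       0.06
#>   Y_CH4          [L/gCOD rem]         0.294      0.116
#>   VSS as COD       [gCOD/L/d]          0.96       0.05
#>   COD fed          [gCOD/L/d]         10.00       0.00
#>   COD removed      [gCOD/L/d]          1.58       0.49
#>   COD tracked           [% fed]        94.1        3.1
#>   Biogas CH4 content      [%]          28.6        1.7
#>   Fed COD as CH4          [%]          12.0        0.6
```

This is the last-10-days summary of a simulated 77-day continuous run
after the OLR step to 10 g_COD L⁻¹ d⁻¹: about 72% of the fed COD is
acidified to VFAs at 7.3 g_COD L⁻¹ d⁻¹, ~12% leaves as methane, and
the tracked pools account for ~94% of the feed on the noisy
observations (exactly ~100% on the generator's ground-truth series —
the gap is sampling noise, not lost COD).

A command-line wrapper ships in `inst/cli/vfaferm.R` with subcommands
`thermo`, `balance`, `simulate`, `speciate`, `classify` and
`defaults`.

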