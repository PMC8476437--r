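# bacfilter

Carbon mass-balance analysis for biological activated carbon (BAC) filters
used in greywater post-treatment.

## The problem

A BAC filter removes residual total organic carbon (TOC) by two entangled
mechanisms: adsorption onto the granular activated carbon (GAC) and
biodegradation by the biofilm growing on it. Operators and designers need the
split — it determines how long the medium lasts, how much sorption capacity
remains in the lower bed to buffer extreme influent concentrations, and how
much biomass the filter produces (which drives pressure loss and backwash
needs). The split cannot be measured directly during operation; it has to be
inferred from long-term monitoring data by a mass balance.

`bacfilter` implements that inference for the standard monitoring setup:
1-minute flow, twice-weekly TOC grab samples at the influent, three bed
depths (7/22/37 cm) and the effluent, sparse flow-cytometric total cell
counts (TCC), an ATP inventory on the GAC and a minute-resolved backwash
record.

## The model

Loads are flow-weighted sums over the 1-minute grid, each minute paired with
the nearest-in-time concentration sample. Removed TOC is partitioned by three
exact identities:

    F_biodegraded = F_removed − F_sorption          (sorption = q_e · M_GAC)
    F_CO2         = F_biodegraded − F_assimilated
    F_assimilated = F_cells,accumulated + F_cells,washed out + F_cells,backwash

with the equilibrium loading `q_e` (mgTOC/gGAC) estimated from an integral
mass balance over the top bed segment up to the day sorption equilibrium is
reached, and cell carbon obtained via cells/gATP and gTOC/cell conversion
constants (with named scenario values for the sensitivity sweep). Long-term
performance drift is characterised per depth by ordinary least squares on

    TOC_out/TOC_in = b0 + b1·time + b2·TOC_in + b3·EBCT

(time in years, EBCT the empty bed contact time in minutes), plus per-segment
removal shares, a capacity-capped per-segment sorption/biodegradation split
and the upper-envelope slope of removal versus influent TOC (exact quantile
regression through the origin).

Because real long-term records of this kind are rarely public, the package
ships a mechanistic intermittent-flow tanks-in-series column simulator
(compiled core; linear-driving-force sorption with Langmuir equilibrium,
biomass-proportional first-order biodegradation of a labile TOC fraction,
biomass growth/detachment/backwash) whose ground truth validates the whole
estimation chain. See the methods vignette
(`vignettes/carbon-mass-balance.Rmd`) for the model, the numerics and every
open design choice.

## Worked example

```r
library(bacfilter)
report <- run_pipeline(default_config(seed = 1))
print(report)
```

```
== BAC filter carbon-fate report ==
Treated volume 297386 L; removed 1020.4 g TOC; influent load 85 gTOC/kgGAC
Estimated q_e = 24.8 mgTOC/gGAC
TOC mass balance (g):
  removed 1020 = sorbed 496.7 + biodegraded 523.7
  biodegraded 523.7 = CO2 517.1 + assimilated 6.646
  assimilated 6.646 = accumulated 0.3735 + washed out 6.212 + backwash 0.06004
  shares: sorption 49%, biodegradation 51%; of biodegraded: assimilated 1%, CO2 99%
  of assimilated: accumulated 6%, washed out 93%, backwash 1%

Per-segment removal shares (%): 55/18/14/13

Top-segment removal envelope slope: 0.68 mg removed per mg influent

Backwash: TOC 3.38 g vs cell carbon 0.060 g (ratio 56; excess attributed to
GAC fines, excluded from the balance)

Ground truth: sorption share 47% (estimate 49%)
```

Reading it: over a simulated 912-day record (~297 m³ treated), about 1 kg of
TOC was removed, roughly half by sorption and half by biodegradation. Of the
biodegraded carbon only ~1 % ended up as biomass — almost all of it washed
out continuously — and 99 % was respired to CO₂. Most removal happens in the
top 7 cm of the bed. The backwash water carries ~56× more TOC than its cells
account for, the signature of GAC fines. The last line is the end-to-end
check a simulated record makes possible: the sample-based estimate (49 %)
against the simulator's true sorption share (47 %).

The pieces are usable on their own: `load_ledger()` / `removed_load()` for
boundary loads, `estimate_qe()` + `mass_balance()` + `scenario_sweep()` for
the partition, `fit_removal_model()` / `effect_size()` for the drift model,
`segment_removal()` / `segment_sorption_split()` for the depth profile,
`backwash_loads()` / `before_after_summary()` / `pressure_loss_summary()`
for the backwash event, and `simulate_column()` / `generate_*()` for
synthetic records. A thin command-line wrapper lives at
`inst/cli/bac-report.R` (YAML config, or `--flow`/`--samples` CSV inputs,
or `--pressure` with a linear head-discharge calibration).

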