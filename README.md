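# phytoflux

Constraint-based modeling of compartmentalized plant metabolism in R:
model assembly and curation, flux balance analysis (FBA), E-Flux
transcriptome integration, and paired growth-condition comparison, with a
deterministic generator for a synthetic photosynthetic study.

## Who this is for

Plant systems biologists who want to reproduce, end to end, the
constraint-based workflow used to compare soil-grown and in-vitro
(tissue-culture) plants: build a five-compartment stoichiometric model
(cytosol `_c`, mitochondrion `_m`, plastid `_p`, peroxisome `_x`, vacuole
`_v`), curate it against thermodynamic and stoichiometric sanity checks,
contextualize it with replicate FPKM expression tables and free amino-acid
measurements, and ask how the predicted flux map shifts between growth
environments.

## The model

All analyses solve variants of the flux balance LP

```
max  c'v     subject to   S v = 0,    v_min <= v <= v_max
```

where `S` is the stoichiometric matrix, `v` the flux vector and the
objective is biomass production; biomass-component drains satisfy
`v_m = t` (drain flux proportional to growth). Parsimonious FBA (pFBA)
re-solves with the objective pinned and total absolute flux minimized, so
reported flux distributions are not solver-dependent vertices. The LP
backend is pluggable; the production backend calls HiGHS through
`scipy.optimize.linprog` in a `python` subprocess.

Around that core, the package implements the curation battery used for
plant genome-scale models:

* **energy-cycle exclusion** — closed-exchange maximization of an
  ATP/NADH/NADPH dissipation flux; any positive optimum is an impossible
  energy-generating cycle and its minimal active set is reported;
* **P/O ratio enforcement** — with a proton-explicit respiratory chain
  (protons compartmentalized to the mitochondrial membrane), LP
  maximization of ATP synthase flux per donor oxidized; the synthetic
  chain translocates 10 H+/NADH and 6 H+/succinate with a 16/3 H+/ATP
  synthase, so the ratios are exactly 1.875 and 1.125;
* **weighted-pFBA gap filling** — minimal-weight reaction additions from a
  universal pool that make a target producible, verified irreducible;
* **reduction-degree yield checks** — FBA yields bounded by the ratio of
  substrate/product degrees of reduction (C=4, H=1, O=-2, N=-3, P=5, S=6);
* **biomass molecular-weight rescaling** — coefficients scaled so the
  biomass molar mass is exactly 1 g/mmol.

E-Flux integration follows the standard recipe: per-gene activity
`log2(mean FPKM + 1)` over replicates, GPR evaluation with OR = sum and
AND = min, normalization by the condition maximum, and bounds scaled by
the normalized score, with exchange reactions reset to availability
magnitude 1. Measured free amino acids replace the 20 amino-acid biomass
coefficients (µmol/gDW → mmol/gDW) followed by re-rescaling to 1 g/mmol.

## Worked example

```r
library(phytoflux)
config <- generator_config(seed = 1)
model  <- generate_toy_plant_model(config)
model
#> <metabolic_model> toyplant
#>   203 metabolites, 207 reactions, 5 compartments
#>   biochemical: 92, biomass: 1, biomass_drain: 47, exchange: 22, transport: 45
#>   objective: Biomass_synthesis

compute_po_ratio(model, "NADH")                      #> 1.875
compute_po_ratio(model, "succinate")                 #> 1.125
biomass_molar_mass(get_biomass_composition(model))   #> 1

specs <- generate_condition_specs(model, config)
soil  <- simulate_condition(model, specs$soil)
vitro <- simulate_condition(model, specs$in_vitro)
c(soil = soil$objective_value, in_vitro = vitro$objective_value)
#>     soil in_vitro
#>  0.02367  0.02111
```

The in-vitro plant grows more slowly. Pathway totals show why: primary
carbon metabolism shrinks while nitrogen assimilation and the cyclic
electron flow share expand.

```r
ps <- summarize_pathways(attr(soil,  "model"), soil)
pv <- summarize_pathways(attr(vitro, "model"), vitro)
#> calvin soil   3.5564  in vitro   0.6385
#> tca    soil   0.1321  in vitro   0.0488
#> gs     soil   0.0105  in vitro   0.0135
#> gogat  soil   0.0075  in vitro   0.0087
#> CEF/LEF ratio: soil 0.0120, in vitro 0.0611

table(compare_fluxes(soil, vitro)$class)
#>       both    neither  soil_only vitro_only
#>        166         20         15          6
```

`compare_fluxes()` also reports `log10(|v_vitro| / |v_soil|)` per shared
reaction; `write_comparison_dot()` renders the condition-specific
reactions (bold = in-vitro-only, dotted = soil-only) as a Graphviz graph.

A command-line front end ships in `inst/cli/phytoflux`
(`phytoflux generate --out DIR --seed N` emits the full synthetic input
bundle; `phytoflux simulate` runs the paired comparison).

## Package layout

| Area | Files |
| --- | --- |
| Core types & I/O | `R/model.R`, `R/io-json.R`, `R/io-sbml.R`, `R/io-tsv.R` |
| Stoichiometry & formulas | `R/stoichiometry.R`, `R/formula.R`, `R/gpr.R` |
| Reconstruction | `R/reconstruction.R` |
| LP core | `R/lp.R`, `inst/python/solve_lp.py`, `R/fba.R` |
| Curation | `R/curation.R` |
| Expression & amino acids | `R/eflux.R` |
| Condition analysis | `R/conditions.R` |
| Synthetic study generator | `R/synthetic-model.R`, `R/synthetic-data.R` |

See `vignettes/phytoflux-methods.Rmd` for the modeling assumptions,
parameter choices and limitations.
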