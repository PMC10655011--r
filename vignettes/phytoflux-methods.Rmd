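---
title: "Methods: constraint-based comparison of soil-grown and in-vitro plant metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based comparison of soil-grown and in-vitro plant metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modeling assumptions, parameter choices and
known limitations behind `phytoflux`. It is the place where genuinely
open design questions are answered; every empirical statement made here
is one the package's test suite or acceptance script computes itself.

## 1. The constraint-based model

A `metabolic_model` is a compartmentalized stoichiometric model. All
analyses reduce to linear programs over the steady-state polytope
`{v : S v = 0, v_min <= v <= v_max}`, maximizing biomass production.
Biomass is represented as 47 drain reactions (`*_biomass`) feeding
per-component pool species consumed by a single biomass reaction, so each
drain flux equals its composition coefficient times the growth rate.

Conventions worth stating explicitly:

* **Import-positive exchanges.** Exchange reactions (`*_Cyto_tx`) carry a
  single cytosolic metabolite with coefficient +1: positive flux is
  uptake, and bounds encode availability. This makes condition presets
  read naturally ("photons up to 4.5 units") and matches the idea of an
  "input reaction". Boundary species are not rows of `S`.
* **Cytosol as transport hub.** Every transport reaction links one
  organelle to the cytosol (`*_pc`, `*_mc`, `*_xc`, `*_vc`); direct
  organelle-organelle transport is rejected at validation.
* **Flux units are arbitrary but consistent.** The literature model this
  workflow follows does not state its internal flux units; we use the
  E-Flux exchange magnitude (1) as the natural scale. Default bounds when
  a table states none are `[0, 1000]` (irreversible) and `[-1000, 1000]`
  (reversible).

### Numerical choices

* LP backend: HiGHS via `scipy.optimize.linprog` in a `python`
  subprocess with JSON I/O and batching. A pure-R simplex was rejected
  after it failed on degenerate flux polytopes; results are cross-checked
  in the tests against exhaustive vertex enumeration on small fixtures,
  which keeps the correctness argument independent of the backend.
* Feasibility/mass-balance tolerance `1e-9`; reported-flux zero threshold
  `1e-8` (used by the flux-comparison classification).
* All reported flux distributions come from **pFBA** (objective pinned at
  its FBA optimum, then total |flux| minimized). Plain FBA vertices are
  degenerate, and per-reaction condition comparisons would otherwise be
  solver-dependent. If the exact pin is numerically infeasible the pin is
  retried with a `1e-9` relative slack.
* Unbounded LPs are reported as `unbounded`, never as a large number.

## 2. Curation battery

* **Energy-generating cycles.** With every exchange closed, a dissipation
  reaction (ATP hydrolysis, or NAD(P)H oxidation) is maximized; any
  optimum above `1e-8` marks a thermodynamically impossible cycle, and
  the pFBA support localizes it. The generated model passes for ATP,
  NADH and NADPH simultaneously.
* **P/O ratios.** Donor oxidation is capped at unit flux (capping rather
  than pinning lets a blocked chain report 0 instead of infeasibility),
  diagnostic source/sink pseudo-reactions supply the donor couple and
  oxygen, and mitochondrial ATP synthase flux is maximized. On a
  proton-explicit chain the optimum equals (H+ translocated per donor) /
  (H+ per ATP); the property is asserted for randomized stoichiometries.
  The donor supply must be capped at the pinned oxidation flux —
  otherwise the LP can launder unlimited reducing power through carbon
  fixation and re-oxidation, inflating the apparent ratio.
* **Gap filling** minimizes the weighted sum of absolute candidate fluxes
  subject to a production constraint (default `min_production = 1e-3`
  flux units), with the standard |v| linearization via auxiliary
  variables. The returned set is verified irreducible by deletion;
  weights are user data (the weighting scheme of the original
  "weight-added" algorithm is not published, so pool files carry explicit
  weights).
* **Reduction degrees** use N = -3 (ammonia reference), matching plant
  nitrogen assimilation through ammonium; yield checks therefore treat
  ammonium and sulfate as electron-neutral co-substrates and close
  nitrate and photon inputs.
* **Biomass rescaling** multiplies all coefficients by one scalar so the
  molar mass is exactly 1 g/mmol; components without elemental formulas
  are rejected rather than guessed.

## 3. E-Flux and amino-acid integration

* Activity scores are `log2(mean(FPKM) + 1)` — mean first, then log.
  The alternative (log before mean) differs only in the third decimal
  for typical replicate spreads; the mean-then-log reading matches the
  transformation as usually stated.
* GPR evaluation: OR = sum (isoenzymes add capacity), AND = min (complex
  subunits limit capacity — the original E-Flux convention). Genes
  absent from the table score 0 with a warning; an empty GPR is a
  "no constraint" sentinel (`NA`), never zero.
* Normalization is over reaction-level GPR values within one condition
  (not over genes), so normalized scores lie in [0, 1] with the maximum
  attained.
* The normalized score scales the reaction's default bound
  (`ub' = s * |ub|`; reversible lower bounds symmetrically; irreversible
  reactions stay irreversible). Exchange bounds are reset to magnitude 1,
  reinterpreted under the import-positive convention as availability 1.
* Free amino-acid concentrations (µmol/gDW) replace the 20 amino-acid
  drain coefficients (divided by 1000), after which the biomass is
  re-rescaled to 1 g/mmol.

At the toy model's flux scale (exchanges of magnitude ~1, growth ~0.02)
the scaled default bounds (hundreds of flux units) bind only for
near-zero expression. The expression integration therefore shapes the
model qualitatively (silencing, availability) while the condition
physiology is carried by the exchange presets — a known property of
E-Flux when bounds are anchored to generous defaults.

## 4. The synthetic study

`generate_toy_plant_model()` builds a 207-reaction, 203-metabolite model
over five compartments: explicit PSII/PSI photon inputs, linear electron
flow to NADPH, cyclic electron flow to the thylakoid proton gradient
only, plastid and mitochondrial ATP synthases, lumped Calvin cycle,
photorespiration through the peroxisome, cytosolic glycolysis and
sucrose metabolism (with a vacuolar invertase route), full TCA cycle, a
proton-explicit respiratory chain (10/6 H+ per NADH/succinate, 16/3
H+/ATP), NR/NiR nitrate reduction, plastidic GS and NADH-GOGAT, and
lumped biosynthesis for all 47 biomass components.

Construction guarantees, all verified by tests:

* every biochemical/transport reaction is elementally balanced (a
  triangular balancing step completes lumped reactions with
  NH4/H2S/Pi/CO2/H2O/H+ bookkeeping species; core energy reactions are
  written exactly and asserted, so electron accounting cannot be papered
  over);
* redox couples differ by explicit hydrogen equivalents, so no free
  reducing power can be created;
* the boundary is attached through the generic reconstruction machinery
  and has exactly 22 exchanges and 47 drains;
* biomass molar mass is exactly 1 g/mmol after rescaling;
* P/O ratios are exactly 1.875 / 1.125 by construction of the proton
  stoichiometry.

### Stand-ins and defaults

The published model's exact 22 exchange species and 47 biomass
components are not public. The shipped boundary completes the named
species (Glc, Suc, starch, PSII/PSI photons, NO3, NH4, SO4, Pi, Ca, Fe,
Mg, K, CO2, O2, H2O) with H+, Cl, Mn, Zn, Cu, Mo — standard plant-medium
micronutrients. The 47 components are 20 amino acids, 5 nucleotide pools,
starch, sucrose, cellulose, 4 lipid classes, chlorophyll a/b, 7 cofactor
pools (NAD, NADP, CoA, ubiquinone, plastoquinone, ferredoxin,
plastocyanin) and 6 mineral ions; this list is a documented synthetic
stand-in (7 cofactors keep the total at exactly 47).

Amino-acid defaults: the soil free pool totals 100 µmol/gDW with
glutamine the largest single pool. The in-vitro table applies the
reported folds (Gln 4.92, Asn 1.92, Ser 1.21, Val 1.19, Pro 0.82) and
gives the 15 unreported acids one common fold solved at run time so the
total ratio is exactly 2.0. That common fold comes out below 1 — a
consequence of the arithmetic (the glutamine fold alone nearly exhausts
a 2x total budget), i.e. synthetic calibration, not biology.

Expression: base FPKM is log-normal (meanlog log 20, sdlog 1), replicate
noise is multiplicative mean-preserving log-normal at CV 0.2 (the
standard RNA-seq abundance model; the original study used real reads).
Condition folds per pathway tag put photosynthesis, Calvin, glycolysis
and TCA below 1 and GS/GOGAT and sucrose handling above 1.

### Condition presets

The photon influx magnitudes are not published, so the presets expose
them as configuration. The defaults were chosen once so the constructed
regime exhibits the study's qualitative physiology, and are documented
here as the emulated growth conditions:

* **soil**: photons 4.5 per photosystem, all organic carbon closed,
  CO2 availability 1 — a photon-limited autotroph that also respires
  part of its fixed carbon;
* **in vitro**: photons 1.3 (suppressed photosynthesis), sucrose up to
  0.06 (medium sugar), CO2 availability 0.10 — the poor gas exchange of
  a sealed culture vessel. Sucrose utilization carries 1 ATP per sucrose,
  lumping the plasma-membrane proton-symport cost of active import.
* nitrogen enters as an equality coupling `v_NO3 = v_NH4` (50% nitrate /
  50% ammonium) in both conditions, so total nitrogen floats with growth.

Under these defaults (and robustly to the expression seed, since the
scaled bounds are non-binding) the paired pFBA solutions reproduce the
qualitative shifts the workflow is designed to expose: lower in-vitro
growth, lower Calvin and TCA totals, higher GS and GOGAT fluxes, a higher
cyclic/linear electron-flow ratio and lower per-biomass NADPH production
in vitro. These are asserted as strict inequalities in the test suite.

### What the generator does not emulate

* The quantitative fold changes reported for the full genome-scale model
  (e.g. 42.9-fold CEF energy, -77% TCA, 4.91-fold GS) require the
  unpublished 2,887-reaction reconstruction and the real transcriptome;
  only their directions are meaningful at toy scale.
* Per-biomass proton-pump ATP does **not** come out higher in vitro in
  the toy regime: soil per-biomass synthase ATP is dominated by the
  Calvin demand (~3 ATP per CO2 at ~30 carbons per biomass unit), which
  a partly heterotrophic in-vitro preset cannot exceed. The package
  reports the accounting faithfully; the direction of that particular
  full-model observation is a documented limitation of desk-scale
  emulation.
* Organelle cofactor pools (NAD(P)(H), quinones, ferredoxin) are
  conserved moieties without dedicated organelle transporters; their
  biomass drains are fed by cytosolic synthesis.
* Photons are massless species; reactions consuming them are exempt from
  elemental balancing (and reported as skipped, not failed).
* No day/night cycling, no maintenance ATP requirement, no isoform
  multiplicity beyond the synthetic GPRs.

## 5. Reconstruction conventions

Localization evidence is consumed as a table (live database or predictor
queries are out of scope) with strict tier priority
`uniprot > related_gem > predictor`. Within one tier and gene, the first
record in file order wins and the conflict is flagged — the source
workflow states no tie rule, so determinism was chosen over cleverness.
If the winning tier names several compartments across a reaction's
genes, the reaction is duplicated per compartment (common practice for
multi-localized enzymes). Reactions without evidence stay cytosolic.
Boundary attachment refuses to run twice rather than duplicating
reactions.

## 6. Problem sizes and runtimes

The shipped analyses run on the 207-reaction toy model; pFBA doubles the
variable count with auxiliary |v| variables. Vertex-enumeration oracles
are used on fixtures of up to 8 reactions and exhaustive gap-fill search
on pools of up to 8 candidates; these sizes keep the oracles exact while
the main implementation is exercised at full model size. The full test
suite solves a few hundred LPs.
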