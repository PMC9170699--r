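# radnano

Quantitative analysis of nanoparticle radioenhancement experiments.

Nanoparticles taken up by tumour cells can amplify the effect of
radiotherapy. How much, and through which mechanism, depends strongly on
the core material and the beam: high-Z particles (Au, HfO₂, WO₃) absorb
kV X-rays far more strongly than tissue (a *physical* enhancement that
collapses at clinical MV energies), while catalytically active surfaces
(TiO₂, WO₃) boost hydroxyl-radical production under any beam (a
*chemical* enhancement), and both feed into the *in-vitro* survival
response. radnano implements the full analysis stack used to disentangle
these contributions for a panel of candidate materials, for
radiobiologists and nanomaterials researchers running comparative
radioenhancement studies.

The core quantities:

* **DEF** (dose-enhancement factor): dose in a compartment with
  nanoparticles over the same compartment with water in their place.
  Analytically, `DEF = 1 + f_Z · ⟨µen/ρ⟩_Z / ⟨µen/ρ⟩_w` for a mass
  fraction `f_Z` under a photon spectrum; microscopically, from a seeded
  simplified Monte Carlo on the standard vesicle and cell scoring
  geometries, with `χ_NP = (DEF − 1)/f_vol` the efficiency per volume
  percent.
* **DEF_ROS**: the radiation-induced DCF-fluorescence gain with
  nanoparticles over the gain without, regressed on surface-area
  concentration.
* **LQ / LD50 / DMR₅₀%**: survival `SF(D) = exp(−αD − βD²)`; the
  dose-modifying ratio is `LD50(control) / LD50(nanoparticles)`, gated by
  a 60% sham-viability cutoff with a sigmoid LC₅₀ toxicity fit.
* **NER / DoP**: the 6 Gy enhancement ratio `SF_ctrl/SF_NP` and the
  degree of DMSO protection
  `DoP = 1 − (NER_DMSO − 1)/(NER_noDMSO − 1)`, the fraction of the
  enhancement mediated by hydroxyl radicals.
* **Uptake**: ICP-MS metal mass per cell, the saturation fit
  `f(x) = A·xᵖ/(Bᵖ + xᵖ)`, and intracellular volume fractions from
  material density and metal mass fraction.

A seeded synthetic-data generator emulates the full experimental design
(48-well plates, triplicate/sextuplicate wells, dose and DMSO grids,
lognormal reader noise), so every pipeline stage is testable end to end
without measurements.

## Worked example

Generate a synthetic experiment and run the survival pipeline:

```r
library(radnano)
cfg <- generator_config(seed = 7)          # study-design defaults
res <- run_survival_pipeline(gen_survival_plate(cfg))
res$dmr
#>   material conc_ug_mL dmr50     sd viability included
#> 1     SiO2        160 0.905 0.0451     0.994     TRUE
#> 2     TiO2        160 2.552 0.1663     1.014     TRUE
#> 3      TiN         80 1.751 0.2291     0.916     TRUE
#> 4      WO3        160 1.955 0.1105     0.968     TRUE
#> 5     HfO2        320 2.566 0.0267     0.992     TRUE
#> 6       Au         40 2.053 0.1375     1.003     TRUE
```

`dmr50` is the dose-modifying ratio at 50% survival (mean ± SD over two
independent batches): TiO₂ at 160 µg/mL modifies the lethal dose by
~2.6×, the inert SiO₂ control sits at ~1, and every condition passed the
60% sham-viability inclusion cutoff. The generator's ground truths here
are the dose-scaling factors solved from the configured 6 Gy enhancement
ratios (`cfg$materials$k`), so recovery can be checked exactly.

Radical quenching decomposes the enhancement:

```r
q <- run_survival_pipeline(gen_survival_plate(cfg, design = "quench"))
subset(q$quench, dmso_M %in% c(0, 1) & material == "TiO2")
#>    material conc_ug_mL dmso_M  ner  dop
#> 6      TiO2        160      0 1.96 0.00
#> 10     TiO2        160      1 1.25 0.74
```

At 1 M DMSO, 74% of the TiO₂ enhancement is suppressed — the
hydroxyl-radical-mediated share.

Microscopic physical enhancement around a nanoparticle-filled vesicle:

```r
g <- build_vesicle_geometry(166, seed = 1)   # 32.4 vol% of 50 nm NPs
simulate_vesicle(g, "Au", load_spectrum("kv150"), 2e4, seed = 1,
                 replicates = 3)
#> <dose_score> Au / kv150, 20,000 histories, seed 1, electrons: csda
#>  compartment     def def_sd ...
#>      vesicle 29.0256 1.1464
#>     shell_01 10.6690 6.2086
#>     shell_02  5.0973 1.0332
#>     ...
#>     shell_10  1.3140 0.0101
```

Gold at kV enhances the in-vesicle dose ~29× at this packing, decaying
monotonically through the surrounding 100 nm water shells; a water
"nanoparticle" control returns DEF = 1 exactly. The same engine scores
cytoplasm and nucleus in the cell model (`build_cell_geometry()`,
`simulate_cell()`), reproducing the kV material ordering
Au > HfO₂ > WO₃ > TiO₂.

A thin CLI over the same functions lives at `inst/cli/radnano.R`
(`synth`, `mc`, `ros`, `survival`, `uptake`, `physchem` subcommands).

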