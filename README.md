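# epivertex

Vertex-model mechanics of ciliated epithelia, with macropinocytosis event
analysis.

Epithelia relieve crowding either destructively, by extruding live cells,
or reversibly, by shrinking apical surfaces — in *Xenopus* embryonic
epidermis through macropinocytosis, the engulfment of apical membrane by
large circular actin ruffles. Multiciliated cells (MCCs) sit in this
tissue as stiff, non-dividing inclusions, and macropinocytosis is biased
toward their neighbours. `epivertex` provides the computational side of
that biology for R users:

* a **vertex model** of a proliferating monolayer whose topology is encoded
  by signed incidence matrices ($BA = 0$ for closed cell loops) and whose
  mechanics follow a logarithmic force–strain law,
  $p_i = -\sigma_i \ln(A_i/A_{0,i})$ and
  $t_i = \sigma_i \Gamma \ln(L_i/L_0)$, with a per-cell stiffness
  prefactor $\sigma$ distinguishing MCCs ($\sigma = 10$) from bulk cells;
* the **growth protocol**: a 61-cell hexagonal founder grown to 400 cells,
  introduction of evenly spaced non-dividing MCCs (no two closer than
  three intermediate cells), growth to 800 cells, division arrest, and
  relaxation to equilibrium, with seeded 10-replicate ensembles;
* **stress statistics**: per-cell stress tensors, effective pressure
  (negative = compressed), cortical tension and shear, and the
  decile-enrichment comparison of MCC-adjacent versus non-adjacent cells
  with paired t-tests across replicates;
* **junction-tension inference** from geometry alone (force balance of
  unit tangents at triple junctions, least squares with mean-1
  normalisation) plus N1–N4 ring labels around an event and before/after
  tension ratios;
* **event analysis**: synchronised apical-area traces, per-event area loss
  and its correlation with ruffle size, junction shortening, event rates
  by MCC adjacency, log2 fold changes, a tissue remodeling index, and
  macropinocytosis rates around extrusions;
* **synthetic-data generators** for tessellated tissues (Poisson disc +
  Voronoi + Lloyd), known-tension equilibrium geometries (the inference
  oracle), and event/track tables with the measured statistical structure
  (ruffle duration 9.3 ± 2.3 min, peak area 94 ± 36 µm², ~10% apical loss
  scaling with event size, 10% junction shortening, compression waves).

The methods vignette (`vignettes/epivertex-methods.Rmd`) documents the
model, the sign conventions, and every numerically material design choice.

## Worked example

```r
library(epivertex)

# scaled-down protocol: 37-cell founder -> 100 cells (MCC introduction)
# -> 200 cells (division arrest) -> equilibrium
run <- run_protocol(protocol_config_ci(sigma_mcc = 10), seed = 1)
run
#> <sim_result> seed 1: 200 cells (4 MCCs, sigma=10), converged: TRUE

st  <- cell_stress_tensors(run$final)
lab <- classify_cells(run$final)
decile_fraction(st$eff_pressure, lab, tail = "lowest")
#> mcc_adjacent non_adjacent       pooled
#>    17.241379     8.108108    10.000000
```

17.2% of MCC-adjacent cells fall in the most-compressed decile of
effective pressure against 8.1% of non-adjacent bulk cells — the rosette
neighbourhood of a stiff MCC is mechanically loaded. `enrichment_report()`
runs the same comparison for compression, low tension and high shear over
a whole ensemble and attaches the paired t-tests.

```r
# junction tensions inferred from geometry alone, against generator truth
kt  <- gen_known_tension_mesh(n_cells = 50, tension_cv = 0.3, seed = 1)
sol <- infer_tensions(kt$network)
ok  <- !is.na(sol$tensions)
cor(kt$tensions[ok] / mean(kt$tensions[ok]), sol$tensions[ok])
#> [1] 1

# synthetic macropinocytosis events on a synthetic epithelium
tissue <- gen_tissue(n_cells = 120, seed = 1, mcc = TRUE)
ev     <- gen_events(tissue, event_gen_params(rate = 0.3),
                     duration = 90, seed = 2)
s <- ruffle_summary(ev$events, tissue$cells$area)
round(c(s$duration, s$peak_area, s$pct_apical), 1)
#> mean   sd mean   sd mean   sd
#>  9.4  2.6 86.9 39.7 21.7 10.1

ar <- area_reduction_and_correlation(ev$tracks, ev$events)
round(c(mean_loss = mean(ar$per_event$delta_area), r_squared = ar$r_squared), 3)
#> mean_loss r_squared
#>     0.105     0.496
```

One 90-minute synthetic recording reproduces the measured event
statistics: ruffles last ~9.4 min, cover ~22% of the host's apical
surface, each event removes ~10% of the host's apical area, and the loss
correlates with event size.

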