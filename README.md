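# capdomain

Capillary-domain analysis and tissue oxygenation modelling for skeletal
muscle.

Muscle endurance depends not just on *how many* capillaries a muscle has
but on *where* they are: the same capillary density spread evenly or
clumped produces very different tissue oxygenation. `capdomain` implements
the quantitative chain that connects a histological capillary map to
predicted function, for physiologists analysing muscle cross-sections
(e.g. the oxidative core vs glycolytic cortex of rat tibialis anterior)
and for anyone studying microvascular remodelling after exercise or
electrical stimulation:

- **Capillary domains**: the Voronoi cell of each capillary clipped to the
  sampling frame — the tissue region that capillary is closest to, used
  both as the local supply area (CDA) and as the closed "trapping region"
  of the oxygen model.
- **Supply indices**: capillary density CD (mm⁻²), capillary-to-fibre
  ratio C:F (unbiased forbidden-line fibre counting), mean fibre area CSA
  (µm²), mean CDA, and the heterogeneity index logSD = SD of ln(CDA).
- **Oxygen transport**: the steady-state Michaelis–Menten
  diffusion–consumption model *D α ∇²P = M₀ P/(P₅₀+P)*, solved per domain
  with Dirichlet conditions on the capillary lumen and no-flux domain
  boundaries, giving tissue PO₂ fields, mean PO₂ and the hypoxic fraction
  at resting or exercise consumption rates.
- **Function metrics**: the fatigue index FI = final/peak tension (each a
  five-consecutive-twitch mean) and functional hyperaemia (peak/resting
  blood flow, relative conductance).
- **Group statistics**: one-way ANOVA + Tukey HSD, volcano tables (fold
  change, Student's *t*, Benjamini–Hochberg FDR) and the strict
  <5 ppm / <30 s / >90% compound-identification filter.
- **Synthetic data**: generators for cross-sections (core/cortex presets),
  twitch trains, hyperaemia traces and log-normal metabolomes with planted
  ground truth, so the whole pipeline runs and is testable with no
  external data.

## A worked example

```r
library(capdomain)

# a synthetic glycolytic-cortex frame (0.145 mm^2, target CD 533 mm^-2)
map  <- generate_cross_section(phenotype_preset("cortex"), seed = 1)
tess <- tessellate(map)

compute_global_indices(map)
#> # A tibble: 1 × 6
#>   region n_capillaries n_fibres_counted    CF CD_per_mm2 CSA_um2
#>   <chr>          <int>            <int> <dbl>      <dbl>   <dbl>
#> 1 whole             80               51  1.57       552.   2825.

compute_local_indices(tess)$summary
#> # A tibble: 1 × 3
#>   n_domains CDA_mean_um2 logSD
#>       <int>        <dbl> <dbl>
#> 1        80        1812. 0.364

field <- solve_frame(tess, map, oxygen_params("exercise"), h = 1)
glance(field)
#> # A tibble: 1 × 7
#>   mean_PO2_mmHg min_PO2_mmHg hypoxic_fraction_pct ...
#> 1          29.8            0              0.00139

percent_change(533, 1120)
#> # A tibble: 1 × 4
#>   control treated percent_change percent_change_rounded
#> 1     533    1120           110.                    110
```

Read: this control-like cortex frame carries 80 capillaries (~552 mm⁻²,
C:F ≈ 1.6), each supplying ~1800 µm² of tissue with moderate spatial
heterogeneity (logSD 0.36). At the exercise consumption rate the model
predicts a mean tissue PO₂ of ~30 mmHg; the largest domain develops a
near-anoxic core, but only ~0.001% of tissue falls below the 1 mmHg
hypoxia threshold. `percent_change()` expresses group-mean shifts the way
they are usually quoted (533 → 1120 mm⁻² is a 110% increase).

`run_pipeline(pipeline_config(seed = 1))` runs the full demonstration —
synthetic core/cortex frames per group, tessellation, indices, oxygen
fields, core:cortex ratios, fatigue/hyperaemia metrics and a volcano
table — and writes CSV/JSON/GeoJSON outputs plus a run manifest.

`autoplot()` methods exist for maps, tessellations, PO₂ fields and
traces; `plot_volcano()` draws the metabolomics contrast.

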