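---
title: "Capillary domains, tissue oxygenation and muscle function: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capillary domains, tissue oxygenation and muscle function: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(capdomain)
```

# Overview

`capdomain` quantifies how the spatial arrangement of capillaries in a
skeletal-muscle cross-section translates into predicted tissue oxygenation
and, downstream, muscle performance. Its pipeline mirrors a standard
histology-to-model workflow:

1. **Capillary maps** — capillary coordinates (µm) inside a rectangular
   sampling frame, optionally with fibre outline polygons
   (`capillary_map()`, `read_capillary_map()`).
2. **Trapping-region tessellation** — the Voronoi cell of each capillary
   clipped to the frame (`tessellate()`): the capillary *domain*, i.e. the
   tissue closer to that capillary than to any other.
3. **Supply indices** — global (C:F, CD, CSA) and local (CDA, logSD)
   capillarity statistics (`compute_global_indices()`,
   `compute_local_indices()`), plus core:cortex normalisation
   (`core_cortex_ratio()`).
4. **Oxygen transport model** — a steady-state diffusion–consumption PDE
   solved independently on each domain (`solve_frame()`), yielding tissue
   PO~2~ fields, mean PO~2~ and the hypoxic tissue fraction.
5. **Function metrics** — fatigue index from twitch trains
   (`fatigue_index()`) and functional hyperaemia from flow traces
   (`relative_conductance()`).
6. **Group statistics** — one-way ANOVA + Tukey HSD, volcano tables
   (fold change, Student's *t*, Benjamini–Hochberg FDR) and the
   compound-identification acceptance filter (`match_compound()`).
7. **Synthetic data** — generators for every input with planted ground
   truth, so each stage is testable without any external data.

# The trapping-region tessellation

The capillary domain of site $i$ is
$V_i = \{x \in F : \|x - s_i\| \le \|x - s_j\| \;\forall j\}$, where $F$ is
the frame rectangle. Cells are computed exactly by clipping $F$ with the
perpendicular-bisector half-planes against the other sites
(Sutherland–Hodgman clipping, with a pruning rule that skips sites more
than twice the current maximum vertex distance away). Because each cell is
the intersection of half-planes with a rectangle, cells are convex, simple
polygons, and their shoelace areas sum to the frame area to machine
precision — the package tests assert a relative conservation error below
$10^{-6}$ and agreement within 0.5% with an independent brute-force
nearest-site raster at 0.25 µm resolution.

Domains touching the frame edge are flagged. By default they are retained
(which keeps the exact identity CDA$_\text{mean}$ = frame area / n = 1/CD);
`exclude_boundary_domains = TRUE` in `compute_local_indices()` drops them
to reduce edge bias, at the cost of that identity. The raster oracle breaks
nearest-site ties in favour of the lowest capillary index — an arbitrary
but deterministic rule that only affects a measure-zero set of cell
centres.

# Supply indices

* **CD** (capillaries·mm⁻²) = capillary count / frame area.
* **C:F** = capillary count / fibre count, with fibres counted by the
  unbiased Gundersen counting-frame rule: fibres crossing the left or
  bottom ("forbidden") frame edges are excluded, right/top included. The
  rule is configurable (`counting_rule = "all"`). CSA averages the whole
  polygon area of the counted fibres.
* **CDA** is the domain area (µm²); its arithmetic mean equals 1/CD when
  all domains are included.
* **logSD** = sample SD (n−1 denominator) of ln(CDA), a dimensionless
  capillary-spacing heterogeneity index, invariant to uniform spatial
  scaling and to the area unit. Natural log is used; a different base
  would rescale logSD by a constant.
* The CDA histogram defaults to 100 µm² bins from 0 to 3000 µm² with an
  open final bin.

# The oxygen model

On each domain we solve the steady-state Michaelis–Menten
diffusion–consumption equation

$$ D\,\alpha\, \nabla^2 P \;=\; \frac{M_0\, P}{P_{50} + P}, $$

with $P = P_\text{cap}$ on the capillary surface (a disc of radius
$r_\text{cap}$ at the capillary position) and zero flux across the domain
boundary — the *trapping-region* assumption that each capillary supplies
exactly its own domain. Solving domains independently (rather than a
whole-frame coupled problem) is the literal geometric-constraint model;
with a common $P_\text{cap}$ the two coincide in the symmetric case, and
per-domain solves make domain-level supply statistics well defined.

**Parameters.** The defaults are literature-magnitude values for mammalian
muscle and are all exposed in `oxygen_params()`: $D = 2400$ µm²·s⁻¹,
$\alpha = 3.89\times10^{-5}$ mL O₂·mL⁻¹·mmHg⁻¹, $P_{50} = 0.5$ mmHg,
$r_\text{cap} = 2.5$ µm, $P_\text{cap} = 40$ mmHg, and maximal consumption
$M_0 = 10^{-4}$ (rest) or $1.5\times10^{-3}$ mL O₂·mL⁻¹·s⁻¹ (simulated
heavy exercise). Tissue below 1 mmHg (configurable) counts as hypoxic.
Because these are not tied to any particular experimental preparation,
absolute PO~2~ outputs should be read as *relative* comparisons between
capillary arrangements, not as calibrated predictions.

**Numerics.** Uniform Cartesian grid (default $h = 1$ µm, required
$h \le r_\text{cap}$), 5-point Laplacian, reflective ghost cells for the
no-flux boundary on the rasterised domain edge, and a Shortley–Weller
embedded-boundary stencil at the capillary surface: a grid link that
crosses the lumen circle applies the Dirichlet value at the exact crossing
point (distance $\theta h$, $\theta$ clamped below at $10^{-6}$), with the
one-dimensional coefficients $2/(h_W(h_W+h_E))$ per axis. This keeps the
boundary-position error at $O(h^2)$; with a binary lumen-cell treatment the
effective capillary radius moves by $O(h)$ and mean PO~2~ converged
visibly slower. Validation against the Krogh–Erlang closed form (disc
geometry, zero-order limit) shows < 0.1% profile error at $h = 0.5$ µm,
and halving $h$ on a default-size synthetic frame moves mean PO~2~ by
< 0.1%.

The Michaelis–Menten nonlinearity is handled by Picard iteration with a
lagged denominator: each step solves the linear system
$(D\alpha L + \mathrm{diag}(M_0/(P_{50}+P^{(k)})))\,P^{(k+1)} = b$ by a
sparse direct factorisation (Matrix package), iterating until
$\max|\Delta P| < 10^{-6}$ mmHg (at most 500 iterations, error on
non-convergence). Negative intermediate values are clamped to zero with a
warning and counted; converged solutions with physically consistent
parameters report zero clamps, and the field obeys the maximum principle
$0 \le P \le P_\text{cap}$. Whole-frame solves partition the grid by
nearest-capillary assignment (the raster counterpart of the tessellation),
so per-domain grids tile the frame exactly and symmetric configurations
produce bitwise-identical subfields.

Summaries — mean PO~2~ (area-weighted), minimum PO~2~, hypoxic fraction —
are taken over tissue cells only; capillary-lumen cells are excluded.

# Function metrics

**Fatigue index.** FI = final tension / peak tension, each the mean of
five consecutive twitch peak amplitudes. Twitch peaks are local maxima
above 10% of the trace maximum separated by at least half the stimulation
period; at least ten peaks are required. "Peak tension" is the best
five-consecutive-twitch mean anywhere in the protocol — robust to delayed
potentiation; for monotonically fatiguing traces it is the initial five.
FI is reported both as a ratio (the form in which group values like
0.47–0.82 are usually quoted) and ×100. Raw peak amplitudes are used; no
baseline subtraction is applied because synthetic and typical recorded
traces return to a zero baseline between twitches at ≤ 10 Hz.

**Functional hyperaemia.** Conductance = flow/pressure (flow alone, with a
message, when pressure is absent), normalised by the pre-stimulation mean.
The hyperaemia ratio is max(smoothed flow during/after stimulation) /
baseline mean flow, with a centred 1-s moving average to suppress sample
noise in the peak estimate.

# Group statistics

Structural and functional indices are compared by classical one-way ANOVA
with Tukey's HSD (all pairwise contrasts, studentized-range adjusted).
Metabolite matrices are analysed per compound: log2 fold change of raw
group means, equal-variance Student's *t* (Welch available via
`var_equal = FALSE`), and Benjamini–Hochberg step-up FDR across compounds.
Compounds with a zero reference mean are flagged, not dropped. Degenerate
zero-variance compounds collapse to $p = 1$ (equal means: no evidence) or
the smallest representable double (distinct means). Significance defaults
to $\alpha = 0.05$, boundary inclusive; the relaxed FDR < 20% screen
sometimes used for heatmap inclusion is a parameter, not a constant.
Compound identifications are accepted only when mass error < 5 ppm,
retention-time difference < 30 s and isotope-pattern match > 90% — all
strict inequalities, applied jointly.

# The synthetic-data generators

The generators define the study conditions under which the package is
exercised and tested:

* **Cross-sections** (`generate_cross_section()`): fibre centres on a
  hexagonal lattice scaled so each Voronoi cell has the target mean fibre
  area, jittered with Gaussian noise (SD = `jitter` × lattice spacing,
  default 0.15 — enough to produce realistic logSD values ~0.3–0.5 while
  keeping a recognisable fibre mosaic); fibre outlines are the Voronoi
  cells of the jittered centres; capillaries sit at fibre-boundary triple
  points, Bernoulli-thinned so the expected count equals CD × frame area.
  Strongly angiogenic targets (more than two capillaries per fibre, e.g.
  a stimulated oxidative core at CD 1360 mm⁻² with C:F 2.4) exceed the
  triple-point supply; the generator then keeps every triple point and
  recruits fibre-edge midpoints as secondary interstitial sites. The two
  presets encode control compartment phenotypes: core CD 984 mm⁻²,
  cortex CD 533 mm⁻², with mean fibre areas (1870 and 2758 µm²) chosen
  for internal consistency with the quoted capillary-to-fibre ratios via
  CSA ≈ C:F/CD — order-of-magnitude choices, as per-compartment fibre-size
  distributions are only partially reported in the source literature.
* **Tension traces**: raised-cosine twitches at the protocol frequency
  (default 10 Hz for 3 min), amplitude decaying exponentially from 1 to
  the planted FI, multiplicative Gaussian amplitude noise per twitch.
* **Flow traces**: logistic rise to baseline × peak-ratio with
  mode-dependent time-to-peak (4 Hz: end of window; 10 Hz: mid-window;
  40 Hz: after the window), exponential return, constant pressure channel.
* **Metabolomes**: log-normal intensities,
  $\ln X \sim N(\ln(\text{base}\times\text{fold}) - \sigma^2/2, \sigma)$,
  the mean correction making the *arithmetic* group-mean ratio equal the
  planted fold. The preset effect table plants the headline group effects
  (e.g. kynurenic acid ×2 and glutamate ×1.5 at 10 Hz).

What the generators deliberately do **not** emulate: fibre-type-specific
capillary affinity, anisotropic fibre shapes, section artefacts
(tearing, oblique cuts), capillary counting errors, LC–MS batch effects or
missing values. Passing tests therefore demonstrate correctness of the
computational chain under idealised geometry and noise, not robustness to
every feature of real histology or spectrometry.

All generators are bit-reproducible given their seed; the pipeline derives
every stage seed from one root seed.

# Design choices and open points

* **Per-animal aggregation**: multiple sampling frames per animal should
  be averaged per animal before group statistics (the default in the demo
  pipeline); pooling frames as independent observations inflates n.
* **Edge handling**: no guard zone is applied by default, keeping area
  conservation exact and testable; boundary-domain exclusion is available
  where edge bias matters more than the conservation identity.
* **Degenerate geometry**: collinear or hull sites have unbounded Voronoi
  cells; clipping to the frame bounds them. Duplicate capillary
  coordinates are rejected at map construction (the tessellation needs
  distinct sites) rather than merged.
* **Problem sizes** used by the test-suite simulations (chosen as a
  balance of statistical resolution and runtime, and stated here as the
  package's own choice): 20 random tessellation instances of 5–60 sites
  on 150 µm subframes for the raster-oracle sweep plus one 50-site
  default-size frame; 100 seeds for capillary-density recovery; 50
  replicates × 1000 compounds for the null-calibration study; 20 matched
  map pairs for the density–oxygenation monotonicity check at h = 2 µm.
* **Known limitations**: 2-D geometry only (no axial gradients or
  intravascular transport), a single capillary PO~2~ for all capillaries
  (no flow-coupled heterogeneity), and absolute PO~2~ values that inherit
  the uncertainty of the literature-magnitude parameter defaults.

# A worked example

```{r example, eval = FALSE}
library(capdomain)

map <- generate_cross_section(phenotype_preset("cortex"), seed = 1)
tess <- tessellate(map)
glance(tess)

compute_global_indices(map)
compute_local_indices(tess)$summary

field <- solve_frame(tess, map, oxygen_params("exercise"), h = 1)
glance(field)
autoplot(field)

res <- run_pipeline(pipeline_config(seed = 1, out_dir = tempfile()))
res$ratios
```
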