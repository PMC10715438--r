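---
title: "Methods: perivascular immune niche quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perivascular immune niche quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`pvniche` quantifies the spatial immune landscape of solid tumors from
*called* single-cell data: one row per segmented cell with a centroid in
micrometers and boolean positivity for a marker panel (PanCK, CD31, CD3,
CD4, CD8, FOXP3, PD-1, PD-L1, TIM-3, LAG-3, CD163), plus per-ROI region
geometry (tumor-cell-island regions and vessel regions). Upstream steps —
segmentation, staining-round registration, intensity thresholding — are
out of scope; their outputs are this package's inputs. Coordinates follow
the image convention (origin top-left, y downward); raster pixels are
half-open `[i·s, (i+1)·s)` with centers at `(i + 0.5)·s`.

## Phenotype gating

Gating is a total, deterministic function from marker booleans to a label,
applied as an ordered rule list (first match wins): endothelial (CD31+) >
TAM (CD163+) > CD8 T (CD3+CD8+) > Treg (CD3+CD4+FOXP3+) > CD4 T
(CD3+CD4+FOXP3−) > cancer (PanCK+) > other. T-cell activation uses PD-1
and LAG-3: PD-1− naïve, PD-1+LAG-3− active, PD-1+LAG-3+ exhausted. Because
multiplex platforms report marker positivity independently, conflicts are
possible; the priority order makes their resolution explicit and the QC
summary counts them (CD4+CD8+ double positives are assigned CD8 T — the
CD8 gate does not condition on CD4; CD8+FOXP3+ cells stay CD8 T because
Tregs are defined within the CD4 lineage; LAG-3 single positives are naïve
because PD-1 negativity dominates). The rule list is data
(`default_gating()`, or YAML/JSON via `read_gating()`), so extended panels
can be re-gated without code changes.

Two partition invariants are enforced by tests: the four PD-L1±/TIM-3±
TAM subsets always sum to the TAM count, and naïve + active + exhausted
always sum to the T-cell count of each lineage.

## Compartments and the perivascular band

Each cell is assigned by its centroid (cell footprint is ignored — the
unit of quantification is the cell) to one of `TCI_PV`, `TCI_NONPV`,
`STROMA_PV`, `STROMA_NONPV`, or `VESSEL_EXCLUDED`. The perivascular band
is tissue within `pv_threshold_um` (default 50 µm, the conventional
definition of the perivascular niche) of the nearest vessel *boundary* —
the abluminal surface, not the centroid; the CD31+ wall and lumen are one
vessel region, and distance 0 is on its boundary. The tie at exactly the
threshold is PV, matching the convention "within 50 µm" vs "> 50 µm".
PV status cross-cuts region, so TCI pixels near a vessel are `TCI_PV`.
Distances are exact for circle and polygon vessels (point-to-segment
minimization); mask-backed geometry uses a Euclidean distance transform,
and the two dialects are required by tests to agree within one pixel.

Compartment areas are integrated on a raster at the stated pixel size:
each pixel is counted once by its center, so the five areas always sum to
the ROI area. The distance-transform dialect carries a discretization
error of roughly half a pixel times the band perimeter; tests verify the
single-vessel annulus area π(60² − 10²) µm² within 2% at 0.5 µm/px with
strictly decreasing error at 1.0 → 0.5 → 0.25 µm/px. The vector dialect
is exact up to pixel-center counting (relative error ~10⁻⁵ in the same
setting), below lattice noise.

## Densities and aggregation

Density is count/area (cells/mm²) per ROI × compartment × phenotype
selector. Selectors are logical expressions over the labeled table
(`"phenotype == 'TAM' & tam_tim3 & !tam_pdl1"`), so any marker-defined
subset can be quantified; density is additive over disjoint selectors.
Aggregation follows per-section cohort practice: the tumor value is the
*unweighted* mean over its ROIs, and the group value is mean ± SEM over
tumors, so every tumor contributes equally regardless of ROI count or ROI
area. A compartment with zero area yields `NA`, which is dropped from the
tumor mean (absence of the compartment, not absence of cells). A
pooled-counts/pooled-area mode (`aggregate_density_pooled()`) is provided
for sensitivity analysis. Subset proportions ("% of TAMs that are
TIM-3+") are compartment-stratified by default; tumor-wide pooling is
available through the same interface by changing the strata.

## Three-cell clusters

"Direct contact" is operationalized as centroid distance ≤ 12 µm — about
two touching leukocyte radii — since no segmentation masks are available
in the data model; the threshold is a visible parameter everywhere. A
cluster is a *mutually contacting* triple (triangle in the contact graph)
of one TAM, one CD4+ or CD8+ T cell, and one Treg; a path-connected mode
exists as an option. All unique id-triples are counted, so one cell can
participate in several; a greedy disjoint counting (most compact triple
first) is provided because either convention is defensible. The contact
graph is built with a grid spatial index whose result is identical to the
all-pairs computation (tested against it, and triangle enumeration against
the exhaustive triple scan). Cluster compartment is the compartment of the
triple centroid; the TAM's compartment is retained alongside for
reference. Composition tables report activation-state and TAM-PD-L1
fractions (each summing to 1 per stratum) and the TIM-3+:TIM-3− ratio
within PD-L1− cluster TAMs.

## Statistics

Group comparisons use the two-sided Mann-Whitney U test: exact by
enumeration when the pooled sample is ≤ 12 and tie-free, otherwise the
normal approximation with tie and continuity correction (the correction
contributes up to ~0.011 absolute difference from the exact p at n = 8+8,
which is why tests compare at 0.015). Bonferroni families are always
explicit: a contrast plan is a list of named blocks and the family size m
is the number of contrasts in the block — never a silent global
correction, because the set of planned comparisons is an analysis
decision. Significance means adjusted p ≤ 0.05. ROC analysis fixes the
orientation "higher score predicts the positive class"; an AUC < 0.5 is
reported as-is with a flag rather than silently flipped, and the p-value
against AUC = 0.5 uses the exact U-test equivalence AUC·n₁n₂ = U. A
blinded mode masks arm identities in comparison output until unblinded.

## The synthetic generator

`simulation_config()` defines a complete in-silico study emulating the
2 × 2 cohort design (untreated/NAC × disease-free/metastatic). Geometry:
non-overlapping Fourier-perturbed ellipse blobs for TCIs (total area
within ±20% of `tci_fraction`; real islands are more irregular but the
compartment logic only sees boundaries), circular vessels of configurable
radius confined to stroma (vessel size/density statistics for such cohorts
are not established; the defaults of 3–4 vessels of 8 µm radius per field
are placeholders and are flagged as such). Cells: each phenotype is an
inhomogeneous Poisson process, sampled by thinning, with intensity = base
rate (stroma vs TCI) × group effect × PV enrichment ρ inside the band and
zero inside vessels. Defaults emulate the qualitative structure of TNBC
immune landscapes: immune exclusion (stromal intensities ≫ TCI), PV
enrichment ρ = 2 for TAMs and Tregs and ρ = 3 for CD4 T cells, cancer
cells at 1500/mm² inside TCIs, a 2× stromal TAM effect in the NAC
disease-free group, ~20% PD-L1+ TAMs, and TIM-3 on 30% of TAMs rising to
55% in the NAC disease-free group. Marker co-expression is sampled
independently given the phenotype (only marginal proportions are
reported for real cohorts, so nothing more is identifiable). Seeded
clusters place TAM + T cell + Treg triples on a 3.5 µm circle (pairwise
≈ 6.1 µm) at random PV-stroma locations with a 4 µm margin inside the
band. The config seed fully determines every output, including written
study directories (byte-identical across runs).

What passing synthetic tests shows — and does not. They demonstrate that
the geometry, gating, density, cluster and statistical machinery is
correct against ground truth and closed forms. They do not validate
segmentation or positivity calling, non-Poisson spatial clustering of
real immune cells beyond the explicit seeded clusters, irregular vessel
shapes, or section-to-section heterogeneity; conclusions about real
tissue require real data through `load_cohort()`.

## Numerical and design choices

* Degenerate inputs: `tci_fraction = 0` yields an all-stroma ROI; no
  vessels yields distance `+Inf` and an everywhere-non-PV ROI; empty cell
  tables and empty strata propagate as empty tables / `NA` proportions
  with warnings, never errors.
* Blob and vessel placement is rejection sampling with a bounded attempt
  budget and a descriptive error on failure; proposals shrink under
  crowding so target fractions up to ~0.45 are reliably achievable.
* Monte-Carlo calibration (`calibrate_comparison()`) holds tissue
  geometries fixed across replicates — the calibration is conditional on
  tissue architecture, which is what makes 1000 replicates affordable —
  while cells, gating, classification and densities are resampled through
  the standard pipeline functions every replicate. Under the null the
  family-wise rejection rate of the Bonferroni-adjusted procedure measured
  0.041 (1000 replicates, n = 8/arm, family of 2); under a 2× TAM density
  effect with 10 tumors/arm, power measured 1.0 (100 replicates).
* Problem sizes in the test suite and acceptance script (400 × 400 µm
  ROIs at 2 µm/px, 4–10 tumors/group, 2–6 ROIs/tumor) are chosen so the
  full validation runs in minutes; all stage logic is size-independent and
  the defaults (600 × 600 µm at 0.5 µm/px, 20 ROIs/tumor, 9 tumors/group)
  reflect the cohort design the generator emulates.

## Known limitations

Distances are measured in the 2-D section plane; 3-D vessel geometry is
not recoverable from thin sections. Cells are points: contact detection by
centroid distance cannot distinguish touching membranes from near
neighbors. The Poisson model understates the clumpiness of real immune
infiltrates, so real-data cluster counts will exceed its chance baseline.
Bonferroni families must be declared by the analyst; the package cannot
know which comparisons constitute one hypothesis family.
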