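# pvniche

Spatial quantification of the perivascular immune niche in solid tumors
from single-cell multiplex immunofluorescence data.

In triple-negative breast cancer (TNBC) and other solid tumors, the
locations of immune cells matter as much as their numbers: tumor-associated
macrophages (TAMs), CD4+ and CD8+ T cells and regulatory T cells (Tregs)
are largely excluded from the PanCK+ tumor cell islands (TCIs) and sit in
the stroma, and distinct subsets concentrate in the *perivascular niche* —
tissue within 50 µm of the abluminal surface of a CD31+ vessel, excluding
the vessel wall and lumen. `pvniche` turns per-cell marker tables and
region geometry into compartment-resolved densities, checkpoint-regulator
subset profiles, three-cell contact clusters, and biomarker statistics. It
is written for image-analysis and immuno-oncology groups who already have
segmented, positivity-called cells and need a tested, reproducible
quantification layer.

## What it computes

Given per-ROI cell tables (centroids in µm plus boolean positivity for
PanCK, CD31, CD3, CD4, CD8, FOXP3, PD-1, PD-L1, TIM-3, LAG-3, CD163) and
ROI geometry (TCI regions and vessel regions, as polygons or labeled
masks):

1. **Phenotype gating** — priority rules over marker booleans:
   CD31+ endothelial; CD163+ TAM (with PD-L1/TIM-3 subset attributes);
   CD3+CD8+ T cell; CD3+CD4+FOXP3+ Treg; CD3+CD4+FOXP3− T cell; PanCK+
   cancer cell. T-cell activation: PD-1− naïve, PD-1+LAG-3− active,
   PD-1+LAG-3+ exhausted. Conflicting co-expression is resolved by a fixed,
   documented priority and tallied in a QC record.
2. **Compartments** — every cell is assigned to stroma/TCI × PV/non-PV by
   its centroid, with d(cell, nearest vessel boundary) ≤ 50 µm defining PV
   (the tie at exactly 50 µm is PV); cells inside vessels are excluded.
   Compartment areas are integrated on a raster at the stated pixel size.
3. **Densities** — cells/mm² per ROI × compartment × phenotype selector,
   aggregated the way cohort studies report them: ROI → unweighted tumor
   mean → group mean ± SEM over tumors.
4. **Clusters** — all mutually-contacting TAM + (CD4 or CD8) T cell + Treg
   triples (centroid distance ≤ 12 µm by default), with composition by
   T-cell activation state and TAM PD-L1/TIM-3 status.
5. **Statistics** — two-sided Mann-Whitney U (exact for small tie-free
   samples) with explicit Bonferroni families, Pearson correlation, and
   ROC/AUC (AUC = P(random positive scores above random negative); the
   AUC × n₁n₂ = U identity is tested, and AUC > 0.7 is flagged with the
   conventional "good" band).

A seeded synthetic tumor-map generator (`simulation_config()` /
`generate_cohort()`) produces whole cohorts — TCI blobs in stroma, vessels,
inhomogeneous-Poisson immune cells with configurable perivascular
enrichment and group effects, seeded contact clusters — with exact ground
truth, so every stage is testable end to end.

## Worked example

```r
library(pvniche)

cfg <- simulation_config(seed = 7, n_tumors_per_group = 4L,
                         rois_per_tumor = 4L,
                         roi_width_um = 400, roi_height_um = 400,
                         pixel_size_um = 2)
bundle <- generate_cohort(cfg)
res <- run_pipeline(bundle)

subset(res$densities$group,
       phenotype_selector == "TAM" & grepl("STROMA", compartment))
#>           group  compartment phenotype_selector n  mean    sem
#>          NAC_DF STROMA_NONPV                TAM 4 320.1 10.906
#>        NAC_Mets STROMA_NONPV                TAM 4 146.8  3.307
#>    untreated_DF STROMA_NONPV                TAM 4 162.5  7.427
#>  untreated_Mets STROMA_NONPV                TAM 4 150.7 12.395
#>          NAC_DF    STROMA_PV                TAM 4 686.7 29.171
#>        NAC_Mets    STROMA_PV                TAM 4 344.7 30.986
#>    untreated_DF    STROMA_PV                TAM 4 397.1 23.650
#>  untreated_Mets    STROMA_PV                TAM 4 413.1 25.527

res$roc$TAM
#> <roc_result> AUC = 1.0000 [good (>0.7)], p = 0.02857 (n+ = 4, n- = 4)
```

Reading the output: stromal TAM densities are roughly doubled in the
NAC disease-free group (the generator's default group effect), are about
twice as high in the perivascular band (the default enrichment factor 2),
and the whole-stroma TAM density separates the NAC disease-free from the
NAC metastatic tumors perfectly at this effect size and n (AUC 1.0; the
Mann-Whitney p reflects n = 4 + 4 tumors). `res$clusters` held 174
three-cell clusters in this run, almost all in perivascular stroma, and
`res$cluster_composition` gives their activation / PD-L1 make-up per group
and T-cell lineage.

Real studies replace `generate_cohort()` with `load_cohort()` on a study
directory (manifest CSV, per-ROI cell CSVs, geometry as polygon JSON or
labeled TIFF masks) — see `?load_cohort` and `?read_cell_table` for the
formats.

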