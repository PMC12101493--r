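# eigenlipid

Weighted correlation network analysis of depth-resolved ocean lipidomes.

Marine plankton remodel their lipids along environmental gradients:
acyl chains lengthen with temperature (homeoviscous adaptation),
non-phosphorus betaine lipids replace phospholipids where phosphate is
scarce, and the chloroplast lipids SQDG, MGDG, DGDG and PG track light and
the deep chlorophyll maximum (DCM). In a multi-region, depth-resolved
lipidomics survey these responses appear as groups of lipid species whose
intensities co-vary across samples. `eigenlipid` recovers those groups —
**eigenlipids (ELs)**, each summarised by the first principal component of
its members' profiles — and characterises their vertical structure,
biogeography, structural composition and environmental drivers. It is
aimed at environmental lipidomics / marine chemical ecology groups with a
lipid feature table (species x samples), blank runs and CTD-style sample
metadata.

## Method core

1. **Preprocess** — features with sample median < 20x the blank median are
   removed; samples are normalised to total annotated intensity and
   centred-log-ratio transformed (`clr_i = ln(x_i / g(x))`, zeros replaced
   multiplicatively).
2. **Network** — signed adjacency `a_ij = ((1 + r_ij)/2)^beta` on Pearson
   correlations of CLR values; topological overlap
   `TOM_ij = (l_ij + a_ij)/(min(k_i, k_j) + 1 - a_ij)`; average-linkage
   clustering of `1 - TOM` with an adaptive, persistence-based branch cut;
   small branches become EL0 (unassigned). Per-module eigenlipids
   (first PC over samples), Spearman membership scores, projection of
   held-out regions onto the reference loadings, and an in-group
   proportion (IGP) permutation test for reproducibility.
3. **Spatial statistics** — EL relative intensities; EL maximum depth per
   station vs the DCM (two-sided Mann-Whitney, Cliff's Delta);
   mixed-layer Longhurst-province enrichment (one-sided); chi-square
   headgroup enrichment; pigment correlations; BH-FDR per family.
   Mann-Whitney p-values are exact by enumeration for n+m <= 12 and
   Edgeworth-corrected normal beyond.
4. **Meta-clustering** — distributional, province and depth distance views
   min-max-normalised and averaged; average-linkage meta-dendrogram with
   Monte Carlo node significance and cophenetic correlation.
5. **Structure** — intensity-weighted structural profiles per EL
   (headgroups, carbons per FA, saturation, phosphorus); Gower-type
   structural dendrogram; tanglegram entanglement (in [0, 1], 0 = same
   leaf order) against the distributional dendrogram; random-intercept
   mixed model `property ~ EL + (1 | sample)` with z tests.
6. **Environment** — OLS of intensity-weighted mean chain length on in
   situ temperature; PCA with environmental loading vectors; random-forest
   attribution of temperature vs PO4 (70:30 split, importances scaled by
   held-out R^2, ICE curves); EL intensity ratios across SST by layer;
   per-class PUFA DCM-vs-mixed-layer contrasts (Welch t, Cohen's d); EPA
   (20:5) maximum depth vs the DCM.

A seeded synthetic-ocean generator (`simulate_ocean()`) plants modules,
gradients, a chain-length-temperature slope and blank contaminants with
full ground truth, and backs the test suite and the benchmark script.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script reads its predecessors' outputs from `results/`:

```sh
Rscript analysis/01_simulate.R              # synthetic cruises + lipidome
Rscript analysis/02_network.R               # preprocessing + WGCNA + IGP
Rscript analysis/03_spatial_patterns.R      # depths, provinces, pigments
Rscript analysis/04_meta_and_structure.R    # meta-clusters + tanglegram
Rscript analysis/05_environmental_drivers.R # temperature/PO4 attribution
```

A run prints, among other lines:

```
simulated 340 lipids x 270 samples over 45 stations
blank filter: 6 of 340 features removed
detected 5 modules (sizes 60, 60, 60, 60, 60), 34 lipids unassigned
in-group proportion over held-out regions: EL1=1.00 (p=0.005), ..., EL5=1.00 (p=0.005)
province enrichment: 10 module-province pairs at FDR 0.05 (EL2>CARB, ...)
tanglegram: entanglement 0.092 after untangling (raw 0.572);
  cophenetic 0.93 (distributional) / 0.86 (structural)
SFA/MUFA chain length ~ temperature: slope 0.0404 C/FA per degree
  (95% CI 0.0394..0.0413), R^2 0.99, n 101
PUFA DCM enrichment: DGDG, MGDG, PG, SQDG
EPA max depth vs DCM: median offset 0 m (signed-rank p = 1.000, 45 stations)
```

Reading: all five planted modules are recovered exactly (the six planted
contaminants fall to the blank filter first), they replicate perfectly in
the held-out regions (IGP = 1 at the permutation floor p = 1/200), the
structural dendrogram aligns closely with the distributional one
(entanglement 0.09 on the 0–1 scale), the planted chain-length response
of 0.04 carbons per fatty acid per degree C is recovered within its
confidence interval, and only the four chloroplast lipid classes show
significant PUFA enrichment at the DCM — exactly the planted signal.

`run_pipeline(default_config())` performs the same end-to-end analysis in
one call and writes a manifest for byte-identical re-runs;
`subset_run(cfg, "mixed_layer", reference = full)` reruns on a sample
subset and reports module overlap (Jaccard) against a reference run.

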