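# mlhgrn

Multi-layer hierarchical gene regulatory network inference for drought
time-course multi-omics.

## What this package does

When a plant experiences progressive drought, transcription-factor (TF)
cascades reorganise the expression of metabolic pathways — flavonoid and
lipid metabolism most visibly — and the metabolome shifts with them.
`mlhgrn` reconstructs that regulatory architecture from bulk expression
and widely-targeted metabolome data:

1. **Differential screening.** Genes are screened per timepoint
   contrast with a simplified negative-binomial Wald test
   (median-of-ratios size factors as offsets, pooled moment dispersion)
   under the rule |log2FC| ≥ 1 with BH FDR < 0.05. Metabolites are
   screened by OPLS-DA VIP > 1 combined with fold change ≥ 2 or ≤ 0.5,
   after KNN imputation of missing peak areas and removal of compounds
   with QC coefficient of variation ≥ 0.5.
2. **Temporal clustering.** Metabolite profiles (z-scored timepoint
   means) are grouped by restarted k-means++ (k = 8 by default).
3. **ML-hGRN construction (the core).** The bottom-to-up weighted
   random forest (BWERF) procedure regresses every pathway gene on all
   candidate TFs with a random forest, iteratively eliminates the least
   important TFs and re-ranks the survivors until one remains, and
   aggregates each TF's importance as its mean over the iterations it
   survived, summed across pathway genes:

   score(TF) = Σ_genes mean over survived iterations of w(TF, gene)

   A two-component Gaussian mixture fitted to these scores separates
   the regulatory layer immediately above the pathway (posterior for
   the high-mean component ≥ 0.5) from background; the selected layer
   becomes the new target set and the procedure repeats upward until
   the requested number of layers is built. Pathway genes are then
   linked to metabolites by Pearson correlation (|r| ≥ 0.8, BH FDR
   < 0.05) and the network is exported as SIF/GraphML for Cytoscape.

Because no public dataset accompanies this design, the package ships
seeded simulators that plant a known two-layer TF hierarchy, NB read
counts, and a metabolome with known fold changes, missingness, and QC
variability — every stage is validated against that planted truth.

## Worked example

```r
library(mlhgrn)

sim <- simulate_hierarchy_expression(
  n_pathway_genes = 40, n_layer1_tfs = 10, n_layer2_tfs = 8,
  n_decoys = 32, timepoints = 6, replicates = 3, noise_sd = 1, seed = 1)
sim$expr
#> expr_set: 90 features x 18 samples [log2au]
#>   timepoints: 0, 2, 4, 6, 8, 10; groups: drought

net <- build_hierarchy(sim$expr,
                       candidate_tfs = names(sim$truth$layer_assignments),
                       pathway_genes = sim$truth$pathway_genes,
                       n_layers = 2, seed = 1)
net
#> hgrn: 40 pathway genes, 2 TF layer(s)
#>   layer 1: 3 TFs
#>   layer 2: 19 TFs
#>   129 TF edges, 0 gene-metabolite edges

true_l1 <- names(which(sim$truth$layer_assignments == 1))
mean(true_l1 %in% net$layers[[1]])   # layer-1 recall for this seed
#> [1] 0.3
mean(net$layers[[1]] %in% true_l1)   # layer-1 precision for this seed
#> [1] 1
```

Layer 1 holds the TFs the mixture model places in the high-importance
component — here a conservative cut (3 TFs, all true regulators);
averaged over 10 seeds at these settings the layer-1 recall is ≈ 0.72
and precision ≈ 0.65. `write_sif(net, "net.sif")` /
`write_graphml(net, "net.graphml")` export the result for Cytoscape,
and `run_pipeline(pipeline_config(...), "out/")` drives the whole
screen → cluster → network workflow from TSV/CSV inputs with a JSON
manifest and an audit log.

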