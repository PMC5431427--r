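# spadix

Organ-resolved transcriptome co-expression analysis for bulk RNA-seq of
small factorial designs (e.g. four organs × three replicates), written for
plant scientists mining co-expression networks for candidate pathway
regulators — the motivating case being flavonoid biosynthesis genes (CHS,
CHI, F3H, DFR, LDOX, …) and their MYB/bHLH-type transcription factors in
aroid organ panels (root, leaf, spathe, spadix).

The pipeline:

1. **Normalization** — TMM scaling factors (trimmed 30% on M, 5% on A per
   tail, inverse-variance weights, geometric mean 1), FPKM on TMM-effective
   library sizes, log2-CPM, median-centered log2 FPKM.
2. **Differential expression** — one-way ANOVA F across organs on log2-CPM
   with a label-permutation null and Benjamini–Hochberg FDR; genes with
   `q < 0.05` and max pairwise |log2FC| `> 1.5` are DE.
3. **Organ atlas** — presence calls (max replicate FPKM `≥ 1` expressed,
   `= 0` absent), Venn partition over organs, organ-exclusive gene sets,
   Euclidean/complete-linkage sample and gene dendrograms (Newick export),
   qPCR-style R² concordance.
4. **Co-expression network** — signed adjacency `a = ((1+cor)/2)^β` with
   `β = 20`, topological overlap
   `TOM_ij = (L_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`, average-linkage
   module detection with a deterministic static cut
   (`(0.99 − 0.02·deepSplit)·h_max`, minModuleSize 30), SVD module
   eigengenes, eigengene merging at dissimilarity 0.2.
5. **Regulator mining** — network sparsification (top-4 edges per gene +
   global top 1%), PFAM-rule TF classification, per-pathway-gene top-10 TF
   lists, retention of TFs recurring in ≥ 2 lists.
6. **Synthetic data** — a negative-binomial multi-organ simulator
   (`var = μ + φμ²`) with planted co-expression modules (shared latent
   factors), graded organ effects, organ-exclusive genes, library-size
   variation, and planted regulator→target links, so recovery (adjusted
   Rand index, precision/recall) is measurable without downloads.

## Worked example

```r
library(spadix)
sim <- generate_dataset(simulation_config(n_genes = 1000, n_modules = 4,
  module_sizes = rep(80, 4), organ_effect = 2, n_tfs = 30, n_pathway_genes = 8,
  n_planted_links = 8, seed = 42))
norm <- normalize_study(sim$study)
round(norm$tmm_factor[1:4], 4)
#> root_1 root_2 root_3 leaf_1
#> 1.0262 1.1934 0.8722 1.2809

tab <- de_table(norm, sim$study$design, n_perm = 500, seed = 42)
length(de_call(tab))
#> [1] 381

pc <- presence_call(norm$fpkm, sim$study$design)
head(venn_partition(pc)[order(-venn_partition(pc)$count), ], 3)
#>                     region bitmask count
#> 15 root+leaf+spathe+spadix      15   880
#> 1                     root       1    30
#> 2                     leaf       2    30

de <- de_call(tab)
net <- build_network(norm$log_fpkm[de, ], network_config())
merged <- merge_modules(norm$log_fpkm[de, ],
                        detect_modules(net$diss_tom, network_config())$module_of_gene)
merged
#> module_partition: 381 genes, 6 modules (sizes 109, 90, 73, 49, 30, 30), 0 unassigned

lists <- top_tf_lists(net$tom, intersect(sim$truth$pathway_genes, net$genes),
                      intersect(sim$truth$tf_genes, net$genes))
rep <- mine_regulators(lists)
head(rep$retained_tfs, 3)
#>       tf n_lists
#> 1 g00321       8
#> 2 g00322       8
#> 3 g00323       8
round(evaluate_recovery(rep, sim$truth), 3)
#> precision    recall
#>         1         1
```

Reading the output: TMM factors hover around 1 (the simulator varies
sequencing depth ±50%); 381 genes are organ-differential (the four planted
80-gene modules carry a graded organ effect of amplitude 2 log2 units, plus
the regulatory module and the organ-exclusive genes); the Venn partition
shows most genes expressed in all four organs with small organ-exclusive
sets (30 per organ planted); module detection on the DE genes finds the
planted modules plus clusters formed by the organ-exclusive genes — which
the planted truth counts as background, so set-level ARI against truth is
deliberately conservative here; and the mining step recovers exactly the 8
planted regulator TFs, each co-expressed with all 8 pathway genes of the
regulatory module (precision = recall = 1).

Whole-pipeline-from-files (TSV in, TSV + manifest out):

```r
paths <- write_study(sim$study, "demo_data", truth = sim$truth)
run_pipeline(list(counts = paths[["counts"]], samples = paths[["samples"]],
                  genes = paths[["genes"]], out_dir = "demo_out", seed = 1))
```

or from the shell (`simulate`, `validate`, `run-all`, `evaluate`, …):

```sh
Rscript inst/scripts/pipeline.R simulate --out demo_data --n-genes 1000 --seed 1
Rscript inst/scripts/pipeline.R run-all --counts demo_data/counts.tsv \
  --samples demo_data/samples.tsv --genes demo_data/genes.tsv --out demo_out
```

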