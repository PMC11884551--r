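# mirdynet

Dynamic miRNA–TF–target network analysis for replicated treatment/mock
time-series expression data, with a single-cell pri-miRNA profiling arm.

## The problem

Plant stress hormones such as abscisic acid (ABA) trigger transcriptome
remodelling in which microRNAs and transcription factors act together in
feed-forward loops (FFLs). Understanding *when* and *in which cell types*
these regulatory circuits are active requires combining per-time-point
differential expression with the topology of a tripartite regulatory
network (TF→target **TTI**, TF→miRNA **TMI**, miRNA→target **MTI** edges)
and, at single-cell resolution, pseudobulk profiles of low-abundance
primary miRNA transcripts (pri-miRNAs).

`mirdynet` is aimed at systems-biology analysts who have (a) an
entities × samples expression table over a treatment/mock time course,
(b) a regulatory edge list, and optionally (c) a cell × gene count matrix
with cell-type and condition labels.

## What it computes

- **Temporal DE classes.** Per time point `t`,
  `log2FC = log2((mean_treat + pc) / (mean_mock + pc))` with a Welch t-test
  on log2 abundances, BH-adjusted within time points. Genes are called at
  FC ≥ 2 and q ≤ 0.05, miRNAs at FC ≥ 1.5 and raw p ≤ 0.05. Each DE
  entity's occurrence bit-vector `b ∈ {0,1}^7` maps to one of 11 classes:
  `only_t` (singleton), `robust` (≥ 6 of 7), `early` (⊆ {0.5, 1, 3} h),
  `late` (⊆ {9, 12, 24} h), else `dynamic`.
- **Dynamic network and rewiring.** A node is active in layer `t` iff DE
  at `t` (TFs configurable); an edge is active iff both endpoints are.
  The per-node rewiring score is the summed Bernoulli variance of
  incident-edge activity, `Dn(i) = Σ_{j∈N(i)} p_ij (1 − p_ij)` with
  `p_ij` the fraction of layers in which the edge is active; the
  degree-corrected variant divides by the union degree `|N(i)|`.
- **Motif census and statistics.** Induced-subgraph census of the four
  3-node shapes — FFL (X→Y, X→Z, Y→Z), fan-out, cascade, fan-in — with
  role typing (the miRNA takes the Y slot in the symmetric roles),
  enrichment z-scores against degree-preserving edge swaps performed
  within each edge class, per-instance persistence (number of layers
  present), pairwise expression coherence, crosstalk degree, and
  clustering-coefficient-by-role profiles.
- **Co-expression modules and the XYZ ratio.** WGCNA-style unsigned
  adjacency `|cor|^β`, topological-overlap dissimilarity, average-linkage
  clustering with a static cut and minimum module size 30; motif
  instances are classified as XYZ (all three members co-module) or XZ
  (X, Z co-module without Y), compared between motif classes by
  chi-square.
- **Single-cell pri-miRNA profiling.** Cell QC (500–10 000 genes,
  500–70 000 UMIs, ≤ 10 % mitochondrial and chloroplast content),
  pseudobulk per (cell type, condition) with CPM, expressed/differential
  pri-miRNA tallies versus mock, and cell-type-unique miRNA-FFL (YM-FFL)
  detection with per-group hub miRNAs.

A synthetic-data module (`sim_config()`, `simulate_timeseries()`,
`simulate_network()`, `simulate_cells()`, `simulate_crosstalk_design()`)
generates all three input kinds with planted ground truth, so every stage
is testable end to end.

## Worked example

```r
library(mirdynet)
library(dplyr)

cfg <- sim_config(seed = 1, n_tfs = 20, n_mirnas = 30, n_targets = 80,
                  n_planted_motifs = c(ffl = 12, fanout = 6, cascade = 6, fanin = 6))
net <- simulate_network(cfg)
ts  <- simulate_timeseries(cfg, nodes = net$truth$nodes)

de <- call_de(ts$expr, ts$meta, kind = "gene")
glance(de)
#>   n_entities n_de_entities n_de_calls kind
#> 1        130           130        382 gene

static <- assemble_static(net$edges)
static
#> mdn_network: 98 nodes (20 TF, 28 miRNA, 50 target), 122 edges (45 TTI, 29 TMI, 48 MTI)

dyn <- build_dynamic(static, de)
head(rank_dynamic_nodes(dn_score(dyn), k = 3), 3)
#>   entity node_type dn_raw dn_degree_corrected union_degree
#> 1 TF12   TF         0.857               0.171            5
#> 2 TF15   TF         0.857               0.171            5
#> 3 TF08   TF         0.857               0.143            6

tidy(motif_enrichment(static, n_random = 200, seed = 1))
#>   motif_type real_count null_mean null_sd     z empirical_p
#> 1 ffl                13      1.78    1.22  9.19     0.00498
#> 2 fanout            125    136.      1.27 -8.78     1
#> 3 cascade            51     62.2     1.32 -8.46     1
#> 4 fanin              45     56.2     1.22 -9.19     1
```

The DE table shows 130 simulated entities, every one DE somewhere (the
generator plants a 3-log2 effect), with 382 entity × time-point calls.
The 12 planted FFLs dominate the enrichment: 13 FFLs observed against a
null mean of 1.78 (z = 9.2), while the two-edge shapes are correspondingly
depleted — randomization breaks planted FFLs into exactly those shapes.
`census_dynamic()`, `xyz_ratio()`, `role_cc_profile()` and the single-cell
stage (`qc_filter_cells()` → `pseudobulk()` → `primirna_profile()` →
`celltype_unique_ymffls()`) continue from these objects; `run_pipeline()`
chains all stages from one config. Each result type has `tidy()`,
`glance()` and `autoplot()` methods.

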