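---
title: "Models and methods behind mirdynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirdynet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdynet)
```

This vignette explains the statistical models, the tunable parameters and
the design choices in `mirdynet`, in the spirit of a methods section: what
each stage assumes, where the defaults come from, and what the planted
synthetic data can and cannot tell you about real data.

## The data model

The bulk arm assumes an entities × samples abundance matrix over a
treatment/mock two-arm design with seven time points (0.5, 1, 3, 6, 9, 12,
24 h by default) and at least two replicates per arm per time point.
Abundances are modelled as log-normal: analysis happens on
`log2(x + pseudocount)`, with a pseudocount default of 1 on the abundance
scale so zeros give finite fold changes. The single-cell arm assumes a
sparse features × cells integer count matrix with cell-type and condition
labels attached per barcode; counts are treated as negative-binomial.

## Differential expression and temporal classes

Per time point, `call_de()` computes the fold change on the raw scale from
arm means and tests `log2(x + pc)` replicate values with a Welch t-test
(Wilcoxon available). q-values are Benjamini–Hochberg within each time
point. Two threshold rules are built in and kind-specific: genes require
fold change ≥ 2 **and** q ≤ 0.05; miRNAs require fold change ≥ 1.5 **and**
raw p ≤ 0.05, reflecting the common practice of gating small-RNA calls on
the unadjusted p-value at typical assay depths. The original analyses in
this field use count-based tools (Cuffdiff-, DESeq-style); the Welch test
on log abundances is a distribution-light equivalent chosen so the
downstream network machinery — the package's actual subject — can be
validated without re-implementing a negative-binomial GLM. A practical
consequence worth knowing: under the compound gene rule the zero-effect
flag rate is far below the nominal α, because the fold-change gate
dominates at realistic replicate noise.

The 11-class temporal vocabulary is defined entirely by the DE occurrence
bit-vector `b` over the seven time points:

* exactly one bit set → `only_<t>`;
* at least `robust_min` (default 6) bits → `robust`;
* two or more bits, all inside the early window {0.5, 1, 3} h → `early`;
* likewise inside the late window {9, 12, 24} h → `late`;
* anything else → `dynamic`.

The window memberships and the robust cutoff are parameters of
`classify_temporal()` because the literature leaves two points open —
whether 3 h still counts as "early", and whether "robust" demands all
seven time points. The defaults above (3 h early; robust at ≥ 6) were
fixed once, before any validation was run, to make the classifier total,
deterministic, and order-independent; every DE entity receives exactly one
label. Early responders (DE at 0.5 or 1 h) are further grouped by breadth:
group 1 responds only in those first two points, group 3 at ≥ `k_robust`
(default 5) points overall, group 2 in between.

## Dynamic network and the rewiring score

The static network is a simple directed tripartite graph whose edge
classes imply node types (TMI targets and MTI regulators are miRNAs; TTI
and TMI regulators are TFs; a node that is both a TF and a target stays a
TF). Layer activity is driven by DE: a miRNA or target is active at `t`
iff DE at `t`; an edge is active iff both endpoints are. TFs default to
`always_active` because curated TF sets typically come from binding data
rather than DE filtering; `de_only` and an abundance-threshold `expressed`
mode (default FPKM-like cutoff 1) are provided since the retention rule
for TFs is genuinely open. Nodes never active anywhere are dropped — that
retained set is the "final" dynamic network.

The rewiring (Dn) score treats each union-neighbourhood edge as a
Bernoulli variable over layers: `dn_raw(i) = Σ_j p_ij (1 − p_ij)` where
`p_ij` is the fraction of layers in which an edge joins `i` and `j`
(direction ignored — rewiring concerns neighbourhood change, not
orientation). The raw score is additive in degree, so it deliberately
favours hubs; `dn_degree_corrected` divides by the union degree for a
size-free view. `dn_raw` is zero iff the incident edge set is identical in
every layer, is invariant to layer order, and is maximised when every
incident edge is active in exactly half the layers.

## Motif census, enrichment and motif statistics

The census counts the four connected 3-node shapes under
**induced-subgraph** semantics: a triple is classified by its complete
induced edge set, so a 3-edge triple is an FFL only — never simultaneously
one of its 2-edge sub-shapes — and triples containing mutual edges match
none of the four shapes. Under the adjacency-bitmask ID convention the
shapes are FFL (id 38), fan-out (id 6), cascade (id 12) and fan-in
(id 36). Roles: FFL X regulates both others, Y is the intermediate, Z the
common sink; in fan-out (targets) and fan-in (regulators) the symmetric
pair puts a miRNA in the Y slot when exactly one candidate is a miRNA,
falling back to lexicographic order — a deterministic tie-break, stated
here because it affects role-conditioned statistics. For the cascade the
trend-carrying node is taken to be the TMI/MTI-constrained middle
position. The implementation classifies all 64 directed patterns of an
ordered triple through a precomputed lookup; an exhaustive `O(n^3)`
triple-enumeration oracle in the test suite pins down its correctness, and
exact counting is guarded by a 2000-node limit (no sampling estimator is
provided).

Enrichment compares the real census to null networks generated by
degree-preserving double-edge swaps performed *within each edge class*, so
in/out degrees, node types and the tripartite structure are all conserved
(10 × |E| attempted swaps per class per null). The null ensemble is
counted with the C-level Davis–Leinhardt triad census for speed; a unit
test asserts it agrees with the instance-level census. Reported are
`z = (real − mean)/sd` (flagged degenerate when the null is constant) and
the empirical p-value `(1 + #{null ≥ real})/(n_random + 1)`.

Instance statistics on the dynamic network: **persistence** is the number
of layers in which the full motif edge set is present under induced
semantics; **coherence** checks, per instance, that the Pearson
correlation of per-time-point treatment log2FC profiles matches the
expected regulatory sign on every edge (activation/positive for TTI and
TMI, repression/negative for MTI; sign-only by default, with an optional
`|r| ≥ r_min` gate) — the one non-edge pair is reported alongside without
an expectation; **crosstalk** is the number of other FFLs sharing at least
one node (a shared-node, not shared-edge, relation); and the
**clustering-coefficient profile** averages each role node's local
undirected CC over the layers where the instance occurs (a `union` mode
computes CC once on the full graph instead, since per-layer versus union
computation is a genuinely open choice), then averages within (motif type,
role, persistence class) cells, with miRNA-only Y rows reported separately
for fan-out and fan-in.

## Co-expression modules and the XYZ ratio

`build_modules()` follows the weighted-co-expression recipe at desk scale:
unsigned adjacency `|cor|^β` over per-condition mean log2 profiles,
topological-overlap dissimilarity, average-linkage clustering, a static
tree cut, and a minimum module size of 30; undersized clusters and
constant-profile entities are unassigned. `choose_beta()` picks the
smallest candidate exponent whose connectivity distribution reaches a
scale-free regression fit of R² ≥ 0.8 (argmax otherwise). Two deliberate
simplifications relative to the full WGCNA stack: the network is unsigned
(no signed-hybrid option), and the dynamic tree cut is replaced by a
static cut. The static cut is placed at a fraction of the maximum merge
height (default 0.98) rather than at a quantile of the dissimilarity
distribution: with topological-overlap dissimilarities the between-module
merges concentrate just below the tree top while within-module structure
merges far lower, so a near-top height fraction separates planted blocks
regardless of how many modules there are, whereas a dissimilarity-quantile
cut moves with the (unknown) within/between pair ratio and fragments
modules when blocks are few. Module–trait relevance is scored as the
correlation of each module eigen-profile (first principal component of
scaled member profiles, oriented along the mean profile) with the
treatment-arm indicator, BH-adjusted across modules.

The XYZ statistic classifies each motif instance into three disjoint
forms: `XYZ` (all members one module), `XZ` (X and Z co-module, Y
elsewhere or unassigned — disjointness is an interpretation choice that
makes the two forms a partition), or `neither`. Ratios are reported per
(motif type, layer) and aggregated per type; classes are compared by 2×2
chi-square on XYZ counts with Yates correction when an expected cell drops
below 5.

## Single-cell pri-miRNA profiling

QC removes cells outside 500–10 000 expressed genes, 500–70 000 UMIs, or
above 10 % mitochondrial or chloroplast content (all configurable;
organellar genes are recognised by `ATMG`/`ATCG` prefixes or explicit
sets), and optionally drops an excluded gene list such as
protoplasting-sensitive genes. Pseudobulk sums counts per (cell type,
condition) and converts to CPM (no length normalisation — 3'-counted UMIs
make CPM the appropriate "TPM"); groups under 10 cells are flagged
low-confidence but computed. A pri-miRNA is *expressed* in a group when
CPM > 0 and *differential* in a treatment group when
`|log2((cpm + 1)/(cpm_mock + 1))| ≥ 1` with the larger CPM ≥ 1 — a
fold-change-only rule, appropriate for a single-library-per-group design
with no replicate-based test. Cell-type-unique YM-FFLs: a group's node
activity is differential-vs-mock for treatment groups and expressed for
mock groups (a pure `expressed` mode exists, as the activity definition is
open); an FFL with a miRNA Y is active in a group when all three members
are, unique when active in exactly one group, and each group's hub miRNA
is the miRNA in the most active YM-FFLs (lexicographic ties). Both the
45-group (mock included) and 36-group (treatment-only) universes are
supported.

## The synthetic-data generators

`simulate_timeseries()` draws per-entity log2 baselines uniformly from
[5, 10], adds the planted class effect (default 3 log2 units, random sign)
at exactly the class's prescribed time points in the treatment arm, and
adds replicate noise (default SD 0.1 log2). The planted class→time-point
map mirrors the classifier's own rules (singletons at their point, early =
{0.5, 1, 3}, late = {9, 12, 24}, robust = all seven, dynamic = {0.5, 6,
24} — a pattern spanning both windows without qualifying for either), so
label recovery is well defined. Co-expression structure enters through
archetypes: each entity carries one of `n_archetypes` (default 6) temporal
shapes, mutually orthogonalised so distinct archetypes are uncorrelated by
construction, added to *both* arms with amplitude 2 so fold changes are
untouched. `simulate_network()` plants motifs on disjoint node triples
while pools last (then distinct random triples), adds background edges
uniformly within each edge class, and couples a planted motif's three
members to one shared archetype with a per-type probability (defaults 0.8
for FFL, 0.6 for cascade, 0 for the two-edge shapes — the miRNA-mediated
shapes are the co-expressed ones). `simulate_cells()` draws NB counts
(dispersion 0.5) with log-normal gene means, low-abundance pri-miRNAs
(mean 0.1 counts/cell), organellar genes for QC covariates, multiplicative
planted responses, and a planted fraction of cells with inflated
mitochondrial load.

`simulate_crosstalk_design()` is a deterministic construction for the
persistence/crosstalk question: persistence class `p` consists of `p` FFLs
sharing one miRNA Y whose TF and target neighbourhoods are fully
co-regulated (so X- and Z-role clustering coefficients are saturated at 1
in every class), while `7 − p` dangling miRNA targets dilute Y's
neighbourhood in low-persistence classes; all class-`p`
members are active in the first `p` layers. The closed forms are exact:
Y's CC in class `p` is `C(2p,2)/C(p+7,2)` (strictly increasing, 1/28 → 1)
and crosstalk is `p² − 1`, so the design realises "persistence grows with
Y-node crosstalk" while holding X and Z flat.

## Validation scenarios and problem sizes

The test suite and `scripts/acceptance.R` run the full method on planted
data at sizes chosen to keep the whole suite near a minute while leaving
the statistics well powered: 700 entities across all 11 classes for label
recovery; 50 zero-effect simulations of 150 entities for null
calibration; 20 planted-FFL networks (~110 nodes) at 200 nulls each for
enrichment power, and class-preserving randomizations of structured
inputs for calibration (mean |z| pooled over motif types and inputs);
two 40-entity blocks for module recovery; 100-cell groups over 3 cell
types × 3 conditions for pri-miRNA recovery.

Two scenario choices deserve explanation. The XYZ coupling-recovery
experiment uses 150 planted FFLs and 150 fan-ins with no planted DE
effect. The instance count matters because coupling is Bernoulli per
motif: at 50 instances the planted ratio itself has binomial SD 0.057, so
no implementation could sit within ±0.07 of the coupling probability in
90 % of runs; 150 instances bring the sampling SD to 0.033. The DE effect
is zeroed because planted class effects are shared across entities of the
same class and therefore add co-expression structure of their own,
merging archetype modules and inflating the chance co-module rate — the
experiment is meant to isolate archetype coupling.

What passing these tests shows — and what it does not. The planted
generators validate the algorithmic pipeline: exact census semantics,
score formulas, threshold rules, recovery under known effect sizes. They
do not emulate count overdispersion in bulk data, correlated replicate
structure, batch effects, doublets, ambient RNA, or cell-type annotation
error; conclusions about real tissues still depend on the upstream
quantification and annotation pipelines that produce this package's
inputs.

## Degenerate inputs and numerical conventions

Constant profiles are excluded before correlation and flagged in
coherence; pairs with fewer than three entities report `NA` correlation
rather than 0; a null-swap ensemble with zero variance flags the z-score
degenerate instead of dividing by zero; nodes of degree < 2 have CC 0 by
convention; empty edge lists build empty networks without error; QC that
removes every cell, all-constant expression, and single-layer Dn scoring
are hard errors. Empirical p-values are never exactly zero
(`≥ 1/(n_random + 1)`). All randomness flows from explicit seeds; every
generator is byte-reproducible given its config.
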