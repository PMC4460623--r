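---
title: "Network-based key driver discovery from matched tumor/normal multi-omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based key driver discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsdriver)
```

# Overview

`omicsdriver` implements an integrative pipeline that turns a matched
tumor/normal cohort — gene expression, promoter DNA methylation, miRNA
expression and somatic variants — into ranked sets of candidate *key
drivers*: the minimal sets of genes and miRNAs that regulate
(topologically dominate) the dysregulated networks, plus somatic
variants in suspicious genomic proximity to dysregulated features. This
vignette documents the model and its assumptions, every tunable
parameter that matters, the synthetic-data generator that serves as the
test surface, the numerical choices, and the design decisions taken
where the design was genuinely open.

# The model, stage by stage

## Pre-processing

Probe-level matrices are collapsed to genes by averaging all probes of a
gene within each sample, after removing probes with any missing value or
with no/ambiguous gene annotation. Methylation probes are restricted to
*promoter CpGs*: sites within the closed interval ±2 kb around a
transcription start site (a CpG in two overlapping promoters is assigned
to both genes and flagged; after collapsing, such ambiguous probes are
dropped like any multi-gene probe). All coordinates are 0-based
half-open internally; BED is native, VCF/MAF positions are shifted on
ingestion. Samples are restricted to those present in every molecular
layer; because somatic calls exist only for tumors, the variant table
constrains the tumor group only.

## Differential analysis (2-of-3 vote)

Three methods are computed per feature on each layer (expression,
promoter methylation, miRNA expression):

* **SAM statistic** `d = (mean_t − mean_n)/(s + s0)`, `s` the pooled
  standard error and `s0` a fudge factor stabilizing low-variance
  features. Significance is a label-permutation FDR: at each observed
  `|d|` cutoff, the q-value is the median permuted exceedance count over
  the observed count.
* **Moderated t**: per-feature variances are shrunk toward a prior
  fitted by method of moments on `log s²` under a scaled-F model
  (Newton inversion of the trigamma function); `t̃` has `d0 + d` degrees
  of freedom and is BH-adjusted across features. The implementation is
  self-contained and agrees with `limma::eBayes` to numerical precision
  (checked in the tests).
* **AUC-ROC** in rank-sum form with ties counted one half.

A feature is differential iff **at least two** of the three methods flag
it. The vote — not any single threshold — is the decision rule; the
per-method cutoffs are conventional and configurable (see parameters).

## Co-expression modules

On the differential genes: unsigned adjacency `a_ij = |cor_ij|^β`, the
topological overlap `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`
with `l_ij = Σ_u a_iu a_uj`, average-linkage hierarchical clustering of
`1 − TOM`, and a *static* cut. Clusters below the minimum size are
labelled 0 ("grey"). Static cutting was chosen over dynamic tree cutting
because it is simpler, deterministic, and directly testable; the cut
height is a parameter. Modules exceeding the Bayesian-learning cap are
not searched; instead their link set is tightened to the top within-
module TOM quantile, mirroring the practice of handling the largest
modules by a stricter co-expression threshold.

## Directed structure: priors and Bayesian consensus

Genes listed in at least one user-supplied TF table are marked TFs.
Within each module, undirected links (TF, g) backed by a curated
regulation TF→g become directed *seed* edges; a PWM promoter scan adds
motif seed edges. Per module, expression is discretized into `r = 3`
equal-frequency bins (deterministic tie handling by stable value order),
candidate parents are the top-`k` partners by mutual information (seed
parents always included), and greedy hill climbing maximizes the BDe
score with moves *add edge, remove edge, reverse edge, swap parent*,
under acyclicity and a max-parent cap. The search runs three times —
runs differ only in the tie-breaking order among equal-score moves,
since no other randomization source is defined — and a directed edge is
kept iff it appears in at least two runs (confidence ≥ 2/3). The final
mixed network contains the seed edges, the consensus edges whose
endpoint pair is also a co-expression link, and the remaining links as
undirected edges, each with provenance.

The PWM scan replaces an external motif-statistics tool with a standard
log2-odds scan whose p-values are **exact**: per-column scores are
discretized (bin 0.05) and the null score distribution under the
background base frequencies is obtained by dynamic-programming
convolution, verified against exhaustive enumeration over all `4^L`
sequences in the tests. Hits are deduplicated to one edge per (TF,
gene); both strands are scanned and the best-hit score is strand
invariant.

## Methylation pruning

For every gene present in both matrices, the Pearson correlation `r`
between expression and promoter methylation is computed across matched
samples. A gene is *silenced* iff it is (a) down-regulated by the vote
and (b) `r < −0.65` strictly. All directed edges into silenced genes are
removed — their downregulation is attributed to promoter methylation
rather than TF binding. "Anti-correlation above 0.65" is read as
`r < −0.65` (not `|r| > 0.65`) because the stated mechanism is
methylation-driven *down*regulation. Undirected links are pruned only
when one endpoint is silenced and the other is a TF (the link is then a
putative regulation of the silenced gene); this rule is configurable and
can be disabled, since the original treatment of undirected links is
ambiguous. Pruning is idempotent.

## miRNA–mRNA network

For each differential miRNA, its annotated targets (within the universe
of measured genes that carry at least one annotation) are tested for
over-representation of differential genes by a one-sided hypergeometric
test; regulators with `p < 0.05` contribute edges to their differential
targets. Symmetrically, TFs that are themselves differential genes are
tested against the miRNA universe of the TF→miRNA table. The filter is
applied **per regulator** (a hypergeometric test needs a set-level
overlap; a per-pair reading admits no such test). Both edge sets are
merged with provenance-preserving deduplication; nodes are typed
gene/miRNA.

## Key drivers: exact minimum dominating set

A node dominates itself and its out-neighbors; undirected edges
dominate both ways. The key drivers of a network are a minimum
dominating set: minimize `Σ_v x_v` subject to
`x_v + Σ_{u ∈ in(v)} x_u ≥ 1`. Because no ILP solver is available in
the supported environment, the solver is an exact branch-and-bound over
the equivalent set-cover formulation: greedy incumbent, lower bound
`⌈uncovered/max-gain⌉`, branching on the element with fewest covering
sets. It returns a proved optimum or raises an error (a clearly labelled
greedy approximation exists behind a flag). A brute-force enumerator
(≤ 20 nodes, all optima) is the independent oracle; the acceptance suite
checks exact agreement on 200 random digraphs. Ties between optimal
sets are resolved arbitrarily (one optimum is returned), matching the
single-set reports of driver analyses; the enumerator exposes the
degeneracy on small instances.

## Somatic-variant proximity

Two analyses: (a) all variants against dysregulated miRNA loci with a
±250 kb window; (b) C→A/C→G/C→T variants against differentially
methylated CpG sites with a ±3 kb window (the CpG-island length scale).
Distance to an interval feature is the distance to its nearest base
(0 inside). The genotype filter applies to the reference allele as
printed (C only); reverse-strand expansion is available behind a flag
but off by default. Significance: each permutation redraws the same
number of variant positions per chromosome, uniformly; all `n_perm + 1`
distance sets (observed + permuted; per-feature distance to the nearest
variant) are pooled and jointly ranked, each set's statistic is its
rank-sum, and `p = (1 + b)/(1 + n_perm)` with `b` the count of permuted
sets at least as close. This exceedance scheme is exchangeable and hence
exactly uniform under the null — a property the tests verify by a
Kolmogorov–Smirnov check over 200 null replicates. A per-iteration
two-sample Wilcoxon p-value series is also returned so alternative
aggregations can be computed. The per-variant *exclusivity* check flags
variants whose window contains only dysregulated features.

## Enrichment and druggability

Driver sets are tested against user-supplied term annotations by the
upper-tail hypergeometric test; a term is reported iff at least two
study genes are annotated to it and `p < 0.05` (raw p by default — the
reference procedure applies no correction — with an optional BH flag;
"at least two genes" is read as two *study-set* genes). Druggability is
a union lookup across drug–target tables with per-source indicator
columns and an overall druggable fraction.

# Parameters

| Parameter | Default | Units / meaning | Why |
|---|---|---|---|
| `beta` | 6 | soft-threshold power | common unsigned-network default |
| `cut_height` | 0.9 | static cut on 1 − TOM | see numerical choices |
| `min_module_size` | 25 | genes | smallest meaningful module (reference module range starts at 26) |
| `tighten_cap` / `tighten_quantile` | 150 / 0.9 | genes / TOM quantile | Bayesian-search complexity cap |
| `sam_q`, `modt_p` | 0.05 | q/p cutoffs | conventional levels; the vote is the mechanism |
| `auc_hi` / `auc_lo` | 0.8 / 0.2 | AUC flags | strong-separation convention |
| `sam_n_perm` | 100 | label permutations | FDR resolution vs cost |
| `s0` | median of `s` | SAM fudge factor | robust default; CV-minimizing percentile optional |
| `discretize_r` | 3 | bins | low/medium/high expression |
| `ess` | 1.0 | BDe equivalent sample size | weak uniform prior |
| `max_parents` | 4 | per node | desk-scale regulatory in-degree |
| `k_candidates` | 5 | MI candidates | sparse-candidate restriction |
| `n_runs` / `min_support` | 3 / 2 | consensus | confidence ≥ 2/3 rule |
| `prune_threshold` | 0.65 | anti-correlation | stated pruning threshold |
| `mirna_p`, `ora_p` | 0.05 | hypergeometric cutoffs | stated levels |
| `mirna_window_bp` | 250000 | bp (half-width) | stated miRNA window |
| `cpg_window_bp` | 3000 | bp (half-width) | CpG-island length bound |
| `n_perm` | 1000 | position permutations | stated count; p floor 1/1001 |
| `promoter_half_window` | 2000 | bp | ±2 kb promoter definition |

# The synthetic cohort

`generate_cohort()` emulates a TCGA-like breast-cancer cohort at desk
scale: 20 tumor + 20 normal samples (the reference cohort is 131 + 20;
a 131 + 20 configuration is exercised in the tests), 600 genes, 120
miRNAs, three 5-Mb chromosomes. Planted truth:

* **Modules**: 4 modules × 40 genes, each driven by a known DAG in which
  3 hub TFs feed every other gene (so the hubs form a planted dominating
  set, verified by an independent checker before emission). Expression
  follows the DAG (child = weighted parent sum + Gaussian noise,
  SD 0.4), standardized per gene, plus measurement noise (SD 0.2).
* **Differential genes**: all module genes plus 40 singletons, tumor
  shift ±2 log2 units. A module gene's direction follows the sign of its
  loading on the module factor, so the group shift *reinforces*
  within-module correlation; with β = 6, the shift-induced cross-module
  correlation (≈ 0.5) is suppressed to adjacency ≈ 0.016 versus ≈ 0.5
  within modules, keeping module recovery well-posed. Background genes
  are i.i.d. Gaussian.
* **Methylation**: logit-normal beta values (logit mean −1.5, SD 0.5),
  two CpG probes per gene inside its ±2 kb promoter. 20 silenced genes
  (a subset of the down-regulated) get methylation equal to a monotone
  transform of minus their standardized expression plus noise (SD 0.2),
  giving Pearson `r < −0.65` in ≥ 95% of seeds (Monte-Carlo checked);
  30 additional differentially methylated genes are planted with a 2:1
  up:down ratio, matching the reported dominance of up-methylated
  proximity cases.
* **Variants**: 60 background variants uniform per chromosome, cycling
  through the tumor samples; 10 variants planted within 25 kb
  (window/10) of differential miRNA loci and 12 C→A/G/T variants within
  300 bp of differentially methylated CpGs.
* **Tables**: curated priors are a 60% sample of the true hub edges;
  every miRNA carries background targets and differential miRNAs carry
  10 differential + 4 background targets; hub TFs regulate 5 + 1
  miRNAs with background regulators widening the universe; drug–target
  and term tables follow the planted modules.

A single master seed drives everything through deterministically derived
sub-seeds; identical seeds give byte-identical fixtures.

**What the generator does not emulate** — and hence what a green test
does *not* establish: linkage disequilibrium, copy-number variation,
batch effects, realistic methylation spatial autocorrelation beyond the
shared gene signal, mutational signatures, or database incompleteness/
bias of real prior tables. Green tests establish that the algorithms
recover *planted* structure of the stated effect sizes, not that the
biology of a real cohort would be recovered.

# Numerical choices

* **Static cut height 0.9**: with realistic planted blocks
  (within-block correlation ≈ 0.9, β = 6), within-module TOM is ≈ 0.5,
  i.e. dissimilarity ≈ 0.5, while between-module dissimilarity is
  ≈ 0.97. A cut at 0.9 separates these cleanly; a cut at 0.25 would
  isolate every gene (no block of imperfectly correlated genes reaches
  TOM > 0.75). The value is configurable.
* **Promoter window closed on both ends**; the boundary CpG at exactly
  ±2000 bp is kept, 2001 bp is dropped.
* **Discretization ties** are broken by stable value order, making
  repeated runs identical.
* **Hill-climbing ties** among equal-score moves (tolerance 1e-9) are
  the only randomized choice, driven by the run seed.
* **Permutation p floor**: `(1 + b)/(1 + n_perm)`, so 1000 permutations
  can report at best p ≈ 0.000999, consistent with a zero-exceedance
  reading of a reported p = 0.001.
* **Degenerate inputs**: constant genes get zero adjacency (warning),
  are excluded from correlation pruning (warning), and collapse to one
  discretization bin (warning); empty intersections and zero-variance
  layers are hard errors.

# Known limitations

* The Bayesian search is greedy hill climbing with a fixed candidate
  set; it finds local optima and only skeleton-level recovery is
  guaranteed by the tests (consensus skeleton F1 ≥ 0.6 on an 8-node
  benchmark). Iterative sparse-candidate refinement is available but
  off by default.
* The branch-and-bound MDS solver is exponential in the worst case; it
  is exact and fast on module-scale networks (hundreds of nodes with
  realistic density) but carries an explicit search budget and errors
  rather than silently approximating.
* Driver/passenger classification of variants and functional-effect
  prediction are out of scope; external scores are carried through as
  annotation columns only.
* The three-run consensus randomizes only tie order; with strongly
  informative data all runs may coincide, making the consensus
  confidence uninformative (always 3/3).
* Methylation enters only as promoter-mean beta values; gene-body
  methylation and CpG-resolution effects are not modelled.
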