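---
title: "Methods: ceRNA network assembly from RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network assembly from RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

`cernet` implements a circRNA-centred competing-endogenous-RNA (ceRNA)
analysis as a reusable pipeline. The biological setting is an
overexpression experiment on the circular isoform of the lncRNA ANRIL
(CDKN2B-AS, chr9p21): if a circRNA sponges miRNAs, raising its level
should derepress — i.e. upregulate — the mRNA targets shared with those
miRNAs. The pipeline takes a raw count table and exported prediction
tables and produces a differential-expression table, enrichment
records, a topologically ranked protein–protein interaction (PPI)
graph, and a tripartite circRNA–miRNA–mRNA network with degree-ranked
hub genes. This vignette documents the models, the tunable parameters,
the synthetic-data generator, and the numerical and design choices.

## Differential expression

### Normalization

Between-sample scaling uses the trimmed mean of M-values (TMM). For
sample *k* against a reference *r* (the column whose
upper-quartile-to-library-size ratio is closest to the across-sample
mean), each gene with positive counts in both samples contributes a log
ratio $M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}$ and abundance
$A_g = \tfrac12 \log_2\!\big(\tfrac{y_{gk}}{N_k}\cdot\tfrac{y_{gr}}{N_r}\big)$.
Both tails of the M distribution (30% per tail) and of the A
distribution (5% per tail) are trimmed; the surviving M-values are
averaged with inverse delta-method (approximately binomial) variance
weights, and factors are rescaled to geometric mean 1. Genes with a
zero in either sample are excluded from the trimmed mean. The test
suite verifies the factors against an independent implementation
(edgeR's `calcNormFactors`) to 1e-8 on random matrices.

log2 CPM is $\log_2\big((y + p)\,/\,(\hat N/10^6)\big)$ with effective
library $\hat N = N \times f_{TMM}$ and pseudo-count $p = 0.5$ by
default.

### Exact negative-binomial test

Counts are modelled as NB with variance $\mu + \phi\mu^2$. A single
common dispersion $\phi$ is estimated by maximizing the conditional
(qCML-style) log-likelihood, summed over genes and groups, on
library-equalized pseudo-counts; the search is a bounded 1-D
optimization on $\log\phi$ over $[10^{-6}, 5]$. Zero-variance data
collapse to the lower bound by construction.

Library equalization scales every sample to the geometric mean of the
effective library sizes and rounds to the nearest integer. This is
simpler than quantile-to-quantile matching; with library sizes within
±20% of each other (the generator's default range) the distortion is
negligible, and the null calibration check below measures the residual
effect directly.

Given equalized libraries, the group sums are NB: a sum of $n$ iid
NB($\mu,\phi$) variables is NB($n\mu, \phi/n$). Conditioning on the
total $s = A + B$ gives a discrete distribution over splits; the
two-sided p-value is the total probability of all splits at most as
probable as the observed one (with a $1+10^{-8}$ relative tolerance for
floating-point ties). At $\phi = 0$ this reduces to the exact binomial
split test. The implementation enumerates the full conditional support
$0..s$; tests verify it against (i) a convolution-built conditional
distribution that never uses the aggregation identity, (ii) the closed
binomial form at $\phi = 0$, and (iii) edgeR's `exactTest` under equal
libraries (agreement to ~1e-15).

Genes are classified `up`/`down`/`ns` at BH FDR < `deg_fdr_max` (0.05)
and |log2FC| > `deg_abs_logfc_min` (1), both from
`pipeline_config()`. logFC is the log2 ratio of TMM-adjusted group-mean
CPM with prior 0.5; positive means higher in the overexpression group.
A low-count filter (CPM > 1 in ≥ 2 samples) is applied by default and
is configurable; it is a pragmatic default, not a claim about any
particular dataset's filtering rule.

If both group sums are zero the test returns p = 1 (no evidence).

### Sample QC

Pearson correlations and PCA are computed on log2 CPM; PCA is the SVD
of the sample-centred matrix, and `pc_variance` are squared singular
values over their total (they sum to 1 and are non-increasing).

## Enrichment

Over-representation uses the hypergeometric upper tail at the observed
hit count $k$, or in EASE mode at $k-1$ (so a single-hit set gets
p = 1) — the conservative DAVID-style variant, which is the default
because the thresholds it is paired with (P < 0.05, fold
enrichment > 5) come from DAVID-based practice. "Enrichment score" is
interpreted as per-term fold enrichment $(k/n)/(K/N)$; cluster-level
scores are out of scope. The universe defaults to the analyzed-gene
background (all genes surviving the low-count filter). Up- and
down-regulated DEGs are tested separately in `run_pipeline()`. Sets are
intersected with the universe before testing; a query gene outside the
universe is an error, not a silent drop.

## PPI topology

Edges come from a STRING-style export. Two score dialects are
supported — fractions in [0,1] and integers in [0,1000]; any value
above 1 switches the file to the integer dialect (divided by 1000), and
the detected dialect is logged. The cut-off (`ppi_score_min`, default
0.9, STRING's "highest confidence") is inclusive. Edges are undirected
and deduplicated; self-loops are dropped.

Centralities are computed without weights: exact degree, unnormalized
Brandes betweenness (sum over unordered pairs, endpoints excluded), and
a component-size-adjusted closeness
$\frac{m}{\sum d}\cdot\frac{m}{|V|-1}$, where $m$ is the number of
vertices reachable from the node. The adjustment keeps closeness
comparable across components of a disconnected graph; a
`closeness_compat` flag switches to plain within-component $1/\sum d$.
Published per-node closeness values from other toolchains are not
generally reproducible without the identical edge set and formula
convention, so the supported contract is the *ranking*, not the raw
closeness value; betweenness is reported unnormalized because that is
the scale on which such rankings are usually printed.

Core proteins are nodes ranked in the top *k* (default 20) for all
three metrics simultaneously. Ties at the k-th boundary value are
resolved deterministically by node name and logged when triggered.

## ceRNA assembly

- circRNA–miRNA pairs are kept at percentile ≥ `percentile_min`
  (default 90). The boundary is inclusive because "within the Nth
  percentile" is ambiguous; the choice is documented and tested.
- miRNA targets survive only if reported by **all six** prediction
  sources (strict intersection, per miRNA).
- Concordance: a consensus target is kept only if it is an upregulated
  DEG *and* a node of the PPI graph — the sponge-direction argument
  (an upregulated circRNA should derepress, not repress, shared
  targets).
- `assemble_cerna()` keeps miRNAs present in both pair sets, applies
  the expression filter (FDR < 1%, |log2FC| > 2, P < 0.01) to mRNA
  nodes, and drops isolated nodes. The filter is applied to mRNA nodes
  only: the design has no miRNA expression data, so miRNA-level
  filtering would be vacuous; if a miRNA DEG table exists the same
  thresholds can be applied upstream to the miRNA list.
- An empty post-filter network is an explicit empty-network result with
  a warning, never a silent success or a crash.
- Hub genes are mRNA nodes ranked by degree (ties by name);
  "crucial" miRNAs are ranked by target-site count (mRNA-side degree).
  Any further biological curation of the ranked list is deliberately
  manual and out of scope.

## The synthetic-data generator

`simulate_counts()` draws gene abundances from a log-normal
(sdlog 1.2), library sizes uniform on 0.8–1.2 million reads, and counts
from NB($\mu, \phi$) with the edgeR variance convention. A
`de_fraction` of genes gets the treatment-group mean multiplied by
$2^{\pm \text{de\_log2fc}}$ (half up, half down). Defaults — 2000
genes, 3 samples per group, 5% DE at |log2FC| = 2, $\phi = 0.1$ —
are a desk-scale version of a 3-vs-3 overexpression experiment: the
gene count is scaled down from a whole-transcriptome ~20k so the exact
test's full-support enumeration stays fast, while per-gene depth
(~hundreds of reads) matches practice.

`simulate_ppi()` plants hubs by wiring them past both 3× the median
background degree and the maximum background degree plus the hub count,
so planted hubs *deterministically* occupy the top degree ranks.
Edge scores land in [0.9, 1] with probability `frac_pass`.

`simulate_predictions()` plants a top miRNA (largest target fan-out)
and hub genes targeted by five planted miRNAs that all pair with
circRNAs above the percentile cut-off. True (miRNA, target) pairs enter
each of the six sources independently with probability `db_agreement`;
decoys enter a random subset of **at most five** sources
(Binomial(5, `db_agreement`/2)), so at `db_agreement = 1` the six-way
consensus equals the planted truth exactly, and at 0 it is empty.

`simulate_study()` chains the three: the PPI is built over the true DE
genes, and the planted hub genes are three well-expressed (above-median
abundance) upregulated genes. The integrated scenario uses
`de_log2fc = 3` rather than 2: the ceRNA node filter demands observed
|log2FC| > 2, and at a true effect of exactly 2 the sampling noise of a
3-vs-3 design (sd ≈ 0.4 in log2) would drop roughly half the planted
hubs for reasons unrelated to the pipeline's correctness. The margin of
five planted miRNA partners per hub gene similarly keeps background
genes (typical degree ≤ 3–4 under the default rates) from overtaking
planted hubs except with negligible probability.

What the generator does **not** emulate: gene–gene correlation,
GC/length biases, outlier samples, batch effects, tagwise dispersion,
or realistic miRNA seed-match structure. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under
the stated model, not robustness to every artefact of real RNA-seq.

## Verification strategy

- **Oracle equivalence**: the exact test against a convolution-built
  conditional distribution (totals ≤ 50) and against edgeR;
  hypergeometric p against full draw enumeration (N ≤ 12); betweenness
  against brute-force shortest-path enumeration on 100 random graphs of
  ≤ 8 nodes.
- **Parameter recovery**: over 20 simulated studies at the default
  conditions the DE stage reaches sensitivity ≥ 0.8 with observed
  FDR ≤ 0.10; on null data $P(p \le \alpha)$ stays within twice the
  Monte-Carlo error of $\alpha$.
- **Planted-truth recovery**: at `db_agreement = 1` the consensus
  equals the truth exactly, planted hub genes sit in the top degree
  stratum, and the planted top miRNA leads the target-site ranking.
- **Monotonicity**: tightening any threshold (DEG FDR or logFC,
  enrichment p, PPI score, percentile, node filter) never enlarges the
  corresponding result set.

`scripts/acceptance.R` recomputes these quantities from scratch for any
`--seed`. One published-count check (pair/node tallies from the
original study's supplementary tables) requires files this repository
does not ship; the corresponding test documents the expected layout
under `inst/extdata/supplementary/` and fails cleanly when the files
are absent.

## Known limitations

- Classic common-dispersion exact test only; no tagwise or trended
  dispersion, no GLM route.
- Library equalization by scaling + rounding (not quantile matching);
  adequate for balanced designs with similar depths.
- Flat gene-set collections (no GO DAG propagation); identifiers are
  opaque case-sensitive strings with no symbol/ID conversion.
- Prediction tables are consumed, not computed: no sequence-based
  miRNA site prediction.
- Closeness raw values depend on formula conventions across tools;
  only the ranking is contractually stable.
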