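---
title: "Methods: prioritizing genetic modifiers from a two-subject multi-omics comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing genetic modifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ModifierNet)
```

## Scope and rationale

ModifierNet addresses a deliberately extreme study design: two subjects,
typically siblings, carrying the same primary disease lesion but showing
opposite phenotypes. Nothing in this design supports population
statistics; what it does support is *convergent evidence* — a gene is a
plausible modifier candidate if several independent data layers point at
it simultaneously: it carries a variant with meaningful predicted impact,
its expression differs between the subjects, it is annotated to the
disease phenotype, and it sits in a connected neighbourhood of other such
genes rather than in isolation. Every stage of the package computes one of
those layers; the integration stage demands their conjunction.

## The variant filter cascade

Variant records are (variant allele, gene) annotation pairs carrying
population allele frequency (gnomAD-style, a fraction in [0, 1] or absent),
PHRED-scaled CADD deleteriousness, pLI constraint, and zygosity derived
from the VCF genotype (two ALT copies = homozygous). The cascade:

* **QC** removes records with missing chromosome or gene symbol, ALT
  alleles longer than 25 bp (a sequencing-artifact heuristic; a 25 bp ALT
  is retained — the rule excludes strictly longer alleles), and
  non-protein-coding biotypes.
* **Rarity** keeps AF strictly below 0.01 *or absent*: absence from the
  reference population is itself evidence of rarity, so the missing-AF
  branch passes. The strict/inclusive pairing (AF < 0.01 but CADD ≥ 30)
  follows the conventional reading of those operators.
* **High impact** keeps CADD ≥ 30 (top 0.1 % of possible variants) for
  highly deleterious screening, or ≥ 15 (top ~3.2 %, the median for
  canonical splice-site and missense variants) at the integration stage.
* **Constraint prioritization** keeps genes with pLI ≥ 0.9. A missing pLI
  fails this filter but no other: pLI is a prioritization criterion, not a
  QC criterion, and missingness carries no evidence of intolerance.

Filters are idempotent, commute with each other, and report per-reason
removal counts that always reconcile (input = output + removed) — all
asserted as properties in the test suite.

At the integration stage the allele-frequency filter is deliberately *not*
re-applied: common polymorphisms can act as modifiers (e.g., a homozygous
burden of common missense variants), so the CADD ≥ 15 overlay operates on
all QC-passed variants.

## Networks

The interactome is consumed as PSI-MITAB 2.5/2.7 with both interactors
restricted to one taxon (default 9606). Gene symbols resolve from the
alias columns — `uniprotkb:SYMBOL(gene name)` first, `display_short`
second — and unresolvable interactors are dropped with a count.

A subject PPI network is the induced subgraph of the interactome on the
subject's variant genes. The conceptual recipe "take first-degree
neighbours, then remove non-input interactors, self-loops and duplicate
edges" is mathematically identical to the induced subgraph, which is what
the implementation computes; the equivalence is asserted in the tests
rather than assumed. Isolated input genes stay in the network as
singletons, because the component decomposition itself is a result:
networks are decomposed into the giant component (largest; ties broken by
the lexicographically smallest member for determinism), secondary clusters
(size ≥ 4), triads, pairs and singletons. Decomposition always runs on the
undirected skeleton, including for the directed FI network — weak
connectivity is what the pair/triad/singleton bookkeeping describes.

The **FI network** starts from the induced subgraph of a directed
functional-interaction database on the high-confidence DEGs and adds
*linker genes*: non-DEG genes adjacent (in either direction) to at least
two DEGs lying in different connected components of the current network,
added greedily in descending order of DEG-neighbour count until no
candidate merges components further. Pathway tools that provide this
"connect disconnected input genes" behaviour do not document a canonical
algorithm, so this greedy rule is the package's own documented heuristic;
consequences: absolute node/edge counts of FI networks are
heuristic-dependent and are never used as fixed expectations. Hub
reporting ranks nodes by edge count (in + out) with a lexicographic
tie-break.

Network intersection takes the node intersection and the edges of a
designated source network (the FI network in the integration workflow,
since its edges carry the expression-level functional structure);
annotation collisions resolve in favour of the first network.

## Differential expression

**Univariate.** Counts are normalized by median-of-ratios size factors
(geometric-mean reference over genes with all-positive counts). Gene-wise
NB dispersions come from the pooled within-group variance of normalized
counts with the shot-noise term removed,
α̂ = max((v − μ·mean(1/s))/μ², 10⁻⁸), and are shrunk on the log scale
toward a parametric trend α(μ) = a₀ + a₁/μ fitted by a Gamma GLM across
genes. The shrinkage weight is `prior_df / (prior_df + residual df)` with
`prior_df = 50` by default: at a 3 + 3 design the residual df is 4, so
gene-wise moment estimates are nearly information-free and the trend
should dominate — the same strong-moderation regime that empirical-Bayes
RNA-seq methods converge to at this sample size, and the regime in which
the test's null behaviour matches its nominal level (checked by a
calibration test on the generator's null). The Wald statistic divides the
log2 ratio of group means (pseudo-count of half a normalized count per
group guards zero means; identical groups yield exactly zero) by its
delta-method standard error, √(ξ/(J₁μ₁) + α/J₁ + ξ/(J₂μ₂) + α/J₂)/ln 2,
and is referred to the standard normal. BH adjustment and a padj < 0.05
direction call follow; no fold-change cutoff is applied. Deliberate
simplifications relative to full GLM machinery: no outlier replacement, no
independent filtering, no fold-change shrinkage — the package validates by
calibration and recovery on synthetic truth, not by bit-equality with any
reference implementation.

**Multivariate.** sPLS-DA encodes the two classes as a centered ±1
response and extracts components maximizing predictor-response covariance
on centered, unit-scaled log2 CPM (constant genes dropped); sparsity
hard-thresholds each loading vector to its largest-magnitude entries
before renormalization, and the predictor matrix is deflated between
components. RFE refits a dense one-component model each iteration
(the "iteratively applied" reading), ranks genes by |first-component
loading| with a lexicographic tie-break, drops the bottom 20 % per
iteration, and truncates the final step to exactly
`floor(retain_fraction × initial count)` — so a 16,403-gene matrix at 10 %
retention yields exactly 1640 genes regardless of the data. The 20 % step
is a schedule choice (only the 10 % endpoint is prescribed); the exact
final truncation makes the endpoint schedule-independent. No
cross-validation tunes the component count or sparsity: with three
replicates per class CV folds are degenerate, so the model is fixed at one
component with dense ranking.

The high-confidence DEG list is the exact set intersection of the
univariate calls and the RFE survivors, with directions carried from the
univariate table.

## Enrichment

ORA uses the upper-tail hypergeometric probability against a supplied
reference universe (no genome is built in; the universe is an input), BH
adjusted per database collection. Redundancy reduction is a greedy
weighted set cover: repeatedly take the term maximizing newly covered
genes divided by weight 1/(−log₁₀ fdr + ε), ε = 10⁻³⁰⁰ guarding fdr = 1;
ties break by fdr then name. Preranked GSEA uses the weighted KS running
sum (weight exponent 1; 0 recovers the classical statistic) with a
gene-label permutation null — sample permutation is impossible at 3 + 3 —
sign-matched p-values, NES = ES / mean |null ES of matching sign|, and BH
across terms.

## Phenotype integration and the shortlist

A phenotype term-to-gene table (genes_to_phenotype dialect) defines a
virtual gene panel — the union of genes over the queried terms. The panel
induces a disease-phenotype network on the interactome; its giant
component is intersected with the FI network; per-subject variants are
overlaid (topology untouched); nodes with any CADD ≥ 15 variant for the
given subject form the subject-specific subnetwork, which is decomposed as
above. Candidates are the giant-component genes, each with evidence flags:
`rare`, `high_cadd`, `homozygous_burden` (at least one homozygous
qualifying variant — the flag marks dosage-relevant genotypes),
`differentially_expressed`, `phenotype_panel_member`,
`giant_component_member`. Three flags are required by construction (high
CADD, panel membership, giant-component membership); the others are
reported evidence. Sorting: flag count, then maximum CADD, then gene.

## The synthetic study

The generators are first-class, tested code, not fixtures. They emulate:

* **Variant tables**: a shared variant body plus subject-unique variants;
  background AF ~ Beta(0.2, 5) with 10 % missing (exercising the
  missing-AF branch of the rare filter), background CADD ~ Uniform(0, 25),
  background zygosity Bernoulli(0.1) homozygous. Planted modifiers are
  subject-1-only, AF < 0.01 or missing, CADD ~ Uniform(30, 50), forced
  homozygous — mirroring a homozygous-burden narrative. The clean CADD
  separation (background capped at 25) is intentional for recovery
  testing; boundary behaviour is tested with explicit fixtures instead.
* **Counts**: NB draws with mean L·p·2^(±log2FC/2) — the effect split
  symmetrically across groups so the expected ratio is exactly 2^log2FC —
  log-normal library sizes with σ = 0.2 (making median-of-ratios
  normalization nontrivial) and log-normal baseline abundances.
* **Networks**: a preferential-attachment backbone densified inside
  pathway-like modules (Erdős–Rényi within-module edges). The module
  structure matters: real functional-interaction databases are locally
  dense around pathways, and the integration stage's CADD-filtered
  subnetworks only retain a connected giant component because of that
  local density. A plain scale-free graph would leave the filtered nodes
  near-isolated, which real pathway databases are not.
* **Phenotype panel**: terms annotate disease-module genes, with the
  planted modifiers guaranteed membership.

`simulateStudy()` ties the layers together: 2,000 genes in 40 modules of
50, the first six modules disease-related, five modifiers planted in
module 1, 7.5 % of genes DE at |log2FC| = 2 and dispersion 0.05 (60 %
of them drawn from disease modules), 4,000 shared + 1,000 unique variants
per subject, and a 12-term panel over the disease modules. The DE fraction
is sized so the planted DE set fits within the 10 % RFE retention budget
with headroom — mirroring the situation where the multivariate selection
is slightly larger than the univariate one. Every generator is fully
deterministic in its seed, and the emitted files round-trip through the
package's readers (asserted in tests).

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: linkage structure between variants,
pedigree transmission, annotation errors and multi-gene overlap of real
VEP output, expression outliers and batch effects, the heavy-tailed
set-size distribution of real pathway databases, and ontology structure
(term ancestry) in the phenotype annotations.

## Numerical and design choices

* Thresholds live in one `runConfig` object: AF 0.01, CADD 30/15, pLI
  0.9, CPM 0.5 in ≥ 2 samples, α 0.05, retention 0.10 — each configurable,
  defaults as above.
* The low-expression rule is read as *retain* genes with CPM ≥ 0.5 in at
  least two samples; the complementary literal reading (remove genes below
  the threshold in two replicates) would discard nearly everything.
* Missing CADD counts as zero in the impact filter; missing AF passes the
  rare filter; missing pLI fails prioritization. Each choice follows the
  meaning of the missingness (unknown impact, unobserved allele, unknown
  constraint).
* Dispersion estimates are clamped to [10⁻⁸, 10]; the trend fit falls
  back to the median moment estimate if the Gamma GLM fails.
* Greedy tie-breaks are lexicographic everywhere (hub ranking, RFE
  ranking, set cover after fdr) so that every pipeline stage is
  deterministic; the only seeded randomness is the GSEA permutation null.
* Degenerate inputs fail loudly before any output is written: missing
  files, one-replicate groups, all-zero matrices, unknown phenotype terms,
  empty universes.
* Problem sizes in the test and acceptance runs: 5,000-gene nulls for
  calibration, a 16,403 × 6 matrix for the RFE endpoint, 2,000-gene
  studies over 20 seeds for end-to-end recovery, and 100-instance
  randomized batches for the oracle-equivalence checks — sizes at which
  the statistical properties under test are stable.

## Known limitations

* A 1-vs-1 comparison confounds subject identity with every other
  biological difference; the package mitigates, but cannot remove, this by
  demanding convergence across layers. Candidates are hypotheses for
  functional follow-up, not associations.
* The NB test's normal-reference Wald p-values lean on the dispersion
  trend; with very few genes (where the trend cannot be fitted) the
  fallback constant-dispersion behaviour is cruder.
* The linker heuristic approximates undocumented pathway-tool behaviour;
  linker sets (and hence FI node counts) should be treated as
  tool-specific.
* HPO ancestry is not traversed: a panel is exactly the union over the
  supplied terms, so term selection is the user's responsibility.
* CADD, AF and pLI are consumed as annotations; the package never
  recomputes or updates them, so results inherit the annotation versions
  used upstream.
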