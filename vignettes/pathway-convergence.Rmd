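---
title: "From de novo CNVs to convergent phenotypes: methods and design"
author: "CNVconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From de novo CNVs to convergent phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CNVconverge)
```

## The scientific problem

Developmental disorders are phenotypically and genetically heterogeneous:
different patients carry de novo copy-number variants (CNVs) over different
genes, yet may share phenotypes because those genes participate in a common
molecular pathway. Given a cohort in which every patient has been
*systematically* phenotyped with a hierarchical ontology (so that the absence
of a recorded phenotype is evidence of absence, not missingness), this package

1. maps each patient's de novo CNVs to the genes they disrupt,
2. groups patients by shared ontology term,
3. asks, per group, whether the pooled disrupted genes share annotations
   (GO-like, KEGG-like, mouse-knockout phenotypes) or cluster in co-expression
   and protein-interaction networks,
4. intersects the engines' gene-level hits into multi-method candidate sets,
   and
5. tests whether patients whose variants *contribute* to the same inferred
   pathway converge phenotypically, and whether that convergence reflects
   distinct co-morbid phenotypes (pleiotropy) or finer subtypes of the group
   phenotype.

## Cohort construction

Patients are retained when they carry at least one de novo CNV and every de
novo CNV is shorter than `maxCnvLen` (default 5 Mb; strictly
`end - start < 5e6` under the half-open input convention, so a CNV of exactly
5 Mb excludes its patient — very large CNVs disrupt so many genes that
specific enrichments become undetectable). Patients without any de novo call
form the replication pool, analysed later through their inherited CNVs.
A patient with several de novo CNVs, one of them over the cap, is excluded
entirely: partial retention would make the "likely causative variant" premise
ambiguous for that patient.

A gene counts as affected by a CNV when either the whole gene lies inside the
CNV, or the CNV intersects at least one exon of *every* transcript. The
second clause prevents long genes with many transcripts from being counted on
the strength of a single clipped transcript, a known source of length bias
towards brain-expressed genes. Genes seen copy-number changed *in the same
direction* in unaffected controls are removed before any enrichment — gains
only strip gain CNVs, losses only loss CNVs.

Internally all intervals are `GRanges` (1-based, closed), the Bioconductor
idiom; BED-like 0-based half-open inputs are converted at the readers. Under
this convention "overlapping by at least 1 bp or bookended" is exactly
`reduce(..., min.gapwidth = 1)`, which is how CNV regions (CNVRs) are merged,
gains and losses combined.

## Enrichment engines

Per patient-phenotype group (every propagated term carried by at least
`minGroupSize = 3` retained patients; groups are non-exclusive), the pooled
gene set is tested against each annotation resource with the exact upper-tail
hypergeometric test, and Benjamini–Hochberg FDR is applied *within one group
× one resource family* (`alpha = 0.05`). The analysis never states a global
correction across groups, and the per-family convention keeps results
re-poolable; the full p/q table is written out so users can re-correct.
The background universe defaults to the resource's own gene coverage and can
be overridden.

The mouse-knockout engine adds three rules: test genes are mapped through
strictly 1:1 orthologs (ambiguous orthology drops the gene); only annotation
terms inside the overarching category configured as most relevant to the
group's human phenotype are tested (the category assignment is an *input*
table — there is no published algorithm for "most relevant", so we refuse to
guess); and terms annotating fewer than `minFrac = 1%` of the category's gene
pool are dropped before FDR as underpowered and uninformative.

## Network clustering with degree-matched nulls

The co-expression network keeps genes expressed at `rpkmMin = 1` or above in
at least 5% of samples, computes pairwise Pearson correlation, and keeps
edges with signed `r >= rMin = 0.7` (positive co-expression only; the sweep
0.6/0.7/0.8 produces nested networks by construction). The clustering
statistic is the sum of induced edge weights (edge count on unit-weight PPI
networks, where the two coincide). Significance is empirical: random gene
sets of equal size and matching degree distribution are drawn (exact degree
classes where possible, nearest degrees within a recorded tolerance where a
class is exhausted; within-set sampling without replacement), and
`p = (1 + #{null >= observed}) / (1 + nSamples)`. The +1/+1 estimator can
never return zero, matching the resolution-limited reporting style of
resampling p-values; `nSamples` is capped at 10,000 in the analysis defaults.

The bait-extension test asks whether genes hit by an independent cohort's
CNVRs interact with a phenotype-associated bait network more than chance
allows. CNVRs containing bait genes, and CNVRs with no genes in the
interaction network, are removed first (both counts reported). Null CNVR
sets re-place each region as a random run of consecutive genes in genomic
order containing the same number of in-network genes, never containing a
bait gene, with chromosomes chosen proportionally to their feasible anchor
counts. Only bait-to-CNVR edges are counted (not CNVR-to-CNVR), matching the
way the extension network is defined; this is a documented choice users can
revisit.

## Goodall3 phenotypic similarity and convergence

Similarity between two patients sums, over every phenotype annotated to any
patient in the comparison population, a frequency-weighted contribution:
`1 - f^2` if both carry the phenotype, `1 - (1 - f)^2` if neither does, and 0
otherwise. Shared rare presences and shared common absences carry the most
information; a ubiquitous phenotype carries none. Frequencies are computed
over the full retained cohort (the "patient population"), not per group; the
replication analysis recomputes them over its own pool.

For each significant enrichment, group members split into contributing
patients (a de novo CNV gene lies in the enrichment's contributing set) and
non-contributing patients. All contributing-contributing pair similarities
("intra") are compared against contributing × non-contributing pairs
("inter") with a two-sided Wilcoxon rank-sum test, run only at
`minEach = 10` patients per side. Non-contributing pairs among themselves
are unused. Because pairs share patients they are not independent: the
rank-sum p-values are *descriptive indices* of convergence, anti-conservative
under a literal null (a patient with many phenotypes raises all of its
pairs), and the package surfaces them as such rather than as calibrated
error rates. The calibration test we do enforce draws intra and inter values
from one distribution, which validates the rank-sum machinery itself.

Three meta-analyses follow: a one-sided binomial test on the excess of
results whose intra median exceeds their inter median (tied medians dropped);
a subterm-restricted re-test using only proper descendants of the group term
(frequencies recomputed over the comparison patients — the convergence is
pleiotropic when the full-universe test is significant but the subterm test
is null); and pooling of groups that share a significant annotation
(contributing = union of the groups' contributing patients), reported with
the number of associated groups.

## Candidates and replication

A gene becomes a candidate when identified by at least `minMethods = 2`
distinct engines — engine-level granularity, so two significant GO terms
still count once. Candidate sets are validated by the PPI clustering test at
`p < 0.05`. The replication analysis assigns each no-de-novo patient to
exactly one of candidate / extended / none (candidate wins when both apply);
extended genes share the enriched annotation or have a direct network edge
to a candidate gene. Candidate patients are compared against everyone else,
and extended against none, with the same convergence machinery.

## What the generator emulates

`simulateStudy()` builds, under one seed: a single-rooted multi-parent DAG
(~300 terms, depth 6, 10% of terms with two parents); a ten-chromosome
genome of 1,500 non-overlapping genes with 1–3 transcripts of 1–6 exons; a
cohort of 120 de novo patients plus 80 replication patients with log-uniform
CNV lengths on [50 kb, 5 Mb) (under the cohort cap by construction) and a
gain fraction of 0.4 (the emulated cohort is loss-dominated); GO/KEGG/MPO
-like resources whose planted terms exactly cover the planted pathway genes
plus random decoy terms; a 1:1 ortholog map over 70% of genes and 33
overarching categories; a block-factor expression model (within-block
correlation 0.75, planted modules at 0.88, block membership assigned by
random permutation so that co-expression is deliberately independent of
genomic adjacency — real co-expression modules are not gene-neighbourhoods,
and CNVs hit gene runs); and a preferential-attachment PPI network with
planted cliques.

The planted causal structure is a pathway gene set whose carriers receive a
de novo CNV over one pathway gene, the target phenotype with configured
penetrance, and five pleiotropy phenotypes at a co-morbidity frequency of
0.8 against a 0.1 background ("comorbid" mode; "subtype" mode elevates child
terms of the target instead, to exercise the subterm contrast). Non-carrier
CNVs avoid planted genes so that truth labels stay exact. Target phenotype
terms are chosen with a bounded number of descendants, because an
upper-level term would be reached by propagation from much of the cohort and
dilute every enrichment.

The generator does not emulate: real genome coordinates or gene structure,
linkage or CNV hotspots, ontology annotation biases, correlated annotation
resources, or measurement error in phenotyping. Passing tests therefore show
the machinery is correct and well-calibrated under the stated generative
model, not that real cohorts meet its assumptions.

## Numerical and design choices

* Hypergeometric tails, BH-FDR, Wilcoxon and binomial tests are delegated to
  R's exact routines (`phyper`, `p.adjust`, `wilcox.test`, `binom.test`);
  the test-suite checks them against independent enumeration oracles.
* Empirical p-values use the +1/+1 estimator throughout; ties count as
  extreme (conservative). Calibration studies are sized so that the
  clustering statistic is effectively continuous (test sets large enough to
  induce edges; bait designs with well-resolved edge counts), because with a
  heavily tied discrete statistic the estimator is conservative by
  construction and its p-values cannot be uniform.
* Degree matching prefers exact degree classes and falls back to nearest
  degrees, recording the tolerance used; duplicate sets across draws are
  allowed (the draw count, not the distinct-set count, defines resolution).
* Fold enrichment is reported as 0 when the overlap is 0.
* Problem sizes in the shipped tests and acceptance study (1,500–2,000 gene
  genomes, 120-patient cohorts, 200–500 resampling replicates, 150–500
  null samples per clustering test) are the package's chosen desk-scale
  defaults; every constant is config-exposed.
* Determinism: one seed drives the generator; the pipeline seeds its
  resampling once at entry; identical config + seed reproduce byte-identical
  output files, and the recorded config hash covers analysis parameters only
  (not paths).

## Known limitations

* Rank-sum convergence p-values are descriptive (pair dependence), as
  discussed above.
* FDR families are per group × resource; results across the hundreds of
  non-exclusive groups are not jointly corrected (the summary table enables
  re-pooling).
* The hypergeometric model treats genes as exchangeable draws, ignoring that
  one CNV contributes a genomic run of genes; control-gene removal mitigates
  but does not remove CNV-occurrence bias, so recurrently enriched pathways
  across many groups deserve scepticism.
* The bait-extension null preserves the count of in-network genes per CNVR
  and genomic contiguity, but not gene length or local network topology.
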