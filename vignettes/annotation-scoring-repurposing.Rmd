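---
title: "Functional-annotation scoring for genomics-driven drug repurposing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-annotation scoring for genomics-driven drug repurposing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snp2drug)
```

## The method

`snp2drug` implements a gene-prioritization and drug-repurposing
procedure that starts from disease-associated SNPs and ends at a ranked
shortlist of candidate drugs. The procedure scores each
disease-associated gene on five binary functional-annotation
categories, each worth one point:

1. **Missense variant** — the gene carries at least one
   disease-associated missense SNP.
2. **cis-eQTL** — at least one associated SNP is a cis-eQTL for the
   gene in whole blood (the tissue filter is configurable).
3. **Pathway (KEGG-style)** — the gene belongs to at least one pathway
   significantly over-represented in the disease gene list.
4. **PPI (GO biological process)** — membership in at least one
   significantly over-represented biological-process term. The field's
   scoring convention labels this category "PPI" while sourcing it from
   gene-ontology biological-process terms; we keep that assignment.
5. **Knockout-mouse phenotype** — membership in at least one
   significantly over-represented mammalian-phenotype term.

The total score is the sum of the five indicators,
$S_g = \sum_{c=1}^{5} \mathbb{1}[g \in c]$, so $S_g \in \{0,\dots,5\}$.
Genes with $S_g \ge 2$ are called *risk genes*. A gene earns at most
one point per category no matter how many significant sets contain it.

Over-representation of a gene set of size $K$ in a query of size $n$
drawn from a background of $N$ annotated genes is tested with the
one-sided hypergeometric tail
$P(X \ge k) \;=\; \sum_{i=k}^{\min(K,n)}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}$,
i.e. Fisher's exact test with alternative "greater" — the standard
realization of gene-set over-representation. Within each collection
(pathway, GO-BP, phenotype) p-values are adjusted with
Benjamini–Hochberg; the three collections are adjusted independently
because they are three separate analyses. Significance uses the strict
inequality $q < \alpha$ with $\alpha = 0.05$ by default.

Risk genes are then expanded through a weighted protein–protein
interaction network: the $k$ highest-confidence edges with at least one
endpoint in the risk set are selected (default $k = 50$; ties broken by
canonical edge order) and their non-risk endpoints join the target set.
Expansion radius is 1 — edges between two non-risk genes are never
selected — because the procedure expands directly from the risk genes.
Confidence scores on the common 0–1000 integer scale are divided by
1000 at read time.

Target genes are joined against a drug–target table; a target is
*druggable* when at least one drug lists it. Finally each drug–target
association is triaged against an evidence snapshot of trial-registry
(clinical) and literature (preclinical) records: associations of drugs
with at least one evidence record are *in development*, the rest are
*novel candidates*. Novel candidates hitting an evidence-backed
("promising") gene, ranked by their target gene's score, form the
repurposing shortlist.

## Why candidates are drug–target pairs

Drug–target snapshots and the printed tables they reproduce are
row-per-association: one drug targeting two genes contributes two
development records (e.g. muromonab under both CD3D and CD247). The
published arithmetic (20 records in development, 15 shortlisted) only
balances at that granularity, so `classify_candidates()` classifies
pairs; `candidate_drugs()` gives the deduplicated drug-level view with
the maximum score over targets.

## The enrichment background

The hypergeometric background defaults to the *annotation universe*:
the union of the query genes and every gene-set member, or an explicit
symbol set when one is supplied (`gene_set_collection(background=)`,
`run_pipeline(background=)`). The pipeline queries the full
disease-associated gene list, so a background restricted to exactly
that list would make query and background coincide and every tail
probability identically 1; including the annotated non-query genes —
but not the whole genome — keeps the test meaningful while still
conditioning on annotation coverage. Analyses with a curated
background file should pass it explicitly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eqtl_tissue` | `"Whole_Blood"` | tissue an eQTL must match (case/underscore-insensitive) |
| `alpha` | 0.05 | FDR level, strict `q < alpha` |
| `risk_threshold` | 2 | minimum total score for a risk gene |
| `k` | 50 | interactions selected during expansion |
| `min_confidence` | 0 | floor on edge confidence before selection |
| `count_nonsense` | `FALSE` | count nonsense variants toward the missense point |
| `strip_salts` | `FALSE` | merge drug salt forms ("atracurium besylate" vs "atracurium") |

Nonsense variants are excluded from the missense point by default
because the scored criterion is missense presence; the switch exists
because truncating variants are arguably as damaging. Salt stripping
is off because distinct salt forms are distinct DrugBank entries.

## Numerical and parsing choices

* Blank indicator cells in reference tables parse as 0; printed totals
  are authoritative and always recomputed from the indicators.
* Ranked outputs break score ties lexicographically by gene symbol
  (by Ensembl id via `tie_break = "gene_id"`).
* Truncated trial accessions are zero-padded to the 8-digit NCT form
  (`normalize_nct("3787290")` → `"NCT03787290"`); the printed form is
  retained alongside for regression.
* Genes without a profile row (e.g. network-added targets) get
  `gene_score = NA` in classifications and rank after scored genes.
* Duplicate undirected edges keep the highest confidence; self-loops
  are rejected.
* Symbols are case-folded before every join.

## What the synthetic generator emulates

`generate_bundle()` draws, for each gene, five independent Bernoulli
indicators, with planted risk genes at elevated rates, and then
*materializes* inputs from which a faithful pipeline can recover the
draws: missense and whole-blood-eQTL SNP rows for the variant
categories; gene-set collections in which category-positive genes are
split into planted sets (about 15 genes each, diluted with ~30% filler
symbols) next to random noise sets; high-confidence network edges from
risk genes to planted neighbors over a bed of lower-confidence noise
edges; and drug/evidence tables over a druggable subset.

Defaults mirror the packaged case study: 632 genes, 5885 SNPs, 65
planted risk genes, per-category planted rates equal to the reference
table's column frequencies (16, 30, 15, 46, 54 of 65) and background
rates set so that the expected study-wide category totals match the
study's reported counts (34 missense, 68 eQTL, 16 pathway, 87 GO-BP,
59 phenotype genes). The background rates are otherwise uncalibrated —
the study's full per-gene appendix is not public.

Ground truth records both the *planted* genes and the *realized* risk
genes — those whose drawn indicators actually sum to ≥ 2 (about 85% of
planted genes under the calibrated rates). Recovery is measured against
the realized labels: the pipeline can only recover signal present in
the materialized data, and measuring against the designated planted
set would bound sensitivity by the draw itself rather than by the
pipeline. Each bundle component consumes its own seeded random stream
derived from the master seed, so changing, say, the drug settings never
perturbs the SNP table.

What the generator does **not** emulate: linkage disequilibrium and
allele-frequency structure among SNPs, ontology hierarchies (every set
is flat and independent), genome-scale backgrounds, correlated
indicators (real annotation categories co-occur), network topology
beyond star-shaped planted neighborhoods, and pharmacological
plausibility of the drug table. Passing the planted-recovery tests
therefore demonstrates pipeline correctness — each stage recovers what
the data encode — not performance on real annotation databases.

Because noise sets are random, a correct FDR procedure will
occasionally call one significant (that is what FDR control permits);
such chance discoveries can add single points to background genes but,
under noise-free indicator rates, never lift a background gene to the
risk threshold. The recovery tests therefore require completeness of
the planted sets and exactness of the downstream gene and drug calls.

## Problem sizes used by the shipped tests

The test suite exercises the full default geometry (632 genes, 5885
SNPs) for the recovery checks — 20 simulated studies for the
sensitivity estimate — and smaller geometries (50–150 genes) for
structural and determinism checks; the enumeration oracle for the
hypergeometric test covers every configuration up to background size
15. These sizes give stable results while keeping a full run around
half a minute.

## Known limitations

* The printed reference tables drive the case-study regression; three
  rows of the published indicator table are internally inconsistent in
  the available rendering and were repaired to match their printed
  totals (the totals are authoritative).
* The expansion rule ("top-k confidence among seed-incident edges") is
  the conventional reading of selecting k interactions from a
  confidence-scored network; the original study does not state its
  selection criterion, so the rule is recorded in the run manifest.
* Promising genes are defined as evidence-backed target genes; no
  further clinical judgment is modeled.
* Scores are unweighted; weighted multi-annotation variants are out of
  scope.
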