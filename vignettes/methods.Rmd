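---
title: "Evidence integration, hub selection and over-representation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence integration, hub selection and over-representation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhub)
```

## The problem

MicroRNAs (miRNAs) repress target mRNAs post-transcriptionally, and a
single mRNA is often regulated synergistically by several miRNAs. Given a
list of differentially expressed miRNAs (here: from a rat heart
hypercholesterolemia model, 47 up- and 10 downregulated), the goal is to
predict which mRNAs those miRNAs collectively target, with a tolerable
false-positive rate, and to find *target hubs* — mRNAs under the control
of many differentially expressed miRNAs at once — as candidates for wet-lab
validation.

Individual prediction databases are noisy. The approach implemented here
integrates three sources — two sequence-based prediction databases (a
miRDB-style source with target scores on a 0–100 confidence scale, and a
microRNA.org-style source with mirSVR downregulation scores, more negative
meaning stronger predicted repression) and one manually curated database of
experimentally validated interactions (miRTarBase-style) — and keeps only
interactions supported by multiple predicted sources or by direct
experimental evidence.

## The scoring model

Three rules, with every constant held in `scoring_config()`:

1. **Per-database quality filters.** miRDB records with target score
   $\le 80.0$ are removed; microRNA.org records with mirSVR score
   $\ge -1.2$ are removed. The boundary values themselves are removed;
   survival requires a *strictly* better score. Validated records carry no
   comparable score and bypass this step.
2. **Compound evidence score.** For each distinct (miRNA, gene) pair,

   $$S = 0.5 \cdot n_{\text{predicted}} + 1.0 \cdot
   \mathbb{1}[\text{validated}],$$

   where $n_{\text{predicted}} \in \{0, 1, 2\}$ counts the predicted
   databases contributing at least one quality-passing record. Each
   database counts once, no matter how many binding-site rows it lists for
   the pair: multiple sites in one database are one piece of evidence, not
   two, since otherwise two sites in a single predicted source would pass
   retention on their own, defeating the single-source exclusion the score
   exists to implement.
3. **Retention.** A pair is kept iff $S \ge 1$. Consequently a pair
   supported by exactly one predicted database and nothing else
   ($S = 0.5$) is always discarded, while validated-only support
   ($S = 1.0$) suffices. Scores are sums of halves, exactly representable
   in binary floating point, so the comparison is an exact `>=` with no
   epsilon.

A pair present in one predicted *and* the validated database scores 1.5
and is treated identically to any other retained pair; the formula makes
no further distinction.

## The network and hubs

Retained interactions restricted to the differentially expressed miRNAs
form a bipartite graph: miRNA nodes (labelled up/down), mRNA nodes, and
evidence-annotated edges. Differentially expressed miRNAs that retain no
interaction are excluded from the network and reported separately — in
the emulated study shape, 4 upregulated and 2 downregulated miRNAs fail
this inclusion criterion.

Target genes partition into three Venn classes: targeted only by
upregulated miRNAs, only by downregulated, or by at least one of each.
`union_total` is the distinct-gene count; the per-direction totals double
count the shared class, so their naive sum is also reported for
comparability with per-direction tallies.

A **hub** is an mRNA with at least `hub_min_degree = 4` interacting
miRNAs. Two degree definitions are defensible — all interacting
differentially expressed miRNAs, or upregulated ones only — and usage in
the field mixes them, so both are implemented (`mode = "TOTAL"`, the
default, and `mode = "UP_ONLY"`); at equal threshold the UP-only hub set
is a subset of the total-degree hub set. Edges are unweighted for degree
purposes; the compound score rides along as an edge attribute only.
Hub tables sort by the mode's degree descending with lexicographic gene-id
tie-break, so output is reproducible byte for byte.

## Over-representation analysis

The historical analysis delegated GO enrichment to a hosted web tool that
does not name its statistic. Here the test is explicit: for each GO term
with at least one annotated background gene, the one-sided hypergeometric
(Fisher) upper tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n)$$

with $N$ the annotated background size, $K$ the background genes carrying
the term, $n$ the annotated study-set size and $k$ the study genes
carrying the term. A binomial alternative
($X \sim B(n, K/N)$) is provided because early annotation portals used
it. Bonferroni correction multiplies by $m$, the number of terms actually
tested (those with $K \ge 1$), not the full ontology size — the
conservative, defensible reading of a correction applied "after" the
analysis. Annotations are taken as a flat gene-to-term table with no
ontology-graph propagation; users wanting ancestor credit should supply
pre-propagated annotations. The background defaults to all genes in the
annotation file.

## The synthetic study generator

`generate_ground_truth()` emulates the shape of the motivating study so
every stage has a closed-loop test with known answers:

* 47 up- and 10 downregulated miRNAs; 4 up and 2 down are planted as
  *excluded*: all their records sit in exactly one predicted database, so
  the retention rule must remove every one of them.
* 500 background genes; 11 planted hubs each receive 5 true interactions
  (above the threshold of 4), while every other target gene is assigned a
  degree strictly below 4 by construction, so in the noise-free regime hub
  recovery must be exact (precision = recall = 1).
* Each true interaction is placed in a primary predicted database, echoed
  in the second with probability 0.7, and given validated membership with
  probability 0.3; any true interaction that would otherwise end up with a
  single predicted source and no validation is forced into the validated
  database, so the planted interaction set is retained by construction.
  True miRDB scores are drawn strictly above 80, true mirSVR scores
  strictly below −1.2.
* Decoys (rate 0.3 per predicted database) are non-true pairs that either
  pass the quality filter but sit in a single database, or carry failing
  scores — including the exact boundary values 80.0 and −1.2, so boundary
  behavior is exercised by real file content, not only unit fixtures.
* 40 GO terms; 3 are planted: network target genes carry them with
  probability 0.8 against a background rate of 0.1, so they must come out
  enriched; the remaining terms are pure background.

Identifiers are synthetic (`rno-mir-sim-001`, `GENE0001`) to avoid
implying real biology; `use_printed_hub_names = TRUE` substitutes the
eleven published rat hub symbols for documentation examples. All
randomness is confined to the generator and controlled by a single seed;
generation restores the caller's RNG state. The analysis pipeline itself
is deterministic: reruns produce byte-identical tables.

What the generator does *not* emulate: sequence-level seed matching,
binding energetics, expression dynamics, correlated database errors, and
the identifier-namespace mess of real database releases (RefSeq
accessions vs symbols — an optional accession-to-symbol map at read time
stands in for that). Passing closed-loop tests therefore demonstrates the
correctness of the rules, not the biological accuracy of any particular
database snapshot.

## Numerical and design choices

* Thresholds are interpreted exactly as printed: removal at $\le 80.0$
  and $\ge -1.2$, boundaries removed.
* Duplicate rows for one pair within one database collapse to the best
  score (max for target scores, min for mirSVR) before scoring.
* Species filtering drops records with a foreign three-letter species
  prefix (e.g. `hsa-`) while adopting prefix-less names (`miR-322` →
  `rno-mir-322`); the `mir`/`let` family tokens are recognized so they are
  never mistaken for species codes.
* The null calibration test of the hypergeometric stage draws study sets
  uniformly from a background of 1000 genes with one term covering half of
  them ($n = 100$, 1000 replicates): at that size the discrete achieved
  level of the nominal 0.05 test is 0.0364, within sampling error of the
  nominal rate, whereas smaller backgrounds make the test conservative
  through discreteness alone.
* Problem sizes in the test suite (typically 100–500 genes, tens of
  miRNAs, up to 20 generator seeds for the enrichment power check) keep
  the full suite under half a minute while leaving every planted effect
  overwhelmingly detectable.

## Known limitations

* The compound score treats databases as independent, equally credible
  witnesses; no weighting by database quality or score magnitude beyond
  the pass/fail filter.
* No ontology structure: parent terms receive no credit from child-term
  annotations unless the input is pre-propagated.
* Hub degree ignores edge weights and miRNA expression magnitude.
* The published headline counts (79/330/32 Venn classes, the eleven named
  hubs) depend on specific 2014–2015 database releases and are not
  recomputable from code alone; the package reproduces the *procedure*
  and verifies it on planted ground truth instead.

## Worked example

```{r example, eval = FALSE}
truth <- generate_ground_truth(generator_config(seed = 1))
manifest <- emit_files(truth, "sim_inputs")

cfg <- list(inputs = list(
  mirdb = "sim_inputs/mirdb.tsv",
  microrna_org_conserved = "sim_inputs/microrna_org_conserved.tsv",
  microrna_org_nonconserved = "sim_inputs/microrna_org_nonconserved.tsv",
  mirtarbase = "sim_inputs/mirtarbase.tsv",
  expression = "sim_inputs/expression.tsv",
  annotation = "sim_inputs/annotation.tsv"
))
report <- run_pipeline(cfg, "out")
report$counts$hub_count        # 11: the planted hubs, recovered
```

The numbered scripts under `analysis/` run the same stages one at a time
and narrate what each found.
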