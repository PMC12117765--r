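---
title: "Methods: background models, overrepresentation tests, and redundancy reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background models, overrepresentation tests, and redundancy reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoenrich)
```

`mycoenrich` performs overrepresentation analysis of functional categories
— KOG/COG letters and classes, GO terms, KEGG pathway levels — in a
user-supplied protein list, against background frequency models built from
the annotation of the same genome. This vignette is the package's own
account of the statistical model, the design decisions behind it, and what
the test suite does and does not demonstrate.

## Background frequency models

A model is a collection of categories, each holding the *set* of proteins
annotated to it, plus a background universe. Two conventions matter:

* **The background is a set union, never a sum.** A protein annotated to
  three categories is still one protein in the background. Summing
  per-category counts would inflate `N` and systematically understate
  enrichment wherever annotations overlap — which in GO (after
  propagation) is everywhere.
* **Empty categories are dropped at construction**, so every category has
  `K >= 1` and the enrichment ratio is always defined.

KOG models come in two levels: the 25 single-letter categories and the
broad classes that group them. A class's protein set is the union over its
letters, so a protein assigned to two letters of one class counts once in
that class. GO records are propagated up the ontology before counting (see
below) and split into one model per namespace, each with its own
background — a protein with only molecular-function annotations is not
part of the biological-process background. KEGG models are built per
aggregation axis (pathway type, class, name, enzyme definition), and each
axis has its own background universe. The per-axis choice is deliberate:
enzyme (EC) annotations often cover proteins the pathway mapping does not,
and a shared universe would deflate enzyme-level enrichment exactly where
the EC fallback is the only annotation available.

For eggNOG-mapper sources, the `COG_category` letters feed the KOG models
through a built-in letter-to-class table (overridable, since eggNOG output
carries only letters), `GOs` feeds the GO models, and `KEGG_Pathway` ids —
`ko`- and `map`-prefixed spellings unified on the 5-digit pathway number —
feed a pathway-name model, optionally expanded from KOs through a
user-supplied KO-to-pathway map.

## The tests

With `N` background proteins, `K` in category `c`, and `k` of the `n`
mapped query proteins in `c`, the default test is the one-sided
hypergeometric upper tail `P(X >= k)` — one-sided because the question is
overrepresentation; depletion is not tested. The implementation rides on
`stats::phyper`'s stable tail; the suite pins it to exhaustive enumeration
of all `C(N, n)` draws for every valid configuration with `N <= 12` at
`1e-12`. The chi-squared alternative builds the 2x2 table
`[[k, n-k], [K-k, (N-K)-(n-k)]]` and applies the 1-df test of independence
with the Yates correction (switchable off). A 2x2 chi-squared test is
inherently two-sided; the direction of an effect is read from the
enrichment ratio `(k/n) / (K/N)`. Degenerate tables (any zero expected
cell) return p = 1 with a warning rather than an error, since saturated
queries legitimately produce them.

**The hypothesis family.** Multiple-testing correction (Benjamini–Hochberg
by default; any `stats::p.adjust` method may be chosen) spans *all*
categories of the model, not only those observed in the query. The
background model defines the family of hypotheses being screened;
restricting the correction to categories the query happens to touch would
overstate significance. Implementation-wise, p-values are computed for
every category — for the hypergeometric test an unobserved category has
`P(X >= 0) = 1` exactly — adjusted together, and only `k >= 1` rows are
reported. Reported rows are ordered by adjusted p, ties broken by category
id, so output order is deterministic.

Query bookkeeping is explicit: ids absent from the model's background are
returned as `dropped_ids`, and `n_input = n_mapped + |dropped|` always
holds. Identifiers are compared as exact strings after whitespace
trimming; there is deliberately no fuzzy matching, because enrichment
against a mismatched background is silently wrong. The
`rewrite_ids()`/`convert_ids()` utilities exist to make identifier
reconciliation explicit instead.

## GO propagation and the ontology graph

The GO DAG is read from a standard OBO flat file; `is_a` and `part_of`
edges are both retained and both traversed by default, each independently
switchable. The true-path rule is applied before model construction:
a protein annotated to a term is annotated to every ancestor, so general
terms inherit their descendants' annotations. Propagation is idempotent
and verified against breadth-first reachability on hundreds of random DAGs.
Obsolete terms are excluded at parse time; `alt_id` accessions resolve
through an alias table; a cyclic ontology is a hard construction error
(reported with one offending cycle) because every downstream guarantee
assumes acyclicity.

Term depth is the *shortest* upward path to the namespace root. The
alternative — longest-path depth — is unstable under ontology edits: adding
one shortcut edge anywhere can renumber whole subtrees.

## Redundancy reduction

Propagation guarantees that significant GO lists contain near-duplicate
lineages. The reduction step groups significant terms (adjusted p at or
below `alpha`, default 0.05, matching the plot star threshold) by the
relation "shares a common ancestor within `depth_limit` upward hops of
each term", takes connected components of that relation, and keeps the
most significant row per component (ties: smaller raw p, then
lexicographic id — fully deterministic).

Two interpretations of "a common ancestor within a user-defined depth"
were on the table: an ancestor within `d` hops of each term, or an
ancestor whose absolute depth in the ontology is at most `d`. The package
implements the hop-distance reading: it is local (a term's grouping
behaviour does not depend on how deep its subtree sits in the ontology),
monotone in `depth_limit`, and has a clean degenerate case —
`depth_limit = 0` groups only identical terms, preserving every
significant row. Namespace roots are never absorbed into a group: at
modest depths the root is an ancestor of everything, and a reduction that
collapses all results into one row is useless; roots present in the input
come back as singletons. Components (computed by union-find over the
term-ancestor incidence) make the result order-independent, unlike greedy
seeded grouping. Adjusted p-values are *not* recomputed after reduction —
they keep the correction over the full model family, and rescaling them
to the surviving subset would misrepresent the screening that was
actually performed.

## Plots

Bar and lollipop plots are plain ggplot2 objects, one mark per category,
ordered by the value axis — the enrichment ratio by default, with
`-log10` adjusted p as the alternative, since significance is already
carried by the label stars (`*`, `**`, `***` for adjusted p below 0.05,
0.01, 0.001; thresholds configurable but required to be strictly
decreasing). Stars are computed from *adjusted* p-values: annotating raw p
next to BH-adjusted tables invites misreading. KOG letter plots are
panelled by KOG class. SVG output uses the cairo device and is
byte-deterministic for a fixed report and spec, which the end-to-end
determinism check relies on.

## The synthetic-data generator

`generate_fixture()` emits every dialect the parsers read — KOG/GO/KEGG
tables in the JGI column layout, a KEGG orthology link file with database
prefixes, an eggNOG-mapper table with `-` sentinels and `ko:` prefixes, an
OBO ontology, a GTF, and a query list — all describing one shared protein
universe, so cross-format consistency is testable by parsing files back
and comparing sets exactly.

Defaults describe a deliberately small but structured world: 1000
proteins, 10 KOG letters, 30 GO terms per namespace (a random single-root
DAG per namespace, each later term wired to one or two earlier terms, with
a part_of edge probability of 0.2, so propagation and grouping exercise
real DAG shapes rather than flat lists), 8 KEGG pathways with two EC
numbers each, and a KOG annotation density of 0.8 — roughly the coverage a
curated fungal annotation achieves, with GO and KEGG coverage scaled down
from it as is typical. A query of 50 proteins against a 1000-protein
universe mirrors a moderate differential-expression hit list.

Planting works by composition: for a planted category at fold `f`, each
query slot is filled from the category with probability `min(0.95, f*K/N)`
and from the rest of that model's background otherwise, so the expected
query rate is `f` times the background rate while fold 1 reduces to the
null. Unplanted configurations sample the query uniformly from the
background without replacement — exactly the hypergeometric null, which is
what makes the null-calibration check honest. Realized `k, K, n, N` are
recorded as ground truth. All randomness flows from the mandatory seed,
and identical configurations yield byte-identical files (radix sorts
everywhere; no locale dependence).

What the generator does *not* emulate: real category-size distributions
(uniform here, heavy-tailed in real genomes), correlated annotations
across frameworks, annotation errors, or the GO ontology's actual scale
(tens of thousands of terms). Passing the recovery and calibration checks
therefore demonstrates that the statistics behave as specified under a
clean, known-truth regime — not that any particular biological dataset
will yield stable results.

## Problem sizes and tolerances

The suite and the acceptance script use: exhaustive hypergeometric
verification for all backgrounds up to `N = 12` (about 3200
configurations) at `1e-12`; 1000 random p-vectors against the literal BH
step-up formula at `1e-12`; 200 random DAGs of up to 50 nodes for the
propagation oracle; 100 random DAG fixtures for the reduction/component
identity; and 200 seeded replicates each for planted recovery (4-fold,
1000-protein background, query 50, requiring recovery in at least 95%)
and null calibration (any false positive in at most 10% of replicates).
These sizes were chosen so each property is checked across genuinely
varied structures while the whole suite stays quick enough to run on
every change.

## Known limitations

* No cross-database identifier translation (Ensembl/RefSeq/UniProt):
  query ids must match the annotation's gene models, with
  `convert_ids()`/`rewrite_ids()` as the explicit bridges.
* No ranked/GSEA-style testing — the model is strictly set
  overrepresentation — and no depletion testing.
* No semantic-similarity GO reduction (Resnik/Lin); the redundancy step is
  purely ancestry-based.
* The KEGG axes reflect the annotation file's own pathway columns; no
  BRITE hierarchy is consulted.
* GAF/GPAD association formats are not parsed.
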