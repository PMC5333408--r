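---
title: "pathmem: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathmem: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmem)
```

## The problem and the model

Over-representation analysis (ORA) asks, for every pathway in a curated
knowledge base, whether a user's list of molecular identifiers contains more
of that pathway's entities than random sampling from the background would
predict. pathmem implements the analysis as four pipelined steps, each backed
by a data structure chosen for that step's access pattern, so that a fully
built knowledge base lives in memory and a genome-scale sample is analysed
interactively:

1. **Identifier search.** All curated main identifiers and cross-reference
   aliases are held in a radix tree (Patricia trie): a prefix tree in which
   every node with a single child and no stored value is merged with that
   child. Accession schemes such as UniProt (`P06213`, `P06850`, ...) share
   long prefixes, so compression saves memory, and a query costs at most one
   comparison per character of the query — a miss is detected without
   reading the whole identifier, unlike hashing. A node's payload is the set
   of entities the identifier refers to; gene-name aliases may legitimately
   point to several.
2. **Structure traversal and projection.** Physical entities form a directed
   graph: each entity node carries edges to every complex, set or polymer
   that contains it, inverse member edges, symmetric ortholog edges across
   species, and direct links into the pathway hierarchy. A matched entity
   contributes the pathway links of itself *and* of everything reachable
   through container edges (a protein inside a complex inside a set is
   annotated wherever any of those are). With projection enabled, matched
   entities are first replaced by their reference-species orthologs, then
   the reference-species graph is traversed.
3. **Aggregation.** Pathways form one rooted forest per species, with nodes
   double-linked (parent and children). A hit on a pathway is propagated
   recursively to every ancestor: an entity present in *Metabolism of
   carbohydrates* is present in *Metabolism*. Found sets are sets of main
   identifiers, not counters, so an entity hitting two sibling sub-pathways
   counts once in their parent.
4. **Statistics.** For each pathway with curated total $T > 0$, given a
   mapped sample of $n$ distinct entities against a background of $N$
   entities, the p-value is the one-sided binomial tail
   $P(X \ge k)$ with $X \sim \mathrm{Binomial}(n, T/N)$, where $k$ is the
   number of sample entities found in the pathway. The one-sided upper tail
   is the ORA question — does the found proportion *exceed* random
   expectation? The false discovery rate is controlled with the
   Benjamini–Hochberg step-up procedure applied once across all reported
   rows of the analysis.

## Semantics of composition

Complexes and sets expand differently. A set groups functionally
interchangeable alternatives (OR): `S2 = {P2, P3}` stands for either
protein, written `[P2,P3]`. A complex requires all components together
(AND): `C1 = {P1, S2}` stands for the cartesian combination of its
components' alternatives, `[{P1,P2},{P1,P3}]`. Nesting is preserved during
deconstruction — a complex containing a resolved complex keeps the inner
grouping, as in `{{P1,P2},P2}` — and a separate flatten operation produces
the plain single-entity sets used for totals, the background, and GMT
export. Polymers are treated as containers with complex semantics; the
knowledge-base model gives them no distinct behaviour.

Pathway totals (`total_entities`) count *distinct single entities by main
identifier* in a node's subtree, flattening any annotated container down to
its constituents. The per-species background $N$ is the union of the
top-level pathway sets — every distinct single entity annotated directly or
via composition. Custom backgrounds are deliberately unsupported.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `project` | `FALSE` | replace matched entities by reference-species orthologs before aggregation |
| `reference_species` | `"Homo sapiens"` | projection target; also the species reported when a sample maps to nothing |
| `case_insensitive` (load time) | `TRUE` | uppercase identifiers and queries before trie operations; UniProt/ChEBI accessions are case-insensitive in practice, and the flag exists because some identifier schemes are not |

Projection order is a genuine design choice: pathmem projects matched
*single entities* first and then traverses the reference-species graph, so
container membership and annotations are always interpreted in the species
whose statistics are being computed. One-to-many orthology is kept lossless
(all reference-species counterparts are used); entities with no
reference-species ortholog are excluded from the statistics but reported in
the result's `unprojected` list — silent exclusion would hide data loss.

## Degenerate inputs and numerical choices

* **Empty or comment lines** in sample files are skipped; only the first
  whitespace-separated column is used, so expression matrices can be
  submitted as-is. Submissions are deduplicated after normalisation.
* **Identifiers resolving only to containers** (possible when a knowledge
  base aliases a complex) appear in the identifier mapping but not in the
  statistics, which count curated single entities.
* **Pathways with $T = 0$** are untestable and excluded both from the rows
  and from the Benjamini–Hochberg $m$; keeping them would inflate the
  correction with hypotheses that can never reject.
* **A sample mapping to nothing** still reports the reference species'
  pathways with $k = 0$; an analysed species with an empty background is an
  error (there is no null model to test against).
* **Tie-breaking**: rows are sorted by ascending p-value, then pathway id,
  making output order — and therefore serialisation — deterministic.
* **Binomial tail** is computed through the survival function of the
  binomial distribution rather than naive summation, which is stable for
  small tail probabilities. `bh_adjust` is the textbook step-up
  `min_{j>=i}(p_(j) m / j)` capped at 1; tied p-values share adjusted
  values.
* **Tokens** are the first 20 hexadecimal characters of an MD5 digest over
  the canonical result JSON (fixed key order, full numeric precision).
  The digest is a cache key, not a security boundary; MD5 is used because
  it is available in base R, keeping the dependency footprint minimal.

## The synthetic knowledge-base generator

Real pathway knowledge bases cannot be bundled, so `generate_kb()` emulates
their structure from a seeded spec: UniProt-shaped protein accessions and
ChEBI-shaped chemical identifiers (exercising trie prefix sharing),
gene-symbol-like aliases including deliberately shared ones (one alias,
several entities), complexes/sets/polymers nested up to a configurable
depth — each container draws members from strictly lower nesting levels,
guaranteeing an acyclic composition — ortholog links from every
non-reference species, and a rooted pathway forest per species with direct
annotations drawn from that species' entities.

Defaults (300 proteins, 40 chemicals, 90 containers, 2 species with
ortholog fraction 0.6, 6 top-level pathways per species, depth 3,
3–10 annotations per pathway, 1–3 aliases per entity) describe a compact
world with every structural feature present; they were chosen once as a
plausible miniature of a curated knowledge base and are not calibrated to
any test outcome. All draws flow from a single generator seeded once, so
generation is byte-deterministic.

What the generator does *not* emulate: the heavy-tailed size distribution
of real pathways, biased annotation density, correlated pathway membership,
real accession semantics, or reaction/regulation structure. A green test on
synthetic data therefore establishes algorithmic correctness — set algebra,
traversal, propagation, statistics — not biological validity of any
particular enrichment call.

`generate_sample()` plants a signal by drawing a fraction of the sample
from one pathway's flattened entity set and the rest uniformly from the
background, optionally swapping identifiers for their aliases as users do.
With enrichment fraction 0 it is a pure null sample. The recovery
experiment enriches a deep pathway rather than a top-level one: a planted
signal in a super-pathway is inherited by its own sub-pathways, which
confounds "was the enriched pathway ranked first".

## Known limitations

* The null distribution of the discrete binomial test is conservative: the
  fraction of null p-values below 0.05 is *at most* — and usually well
  below — 0.05. Calibration checks must be one-sided bounds, not two-sided
  bands around the nominal level.
* The binomial model treats pathway membership draws as independent with
  constant success probability $T/N$; the exact model for sampling without
  replacement is hypergeometric. For $n \ll N$ the difference is
  negligible; for samples approaching the background size the binomial
  p-values are approximate.
* Deconstruction of a container with many nested sets can produce a
  combinatorial number of variants; `expand_structure()` is meant for
  inspection of individual structures, while all aggregate computations use
  flattened sets, which stay linear.
* No reaction, catalysis or regulation semantics: only composition,
  orthology and annotation edges participate in the analysis.
* Concurrency is modelled, not implemented: per-analysis state is isolated
  from the shared knowledge base, but no locking or parallel execution is
  provided.
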