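# pathmem

High-performance in-memory pathway over-representation analysis for R.

Pathway over-representation analysis (ORA) asks, for a list of molecular
identifiers — typically the differentially expressed genes, proteins or
metabolites from a high-throughput experiment — which curated pathways
contain more of those molecules than chance would predict. pathmem is aimed
at bioinformaticians who need that analysis as a fast, scriptable,
self-contained engine: a whole knowledge base is loaded once into memory
and genome-scale samples are analysed in seconds on one CPU, with no
database behind it.

The engine mirrors the four-step decomposition used by production pathway
servers, one purpose-built data structure per step:

| Step | Structure | Job |
|---|---|---|
| identifier search | radix tree (Patricia trie) | is this identifier curated, and for which entities? |
| structure traversal | directed entity graph | complexes/sets containing each entity; ortholog projection across species |
| aggregation | double-linked pathway tree | propagate hits recursively into super-pathways |
| statistics | binomial test + BH | score each pathway, control the FDR |

For a pathway with curated total *T*, a mapped sample of *n* distinct
entities and a background of *N* annotated entities, the p-value is the
one-sided binomial tail

> p = P(X ≥ k),  X ~ Binomial(n, T/N)

where *k* is the number of sample entities found in the pathway (directly
or through any containing complex/set). FDR is Benjamini–Hochberg across
all reported pathways.

Knowledge bases are exchanged as six plain TSV files (entities, aliases,
composition, orthologs, pathway hierarchy, annotations — see
`?kb_format`). A seeded generator (`generate_kb()`) produces structurally
realistic synthetic knowledge bases so everything is testable without
external resources, and `export_gmt()` writes flattened gene sets for
standard gene-set tools.

## Worked example

Generate a two-species synthetic knowledge base, plant an enriched sample,
and analyse it:

```r
library(pathmem)

kb_dir <- file.path(tempdir(), "demo_kb")
generate_kb(synthetic_kb_spec(seed = 42), kb_dir)
kb <- load_knowledge_base(kb_dir)
kb
#> <knowledge_base>
#> <radix_trie> 1611 keys, 2195 nodes, 5629 stored characters
#> <entity_graph> 621 entities, 2 species
#>    chemical: 61, complex: 52, polymer: 8, protein: 470, set: 30
#> <pathway_forest> 55 pathways across 2 species
#>   Homo sapiens: 6 top-level pathways, background 146
#>   Mus musculus: 6 top-level pathways, background 128

# 40 identifiers, half drawn from pathway PW00003 (73 curated entities),
# half uniformly from the background; some arrive as gene-name aliases
ids <- generate_sample(kb, "PW00003", n_sample = 40,
                       enrichment_fraction = 0.5, seed = 7)
head(ids)
#> [1] "O85550" "O15017" "TZVU6"  "O26911" "O13853" "Q96630"

res <- run_analysis(ids, kb)
res
#> <analysis_result> 40 submitted, 40 mapped, 0 not found; 22 pathway rows
#>  pathway_id         pathway_name entities_found entities_total     p_value
#>     PW00003  Synthetic pathway 3             30             73 0.001110717
#>     PW00016 Synthetic pathway 16              8             16 0.065626141
#>     PW00009  Synthetic pathway 9             11             25 0.068632744
#>     PW00004  Synthetic pathway 4              4              6 0.080855349
#>     PW00008  Synthetic pathway 8             10             25 0.134257685
#>         fdr
#>  0.02443577
#>  0.44470442
#>  0.44470442
#>  0.44470442
#>  0.51807468
```

Reading the top row: 30 of the 40 mapped sample entities fall in
`PW00003` — the 20 planted ones plus 10 that landed there by chance from
the background draw and from hit propagation out of sub-pathways — against
73 curated entities out of a background of 146, giving a binomial tail
p-value of 1.1×10⁻³. After BH correction it is the only pathway below an
FDR of 0.05; the planted pathway is recovered and nothing else is.

Results persist under a content-hash token for later server-side-style
filtering without recomputation:

```r
tok <- save_result(res, file.path(tempdir(), "store"))
tok
#> <analysis_token> 9e985c811905015271e4 -> .../store/9e985c811905015271e4.json
nrow(filter_result(tok, fdr_max = 0.05))
#> [1] 1
```

Samples from other species can be projected onto the reference species'
more complete annotation with
`run_analysis(ids, kb, analysis_options(project = TRUE))`; identifiers
whose entities lack a reference-species ortholog are reported in
`res$unprojected` rather than silently dropped.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch against the
installed package — synthetic knowledge-base generation, validation, an
enriched-sample analysis and the persistence round trip — and writes its
report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/pathmem-methods.Rmd`) documents the model
and its assumptions, composition semantics (AND-complexes vs OR-sets),
projection order, numerical and tie-breaking choices, what the synthetic
generator does and does not emulate, and known limitations.
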