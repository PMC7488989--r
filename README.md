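# comention

Literature co-mention mining for typed biomedical entities: dictionary-based
tagging of abstract corpora, association scoring of entity pairs, empirical
significance, publication-trend analysis, boolean querying, and associative
network export — fully testable offline through a seeded synthetic-corpus
generator with known ground truth.

## Who this is for

Researchers who want a transparent, reproducible engine for the classic
"co-mention" analysis over PubMed-style abstracts: given a dictionary of
typed entities (genes, diseases, drugs, ...) with synonym lists, find every
mention, score how strongly two entities travel together in the literature,
test whether interest in an entity is rising or falling over the years, run
boolean queries ("this disease AND any other disease AND one of these
keywords"), and export the resulting digest tables and networks for
downstream analysis.

## The model

**Weighted co-occurrence (C).** For an unordered pair of entities, summed
over the *n* abstracts of the corpus:

    C = sum_k [ omega_a * delta_ak + omega_s * delta_sk ]

where `delta_ak` = 1 iff both entities appear in abstract *k* and
`delta_sk` = 1 iff they share at least one sentence of abstract *k*
(both indicators are binary per abstract). Defaults: `omega_a = 3`,
`omega_s = 0.2`.

**Association score (s-score).** A geometric blend of the raw count and its
marginally normalised lift, with mixing exponent `alpha = 0.6`:

    S = C^alpha * ( C * C(t1,t2) / ( C(e1,t2) * C(t1,e2) ) )^(1-alpha)

`C(e1,t2)` sums C over all partners of entity e1 within type t2, and
`C(t1,t2)` over all stored pairs of the two types. `alpha = 1` reduces S to
C.

**Significance.** Each pair's S is standardised against the mean/SD of a
seeded negative sample of stored pairs of the same type-pair; the z-score's
one-sided upper normal tail gives p (z = 1.65 corresponds to p < 0.05).

**Trend strength.** Per entity, the yearly count of mentioning abstracts is
normalised by the yearly corpus totals and tested with the tie-corrected
Mann-Kendall statistic: `S_mk = sum_{i<j} sign(x_j - x_i)`, z with
continuity correction, two-sided p. A digest's interest score is the mean
trend z over its query-matching entities.

## Worked example

```r
library(comention)

spec <- generator_spec(n_abstracts = 500, seed = 42)  # synthetic demo corpus
gen  <- generate_corpus(spec)
ann  <- annotate(gen$corpus, compile_matcher(gen$dictionary))
ann
#> annotated corpus: 500 abstracts, 1740 mentions of 139 entities

sc <- score_corpus(ann, scoring_params(seed = 1))
sc
#> pair score table: 1341 co-occurring pairs
#>     entity_a entity_b     C     S     z         p
#>     gene_004 gene_032  37.2 24.96 6.888 2.828e-12
#>  disease_005 gene_006  28.0 21.74 6.165 3.523e-10
#>  disease_042 gene_031 146.6 21.46 6.068 6.477e-10
#>     drug_049 gene_026  18.6 20.32 6.100 5.301e-10
#>  disease_016 drug_023  18.8 18.95 5.604 1.049e-08

tt <- trend_table(ann)
tt
#> trend table: 139 entities, 1990 - 2020
#>    entity_id S_mk  z_mk      p_mk
#>     drug_010  284 4.833 1.348e-06
#>     gene_015  254 4.320 1.558e-05
#>     drug_025  239 4.049 5.151e-05
```

The top pairs carry large weighted counts `C` or strong marginal lifts; the
`z`/`p` columns say how far each s-score sits above its type-pair's negative
background. The trend table ranks entities by the strength of their yearly
publication trend (here the generator's planted rising-interest entities
surface at the top).

Querying and export:

```r
q <- corpus_query(list(
  query_clause("include", entity = "disease_007"),
  query_clause("include", type = "gene")))
res <- add_digest_scores(evaluate_query(q, ann), ann, tt)
res
#> digest list: 11 of 11 matching abstracts
net <- layout_nodes(build_network(res, ann, sc, tt))
net
#> associative network: 10 nodes, 18 edges
export_json(net, res, ann, "results.json")   # digests + network, schema-validated
export_csv(net, res, ann, "results_csv")     # digests/nodes/edges tables
```

Real corpora are read with `read_medline_xml()` (PubMed `PubmedArticleSet`
subset) or `read_jsonl_corpus()` (one JSON object per line: `id`, `title`,
`abstract`, `year`, `journal`, `citations`), and dictionaries with
`load_dictionary()` (TSV: `entity_id`, `entity_type`, `canonical_name`,
pipe-separated `synonyms`, `quality` 1-5). A thin command-line front end
lives at `inst/cli/comention.R` (subcommands `simulate`, `annotate`,
`score`, `trend`, `query`).

## Limitations

The named-entity recogniser is deterministic dictionary matching
(token-boundary, leftmost-longest), not a learned model; the synthetic
corpus emulates the statistical structure of co-mentions and trends, not
biomedical prose. See the methods vignette (`vignettes/comention-methods.Rmd`)
for the full model description, parameter choices and caveats.
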