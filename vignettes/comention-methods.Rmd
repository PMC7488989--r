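---
title: "Co-mention mining: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-mention mining: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comention)
```

This vignette is the package's own account of the science it implements:
the co-occurrence association model, its significance machinery, the trend
test, the query semantics, and the design decisions taken where more than
one reasonable choice existed. It states no empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## The co-occurrence association model

Dictionary entities are typed objects (genes, proteins, diseases, drugs,
... — thirteen labels by default, configurable) with synonym lists and a
recognition-quality grade from 1 (lowest) to 5. After annotation, every
unordered pair of distinct entities receives a weighted co-occurrence count
over the $n$ abstracts of the corpus:

$$C(e_1, e_2) = \sum_{k=1}^{n}\left[\omega_a\,\delta_{ak} +
  \omega_s\,\delta_{sk}\right]$$

where $\delta_{ak} \in \{0,1\}$ indicates joint presence in abstract $k$
and $\delta_{sk} \in \{0,1\}$ joint presence in at least one sentence of
abstract $k$. Because the sum runs over abstracts, both indicators are
binary per abstract: an abstract where the pair shares three sentences
contributes exactly $\omega_a + \omega_s$. Defaults are $\omega_a = 3$ and
$\omega_s = 0.2$; both are plain parameters of `scoring_params()`, so the
opposite (sentence-heavy) weighting convention used by some co-occurrence
systems is one argument away. Pairs of the same entity are excluded; two
entities of different types sharing a symbol (a gene and its protein, say)
are distinct objects and are scored like any other pair.

The association score blends the raw count with its marginally normalised
lift through a mixing exponent $\alpha$:

$$S(e_1, e_2) = C^{\alpha}\left(\frac{C \cdot C(t_1, t_2)}
  {C(e_1, t_2)\, C(t_1, e_2)}\right)^{1-\alpha}, \qquad \alpha = 0.6 .$$

$C(e_1, t_2)$ sums $C$ over all partners of $e_1$ within type $t_2$ and
$C(t_1, t_2)$ over all stored pairs of the two types. The ratio is a
lift: how much more often the two entities co-occur than their overall
"promiscuity" within this type-pair predicts. $\alpha = 1$ collapses $S$
to $C$; $\alpha = 0$ is pure lift. Marginals are always computed over the
whole annotated corpus, never over a query's result subset, because the
normaliser is defined over *all* pairs of the two types.

One convention deserves a note: for a same-type pair the normaliser
$C(t,t)$ counts each unordered pair from both ends (an ordered sum). This
is the only convention under which the identity
$C(t_1,t_2) = \sum_{e \in t_1} C(e, t_2)$ holds uniformly for every type
combination; the package asserts this conservation identity after every
marginal build. A corpus whose only co-occurring pair is cross-type
therefore has all four terms equal and $S = C^{\alpha}$ exactly — a closed
form the tests exploit.

## Empirical significance

Each pair's s-score is standardised against a negative background: a
seeded uniform sample (default size 10,000, with replacement when fewer
exist) of stored pairs of the same type-pair. $z = (S - \mu_{neg}) /
\sigma_{neg}$, and $p$ is the one-sided upper normal tail, so $z = 1.65$
corresponds to $p < 0.05$ — the conventional filtering threshold for
"significantly associated" pairs. Type-pairs with fewer than 30 stored
pairs are pooled into a global background (the pooled groups are recorded
on the score table). A degenerate background with zero spread yields
$z = 0$, $p = 0.5$ rather than an infinity.

Two open choices were resolved as follows. The negative sets are drawn
from *stored* (co-occurring) pairs rather than from all possible pairs:
the background then describes the population the user actually ranks, and
never mixes in the structural zeros of pairs that were never observed
together. And significance of co-occurrence is one-sided (high $S$ is
interesting) while trend significance below is two-sided (declining
interest is as real as growing interest); this asymmetry is intentional.

## Trend analysis

Per entity, the package counts mentioning abstracts per publication year
(an abstract counts once regardless of mention multiplicity; abstracts
with unknown year are kept for scoring but excluded here), zero-fills the
contiguous range from the first to the last corpus year, and divides by
the per-year corpus totals. Trend strength is the Mann-Kendall statistic
on this normalised series:

$$S_{mk} = \sum_{i<j} \mathrm{sign}(x_j - x_i),\qquad
  \mathrm{Var}(S_{mk}) = \frac{m(m-1)(2m+5) - \sum_g t_g(t_g-1)(2t_g+5)}{18}$$

with tie groups $g$ of size $t_g$, the continuity-corrected
$z_{mk} = (S_{mk}\mp 1)/\sqrt{\mathrm{Var}}$, and a two-sided normal $p$.
An all-tied series returns $S_{mk} = 0, p = 1$. The statistic is a rank
statistic, hence invariant under positive scaling — so whenever the yearly
totals are flat, raw and normalised dynamics give identical $S_{mk}$.
`trend_table()` reports normalised dynamics by default (`normalized =
FALSE` switches to raw), matching how the trend strengths are estimated.
The implementation is validated in the test suite against an independent
$O(m^2)$ brute-force enumeration of the sign terms, exactly for $S_{mk}$
and to $10^{-12}$ for $z$ and $p$.

A digest's interest score is the arithmetic mean of $z_{mk}$ over the
entities in the abstract that satisfy the user's query. The phrase "all
mapped objects satisfying the query" is grammatically ambiguous; the
default averages the query-satisfying entities only, and
`add_digest_scores(..., all_mapped = TRUE)` widens it to every mapped
entity of the abstract.

## Annotation

The recogniser is deterministic dictionary matching: every synonym is a
token-boundary-delimited phrase (token = alphanumeric run; hyphens inside
synonyms are literal). Matching is case-insensitive except for synonyms
shorter than 4 characters (configurable), which match case-sensitively —
"PGF" must not fire on "pgf". Within a sentence, overlapping candidates of
the same type resolve leftmost-longest ("placental growth factor" beats
the nested "growth factor"); overlaps across types are all retained;
identical spans of the same type tie-break lexicographically. Two entities
of the same type sharing a normalised synonym make a dictionary ambiguous,
and the matcher refuses it with a conflict report rather than guessing.
Titles are treated as sentence index 0 of each abstract, since titles
carry entity mentions in practice; `abstract(..., include_title = FALSE)`
switches this off. Character offsets are 0-based and half-open throughout.

Sentence segmentation is rule-based: a sentence ends at `.`, `!` or `?`
followed by whitespace and a capital or digit, unless the text up to the
period ends with an entry of a configurable abbreviation guard list
("e.g.", "Fig.", "et al.", ...). The guard trades a rare missed split
(a sentence genuinely ending in "et al.") for not shattering citations;
the choice is deterministic and dependency-free.

## Query semantics

A query is a list of clauses plus free keyword groups. Every include
clause must be satisfied — a fixed entity by being mentioned, a type
wildcard by some entity of that type *other than the query's own fixed
entities of that type* ("any other disease"). No exclude clause may be
satisfied. Keyword groups are OR within and AND across; excluded groups
are NOT. Bound keyword groups must share a sentence with a mention of
their own clause's matched entity (per-clause, not per-query). Keyword
matching is case-insensitive at token boundaries with no stemming:
deterministic and explainable, at the price of "comorbid" not matching
"comorbidities" unless both are listed in the group — which is exactly how
the OR-groups are meant to be used.

Results are capped at 5,000 digests for keyword-free queries and 30,000
otherwise, keeping the head of the current order and setting a
`truncated` flag; the exact pre-cap count is always reported (no
estimation is needed at package scale). Filtering removes entities below
the recognition-quality threshold from view, and drops wildcard-matched
entities whose s-score against every fixed query entity is below the
s-score threshold — digests left without a required wildcard match are
dropped. Sorting (date, journal H-index, citations, digest score) is
stable with ties broken by abstract id; journals missing from the H-index
table sort with H = 0.

## Network export

The associative network has one node per visible entity and one edge per
pair co-occurring in at least one result abstract; mention and co-mention
counts are computed over the result set, while the edge's s-score, z and p
are copied unchanged from the corpus-wide table. Node size is
$10 + 20\log(1+\text{mentions})$ and edge size $1 + \log(1+\text{count})$
— any strictly increasing map satisfies the contract; these were chosen
for visual range. Colours come from a fixed per-type palette shipped in
code. The default layout is a deterministic circle ordered by type and
mention count; a small seeded force-directed loop is optional. JSON
exports carry a digest table (`anddigest`: pmid, date, digest score,
citations, and the full text with inline `<e id=...>` mention tags) and
the network, validate against the schema shipped in
`inst/extdata/network_schema.json`, and round-trip losslessly (numeric
fields are written at full precision; IEEE negative zeros are folded). CSV
exports deliberately omit colours, sizes and coordinates. GraphML is an
optional extra via igraph.

## The synthetic corpus generator

The generator emulates the statistical structure the scoring and trend
machinery assume, not biomedical prose: sentences are neutral English
frames with embedded synonym codes, so tests exercise the matcher and the
statistics rather than language understanding. Its default specification —
2,000 abstracts over 1990–2020, three types × 50 entities, 10 planted
pairs, 5 planted trends, seed 42 — is the package's demo fixture.

Entities receive Zipf-distributed base inclusion probabilities
(exponent 1, scaled to a mean of 3 entities per abstract, capped at 0.3).
Planted pairs are entity-disjoint and drawn from the moderately studied
band of the frequency order (ranks 5–40%): frequent enough that an
association has material support, not so frequent that chance
co-occurrence swamps it. Each planted pair gets a joint-inclusion
probability $p_j = \min(\text{lift} \cdot p_a p_b,\; 0.9\min(p_a, p_b))$
with a default lift of 200 — chance joint inclusion is of order $10^{-4}$,
so a true association showing up dozens of times is a few-hundred-fold
lift. Given joint inclusion the pair shares a sentence with probability
0.6. When the joint draw fails, the two entities are mutually exclusive
with probabilities chosen so their marginal rates stay exactly $p_a$ and
$p_b$; joint inclusion is therefore the *only* source of co-occurrence for
a planted pair, which makes the ground-truth ledger exact and gives the
closed form $E[C] = \omega_a n p_j + \omega_s n p_j \cdot
\text{sentence\_prob}$ implemented in `expected_C()`.

Planted trend entities replace their base probability with a linear ramp,
0.01 in the first year rising by 0.01 per year — the profile of an
emerging topic. Citation counts are log-normal, journals are drawn from a
small fixed list whose H-index table deliberately omits two journals (to
exercise the H = 0 default). What the generator does *not* emulate: real
synonym ambiguity, abbreviations, morphological variation, non-English
text, citation networks, or the heavy correlation structure of actual
PubMed — so green tests certify the statistical machinery, not
named-entity recognition performance on real text.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale, chosen
by design-stage power calculations: brute-force table agreement on 100
corpora of ≤ 20 abstracts; Mann-Kendall exactness on 1,000 series of
length 3–40; planted-pair recovery and null calibration on the 2,000
abstract demo fixture (with 2,000 reference pairs); trend power and type-I
error on 100 replicates of 400-abstract corpora with 30 entities and 3
planted trends each; query-engine agreement on 200 randomised queries over
100-abstract fixtures. Tolerances: exact integer agreement for counts and
$S_{mk}$; $10^{-12}$ for $C$, $z$ and $p$ against oracles; the stochastic
checks assert the bands the generator's design implies (recovery AUC
> 0.9, null AUC in [0.45, 0.55], trend power ≥ 0.9, type-I ≤ 0.07, null
z-exceedance ≤ 0.07 at the 1.65 threshold).

Degenerate inputs are defined rather than accidental: empty corpora give
empty tables; an all-tied trend series gives $S_{mk}=0, p=1$; a zero-SD
significance background gives $z=0, p=0.5$; zero yearly totals normalise
to 0 with a warning; series shorter than 3 years, single-class AUC inputs
and exhausted negative-sample pools are errors with actionable messages.

## Known limitations

Dictionary matching cannot resolve same-type homonyms (it refuses such
dictionaries instead); the s-score's lift term inflates rare pairs with a
single co-occurrence, which is intrinsic to this normalisation family and
the reason the raw count enters with exponent $\alpha$; the negative
backgrounds are descriptive (sampled from observed pairs), so z-scores are
calibrated against the corpus's own co-occurrence population rather than
an external null; and trend normalisation uses the corpus's own yearly
totals, which stands in for whole-database yearly totals when running on a
sub-corpus.
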