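## In-code fixtures shared across test files. Everything is built at test
## time; nothing is read from disk except files the tests themselves write.

## Two-type dictionary exercising case rules, multi-word synonyms and
## cross-type homonyms.
tiny_dictionary <- function() {
  entity_dictionary(
    entity_id = c("D1", "D2", "G1", "P1", "G2"),
    entity_type = c("disease", "disease", "gene", "protein", "gene"),
    canonical_name = c("preeclampsia", "obesity", "PGF", "PGF",
                       "growth factor receptor"),
    synonyms = list(c("preeclampsia", "pre-eclampsia"),
                    "obesity",
                    c("PGF", "placental growth factor"),
                    "PGF",
                    "growth factor receptor"),
    quality = c(5L, 4L, 5L, 3L, 2L))
}

tiny_corpus <- function() {
  corpus(list(
    abstract("A1", "Preeclampsia and obesity",
             "Preeclampsia worsens obesity. PGF is elevated in preeclampsia.",
             year = 2001L, journal = "Mock Med J", citation_count = 10L),
    abstract("A2", "PGF in disease",
             "Placental growth factor signalling was reviewed. Obesity was not discussed.",
             year = 2003L, journal = "J Synth Biol", citation_count = 3L),
    abstract("A3", "Unrelated report",
             "No dictionary entities appear in this text.",
             year = 2001L, journal = "Unknown J", citation_count = 0L)))
}

tiny_ann <- function() annotate(tiny_corpus(), compile_matcher(tiny_dictionary()))

## small generated corpus for pipeline tests
small_generated <- function(seed = 5L, n = 120L) {
  spec <- generator_spec(n_abstracts = n,
                         entity_counts = c(gene = 10L, disease = 10L),
                         n_planted_pairs = 2L, n_planted_trends = 2L,
                         seed = seed)
  gen <- generate_corpus(spec)
  ann <- annotate(gen$corpus, compile_matcher(gen$dictionary))
  list(spec = spec, gen = gen, ann = ann)
}
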