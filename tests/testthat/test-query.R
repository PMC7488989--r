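## hand-built corpus with transparent query structure
query_fixture <- function() {
  d <- entity_dictionary(
    c("D1", "D2", "D3", "G1"),
    c("disease", "disease", "disease", "gene"),
    c("preeclampsia", "obesity", "diabetes", "flt1gene"),
    quality = c(5L, 2L, 4L, 5L))
  corp <- corpus(list(
    abstract("Q1", "", "Preeclampsia is frequent. Obesity is a comorbidity here.",
             year = 1999L, journal = "Mock Med J", citation_count = 4L),
    abstract("Q2", "", "Preeclampsia with diabetes. Comorbid burden was high.",
             year = 2005L, journal = "J Synth Biol", citation_count = 9L),
    abstract("Q3", "", "Preeclampsia alone was recorded.",
             year = 2001L, journal = "Nowhere J", citation_count = 1L),
    abstract("Q4", "", "Obesity and diabetes without the main disease.",
             year = 2003L, journal = "Mock Med J", citation_count = 2L),
    abstract("Q5", "", "Preeclampsia and flt1gene in one sentence with comorbidity.",
             year = 2010L, journal = "J Synth Biol", citation_count = 30L),
    abstract("Q6", "", "Nothing of interest.", year = 2000L)))
  annotate(corp, compile_matcher(d))
}

test_that("fixed-entity queries select exactly the mentioning abstracts", {
  ann <- query_fixture()
  q <- corpus_query(query_clause("include", entity = "D1"))
  res <- evaluate_query(q, ann)
  expect_setequal(res$abstract_id, c("Q1", "Q2", "Q3", "Q5"))
  expect_equal(attr(res, "matching_total"), 4L)
  expect_false(attr(res, "truncated"))
})

test_that("wildcards, keyword groups and exclusions combine correctly", {
  ann <- query_fixture()
  ## fixed disease + any other disease + comorbidity keyword group
  q <- corpus_query(
    list(query_clause("include", entity = "D1"),
         query_clause("include", type = "disease")),
    free_groups = list(c("comorbid", "comorbidity")))
  res <- evaluate_query(q, ann)
  expect_setequal(res$abstract_id, c("Q1", "Q2"))
  expect_setequal(attr(res, "wildcard_matched"), c("D2", "D3"))
  ## excluded keyword group removes Q2
  q2 <- corpus_query(
    list(query_clause("include", entity = "D1"),
         query_clause("include", type = "disease")),
    free_groups = list(c("comorbid", "comorbidity")),
    excluded_groups = list("burden"))
  expect_setequal(evaluate_query(q2, ann)$abstract_id, "Q1")
  ## exclude clause on an entity
  q3 <- corpus_query(list(query_clause("include", entity = "D1"),
                          query_clause("exclude", entity = "D3")))
  expect_setequal(evaluate_query(q3, ann)$abstract_id, c("Q1", "Q3", "Q5"))
  ## bound keywords must share a sentence with the clause entity
  q4 <- corpus_query(query_clause("include", entity = "D1",
                                  bound_keywords = list("comorbidity")))
  expect_setequal(evaluate_query(q4, ann)$abstract_id, "Q5")
  ## keyword matching is at token boundaries: "comorbid" != "comorbidity"
  q5 <- corpus_query(query_clause("include", entity = "D1"),
                     free_groups = list("comorbid"))
  expect_setequal(evaluate_query(q5, ann)$abstract_id, "Q2")
})

test_that("invalid queries are rejected with reasons", {
  expect_error(corpus_query(list(query_clause("include", type = "disease"))),
               "fixed entity")
  expect_error(corpus_query(query_clause("include", entity = "D1"),
                            free_groups = list(character(0))),
               "non-empty")
  expect_error(query_clause("include", entity = "D1", type = "disease"),
               "exactly one")
})

test_that("query JSON round-trips through the documented schema", {
  path <- tempfile(fileext = ".json")
  writeLines('{
    "clauses": [
      {"mode": "include", "entity": "D1"},
      {"mode": "include", "type": "disease",
       "bound_keywords": [["risk", "burden"]]},
      {"mode": "exclude", "entity": "D2"}
    ],
    "free_groups": [["comorbid", "comorbidity"]],
    "excluded_groups": [["retracted"]]
  }', path)
  q <- read_query_json(path)
  expect_length(q$clauses, 3L)
  expect_equal(q$clauses[[2]]$bound_keywords, list(c("risk", "burden")))
  expect_equal(q$free_groups, list(c("comorbid", "comorbidity")))
  expect_equal(q$excluded_groups, list("retracted"))
})

test_that("randomised queries match the brute-force evaluator", {
  sg <- small_generated(seed = 17L, n = 60L)
  for (qs in 1:40) {
    q <- random_query(sg$gen$dictionary, seed = 1000L + qs)
    got <- sort(evaluate_query(q, sg$ann)$abstract_id)
    want <- bf_query_eval(q, sg$ann)
    expect_identical(got, want, label = paste("query seed", qs))
  }
})

test_that("adding clauses never enlarges the result set", {
  sg <- small_generated(seed = 19L, n = 60L)
  ids <- sg$gen$dictionary$entity_id
  base <- corpus_query(query_clause("include", entity = ids[1]))
  r0 <- evaluate_query(base, sg$ann)$abstract_id
  plus_inc <- corpus_query(list(query_clause("include", entity = ids[1]),
                                query_clause("include", type = "disease")))
  plus_exc <- corpus_query(list(query_clause("include", entity = ids[1]),
                                query_clause("exclude", entity = ids[2])))
  expect_true(all(evaluate_query(plus_inc, sg$ann)$abstract_id %in% r0))
  expect_true(all(evaluate_query(plus_exc, sg$ann)$abstract_id %in% r0))
})

test_that("quality and s-score filters shrink the visible set monotonically", {
  sg <- small_generated(seed = 23L, n = 150L)
  sc <- score_corpus(sg$ann, scoring_params(seed = 1))
  fixed <- sg$spec$planted_pairs$entity_a[1]
  q <- corpus_query(list(query_clause("include", entity = fixed),
                         query_clause("include", type = "disease")))
  res <- evaluate_query(q, sg$ann)
  f0 <- apply_filters(res, sg$ann, sc, min_quality = 1L, min_s = 0)
  ## min_s = 0 keeps everything
  expect_equal(nrow(f0$digests), nrow(res))
  ## quality threshold removes low-quality entities from view
  f5 <- apply_filters(res, sg$ann, sc, min_quality = 5L, min_s = 0)
  qual <- sg$gen$dictionary$quality[match(f5$visible_entities,
                                          sg$gen$dictionary$entity_id)]
  expect_true(all(qual == 5L))
  ## sweeping min_s upward shrinks both sets monotonically
  svals <- quantile(sc$S, c(0, 0.5, 0.9))
  prev_n <- Inf; prev_v <- Inf
  for (s in svals) {
    f <- apply_filters(res, sg$ann, sc, min_quality = 1L, min_s = s)
    expect_lte(nrow(f$digests), prev_n)
    expect_lte(length(f$visible_entities), prev_v)
    prev_n <- nrow(f$digests); prev_v <- length(f$visible_entities)
  }
})

test_that("digest sorting is a stable permutation with documented defaults", {
  ann <- query_fixture()
  q <- corpus_query(query_clause("include", entity = "D1"))
  res <- evaluate_query(q, ann)
  by_date <- sort_digests(res, key = "date", order = "desc")
  expect_equal(by_date$year[1], 2010L)
  expect_setequal(by_date$abstract_id, res$abstract_id)   # permutation
  hx <- c("Mock Med J" = 40L, "J Synth Biol" = 220L)
  by_h <- sort_digests(res, key = "h_index", order = "desc", hindex = hx)
  ## "Nowhere J" is absent from the table: sorts as H = 0, last
  expect_equal(by_h$abstract_id[nrow(by_h)], "Q3")
  by_cit <- sort_digests(res, key = "citations", order = "asc")
  expect_equal(by_cit$citation_count, sort(res$citation_count))
  tt <- trend_table(ann)
  scored <- add_digest_scores(res, ann, tt)
  by_score <- sort_digests(scored, key = "digest_score", order = "desc")
  expect_equal(nrow(by_score), nrow(res))
  expect_true(!is.unsorted(rev(by_score$digest_score)))
})

test_that("display caps truncate with a flag", {
  ## end-to-end at the plain-query cap: inflated fixture built directly
  d <- entity_dictionary("G1", "gene", "commongene")
  abs_list <- lapply(1:5200, function(i) {
    abstract(sprintf("I%05d", i), "", "The commongene was assayed.",
             year = 2000L)
  })
  ann <- annotate(corpus(abs_list), compile_matcher(d))
  top <- "G1"
  q <- corpus_query(query_clause("include", entity = top))
  res <- evaluate_query(q, ann)
  expect_gt(attr(res, "matching_total"), 5000L)
  expect_equal(nrow(res), 5000L)
  expect_true(attr(res, "truncated"))
  ## keyword queries get the larger cap on the same truncation path
  fake <- data.frame(abstract_id = sprintf("F%06d", 1:30500),
                     year = 2000L, journal = "j", citation_count = 0L,
                     n_mentions = 1L, stringsAsFactors = FALSE)
  qk <- corpus_query(query_clause("include", entity = top),
                     free_groups = list("word"))
  capped <- comention:::new_digest_list(fake, setNames(vector("list", 0), character(0)),
                                        character(0), qk, cap = 30000L)
  expect_equal(nrow(capped), 30000L)
  expect_true(attr(capped, "truncated"))
  expect_equal(attr(capped, "matching_total"), 30500L)
})
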