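## fixture with a fully known co-occurrence structure:
## A1: D1 + G1 share sentence 1 (body); A2: D1 + G1 in different sentences;
## A3: D1 alone.
two_entity_ann <- function() {
  d <- entity_dictionary(c("D1", "G1"), c("disease", "gene"),
                         c("preeclampsia", "flt1gene"))
  corp <- corpus(list(
    abstract("A1", "", "Preeclampsia involves flt1gene. Nothing else here."),
    abstract("A2", "", "Preeclampsia was studied. The flt1gene was measured."),
    abstract("A3", "", "Preeclampsia alone in this record.")))
  annotate(corp, compile_matcher(d))
}

test_that("weighted co-occurrence counts follow the abstract/sentence weights", {
  params <- scoring_params()
  tab <- count_all_pairs(two_entity_ann(), params)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$abstract_count, 2L)
  expect_equal(tab$sentence_count, 1L)
  ## 2 joint abstracts, 1 with a shared sentence: C = 3*2 + 0.2*1
  expect_equal(tab$C, 6.2)

  ## single abstract, same sentence: C = 3 + 0.2
  d <- entity_dictionary(c("D1", "G1"), c("disease", "gene"),
                         c("preeclampsia", "flt1gene"))
  ann1 <- annotate(corpus(list(
    abstract("A1", "", "Preeclampsia involves flt1gene."))),
    compile_matcher(d))
  expect_equal(count_all_pairs(ann1, params)$C, 3.2)

  ## entities never sharing an abstract are absent
  ann2 <- annotate(corpus(list(
    abstract("A1", "", "Preeclampsia here."),
    abstract("A2", "", "Only flt1gene there."))), compile_matcher(d))
  expect_equal(nrow(count_all_pairs(ann2, params)), 0L)
})

test_that("multiple co-mention sentences in one abstract count once", {
  d <- entity_dictionary(c("D1", "G1"), c("disease", "gene"),
                         c("preeclampsia", "flt1gene"))
  ann <- annotate(corpus(list(
    abstract("A1", "",
             "Preeclampsia involves flt1gene. Moreover preeclampsia needs flt1gene."))),
    compile_matcher(d))
  tab <- count_all_pairs(ann, scoring_params())
  expect_equal(tab$abstract_count, 1L)
  expect_equal(tab$sentence_count, 1L)
  expect_equal(tab$C, 3.2)
})

test_that("s-score closed forms hold", {
  ## alpha = 1 reduces S to C
  p1 <- scoring_params(alpha = 1)
  expect_equal(s_score(6.2, 100, 50, 1000, p1), 6.2)
  ## single cross-type co-occurring pair: all marginals equal C, S = C^0.6
  ann <- annotate(corpus(list(
    abstract("A1", "", "Preeclampsia involves flt1gene."))),
    compile_matcher(entity_dictionary(c("D1", "G1"), c("disease", "gene"),
                                      c("preeclampsia", "flt1gene"))))
  sc <- score_corpus(ann, scoring_params(seed = 1))
  expect_equal(sc$S, 3.2^0.6)
  ## zero marginal with positive C is an internal-consistency error
  expect_error(s_score(3, 0, 3, 10, scoring_params()), "consistency")
})

test_that("score table matches the brute-force oracle on small corpora", {
  params <- scoring_params(seed = 1)
  for (seed in c(2L, 13L, 31L)) {
    sg <- small_generated(seed = seed, n = 18L)
    tab <- score_corpus(sg$ann, params)
    bf <- bf_pair_table(sg$ann, params)
    if (is.null(bf)) {
      expect_equal(nrow(tab), 0L)
      next
    }
    bf <- bf[order(bf$entity_a, bf$entity_b), ]
    expect_equal(tab$entity_a, bf$entity_a)
    expect_equal(tab$entity_b, bf$entity_b)
    expect_identical(tab$abstract_count, bf$abstract_count)
    expect_identical(tab$sentence_count, bf$sentence_count)
    expect_equal(tab$C, bf$C, tolerance = 1e-12)
    expect_equal(tab$S, bf_s_scores(bf, sg$ann, params), tolerance = 1e-10)
  }
})

test_that("scoring is invariant to abstract order and symmetric by construction", {
  sg <- small_generated(seed = 4L, n = 30L)
  params <- scoring_params(seed = 7)
  tab1 <- score_corpus(sg$ann, params)
  perm <- rev(seq_len(sg$gen$corpus$n))
  corp2 <- corpus(sg$gen$corpus$abstracts[perm])
  ann2 <- annotate(corp2, compile_matcher(sg$gen$dictionary))
  tab2 <- score_corpus(ann2, params)
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))
  expect_true(all(tab1$entity_a < tab1$entity_b))
  expect_true(all(tab1$sentence_count <= tab1$abstract_count))
  expect_true(all(tab1$C > 0) && all(tab1$S >= 0))
})

test_that("adding a co-mention abstract increases only that pair's C", {
  sg <- small_generated(seed = 6L, n = 25L)
  params <- scoring_params()
  before <- count_all_pairs(sg$ann, params)
  pick <- before[1, ]
  extra <- abstract("EXTRA1", "",
                    sprintf("%s with %s appeared once more.",
                            sg$gen$dictionary$canonical_name[
                              match(pick$entity_a, sg$gen$dictionary$entity_id)],
                            sg$gen$dictionary$canonical_name[
                              match(pick$entity_b, sg$gen$dictionary$entity_id)]),
                    year = 2000L)
  corp2 <- corpus(c(sg$gen$corpus$abstracts, list(extra)))
  after <- count_all_pairs(annotate(corp2, compile_matcher(sg$gen$dictionary)),
                           params)
  key_b <- paste(before$entity_a, before$entity_b)
  key_a <- paste(after$entity_a, after$entity_b)
  target <- paste(pick$entity_a, pick$entity_b)
  expect_gt(after$C[key_a == target], before$C[key_b == target])
  same <- setdiff(key_b, target)
  expect_equal(after$C[match(same, key_a)], before$C[match(same, key_b)])
})

test_that("marginal table satisfies its conservation invariants", {
  sg <- small_generated(seed = 8L, n = 60L)
  pairs <- count_all_pairs(sg$ann, scoring_params())
  m <- marginal_table(pairs)   # asserts conservation internally
  ## spot-check one entity marginal against a direct sum
  e <- pairs$entity_a[1]
  t2 <- pairs$type_b[1]
  direct <- sum(pairs$C[(pairs$entity_a == e & pairs$type_b == t2) |
                          (pairs$entity_b == e & pairs$type_a == t2)])
  expect_equal(unname(m$entity_type[paste(e, t2, sep = "\r")]), direct)
})

## reproduce the package's seeded negative draw (test-side mirror of the
## documented sampling contract)
with_seed_sample <- function(values, params) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  sample(values, params$n_negative_samples,
         replace = length(values) < params$n_negative_samples)
}

test_that("significance is standardised against the negative background", {
  params <- scoring_params(n_negative_samples = 5000L, min_type_pair = 3L,
                           seed = 2)
  sg <- small_generated(seed = 10L, n = 60L)
  tab <- score_corpus(sg$ann, params)
  ## z = 0, p = 0.5 when S equals the negative mean: verify via the
  ## reported z/p relationship instead of constructing an exact-mean pair
  expect_equal(tab$p, pnorm(tab$z, lower.tail = FALSE), tolerance = 1e-12)
  ## one-sided threshold logic: z >= 1.65 iff p <= 0.05 (approx point)
  expect_true(all((tab$z >= 1.6449) == (tab$p <= 0.05)))
  ## a pair scoring exactly at the background mean gets z ~ 0
  one <- tab[1, ]
  tp <- paste(pmin(tab$type_a, tab$type_b), pmax(tab$type_a, tab$type_b))
  bg_pairs <- tab[tp == paste(min(one$type_a, one$type_b),
                              max(one$type_a, one$type_b)), ]
  one$S <- mean(with_seed_sample(bg_pairs$S, params))
  zp <- estimate_significance(one, tab, params)
  expect_equal(unname(zp["z"]), 0, tolerance = 1e-9)
  expect_equal(unname(zp["p"]), 0.5, tolerance = 1e-9)
  ## degenerate background: sd = 0
  flat <- tab[1:3, ]
  flat$S <- 5
  flat$type_a <- "gene"; flat$type_b <- "gene"
  zp0 <- estimate_significance(flat[1, ], flat,
                               scoring_params(min_type_pair = 1L, seed = 1))
  expect_equal(unname(zp0["z"]), 0)
  expect_equal(unname(zp0["p"]), 0.5)
  expect_error(estimate_significance(one, tab[0, ], params), "empty")
})

test_that("template flag marks pairs from an external relation list", {
  sg <- small_generated(seed = 12L, n = 40L)
  tab0 <- score_corpus(sg$ann, scoring_params(seed = 1))
  rel <- data.frame(a = tab0$entity_b[2], b = tab0$entity_a[2])  # reversed order
  tab <- score_corpus(sg$ann, scoring_params(seed = 1), template_pairs = rel)
  expect_true(tab$template_flag[2])
  expect_equal(sum(tab$template_flag), 1L)
})

test_that("empty annotation yields an empty score table", {
  d <- entity_dictionary("G1", "gene", "absentgene")
  ann <- annotate(corpus(list(abstract("A1", "", "Nothing to find here."))),
                  compile_matcher(d))
  tab <- score_corpus(ann, scoring_params())
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("C", "S", "z", "p") %in% names(tab)))
})
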