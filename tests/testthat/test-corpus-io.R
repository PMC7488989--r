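medline_fixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0"?>',
    "<PubmedArticleSet>",
    "  <PubmedArticle><MedlineCitation>",
    "    <PMID>1001</PMID>",
    "    <Article>",
    "      <Journal><Title>Mock Med J</Title>",
    "        <JournalIssue><PubDate><Year>2019</Year></PubDate></JournalIssue>",
    "      </Journal>",
    "      <ArticleTitle>First record</ArticleTitle>",
    "      <Abstract><AbstractText>Alpha binds beta. Gamma inhibits delta.</AbstractText></Abstract>",
    "    </Article>",
    "    <CitationCount>7</CitationCount>",
    "  </MedlineCitation></PubmedArticle>",
    "  <PubmedArticle><MedlineCitation>",
    "    <PMID>1002</PMID>",
    "    <Article>",
    "      <Journal><Title>J Synth Biol</Title>",
    "        <JournalIssue><PubDate><Year>2005</Year></PubDate></JournalIssue>",
    "      </Journal>",
    "      <ArticleTitle>No abstract here</ArticleTitle>",
    "    </Article>",
    "  </MedlineCitation></PubmedArticle>",
    "  <PubmedArticle><MedlineCitation>",
    "    <PMID>1003</PMID>",
    "    <Article>",
    "      <Journal><Title>Mock Med J</Title>",
    "        <JournalIssue><PubDate><MedlineDate>1998 Jan-Feb</MedlineDate></PubDate></JournalIssue>",
    "      </Journal>",
    "      <ArticleTitle>Third record</ArticleTitle>",
    "      <Abstract><AbstractText>Single sentence only</AbstractText></Abstract>",
    "    </Article>",
    "  </MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), path)
  path
}

test_that("MEDLINE XML reader skips abstract-less records and parses fields", {
  path <- medline_fixture(tempfile(fileext = ".xml"))
  corp <- read_medline_xml(path)
  expect_equal(corp$n, 2L)
  expect_equal(unname(corp$skip_report["no_abstract"]), 1L)
  a <- corp$abstracts[[1]]
  expect_equal(a$abstract_id, "1001")
  expect_equal(a$year, 2019L)
  expect_equal(a$citation_count, 7L)
  ## title is sentence 0, body contributes 2 sentences
  expect_equal(nrow(a$sentences), 3L)
  b <- corp$abstracts[[2]]
  expect_equal(b$year, 1998L)       # from MedlineDate
  expect_equal(b$citation_count, 0L)
})

test_that("empty article set and malformed XML are handled", {
  path <- tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet></PubmedArticleSet>", path)
  expect_equal(read_medline_xml(path)$n, 0L)
  writeLines("<PubmedArticleSet><oops>", path)
  expect_error(read_medline_xml(path))
  expect_error(read_medline_xml(tempfile()), "not found")
})

test_that("JSONL reader validates schema and matches the XML reader", {
  path <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"1001","title":"First record","abstract":"Alpha binds beta. Gamma inhibits delta.","year":2019,"journal":"Mock Med J","citations":7}',
    '{"id":"1003","title":"Third record","abstract":"Single sentence only","year":1998,"journal":"Mock Med J","citations":0}'), path)
  jl <- read_jsonl_corpus(path)
  expect_equal(jl$n, 2L)
  xml <- read_medline_xml(medline_fixture(tempfile(fileext = ".xml")))
  for (f in c("abstract_id", "title", "body", "year", "citation_count")) {
    expect_equal(lapply(jl$abstracts, `[[`, f), lapply(xml$abstracts, `[[`, f),
                 info = f)
  }
  expect_identical(jl$abstracts[[1]]$sentences, xml$abstracts[[1]]$sentences)

  bad <- tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"x","title":"t","abstract":"a","year":2000,"journal":"j","citations":0}',
    '{"id":"y","title":"t","abstract":"a","journal":"j","citations":0}'), bad)
  expect_error(read_jsonl_corpus(bad), "line 2")
})

test_that("a corpus round-trips through JSONL", {
  corp <- tiny_corpus()
  path <- tempfile(fileext = ".jsonl")
  write_jsonl_corpus(corp, path)
  back <- read_jsonl_corpus(path)
  expect_equal(back$n, corp$n)
  for (i in seq_len(corp$n)) {
    for (f in c("abstract_id", "title", "body", "year", "journal",
                "citation_count", "text")) {
      expect_equal(back$abstracts[[i]][[f]], corp$abstracts[[i]][[f]])
    }
    expect_identical(back$abstracts[[i]]$sentences, corp$abstracts[[i]]$sentences)
  }
})

test_that("sentence segmentation follows the punctuation + guard rules", {
  expect_equal(nrow(segment_sentences("A binds B. C inhibits D.")), 2L)
  expect_equal(nrow(segment_sentences("no terminal punctuation at all")), 1L)
  expect_equal(nrow(segment_sentences("")), 0L)
  ## abbreviation guard: "E." must not split
  spans <- segment_sentences("E. coli grows. It divides.",
                             abbreviations = c("E.", default_abbreviations()))
  expect_equal(nrow(spans), 2L)
  ## "et al." guarded by default: the citation period never splits
  expect_equal(nrow(segment_sentences("See Smith et al. (2019) for details. The effect was large.")), 2L)
  expect_equal(nrow(segment_sentences("Reported by Smith et al. in 2019. It was large.")), 2L)
})

test_that("sentence spans cover all non-whitespace characters in order", {
  texts <- c("One sentence. Another one! A third? Yes.",
             "Weird   spacing.   Next sentence here.",
             "Trailing text without stop")
  for (txt in texts) {
    spans <- segment_sentences(txt)
    expect_true(all(diff(spans[, "start"]) > 0))
    expect_true(all(spans[, "end"] <= nchar(txt)))
    covered <- unlist(lapply(seq_len(nrow(spans)), function(i) {
      seq(spans[i, "start"] + 1L, spans[i, "end"])
    }))
    chars <- strsplit(txt, "")[[1]]
    non_ws <- which(!grepl("[[:space:]]", chars))
    expect_true(all(non_ws %in% covered), info = txt)
    ## spans reconstruct the original text up to inter-span whitespace
    rebuilt <- paste(substring(txt, spans[, "start"] + 1L, spans[, "end"]),
                     collapse = " ")
    expect_equal(gsub("[[:space:]]+", " ", rebuilt),
                 gsub("[[:space:]]+", " ", trimws(txt)))
  }
})

test_that("yearly totals count known-year abstracts only", {
  corp <- tiny_corpus()
  expect_equal(yearly_totals(corp), c("2001" = 2L, "2003" = 1L))
  expect_length(yearly_totals(corpus(list())), 0L)
  ## unknown year is excluded but the abstract is retained
  corp2 <- corpus(list(
    abstract("U1", "t", "Body text.", year = NA),
    abstract("U2", "t", "Body text.", year = 2000L)))
  expect_equal(sum(yearly_totals(corp2)), 1L)
  expect_equal(corp2$n, 2L)
})

test_that("generator yearly counts match uniform weights", {
  spec <- generator_spec(n_abstracts = 100L, year_range = c(1990L, 1999L),
                         entity_counts = c(gene = 5L), n_planted_pairs = 0L,
                         n_planted_trends = 0L, seed = 3L)
  gen <- generate_corpus(spec)
  tot <- yearly_totals(gen$corpus)
  expect_equal(sum(tot), 100L)
  chisq <- sum((tot - 10)^2 / 10)
  expect_lt(chisq, qchisq(0.999, df = 9))
})
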