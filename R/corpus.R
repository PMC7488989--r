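## corpus_io: abstract corpora, sentence segmentation, yearly totals.
##
## An abstract's analysable text is title + "\n" + body; all character
## offsets in the package are 0-based, half-open over that string.

#' Construct a single abstract record
#'
#' @param abstract_id Record identifier (PubMed PMID when available).
#' @param title Title text (may be empty).
#' @param body Abstract body text.
#' @param year Publication year (4-digit integer) or `NA` when unknown.
#' @param journal Journal name.
#' @param citation_count Non-negative citation count (default 0).
#' @param include_title Treat the title as sentence index 0 (default TRUE).
#' @param abbreviations Abbreviation guard list for sentence segmentation.
#' @return A list of class `"abstract"` with fields `abstract_id`, `title`,
#'   `body`, `year`, `journal`, `citation_count`, `text` (title, newline,
#'   body) and `sentences` (integer matrix of 0-based half-open spans).
#' @export
abstract <- function(abstract_id, title, body, year = NA_integer_,
                     journal = "", citation_count = 0L,
                     include_title = TRUE,
                     abbreviations = default_abbreviations()) {
  abstract_id <- as.character(abstract_id)
  title <- as.character(title %||% "")
  body <- as.character(body)
  if (is.na(title)) title <- ""
  if (!is.na(year)) {
    year <- as.integer(year)
    if (!is.na(year) && (year < 1000L || year > 9999L)) {
      stop_("abstract ", abstract_id, ": year must be a 4-digit integer or NA")
    }
  } else {
    year <- NA_integer_
  }
  citation_count <- as.integer(citation_count)
  if (is.na(citation_count) || citation_count < 0L) {
    stop_("abstract ", abstract_id, ": citation_count must be >= 0")
  }
  text <- paste0(title, "\n", body)
  offset <- nchar(title) + 1L
  spans <- segment_sentences(body, abbreviations = abbreviations)
  if (nrow(spans) > 0L) spans <- spans + offset
  if (include_title && nzchar(trimws(title))) {
    tspan <- matrix(c(0L, nchar(title)), nrow = 1L)
    spans <- rbind(tspan, spans)
  }
  colnames(spans) <- c("start", "end")
  structure(list(abstract_id = abstract_id, title = title, body = body,
                 year = year, journal = as.character(journal),
                 citation_count = citation_count, text = text,
                 sentences = spans),
            class = "abstract")
}

#' Construct a corpus from a list of abstracts
#'
#' @param abstracts List of [abstract()] records.
#' @param skip_report Named integer vector describing skipped input records.
#' @return An object of class `"corpus"`: list with `abstracts` and `n`.
#' @export
corpus <- function(abstracts, skip_report = c(no_abstract = 0L)) {
  ids <- vapply(abstracts, function(a) a$abstract_id, "")
  if (anyDuplicated(ids)) {
    stop_("duplicate abstract_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(abstracts = abstracts, n = length(abstracts),
                 skip_report = skip_report),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  yrs <- corpus_years(x)
  cat("corpus of", x$n, "abstracts")
  if (length(yrs)) cat(",", min(yrs), "-", max(yrs))
  cat("\n")
  if (any(x$skip_report > 0L)) {
    cat("skipped on read:",
        paste(names(x$skip_report), x$skip_report, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

corpus_years <- function(corpus) {
  y <- vapply(corpus$abstracts, function(a) a$year, integer(1))
  y[!is.na(y)]
}

#' Default abbreviation guard list for sentence segmentation
#'
#' Strings ending in a period that must not terminate a sentence.
#' @return Character vector.
#' @export
default_abbreviations <- function() {
  c("e.g.", "i.e.", "cf.", "vs.", "ca.", "Fig.", "Figs.", "Eq.", "No.",
    "et al.", "al.", "Dr.", "St.", "approx.", "resp.")
}

#' Segment text into sentence spans
#'
#' Rule-based splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an upper-case letter or digit, unless the text up to and
#' including the period ends with an entry of the abbreviation guard list.
#' Spans are 0-based half-open and trimmed of surrounding whitespace, so
#' they cover every non-whitespace character of the input.
#'
#' @param text Character scalar.
#' @param abbreviations Guard list, see [default_abbreviations()].
#' @return Integer matrix with columns `start`, `end`; zero rows for
#'   empty/whitespace-only input.
#' @export
segment_sentences <- function(text, abbreviations = default_abbreviations()) {
  empty <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  m <- gregexpr("[.!?]+(?=[[:space:]]+[[:upper:][:digit:]])", text, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L   # 1-based last punct char
    for (e in ends) {
      prefix <- substr(text, 1L, e)
      guarded <- any(vapply(abbreviations, function(g) endsWith(prefix, g), logical(1)))
      if (!guarded) breaks <- c(breaks, e)
    }
  }
  starts1 <- c(1L, breaks + 1L)                 # 1-based candidate starts
  ends1 <- c(breaks, nchar(text))               # 1-based inclusive ends
  spans <- matrix(integer(0), ncol = 2L)
  for (i in seq_along(starts1)) {
    seg <- substr(text, starts1[i], ends1[i])
    lead <- nchar(seg) - nchar(sub("^[[:space:]]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[[:space:]]+$", "", seg))
    s <- starts1[i] + lead
    e <- ends1[i] - trail
    if (e >= s) spans <- rbind(spans, c(s - 1L, e))  # to 0-based half-open
  }
  if (nrow(spans) == 0L) return(empty)
  colnames(spans) <- c("start", "end")
  spans
}

#' Read a MEDLINE/PubMed XML corpus
#'
#' Parses a `PubmedArticleSet` subset: PMID, ArticleTitle, AbstractText
#' (multiple nodes concatenated), Journal Title, publication year (the
#' earliest complete date among PubDate/Year and MedlineDate), and an
#' optional `CitationCount` element (0 when absent). Records without
#' abstract text are skipped and counted in the corpus skip report.
#'
#' @param path XML file path.
#' @inheritParams abstract
#' @return A [corpus()].
#' @export
read_medline_xml <- function(path, include_title = TRUE,
                             abbreviations = default_abbreviations()) {
  if (!file.exists(path)) stop_("file not found: ", path)
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
  abstracts <- list()
  skipped <- 0L
  for (node in arts) {
    pmid <- xml2::xml_text(xml2::xml_find_first(node, ".//PMID"))
    body_nodes <- xml2::xml_find_all(node, ".//Abstract/AbstractText")
    body <- paste(trimws(xml2::xml_text(body_nodes)), collapse = " ")
    if (!nzchar(trimws(body))) {
      skipped <- skipped + 1L
      next
    }
    title <- xml2::xml_text(xml2::xml_find_first(node, ".//ArticleTitle"))
    if (is.na(title)) title <- ""
    journal <- xml2::xml_text(xml2::xml_find_first(node, ".//Journal/Title"))
    if (is.na(journal)) journal <- ""
    year <- parse_medline_year(node)
    cites <- xml2::xml_text(xml2::xml_find_first(node, ".//CitationCount"))
    cites <- if (is.na(cites)) 0L else as.integer(cites)
    abstracts[[length(abstracts) + 1L]] <-
      abstract(pmid, title, body, year = year, journal = journal,
               citation_count = cites, include_title = include_title,
               abbreviations = abbreviations)
  }
  corpus(abstracts, skip_report = c(no_abstract = skipped))
}

parse_medline_year <- function(node) {
  years <- integer(0)
  for (y in xml2::xml_find_all(node, ".//PubDate/Year")) {
    yy <- suppressWarnings(as.integer(xml2::xml_text(y)))
    if (!is.na(yy)) years <- c(years, yy)
  }
  md <- xml2::xml_text(xml2::xml_find_first(node, ".//PubDate/MedlineDate"))
  if (!is.na(md)) {
    yy <- suppressWarnings(as.integer(regmatches(md, regexpr("[0-9]{4}", md))))
    if (length(yy) && !is.na(yy)) years <- c(years, yy)
  }
  if (length(years)) min(years) else NA_integer_
}

#' Read a JSONL corpus
#'
#' One JSON object per line with keys `id`, `title`, `abstract`, `year`,
#' `journal`, `citations`. Produces the same corpus value as
#' [read_medline_xml()] on equivalent content; records with empty abstract
#' text are skipped and counted.
#'
#' @param path JSONL file path.
#' @inheritParams abstract
#' @return A [corpus()].
#' @export
read_jsonl_corpus <- function(path, include_title = TRUE,
                              abbreviations = default_abbreviations()) {
  if (!file.exists(path)) stop_("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  required <- c("id", "title", "abstract", "year", "journal", "citations")
  abstracts <- list()
  skipped <- 0L
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop_("line ", i, ": malformed JSON: ",
                                              conditionMessage(e)))
    missing <- setdiff(required, names(rec))
    if (length(missing)) {
      stop_("line ", i, ": missing field(s): ", paste(missing, collapse = ", "))
    }
    if (!nzchar(trimws(rec$abstract %||% ""))) {
      skipped <- skipped + 1L
      next
    }
    year <- rec$year
    year <- if (is.null(year) || is.na(year)) NA_integer_ else as.integer(year)
    abstracts[[length(abstracts) + 1L]] <-
      abstract(rec$id, rec$title, rec$abstract, year = year,
               journal = rec$journal %||% "",
               citation_count = rec$citations %||% 0L,
               include_title = include_title, abbreviations = abbreviations)
  }
  corpus(abstracts, skip_report = c(no_abstract = skipped))
}

#' Write a corpus as JSONL
#'
#' @param corpus A [corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jsonl_corpus <- function(corpus, path) {
  lines <- vapply(corpus$abstracts, function(a) {
    jsonlite::toJSON(list(id = a$abstract_id, title = a$title,
                          abstract = a$body,
                          year = if (is.na(a$year)) NA else a$year,
                          journal = a$journal,
                          citations = a$citation_count),
                     auto_unbox = TRUE, na = "null", digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a corpus as a MEDLINE-style XML dialect
#'
#' Emits the `PubmedArticleSet` subset that [read_medline_xml()] consumes,
#' including the non-standard `CitationCount` element.
#'
#' @param corpus A [corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(corpus, path) {
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (a in corpus$abstracts) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", a$abstract_id)
    article <- xml2::xml_add_child(cit, "Article")
    journal <- xml2::xml_add_child(article, "Journal")
    xml2::xml_add_child(journal, "Title", a$journal)
    issue <- xml2::xml_add_child(journal, "JournalIssue")
    pd <- xml2::xml_add_child(issue, "PubDate")
    if (!is.na(a$year)) xml2::xml_add_child(pd, "Year", as.character(a$year))
    xml2::xml_add_child(article, "ArticleTitle", a$title)
    abs_node <- xml2::xml_add_child(article, "Abstract")
    xml2::xml_add_child(abs_node, "AbstractText", a$body)
    xml2::xml_add_child(cit, "CitationCount", as.character(a$citation_count))
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Per-year article totals
#'
#' @param corpus A [corpus()].
#' @return Named integer vector (names = years present in the corpus,
#'   sorted); abstracts with unknown year are omitted.
#' @export
yearly_totals <- function(corpus) {
  y <- corpus_years(corpus)
  if (!length(y)) return(stats::setNames(integer(0), character(0)))
  tab <- table(y)
  stats::setNames(as.integer(tab), names(tab))
}
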