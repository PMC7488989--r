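## query_engine: boolean entity/concept/keyword queries over an annotated
## corpus, with digest filtering and sorting.
##
## Query semantics: every include clause must be satisfied (fixed entity:
## mentioned; type wildcard: some entity of that type other than the
## query's fixed entities of the same type is mentioned), no exclude
## clause may be satisfied, every free keyword group must have at least
## one member in the abstract, every excluded group none, and each bound
## keyword group must co-occur in one sentence with a mention of its
## clause's matched entity. Keywords match case-insensitively at token
## boundaries, without stemming.

#' Build a query clause
#'
#' @param mode `"include"` or `"exclude"`.
#' @param entity Fixed entity id (exactly one of `entity`/`type`).
#' @param type Type wildcard ("any entity of this type").
#' @param bound_keywords List of character vectors; each group must have a
#'   member in the same sentence as the clause's matched entity (OR within
#'   a group, AND across groups).
#' @return A list of class `"query_clause"`.
#' @export
query_clause <- function(mode = c("include", "exclude"), entity = NULL,
                         type = NULL, bound_keywords = list()) {
  mode <- match.arg(mode)
  if (is.null(entity) == is.null(type)) {
    stop_("a clause needs exactly one of `entity` or `type`")
  }
  if (length(bound_keywords) && !all(lengths(bound_keywords) > 0)) {
    stop_("bound keyword groups must be non-empty")
  }
  structure(list(mode = mode, entity = entity, type = type,
                 bound_keywords = lapply(bound_keywords, as.character)),
            class = "query_clause")
}

#' Build a corpus query
#'
#' @param clauses List of [query_clause()]s; at least one include clause
#'   with a fixed entity is required.
#' @param free_groups List of keyword groups that must match anywhere in
#'   the abstract (OR within a group, AND across groups).
#' @param excluded_groups List of keyword groups none of whose members may
#'   appear in the abstract (logical NOT).
#' @return A list of class `"corpus_query"`.
#' @export
corpus_query <- function(clauses, free_groups = list(), excluded_groups = list()) {
  if (inherits(clauses, "query_clause")) clauses <- list(clauses)
  problems <- character(0)
  if (!length(clauses) ||
      !any(vapply(clauses, function(cl) cl$mode == "include" && !is.null(cl$entity),
                  logical(1)))) {
    problems <- c(problems, "query must contain at least one include clause with a fixed entity")
  }
  for (g in c(free_groups, excluded_groups)) {
    if (!length(g) || !all(nzchar(g))) {
      problems <- c(problems, "keyword groups must be non-empty")
    }
  }
  if (length(problems)) stop_("invalid query: ", paste(unique(problems), collapse = "; "))
  structure(list(clauses = clauses,
                 free_groups = lapply(free_groups, as.character),
                 excluded_groups = lapply(excluded_groups, as.character)),
            class = "corpus_query")
}

#' Read a query from JSON
#'
#' Schema: `{"clauses": [{"mode": "include", "entity": "D1"} | {"mode":
#' "exclude", "type": "disease", "bound_keywords": [["kw1","kw2"]]}],
#' "free_groups": [["comorbid","comorbidity"]], "excluded_groups": []}`.
#'
#' @param path JSON file path.
#' @return A [corpus_query()].
#' @export
read_query_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  clauses <- lapply(spec$clauses, function(cl) {
    query_clause(mode = cl$mode %||% "include",
                 entity = cl$entity, type = cl$type,
                 bound_keywords = lapply(cl$bound_keywords %||% list(), unlist))
  })
  corpus_query(clauses,
               free_groups = lapply(spec$free_groups %||% list(), unlist),
               excluded_groups = lapply(spec$excluded_groups %||% list(), unlist))
}

query_fixed_entities <- function(query) {
  unlist(lapply(query$clauses, function(cl) cl$entity), use.names = FALSE) %||% character(0)
}

query_has_keywords <- function(query) {
  length(query$free_groups) > 0L || length(query$excluded_groups) > 0L ||
    any(vapply(query$clauses, function(cl) length(cl$bound_keywords) > 0L, logical(1)))
}

keyword_in_text <- function(keyword, text) {
  grepl(boundary_pattern(keyword), text, perl = TRUE, ignore.case = TRUE)
}

group_in_text <- function(group, text) {
  any(vapply(group, keyword_in_text, logical(1), text = text))
}

sentence_texts <- function(abstract) {
  spans <- abstract$sentences
  if (!nrow(spans)) return(character(0))
  substring(abstract$text, spans[, "start"] + 1L, spans[, "end"])
}

## entities of `type` satisfying a clause's bound keyword groups in `ab`
clause_matched_entities <- function(cl, ab, mentions, fixed_ids) {
  if (!is.null(cl$entity)) {
    cand <- cl$entity
    present <- cl$entity %in% mentions$entity_id
    if (!present) return(character(0))
  } else {
    cand <- setdiff(unique(mentions$entity_id[mentions$entity_type == cl$type]),
                    fixed_ids)
    if (!length(cand)) return(character(0))
  }
  if (!length(cl$bound_keywords)) return(cand)
  sents <- sentence_texts(ab)
  ok <- vapply(cand, function(e) {
    sidx <- unique(mentions$sentence_index[mentions$entity_id == e]) + 1L
    all(vapply(cl$bound_keywords, function(g) {
      any(vapply(sidx, function(s) group_in_text(g, sents[s]), logical(1)))
    }, logical(1)))
  }, logical(1))
  cand[ok]
}

#' Evaluate a boolean query over an annotated corpus
#'
#' See the module header for the exact semantics. The result is capped at
#' `cap_plain` digests (default 5000) when the query carries no keyword
#' groups and `cap_keywords` (default 30000) otherwise; truncation keeps
#' the current order's head and sets the `truncated` attribute. The exact
#' pre-cap count is reported in the `matching_total` attribute.
#'
#' @param query A [corpus_query()].
#' @param ann An [annotate()]d corpus.
#' @param cap_plain,cap_keywords Display caps.
#' @return Data frame of class `"digest_list"`: `abstract_id`, `year`,
#'   `journal`, `citation_count`, `n_mentions`. Attributes: `matched`
#'   (named list: query-matching entity ids per abstract), `wildcard_matched`
#'   (entity ids matched by wildcard clauses overall), `query`,
#'   `truncated`, `matching_total`.
#' @export
evaluate_query <- function(query, ann, cap_plain = 5000L, cap_keywords = 30000L) {
  stopifnot(inherits(query, "corpus_query"))
  fixed_ids <- query_fixed_entities(query)
  rows <- list()
  matched <- list()
  wildcard_all <- character(0)
  for (ab in ann$corpus$abstracts) {
    idx <- ann$by_abstract[[ab$abstract_id]]
    mentions <- if (is.null(idx)) ann$mentions[0, ] else ann$mentions[idx, , drop = FALSE]
    if (!nrow(mentions)) next
    ok <- TRUE
    ab_matched <- character(0)
    ab_wild <- character(0)
    for (cl in query$clauses) {
      hits <- clause_matched_entities(cl, ab, mentions, fixed_ids)
      if (cl$mode == "include") {
        if (!length(hits)) { ok <- FALSE; break }
        ab_matched <- c(ab_matched, hits)
        if (is.null(cl$entity)) ab_wild <- c(ab_wild, hits)
      } else if (length(hits)) { ok <- FALSE; break }
    }
    if (!ok) next
    for (g in query$free_groups) {
      if (!group_in_text(g, ab$text)) { ok <- FALSE; break }
    }
    if (ok) for (g in query$excluded_groups) {
      if (group_in_text(g, ab$text)) { ok <- FALSE; break }
    }
    if (!ok) next
    rows[[length(rows) + 1L]] <- data.frame(
      abstract_id = ab$abstract_id, year = ab$year, journal = ab$journal,
      citation_count = ab$citation_count, n_mentions = nrow(mentions),
      stringsAsFactors = FALSE)
    matched[[ab$abstract_id]] <- sort(unique(ab_matched))
    wildcard_all <- c(wildcard_all, ab_wild)
  }
  digests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(abstract_id = character(0), year = integer(0),
               journal = character(0), citation_count = integer(0),
               n_mentions = integer(0), stringsAsFactors = FALSE)
  cap <- if (query_has_keywords(query)) cap_keywords else cap_plain
  new_digest_list(digests, matched, sort(unique(wildcard_all)), query, cap)
}

new_digest_list <- function(digests, matched, wildcard, query, cap) {
  total <- nrow(digests)
  truncated <- total > cap
  if (truncated) {
    digests <- digests[seq_len(cap), , drop = FALSE]
    matched <- matched[digests$abstract_id]
  }
  rownames(digests) <- NULL
  structure(digests, matched = matched, wildcard_matched = wildcard,
            query = query, truncated = truncated, matching_total = total,
            class = c("digest_list", "data.frame"))
}

#' @export
print.digest_list <- function(x, ...) {
  cat("digest list:", nrow(x), "of", attr(x, "matching_total"),
      "matching abstracts",
      if (isTRUE(attr(x, "truncated"))) "(truncated)" else "", "\n")
  invisible(x)
}

#' Filter digests by recognition quality and s-score
#'
#' Entities below `min_quality` are removed from the visible entity set.
#' Wildcard-matched entities whose s-score against *every* fixed query
#' entity is below `min_s` are removed; digests left without a qualifying
#' wildcard match (while the query demands one) are dropped.
#'
#' @param digests A [evaluate_query()] result.
#' @param ann The annotated corpus.
#' @param scores A [score_corpus()] table.
#' @param min_quality Recognition-quality threshold, 1-5 (default 1).
#' @param min_s s-score threshold (default 0 = no filtering).
#' @return List with `digests` (filtered digest_list) and
#'   `visible_entities` (character vector).
#' @export
apply_filters <- function(digests, ann, scores, min_quality = 1L, min_s = 0) {
  if (min_quality < 1L || min_quality > 5L) stop_("min_quality must be in 1..5")
  query <- attr(digests, "query")
  matched <- attr(digests, "matched")
  fixed_ids <- query_fixed_entities(query)
  wildcard <- attr(digests, "wildcard_matched")
  visible <- unique(unlist(matched, use.names = FALSE)) %||% character(0)
  qual <- ann$dictionary$quality[match(visible, ann$dictionary$entity_id)]
  visible <- visible[qual >= min_quality]
  if (min_s > 0 && length(wildcard)) {
    keep_wild <- vapply(wildcard, function(w) {
      s <- vapply(fixed_ids, function(f) pair_s(scores, w, f), numeric(1))
      any(!is.na(s) & s >= min_s)
    }, logical(1))
    visible <- setdiff(visible, wildcard[!keep_wild])
  }
  has_wildcard <- any(vapply(query$clauses,
                             function(cl) cl$mode == "include" && is.null(cl$entity),
                             logical(1)))
  keep <- vapply(digests$abstract_id, function(id) {
    vis <- intersect(matched[[id]], visible)
    if (has_wildcard && !length(intersect(vis, wildcard))) return(FALSE)
    TRUE
  }, logical(1))
  out <- digests[keep, , drop = FALSE]
  matched <- lapply(matched[out$abstract_id], intersect, visible)
  dl <- new_digest_list(as.data.frame(out), matched,
                        intersect(wildcard, visible), query,
                        cap = nrow(out) + 1L)
  list(digests = dl, visible_entities = visible)
}

#' Read a journal H-index table
#'
#' TSV with columns `journal`, `h_index`. Journals absent from the table
#' sort with H-index 0.
#'
#' @param path TSV file path.
#' @return Named integer vector.
#' @export
read_hindex <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  stats::setNames(as.integer(tab$h_index), tab$journal)
}

#' Attach digest interest scores
#'
#' Computes the [digest_score()] of every digest from the trend table and
#' stores it as a `digest_score` column.
#'
#' @param digests A [evaluate_query()] result.
#' @param ann The annotated corpus.
#' @param trends A [trend_table()].
#' @param all_mapped Average over all mapped entities rather than only the
#'   query-matching ones.
#' @return The digest list with a `digest_score` column.
#' @export
add_digest_scores <- function(digests, ann, trends, all_mapped = FALSE) {
  matched <- attr(digests, "matched")
  digests$digest_score <- vapply(digests$abstract_id, function(id) {
    digest_score(id, ann, trends, matched[[id]] %||% character(0),
                 all_mapped = all_mapped)$score
  }, numeric(1))
  digests
}

#' Sort digests
#'
#' Stable sort by publication date, journal H-index, citation count or
#' digest score; ties are broken by `abstract_id`. Journals missing from
#' the H-index table sort as H = 0; unknown years sort last.
#'
#' @param digests A digest list.
#' @param key One of `"date"`, `"h_index"`, `"citations"`, `"digest_score"`.
#' @param order `"asc"` or `"desc"`.
#' @param hindex Named vector from [read_hindex()] (required for
#'   `key = "h_index"`).
#' @return The permuted digest list.
#' @export
sort_digests <- function(digests, key = c("date", "h_index", "citations",
                                          "digest_score"),
                         order = c("desc", "asc"), hindex = NULL) {
  key <- match.arg(key)
  order <- match.arg(order)
  v <- switch(key,
    date = as.numeric(digests$year),
    h_index = {
      h <- if (is.null(hindex)) rep(0L, nrow(digests)) else
        as.integer(hindex[digests$journal])
      ifelse(is.na(h), 0L, h)
    },
    citations = as.numeric(digests$citation_count),
    digest_score = {
      if (is.null(digests$digest_score)) stop_("run add_digest_scores() first")
      digests$digest_score
    })
  v[is.na(v)] <- -Inf
  ord <- order(if (order == "desc") -v else v, digests$abstract_id)
  out <- digests[ord, , drop = FALSE]
  attributes(out)[c("matched", "wildcard_matched", "query", "truncated",
                    "matching_total")] <-
    attributes(digests)[c("matched", "wildcard_matched", "query", "truncated",
                          "matching_total")]
  rownames(out) <- NULL
  out
}
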