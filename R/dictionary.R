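## entity_dictionary: typed dictionaries with synonyms and recognition
## quality, plus dictionary-based annotation of corpus text.

#' Default entity type vocabulary
#'
#' The 13 object types recognised by default; [load_dictionary()] and
#' [entity_dictionary()] accept a custom vocabulary.
#' @return Character vector of type labels.
#' @export
default_entity_types <- function() {
  c("gene", "protein", "metabolite", "microRNA", "biological_process",
    "phenotype", "drug", "side_effect", "disease", "cell", "organism",
    "pathway", "tissue")
}

#' Build an entity dictionary from vectors
#'
#' @param entity_id Unique entity identifiers.
#' @param entity_type Type label per entity (must be in `types`).
#' @param canonical_name Canonical name per entity.
#' @param synonyms List of character vectors, one per entity. The canonical
#'   name is added when absent.
#' @param quality Integer recognition-quality grade, 1 (lowest) to 5.
#' @param external_refs Optional list of database-id vectors.
#' @param types Allowed type vocabulary.
#' @return A data frame of class `"entity_dictionary"` with list-columns
#'   `synonyms` and `external_refs`.
#' @export
entity_dictionary <- function(entity_id, entity_type, canonical_name,
                              synonyms = NULL, quality = 3L,
                              external_refs = NULL,
                              types = default_entity_types()) {
  n <- length(entity_id)
  entity_id <- as.character(entity_id)
  entity_type <- as.character(entity_type)
  canonical_name <- as.character(canonical_name)
  quality <- as.integer(rep_len(quality, n))
  if (is.null(synonyms)) synonyms <- as.list(canonical_name)
  if (is.null(external_refs)) external_refs <- rep(list(character(0)), n)
  if (anyDuplicated(entity_id)) {
    stop_("duplicate entity_id: ",
          paste(unique(entity_id[duplicated(entity_id)]), collapse = ", "))
  }
  bad_type <- which(!entity_type %in% types)
  if (length(bad_type)) {
    stop_("row ", bad_type[1], ": unknown entity_type '", entity_type[bad_type[1]], "'")
  }
  bad_q <- which(is.na(quality) | quality < 1L | quality > 5L)
  if (length(bad_q)) {
    stop_("row ", bad_q[1], ": quality must be an integer in 1..5")
  }
  synonyms <- lapply(seq_len(n), function(i) {
    s <- unique(as.character(synonyms[[i]]))
    s <- s[nzchar(s)]
    if (!canonical_name[i] %in% s) s <- c(canonical_name[i], s)
    s
  })
  d <- data.frame(entity_id = entity_id, entity_type = entity_type,
                  canonical_name = canonical_name, quality = quality,
                  stringsAsFactors = FALSE)
  d$synonyms <- synonyms
  d$external_refs <- external_refs
  class(d) <- c("entity_dictionary", "data.frame")
  d
}

#' Load an entity dictionary from TSV
#'
#' Expected columns: `entity_id`, `entity_type`, `canonical_name`,
#' `synonyms` (pipe-separated), `quality`; optional `external_refs`
#' (pipe-separated). Every record is validated: unknown types, qualities
#' outside 1..5 and duplicate ids raise errors naming the offending row.
#'
#' @param path TSV file path.
#' @param types Allowed type vocabulary.
#' @return An [entity_dictionary()].
#' @export
load_dictionary <- function(path, types = default_entity_types()) {
  if (!file.exists(path)) stop_("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  required <- c("entity_id", "entity_type", "canonical_name", "synonyms", "quality")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop_("dictionary lacks column(s): ", paste(missing, collapse = ", "))
  refs <- if ("external_refs" %in% names(tab)) {
    lapply(strsplit(tab$external_refs, "|", fixed = TRUE),
           function(x) x[nzchar(x)])
  } else NULL
  entity_dictionary(tab$entity_id, tab$entity_type, tab$canonical_name,
                    synonyms = strsplit(tab$synonyms, "|", fixed = TRUE),
                    quality = suppressWarnings(as.integer(tab$quality)),
                    external_refs = refs, types = types)
}

#' Write an entity dictionary as TSV
#'
#' @param dictionary An [entity_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  tab <- data.frame(entity_id = dictionary$entity_id,
                    entity_type = dictionary$entity_type,
                    canonical_name = dictionary$canonical_name,
                    synonyms = vapply(dictionary$synonyms, paste, "", collapse = "|"),
                    quality = dictionary$quality,
                    external_refs = vapply(dictionary$external_refs, paste, "", collapse = "|"),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compile a dictionary into a phrase matcher
#'
#' Every synonym is recognised as a token-boundary-delimited phrase (token
#' boundaries = alphanumeric runs; hyphens inside synonyms are literal).
#' Matching is case-insensitive by default, except that synonyms shorter
#' than `min_case_length` characters match case-sensitively — this guards
#' short gene symbols ("PGF") against spurious lower-case hits. Two
#' entities of the same type sharing an identical normalised synonym make
#' the dictionary ambiguous: compilation fails with a conflict report.
#'
#' @param dictionary An [entity_dictionary()].
#' @param case_sensitive Force case-sensitive matching for all synonyms.
#' @param min_case_length Synonyms shorter than this match case-sensitively
#'   (default 4).
#' @return An object of class `"entity_matcher"`.
#' @export
compile_matcher <- function(dictionary, case_sensitive = FALSE,
                            min_case_length = 4L) {
  if (!nrow(dictionary)) stop_("empty dictionary")
  syn <- data.frame(
    synonym = unlist(dictionary$synonyms, use.names = FALSE),
    entity_id = rep(dictionary$entity_id, lengths(dictionary$synonyms)),
    entity_type = rep(dictionary$entity_type, lengths(dictionary$synonyms)),
    stringsAsFactors = FALSE)
  syn$ci <- !case_sensitive & nchar(syn$synonym) >= min_case_length
  syn$norm <- ifelse(syn$ci, tolower(syn$synonym), syn$synonym)
  key <- paste(syn$entity_type, syn$norm, sep = "\r")
  n_ent <- tapply(syn$entity_id, key, function(x) length(unique(x)))
  bad <- names(n_ent)[n_ent > 1L]
  if (length(bad)) {
    report <- paste(gsub("\r", ": ", bad, fixed = TRUE), collapse = "; ")
    stop_("ambiguous dictionary (same-type synonym conflicts): ", report)
  }
  ## deduplicate identical (entity, synonym) rows
  syn <- syn[!duplicated(paste(syn$entity_id, syn$norm)), , drop = FALSE]
  syn$pattern <- boundary_pattern(syn$synonym)
  rownames(syn) <- NULL
  structure(list(table = syn,
                 dictionary = dictionary,
                 case_sensitive = case_sensitive,
                 min_case_length = as.integer(min_case_length)),
            class = "entity_matcher")
}

#' @export
print.entity_matcher <- function(x, ...) {
  cat("entity matcher:", nrow(x$dictionary), "entities,",
      nrow(x$table), "synonym patterns\n")
  invisible(x)
}

#' Resolve overlapping candidate matches within one sentence
#'
#' Leftmost-longest wins among overlapping candidates of the *same* entity
#' type; overlaps across different types are all kept; candidates with an
#' identical span and type are tie-broken by lexicographic `entity_id`
#' (first wins).
#'
#' @param candidates Data frame with columns `start`, `end` (0-based
#'   half-open), `entity_id`, `entity_type` (plus any others, carried
#'   through), all within one sentence.
#' @return The retained subset, ordered by `start`.
#' @export
resolve_overlaps <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  keep <- logical(nrow(candidates))
  for (tp in unique(candidates$entity_type)) {
    idx <- which(candidates$entity_type == tp)
    sub <- candidates[idx, , drop = FALSE]
    ord <- order(sub$start, -(sub$end - sub$start), sub$entity_id)
    last_end <- -1L
    for (o in ord) {
      if (sub$start[o] >= last_end) {
        keep[idx[o]] <- TRUE
        last_end <- sub$end[o]
      }
    }
  }
  out <- candidates[keep, , drop = FALSE]
  out[order(out$start, out$entity_type, out$entity_id), , drop = FALSE]
}

#' Annotate a corpus with dictionary mentions
#'
#' Scans each abstract's text (title + body) with the compiled matcher and
#' emits one mention per retained match. Matches that would cross a
#' sentence boundary are discarded; overlaps are resolved per sentence by
#' [resolve_overlaps()]. The result is deterministic: the same corpus and
#' dictionary always produce the identical mention table.
#'
#' @param corpus A [corpus()].
#' @param matcher An [compile_matcher()] result.
#' @return An object of class `"annotated_corpus"`: list with `corpus`,
#'   `dictionary`, `mentions` (data frame: `abstract_id`, `entity_id`,
#'   `entity_type`, `sentence_index`, `start`, `end`, `surface`) and
#'   index lists `by_abstract`, `by_entity` (row indices into `mentions`).
#' @export
annotate <- function(corpus, matcher) {
  texts <- vapply(corpus$abstracts, function(a) a$text, "")
  ids <- vapply(corpus$abstracts, function(a) a$abstract_id, "")
  tab <- matcher$table
  ## prefilter with fixed-string search to keep the regex pass cheap
  lowered <- tolower(texts)
  rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    needle <- if (tab$ci[i]) tolower(tab$synonym[i]) else tab$synonym[i]
    hay <- if (tab$ci[i]) lowered else texts
    cand <- which(grepl(needle, hay, fixed = TRUE))
    if (!length(cand)) next
    m <- gregexpr(tab$pattern[i], texts[cand], perl = TRUE,
                  ignore.case = tab$ci[i])
    hits <- lapply(seq_along(cand), function(k) {
      mk <- m[[k]]
      if (mk[1] == -1L) return(NULL)
      data.frame(abstract = cand[k],
                 start = as.integer(mk) - 1L,
                 end = as.integer(mk) + attr(mk, "match.length") - 1L,
                 stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits) || !nrow(hits)) next
    hits$entity_id <- tab$entity_id[i]
    hits$entity_type <- tab$entity_type[i]
    rows[[i]] <- hits
  }
  cand <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  empty <- data.frame(abstract_id = character(0), entity_id = character(0),
                      entity_type = character(0), sentence_index = integer(0),
                      start = integer(0), end = integer(0),
                      surface = character(0), stringsAsFactors = FALSE)
  if (is.null(cand) || !nrow(cand)) {
    return(new_annotated_corpus(corpus, matcher$dictionary, empty))
  }
  ## locate the sentence containing each candidate; drop boundary-crossers
  out <- vector("list", length(unique(cand$abstract)))
  u <- 0L
  for (ab in unique(cand$abstract)) {
    spans <- corpus$abstracts[[ab]]$sentences
    sub <- cand[cand$abstract == ab, , drop = FALSE]
    if (!nrow(spans)) next
    sent <- rep(NA_integer_, nrow(sub))
    for (j in seq_len(nrow(sub))) {
      hit <- which(spans[, "start"] <= sub$start[j] & sub$end[j] <= spans[, "end"])
      if (length(hit)) sent[j] <- hit[1] - 1L   # sentence_index is 0-based
    }
    sub$sentence_index <- sent
    sub <- sub[!is.na(sent), , drop = FALSE]
    if (!nrow(sub)) next
    parts <- lapply(split(sub, sub$sentence_index), resolve_overlaps)
    sub <- do.call(rbind, parts)
    sub$abstract_id <- ids[ab]
    sub$surface <- substring(texts[ab], sub$start + 1L, sub$end)
    u <- u + 1L
    out[[u]] <- sub[, c("abstract_id", "entity_id", "entity_type",
                        "sentence_index", "start", "end", "surface")]
  }
  mentions <- if (u) do.call(rbind, out[seq_len(u)]) else empty
  ## canonical deterministic order
  mentions <- mentions[order(match(mentions$abstract_id, ids),
                             mentions$start, mentions$entity_type,
                             mentions$entity_id), , drop = FALSE]
  rownames(mentions) <- NULL
  new_annotated_corpus(corpus, matcher$dictionary, mentions)
}

new_annotated_corpus <- function(corpus, dictionary, mentions) {
  structure(list(corpus = corpus, dictionary = dictionary,
                 mentions = mentions,
                 by_abstract = split(seq_len(nrow(mentions)), mentions$abstract_id),
                 by_entity = split(seq_len(nrow(mentions)), mentions$entity_id)),
            class = "annotated_corpus")
}

#' @export
print.annotated_corpus <- function(x, ...) {
  cat("annotated corpus:", x$corpus$n, "abstracts,",
      nrow(x$mentions), "mentions of",
      length(x$by_entity), "entities\n")
  invisible(x)
}

entity_type_of <- function(ann, entity_id) {
  ann$dictionary$entity_type[match(entity_id, ann$dictionary$entity_id)]
}
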