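## trend_analysis: yearly mention dynamics, Mann-Kendall trend strength,
## and per-digest interest scores.

#' Yearly mention dynamics for one entity
#'
#' Counts, per publication year, the number of distinct abstracts
#' mentioning the entity (mention multiplicity within an abstract is
#' ignored; abstracts with unknown year are excluded). Years span the
#' contiguous range from the first to the last known corpus year,
#' zero-filled.
#'
#' @param entity_id Entity identifier (must exist in the dictionary).
#' @param ann An [annotate()]d corpus.
#' @return List with `years` (integer vector) and `raw_counts`.
#' @export
mention_dynamics <- function(entity_id, ann) {
  if (!entity_id %in% ann$dictionary$entity_id) {
    stop_("unknown entity: ", entity_id)
  }
  yrs <- corpus_years(ann$corpus)
  if (!length(yrs)) stop_("corpus has no abstracts with a known year")
  years <- seq.int(min(yrs), max(yrs))
  idx <- ann$by_entity[[entity_id]]
  counts <- integer(length(years))
  if (!is.null(idx)) {
    ids <- unique(ann$mentions$abstract_id[idx])
    all_ids <- vapply(ann$corpus$abstracts, function(a) a$abstract_id, "")
    ab_years <- vapply(ann$corpus$abstracts, function(a) a$year, integer(1))
    y <- ab_years[match(ids, all_ids)]
    y <- y[!is.na(y)]
    if (length(y)) {
      tab <- table(factor(y, levels = years))
      counts <- as.integer(tab)
    }
  }
  list(years = years, raw_counts = counts)
}

#' Normalise yearly mention counts by corpus totals
#'
#' Divides each year's mention count by the total number of articles
#' published that year. Years with a zero total give a normalised value of
#' 0 with a warning.
#'
#' @param raw Integer vector of per-year mention counts.
#' @param totals Per-year article totals aligned with `raw`.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_dynamics <- function(raw, totals) {
  if (length(raw) != length(totals)) {
    stop_("raw and totals must have equal length")
  }
  zero <- totals == 0
  if (any(zero & raw > 0)) stop_("mention count exceeds a zero yearly total")
  if (any(zero)) warning("zero yearly total: normalised value set to 0")
  out <- ifelse(zero, 0, raw / totals)
  as.numeric(out)
}

#' Mann-Kendall trend test (tie-corrected)
#'
#' `S = sum_{i<j} sign(x_j - x_i)`; the variance uses the tie correction
#' `Var = [m(m-1)(2m+5) - sum_g t_g(t_g-1)(2t_g+5)] / 18` over tie groups
#' g; the continuity-corrected standardised statistic is
#' `z = (S-1)/sqrt(Var)` for `S > 0`, `0` for `S = 0`, `(S+1)/sqrt(Var)`
#' for `S < 0`; p is the two-sided normal tail. An all-tied series returns
#' `S = 0, z = 0, p = 1`.
#'
#' @param series Numeric vector, length >= 3.
#' @return Named list `S_mk` (integer), `z_mk`, `p_mk`.
#' @export
mann_kendall <- function(series) {
  m <- length(series)
  if (m < 3L) stop_("Mann-Kendall requires a series of length >= 3")
  if (anyNA(series)) stop_("series contains NA")
  d <- outer(series, series, function(a, b) b - a)  # d[i, j] = x_j - x_i
  S <- sum(sign(d[upper.tri(d)]))
  ties <- table(series)
  t_g <- as.numeric(ties[ties > 1L])
  varS <- (m * (m - 1) * (2 * m + 5) -
             sum(t_g * (t_g - 1) * (2 * t_g + 5))) / 18
  if (varS <= 0) {                       # all observations tied
    return(list(S_mk = 0L, z_mk = 0, p_mk = 1))
  }
  z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(S_mk = as.integer(S), z_mk = z, p_mk = p)
}

#' Trend table for all mentioned entities
#'
#' Computes per-entity yearly dynamics (normalised by the corpus yearly
#' totals by default, matching how trend strengths are estimated), and the
#' Mann-Kendall S/z/p per entity. Note that S (trend strength) is a rank
#' statistic, so it is identical for raw and normalised dynamics whenever
#' the yearly totals are constant.
#'
#' @param ann An [annotate()]d corpus.
#' @param normalized Use normalised dynamics (default TRUE).
#' @param entities Entities to include (default: all with >= 1 mention).
#' @return Data frame of class `"trend_table"`: `entity_id`, `S_mk`,
#'   `z_mk`, `p_mk`, `first_year`, `last_year`, `series` (comma-joined).
#' @export
trend_table <- function(ann, normalized = TRUE, entities = NULL) {
  if (is.null(entities)) entities <- names(ann$by_entity)
  yrs <- corpus_years(ann$corpus)
  if (length(yrs) == 0L) stop_("corpus has no abstracts with a known year")
  totals_map <- yearly_totals(ann$corpus)
  years <- seq.int(min(yrs), max(yrs))
  totals <- as.integer(totals_map[as.character(years)])
  totals[is.na(totals)] <- 0L
  rows <- lapply(entities, function(e) {
    dyn <- mention_dynamics(e, ann)
    x <- if (normalized) {
      suppressWarnings(normalize_dynamics(dyn$raw_counts, totals))
    } else {
      as.numeric(dyn$raw_counts)
    }
    mk <- mann_kendall(x)
    data.frame(entity_id = e, S_mk = mk$S_mk, z_mk = mk$z_mk, p_mk = mk$p_mk,
               first_year = years[1], last_year = years[length(years)],
               series = paste(signif(x, 8), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trend_table", "data.frame")
  out
}

#' @export
print.trend_table <- function(x, ...) {
  cat("trend table:", nrow(x), "entities,",
      x$first_year[1], "-", x$last_year[1], "\n")
  if (nrow(x)) {
    top <- utils::head(x[order(-abs(x$z_mk)),
                         c("entity_id", "S_mk", "z_mk", "p_mk")], 5L)
    print.data.frame(top, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a trend table as TSV
#' @param trends A [trend_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trends <- function(trends, path) {
  utils::write.table(as.data.frame(trends), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interest score of one digest
#'
#' The digest score is the arithmetic mean of the trend z-scores of the
#' entities mentioned in the abstract that satisfy the user's query
#' (`query_matched`); with `all_mapped = TRUE` it averages over all mapped
#' entities of the abstract instead. An empty intersection gives score 0
#' with `empty = TRUE`.
#'
#' @param abstract_id Abstract identifier.
#' @param ann An [annotate()]d corpus.
#' @param trends A [trend_table()].
#' @param query_matched Character vector of query-matching entity ids.
#' @param all_mapped Average over all mapped entities instead.
#' @return List `abstract_id`, `score`, `contributing_entities`, `empty`.
#' @export
digest_score <- function(abstract_id, ann, trends, query_matched,
                         all_mapped = FALSE) {
  idx <- ann$by_abstract[[abstract_id]]
  mapped <- if (is.null(idx)) character(0) else unique(ann$mentions$entity_id[idx])
  contributing <- if (all_mapped) mapped else intersect(mapped, query_matched)
  contributing <- intersect(contributing, trends$entity_id)
  if (!length(contributing)) {
    return(list(abstract_id = abstract_id, score = 0,
                contributing_entities = character(0), empty = TRUE))
  }
  z <- trends$z_mk[match(contributing, trends$entity_id)]
  list(abstract_id = abstract_id, score = mean(z),
       contributing_entities = contributing, empty = FALSE)
}
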