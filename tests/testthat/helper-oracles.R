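## Independent brute-force oracles. These deliberately share no code with
## the implementation: plain loops and direct definitions only.

## delta-enumeration of the weighted co-occurrence table
bf_pair_table <- function(ann, params) {
  ents <- sort(unique(ann$mentions$entity_id))
  rows <- list()
  for (i in seq_along(ents)) {
    for (j in seq_along(ents)) {
      if (j <= i) next
      a <- ents[i]
      b <- ents[j]
      ac <- 0L
      sc <- 0L
      for (ab in ann$corpus$abstracts) {
        mm <- ann$mentions[ann$mentions$abstract_id == ab$abstract_id, ]
        if (a %in% mm$entity_id && b %in% mm$entity_id) {
          ac <- ac + 1L
          sa <- mm$sentence_index[mm$entity_id == a]
          sb <- mm$sentence_index[mm$entity_id == b]
          if (length(intersect(sa, sb)) > 0L) sc <- sc + 1L
        }
      }
      if (ac > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          entity_a = a, entity_b = b, abstract_count = ac,
          sentence_count = sc,
          C = params$omega_a * ac + params$omega_s * sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

## s-scores from first principles: marginals summed by loops over the
## brute-force table
bf_s_scores <- function(bf, ann, params) {
  type_of <- function(e) {
    ann$dictionary$entity_type[ann$dictionary$entity_id == e]
  }
  bf$type_a <- vapply(bf$entity_a, type_of, "")
  bf$type_b <- vapply(bf$entity_b, type_of, "")
  marg <- function(entity, ptype) {
    tot <- 0
    for (r in seq_len(nrow(bf))) {
      if (bf$entity_a[r] == entity && bf$type_b[r] == ptype) tot <- tot + bf$C[r]
      if (bf$entity_b[r] == entity && bf$type_a[r] == ptype) tot <- tot + bf$C[r]
    }
    tot
  }
  norm <- function(t1, t2) {
    tot <- 0
    for (r in seq_len(nrow(bf))) {
      tsort <- sort(c(bf$type_a[r], bf$type_b[r]))
      if (identical(tsort, sort(c(t1, t2)))) {
        tot <- tot + bf$C[r] * (if (t1 == t2) 2 else 1)
      }
    }
    tot
  }
  vapply(seq_len(nrow(bf)), function(r) {
    C <- bf$C[r]
    m1 <- marg(bf$entity_a[r], bf$type_b[r])
    m2 <- marg(bf$entity_b[r], bf$type_a[r])
    nn <- norm(bf$type_a[r], bf$type_b[r])
    C^params$alpha * (C * nn / (m1 * m2))^(1 - params$alpha)
  }, numeric(1))
}

## Mann-Kendall by direct enumeration of the sign terms
bf_mann_kendall <- function(x) {
  m <- length(x)
  S <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      S <- S + sign(x[j] - x[i])
    }
  }
  tie_sizes <- as.numeric(table(x))
  tie_sizes <- tie_sizes[tie_sizes > 1]
  varS <- (m * (m - 1) * (2 * m + 5) -
             sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  if (varS <= 0) return(list(S = 0L, z = 0, p = 1))
  z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  list(S = as.integer(S), z = z, p = 2 * pnorm(-abs(z)))
}

## AUC by enumerating every positive-negative comparison
bf_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
  }
  tot / (length(pos) * length(neg))
}

## Naive per-abstract boolean query evaluation, straight from the
## semantics: token-boundary keyword regex, per-clause bound groups.
bf_query_eval <- function(query, ann) {
  kw_hit <- function(kw, text) {
    grepl(paste0("(?<![[:alnum:]])",
                 gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", kw),
                 "(?![[:alnum:]])"),
          text, perl = TRUE, ignore.case = TRUE)
  }
  fixed_ids <- unlist(lapply(query$clauses, function(cl) cl$entity))
  hits <- character(0)
  for (ab in ann$corpus$abstracts) {
    mm <- ann$mentions[ann$mentions$abstract_id == ab$abstract_id, ]
    if (nrow(mm) == 0L) next
    spans <- ab$sentences
    sent_txt <- substring(ab$text, spans[, "start"] + 1L, spans[, "end"])
    ent_ok <- function(cl, e) {
      if (!e %in% mm$entity_id) return(FALSE)
      for (g in cl$bound_keywords) {
        found <- FALSE
        for (s in unique(mm$sentence_index[mm$entity_id == e])) {
          if (any(sapply(g, kw_hit, text = sent_txt[s + 1L]))) found <- TRUE
        }
        if (!found) return(FALSE)
      }
      TRUE
    }
    clause_ok <- function(cl) {
      cand <- if (!is.null(cl$entity)) cl$entity else
        setdiff(unique(mm$entity_id[mm$entity_type == cl$type]), fixed_ids)
      any(vapply(cand, function(e) ent_ok(cl, e), logical(1)))
    }
    ok <- TRUE
    for (cl in query$clauses) {
      sat <- clause_ok(cl)
      if (cl$mode == "include" && !sat) ok <- FALSE
      if (cl$mode == "exclude" && sat) ok <- FALSE
    }
    for (g in query$free_groups) {
      if (!any(sapply(g, kw_hit, text = ab$text))) ok <- FALSE
    }
    for (g in query$excluded_groups) {
      if (any(sapply(g, kw_hit, text = ab$text))) ok <- FALSE
    }
    if (ok) hits <- c(hits, ab$abstract_id)
  }
  sort(hits)
}

## random query sampler over a generated corpus's dictionary and the
## words the generator embeds in text
random_query <- function(dictionary, seed) {
  set.seed(seed)
  ids <- dictionary$entity_id
  types <- unique(dictionary$entity_type)
  fixed <- sample(ids, 1L)
  clauses <- list(query_clause("include", entity = fixed))
  if (runif(1) < 0.6) {
    clauses <- c(clauses, list(query_clause("include",
                                            type = sample(types, 1L))))
  }
  if (runif(1) < 0.4) {
    tgt <- sample(setdiff(ids, fixed), 1L)
    clauses <- c(clauses, list(query_clause("exclude", entity = tgt)))
  }
  words <- c("association", "cohort", "replication", "prospectively",
             "robust", "measured", "zebra")
  free <- if (runif(1) < 0.5) list(sample(words, 2L)) else list()
  excl <- if (runif(1) < 0.3) list(sample(words, 1L)) else list()
  if (runif(1) < 0.3) {
    clauses[[1]] <- query_clause("include", entity = fixed,
                                 bound_keywords = list(sample(words, 2L)))
  }
  corpus_query(clauses, free_groups = free, excluded_groups = excl)
}
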