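## comention_scoring: weighted co-occurrence counts, marginally normalised
## s-scores, and empirical z/p significance against sampled negative sets.
##
## For an unordered pair of entities the weighted co-occurrence over the n
## corpus abstracts is
##   C = sum_k [ omega_a * delta_ak + omega_s * delta_sk ],
## where delta_ak (delta_sk) is 1 iff the two entities co-occur in abstract
## k (in at least one sentence of abstract k). The association score blends
## C with its marginal-normalised lift:
##   S = C^alpha * ( C * C(t1,t2) / ( C(e1,t2) * C(t1,e2) ) )^(1-alpha),
## where C(e1,t2) sums C over all partners of e1 with type t2 and C(t1,t2)
## sums over all stored pairs of those types (each same-type pair counted
## from both ends).

#' Scoring parameters
#'
#' @param omega_a Weight for same-abstract co-occurrence (default 3).
#' @param omega_s Weight for same-sentence co-occurrence (default 0.2).
#' @param alpha Mixing exponent between the raw count and its normalised
#'   lift, in `[0, 1]` (default 0.6). `alpha = 1` reduces the s-score to C.
#' @param n_negative_samples Size of the sampled negative set used for the
#'   empirical z-score (default 10000).
#' @param min_type_pair Minimum number of stored pairs of a type-pair
#'   before it gets its own negative background; smaller groups are pooled
#'   into a global background (default 30).
#' @param seed Seed for negative-set sampling.
#' @return A list of class `"scoring_params"`.
#' @export
scoring_params <- function(omega_a = 3, omega_s = 0.2, alpha = 0.6,
                           n_negative_samples = 10000L,
                           min_type_pair = 30L, seed = 1L) {
  if (!(omega_a > 0)) stop_("omega_a must be > 0")
  if (omega_s < 0) stop_("omega_s must be >= 0")
  if (alpha < 0 || alpha > 1) stop_("alpha must be in [0, 1]")
  structure(list(omega_a = omega_a, omega_s = omega_s, alpha = alpha,
                 n_negative_samples = as.integer(n_negative_samples),
                 min_type_pair = as.integer(min_type_pair),
                 seed = as.integer(seed)),
            class = "scoring_params")
}

empty_pair_table <- function() {
  data.frame(entity_a = character(0), entity_b = character(0),
             type_a = character(0), type_b = character(0),
             abstract_count = integer(0), sentence_count = integer(0),
             C = numeric(0), stringsAsFactors = FALSE)
}

#' Count weighted co-occurrences for all entity pairs
#'
#' For every unordered pair of distinct entities co-occurring in at least
#' one abstract: `abstract_count` = number of abstracts mentioning both,
#' `sentence_count` = number of abstracts where both share at least one
#' sentence (binary per abstract), and
#' `C = omega_a * abstract_count + omega_s * sentence_count`.
#' Self-pairs are excluded; pairs that never share an abstract are absent.
#'
#' @param ann An [annotate()]d corpus.
#' @param params [scoring_params()].
#' @return Data frame with columns `entity_a`, `entity_b` (entity_a <
#'   entity_b), `type_a`, `type_b`, `abstract_count`, `sentence_count`,
#'   `C`, sorted by pair.
#' @export
count_all_pairs <- function(ann, params = scoring_params()) {
  m <- ann$mentions
  if (!nrow(m)) return(empty_pair_table())
  ab_keys <- character(0)
  sent_keys <- character(0)
  for (idx in ann$by_abstract) {
    sub <- m[idx, , drop = FALSE]
    ents <- sort(unique(sub$entity_id))
    if (length(ents) >= 2L) {
      cmb <- utils::combn(ents, 2L)
      ab_keys <- c(ab_keys, paste(cmb[1L, ], cmb[2L, ], sep = "\r"))
      sk <- character(0)
      for (s in unique(sub$sentence_index)) {
        se <- sort(unique(sub$entity_id[sub$sentence_index == s]))
        if (length(se) >= 2L) {
          cs <- utils::combn(se, 2L)
          sk <- c(sk, paste(cs[1L, ], cs[2L, ], sep = "\r"))
        }
      }
      sent_keys <- c(sent_keys, unique(sk))
    }
  }
  if (!length(ab_keys)) return(empty_pair_table())
  ab_tab <- table(ab_keys)
  sent_tab <- table(sent_keys)
  keys <- sort(names(ab_tab))
  parts <- split_pair_key(keys)
  out <- data.frame(entity_a = parts$a, entity_b = parts$b,
                    stringsAsFactors = FALSE)
  out$type_a <- entity_type_of(ann, out$entity_a)
  out$type_b <- entity_type_of(ann, out$entity_b)
  out$abstract_count <- as.integer(ab_tab[keys])
  sc <- as.integer(sent_tab[keys])
  out$sentence_count <- ifelse(is.na(sc), 0L, sc)
  out$C <- params$omega_a * out$abstract_count + params$omega_s * out$sentence_count
  rownames(out) <- NULL
  out
}

#' Build the marginal table for s-score normalisation
#'
#' Computes per-(entity, partner-type) sums of C and per-type-pair
#' normalisers. For a same-type pair the normaliser counts each unordered
#' pair from both ends, so that the invariant
#' `C(t1,t2) = sum over entities e of type t1 of C(e,t2)` holds for every
#' type combination; this is asserted on every build.
#'
#' @param pairs A [count_all_pairs()] table.
#' @return A list of class `"marginal_table"` with named numeric vectors
#'   `entity_type` (key `entity\rtype`) and `type_type` (key sorted
#'   `type\rtype`).
#' @export
marginal_table <- function(pairs) {
  et <- numeric(0)
  tt <- numeric(0)
  if (nrow(pairs)) {
    key1 <- paste(pairs$entity_a, pairs$type_b, sep = "\r")
    key2 <- paste(pairs$entity_b, pairs$type_a, sep = "\r")
    et_tab <- tapply(c(pairs$C, pairs$C), c(key1, key2), sum)
    et <- as.numeric(et_tab)
    names(et) <- names(et_tab)
    tkey <- pair_key(pairs$type_a, pairs$type_b)
    mult <- ifelse(pairs$type_a == pairs$type_b, 2, 1)
    tt_tab <- tapply(pairs$C * mult, tkey, sum)
    tt <- as.numeric(tt_tab)
    names(tt) <- names(tt_tab)
  }
  out <- structure(list(entity_type = et, type_type = tt,
                        entity_types = stats::setNames(
                          c(pairs$type_a, pairs$type_b),
                          c(pairs$entity_a, pairs$entity_b))),
                   class = "marginal_table")
  assert_marginals(out)
  out
}

## marginal-conservation invariant, asserted after every build
assert_marginals <- function(marginals) {
  if (!length(marginals$entity_type)) return(invisible(TRUE))
  parts <- strsplit(names(marginals$entity_type), "\r", fixed = TRUE)
  ent <- vapply(parts, `[[`, "", 1L)
  ptype <- vapply(parts, `[[`, "", 2L)
  etype <- marginals$entity_types[ent]
  key <- pair_key(etype, ptype)
  sums <- tapply(marginals$entity_type, key, sum)
  ## cross-type pairs are reached from both type ends, same-type from one
  same <- vapply(strsplit(names(sums), "\r", fixed = TRUE),
                 function(p) p[1] == p[2], logical(1))
  expect <- marginals$type_type[names(sums)] * ifelse(same, 1, 2)
  if (any(abs(sums - expect) > 1e-9 * pmax(1, abs(expect)))) {
    stop_("internal error: marginal conservation violated")
  }
  invisible(TRUE)
}

marginal_lookup <- function(marginals, entity, ptype) {
  v <- marginals$entity_type[paste(entity, ptype, sep = "\r")]
  ifelse(is.na(v), 0, as.numeric(v))
}

#' Compute the s-score for one pair
#'
#' @param pair_C Weighted co-occurrence C of the pair (must be > 0).
#' @param m1 Marginal `C(entity_a, type_b)`.
#' @param m2 Marginal `C(type_a, entity_b)`.
#' @param norm Type-pair normaliser `C(type_a, type_b)`.
#' @param params [scoring_params()] (uses `alpha`).
#' @return Non-negative finite s-score; `alpha = 1` returns `pair_C`.
#' @export
s_score <- function(pair_C, m1, m2, norm, params = scoring_params()) {
  if (any(pair_C <= 0)) stop_("s_score requires pair_C > 0")
  if (any((m1 <= 0 | m2 <= 0 | norm <= 0) & pair_C > 0)) {
    stop_("internal-consistency error: zero marginal with nonzero C")
  }
  alpha <- params$alpha
  pair_C^alpha * (pair_C * norm / (m1 * m2))^(1 - alpha)
}

type_pair_of <- function(pairs) pair_key(pairs$type_a, pairs$type_b)

## negative-background statistics per type-pair group (with pooling)
negative_backgrounds <- function(pairs, params) {
  tp <- type_pair_of(pairs)
  groups <- sort(unique(tp))
  small <- groups[vapply(groups, function(g) sum(tp == g), 0L) < params$min_type_pair]
  bg <- list()
  draw <- function(values) {
    n <- params$n_negative_samples
    samp <- with_seed(params$seed,
                      sample(values, n, replace = length(values) < n))
    c(mean = mean(samp), sd = stats::sd(samp))
  }
  for (g in setdiff(groups, small)) bg[[g]] <- draw(pairs$S[tp == g])
  if (length(small)) {
    pooled <- draw(pairs$S)
    for (g in small) bg[[g]] <- pooled
  }
  attr(bg, "pooled_type_pairs") <- gsub("\r", "-", small, fixed = TRUE)
  bg
}

z_from_background <- function(S, bg) {
  sdv <- bg[["sd"]]
  if (!is.finite(sdv) || sdv == 0) return(c(z = 0, p = 0.5))
  z <- (S - bg[["mean"]]) / sdv
  c(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' Empirical significance of one pair's s-score
#'
#' The negative set is a seeded uniform sample of stored (co-occurring)
#' pairs of the same type-pair (with replacement when fewer than
#' `n_negative_samples` exist); type-pairs with fewer than `min_type_pair`
#' stored pairs are pooled into a global background. The z-score is the
#' pair's s-score standardised by the negative set's mean/SD, and p is the
#' one-sided upper normal tail (z = 1.65 corresponds to p < 0.05). A
#' zero-SD background yields z = 0, p = 0.5.
#'
#' @param pair One row of a scored pair table (or a list with `entity_a`,
#'   `entity_b`, `type_a`, `type_b`, `S`).
#' @param table The full pair table with `S` computed.
#' @param params [scoring_params()].
#' @return Named numeric vector `c(z, p)`.
#' @export
estimate_significance <- function(pair, table, params = scoring_params()) {
  if (!nrow(table)) stop_("empty score table")
  bg <- negative_backgrounds(table, params)
  g <- pair_key(pair$type_a, pair$type_b)
  z_from_background(pair$S, bg[[g]])
}

#' Score an annotated corpus: full pair table with C, S, z, p
#'
#' Composes [count_all_pairs()], [marginal_table()], [s_score()] and the
#' negative-set significance estimate into one deterministic pass. The
#' table is symmetric under pair order by construction (pairs are stored
#' with `entity_a < entity_b`) and invariant to abstract order.
#'
#' @param ann An [annotate()]d corpus.
#' @param params [scoring_params()].
#' @param template_pairs Optional two-column data frame (or matrix) of
#'   entity-id pairs confirmed by an external relation list; matching rows
#'   get `template_flag = TRUE`.
#' @return Data frame of class `"pair_scores"` with columns `entity_a`,
#'   `entity_b`, `type_a`, `type_b`, `abstract_count`, `sentence_count`,
#'   `C`, `S`, `z`, `p`, `template_flag`. Attributes: `params`,
#'   `marginals`, `pooled_type_pairs`.
#' @export
score_corpus <- function(ann, params = scoring_params(), template_pairs = NULL) {
  pairs <- count_all_pairs(ann, params)
  if (!nrow(pairs)) {
    out <- cbind(pairs, data.frame(S = numeric(0), z = numeric(0),
                                   p = numeric(0), template_flag = logical(0)))
    class(out) <- c("pair_scores", "data.frame")
    return(out)
  }
  marginals <- marginal_table(pairs)
  m1 <- marginal_lookup(marginals, pairs$entity_a, pairs$type_b)
  m2 <- marginal_lookup(marginals, pairs$entity_b, pairs$type_a)
  norm <- as.numeric(marginals$type_type[type_pair_of(pairs)])
  pairs$S <- s_score(pairs$C, m1, m2, norm, params)
  bg <- negative_backgrounds(pairs, params)
  tp <- type_pair_of(pairs)
  zp <- t(vapply(seq_len(nrow(pairs)),
                 function(i) z_from_background(pairs$S[i], bg[[tp[i]]]),
                 c(z = 0, p = 0)))
  pairs$z <- zp[, "z"]
  pairs$p <- zp[, "p"]
  pairs$template_flag <- FALSE
  if (!is.null(template_pairs) && NROW(template_pairs)) {
    tk <- pair_key(as.character(template_pairs[[1]]),
                   as.character(template_pairs[[2]]))
    pairs$template_flag <- pair_key(pairs$entity_a, pairs$entity_b) %in% tk
  }
  attr(pairs, "params") <- params
  attr(pairs, "marginals") <- marginals
  attr(pairs, "pooled_type_pairs") <- attr(bg, "pooled_type_pairs")
  class(pairs) <- c("pair_scores", "data.frame")
  pairs
}

#' @export
print.pair_scores <- function(x, ...) {
  cat("pair score table:", nrow(x), "co-occurring pairs\n")
  if (nrow(x)) {
    top <- utils::head(x[order(-x$S),
                         c("entity_a", "entity_b", "C", "S", "z", "p")], 5L)
    print.data.frame(top, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Look up the s-score of one unordered pair
#'
#' @param scores A [score_corpus()] table.
#' @param a,b Entity ids.
#' @return The s-score, or `NA` when the pair never co-occurs.
#' @export
pair_s <- function(scores, a, b) {
  i <- match(pair_key(a, b), pair_key(scores$entity_a, scores$entity_b))
  if (is.na(i)) NA_real_ else scores$S[i]
}

#' Write a pair score table as TSV
#' @param scores A [score_corpus()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
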