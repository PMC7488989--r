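## evaluation: the accuracy-assessment protocol — reference positive and
## negative pair samples, ROC/AUC by the Mann-Whitney formulation, and
## balanced-subsample stability.

#' Build a negative reference sample of entity pairs
#'
#' Draws a seeded uniform sample (without replacement) of candidate pairs.
#' With `strategy = "random_pairs"` candidates are all unordered pairs of
#' entities of the requested types; with `strategy = "comention_filtered"`
#' candidates are restricted to pairs found together in the text at least
#' once (C > 0, i.e. present in the score table). Pairs listed in
#' `exclude` (e.g. the positive sample or a curated database) never appear.
#'
#' @param dictionary An [entity_dictionary()].
#' @param scores A [score_corpus()] table (needed for the co-mention
#'   filter).
#' @param strategy `"random_pairs"` or `"comention_filtered"`.
#' @param size Number of pairs to draw.
#' @param exclude Two-column data frame (or list of such) of pairs to
#'   exclude, order-insensitive.
#' @param type_pair Length-2 character vector restricting entity types
#'   (e.g. `c("gene", "disease")`); `NULL` = any.
#' @param seed Integer seed.
#' @return Data frame `entity_a`, `entity_b`.
#' @export
build_negative_sample <- function(dictionary, scores = NULL,
                                  strategy = c("random_pairs",
                                               "comention_filtered"),
                                  size, exclude = NULL, type_pair = NULL,
                                  seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "comention_filtered") {
    if (is.null(scores) || !nrow(scores)) {
      stop_("comention_filtered strategy needs a non-empty score table")
    }
    keys <- pair_key(scores$entity_a, scores$entity_b)
    if (!is.null(type_pair)) {
      keep <- pair_key(scores$type_a, scores$type_b) ==
        pair_key(type_pair[1], type_pair[2])
      keys <- keys[keep]
    }
  } else {
    ids_a <- dictionary$entity_id
    ids_b <- dictionary$entity_id
    if (!is.null(type_pair)) {
      ids_a <- dictionary$entity_id[dictionary$entity_type == type_pair[1]]
      ids_b <- dictionary$entity_id[dictionary$entity_type == type_pair[2]]
    }
    grid <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    keys <- unique(pair_key(grid$a, grid$b))
  }
  if (!is.null(exclude)) {
    if (is.data.frame(exclude)) exclude <- list(exclude)
    for (ex in exclude) {
      keys <- setdiff(keys, pair_key(as.character(ex[[1]]),
                                     as.character(ex[[2]])))
    }
  }
  if (length(keys) < size) {
    stop_("candidate pool (", length(keys), ") smaller than requested size (",
          size, "); try a smaller sample")
  }
  keys <- sort(keys)
  samp <- with_seed(seed, sample(keys, size, replace = FALSE))
  parts <- split_pair_key(samp)
  data.frame(entity_a = parts$a, entity_b = parts$b, stringsAsFactors = FALSE)
}

#' ROC AUC by the Mann-Whitney formulation
#'
#' AUC = probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted 1/2 (midrank formulation).
#'
#' @param scores Numeric scores (higher = more association).
#' @param labels Logical (or 0/1) labels, `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop_("scores/labels length mismatch")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop_("both positive and negative labels are required")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame `threshold`, `fpr`, `tpr` suitable for plotting or
#'   CSV export.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  tp <- cumsum(l)
  fp <- cumsum(!l)
  keep <- c(diff(s) != 0, TRUE)   # one point per distinct threshold
  data.frame(threshold = s[keep],
             fpr = fp[keep] / sum(!labels),
             tpr = tp[keep] / sum(labels))
}

#' AUC stability under balanced negative subsampling
#'
#' Recomputes the AUC after subsampling the negatives down to the number
#' of positives (seeded, without replacement) and reports both values and
#' their absolute difference.
#'
#' @inheritParams roc_auc
#' @param seed Integer seed for the subsample.
#' @return List `auc_full`, `auc_balanced`, `delta`.
#' @export
balanced_auc <- function(scores, labels, seed = 1L) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  neg_idx <- which(!labels)
  if (length(neg_idx) < n_pos) stop_("need at least as many negatives as positives")
  auc_full <- roc_auc(scores, labels)
  sub <- with_seed(seed, sample(neg_idx, n_pos, replace = FALSE))
  idx <- c(which(labels), sub)
  auc_bal <- roc_auc(scores[idx], labels[idx])
  list(auc_full = auc_full, auc_balanced = auc_bal,
       delta = abs(auc_full - auc_bal))
}

#' Evaluate s-score ranking against reference pair samples
#'
#' Labels every reference pair, looks up its s-score in the table (pairs
#' never co-occurring score 0, below every stored s-score), and reports
#' the AUC plus balanced-subsample stability.
#'
#' @param scores A [score_corpus()] table.
#' @param positives,negatives Two-column data frames of entity pairs.
#' @param seed Seed for the balanced subsample.
#' @return List `auc`, `auc_balanced`, `delta`, `n_pos`, `n_neg`,
#'   `points` (ROC curve data frame).
#' @export
evaluate_ranking <- function(scores, positives, negatives, seed = 1L) {
  lookup <- function(pairs) {
    vapply(seq_len(nrow(pairs)), function(i) {
      s <- pair_s(scores, as.character(pairs[[1]][i]), as.character(pairs[[2]][i]))
      if (is.na(s)) 0 else s
    }, numeric(1))
  }
  s <- c(lookup(positives), lookup(negatives))
  l <- c(rep(TRUE, nrow(positives)), rep(FALSE, nrow(negatives)))
  bal <- if (sum(!l) >= sum(l)) balanced_auc(s, l, seed = seed) else
    list(auc_full = roc_auc(s, l), auc_balanced = NA_real_, delta = NA_real_)
  list(auc = bal$auc_full, auc_balanced = bal$auc_balanced,
       delta = bal$delta, n_pos = nrow(positives), n_neg = nrow(negatives),
       points = roc_points(s, l))
}
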