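## synthetic_corpus: seeded MEDLINE-like corpora and dictionaries with
## known ground truth — Zipf-like entity frequencies, planted associated
## pairs with elevated joint-abstract/sentence rates, planted monotone
## publication trends.
##
## Planted-pair mechanism: each planted pair gets a joint-inclusion
## probability pj = min(lift * pa * pb, 0.9 * min(pa, pb)). Per abstract a
## Bernoulli(pj) draw includes both entities; otherwise the two entities
## are mutually exclusive, with probabilities chosen so the marginal
## inclusion rates stay exactly pa and pb. Joint inclusion is therefore
## the only source of co-occurrence for a planted pair, which makes the
## delta ledger and the closed-form expected_C exact.

#' Build a synthetic-corpus generator specification
#'
#' The default specification is the package's demo fixture: 2000 abstracts
#' over 1990-2020, three entity types with 50 entities each, 10 planted
#' associated pairs and 5 planted increasing trends, seed 42. Entity
#' identities, synonyms, qualities, base inclusion probabilities and the
#' planted structure are all fixed deterministically here, so that
#' [expected_C()] is a pure function of the spec.
#'
#' @param n_abstracts Number of abstracts.
#' @param year_range First and last publication year.
#' @param yearly_weights Sampling weights over years (default uniform).
#' @param entity_counts Named integer vector, type -> number of entities.
#' @param synonym_range Min/max synonyms per entity (uniform, default 1-4).
#' @param zipf_exponent Zipf exponent for base mention frequencies.
#' @param mean_entities_per_abstract Target mean dictionary entities
#'   included per abstract (scales the Zipf weights).
#' @param n_planted_pairs Number of planted associated pairs (entity-
#'   disjoint, drawn from distinct types where possible).
#' @param abstract_lift Multiplier on joint abstract inclusion for planted
#'   pairs (>= 1).
#' @param sentence_prob Probability a jointly included planted pair shares
#'   a sentence.
#' @param n_planted_trends Number of entities with a planted increasing
#'   trend (disjoint from planted pairs).
#' @param trend_baseline Inclusion probability of a trend entity in the
#'   first year.
#' @param trend_slope Per-year increase of the inclusion probability.
#' @param seed Integer seed; all generation is deterministic under it.
#' @return A list of class `"generator_spec"`.
#' @export
generator_spec <- function(n_abstracts = 2000L, year_range = c(1990L, 2020L),
                           yearly_weights = NULL,
                           entity_counts = c(gene = 50L, disease = 50L,
                                             drug = 50L),
                           synonym_range = c(1L, 4L), zipf_exponent = 1,
                           mean_entities_per_abstract = 3,
                           n_planted_pairs = 10L, abstract_lift = 200,
                           sentence_prob = 0.6, n_planted_trends = 5L,
                           trend_baseline = 0.01, trend_slope = 0.01,
                           seed = 42L) {
  if (n_abstracts < 1L) stop_("n_abstracts must be >= 1")
  if (any(entity_counts < 1L)) stop_("entity counts must be >= 1")
  if (abstract_lift < 1) stop_("abstract_lift must be >= 1")
  if (sentence_prob < 0 || sentence_prob > 1) stop_("sentence_prob must be in [0, 1]")
  if (trend_baseline < 0 || trend_baseline > 1 || trend_slope < 0) {
    stop_("trend parameters must be probabilities/non-negative slope")
  }
  years <- seq.int(year_range[1], year_range[2])
  if (is.null(yearly_weights)) yearly_weights <- rep(1, length(years))
  if (length(yearly_weights) != length(years) || any(yearly_weights < 0)) {
    stop_("yearly_weights must be non-negative, one per year")
  }
  n_ent <- sum(entity_counts)
  if (2L * n_planted_pairs + n_planted_trends > n_ent) {
    stop_("infeasible spec: not enough entities for disjoint planted pairs and trends")
  }
  with_seed(seed, {
    types <- rep(names(entity_counts), entity_counts)
    idx_in_type <- unlist(lapply(entity_counts, seq_len), use.names = FALSE)
    entity_id <- sprintf("%s_%03d", types, idx_in_type)
    canonical <- make.unique(sprintf("%s%03dxx", substr(types, 1L, 3L),
                                     idx_in_type), sep = "v")
    n_syn <- sample(seq.int(synonym_range[1], synonym_range[2]), n_ent,
                    replace = TRUE)
    synonyms <- lapply(seq_len(n_ent), function(i) {
      extra <- if (n_syn[i] > 1L) {
        paste0(canonical[i], letters[seq_len(n_syn[i] - 1L)])
      } else character(0)
      c(canonical[i], extra)
    })
    quality <- sample(1:5, n_ent, replace = TRUE)
    dictionary <- entity_dictionary(entity_id, types, canonical,
                                    synonyms = synonyms, quality = quality,
                                    types = unique(types))
    ## Zipf base inclusion probabilities over a global random rank order
    ranks <- sample.int(n_ent)
    w <- ranks^(-zipf_exponent)
    p <- pmin(0.3, w / sum(w) * mean_entities_per_abstract)
    base_prob <- stats::setNames(p, entity_id)
    ## planted structure on mid-frequency entities, entity-disjoint
    ord <- order(ranks)                      # entities by decreasing weight
    ## planted structure lives among moderately studied entities: frequent
    ## enough that an association has material support, not so frequent
    ## that chance co-occurrence swamps it
    band <- ord[seq.int(from = max(1L, ceiling(n_ent * 0.05)),
                        length.out = min(n_ent - max(1L, ceiling(n_ent * 0.05)) + 1L,
                                         ceiling(n_ent * 0.35)))]
    n_pick <- 2L * n_planted_pairs + n_planted_trends
    if (n_pick > length(band)) band <- ord
    picked <- sample(band, n_pick)
    pair_ents <- picked[seq_len(2L * n_planted_pairs)]
    trend_ents <- picked[2L * n_planted_pairs + seq_len(n_planted_trends)]
    planted_pairs <- if (n_planted_pairs > 0L) {
      a <- entity_id[pair_ents[seq_len(n_planted_pairs)]]
      b <- entity_id[pair_ents[n_planted_pairs + seq_len(n_planted_pairs)]]
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
      pj <- pmin(abstract_lift * base_prob[a] * base_prob[b],
                 0.9 * pmin(base_prob[a], base_prob[b]))
      data.frame(entity_a = a, entity_b = b, abstract_lift = abstract_lift,
                 sentence_prob = sentence_prob, joint_prob = unname(pj),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(entity_a = character(0), entity_b = character(0),
                 abstract_lift = numeric(0), sentence_prob = numeric(0),
                 joint_prob = numeric(0), stringsAsFactors = FALSE)
    }
    planted_trends <- data.frame(
      entity_id = entity_id[trend_ents],
      baseline = rep(trend_baseline, length(trend_ents)),
      slope = rep(trend_slope, length(trend_ents)),
      stringsAsFactors = FALSE)
    journals <- c("J Synth Biol", "Ann Fabricated Res", "Mock Med J",
                  "Simul Genet", "Placebo Rep", "Arch Artif Data")
    hindex <- stats::setNames(c(220L, 95L, 40L, 12L), journals[1:4])
    structure(list(n_abstracts = as.integer(n_abstracts), years = years,
                   yearly_weights = yearly_weights / sum(yearly_weights),
                   dictionary = dictionary, base_prob = base_prob,
                   planted_pairs = planted_pairs,
                   planted_trends = planted_trends,
                   journals = journals, hindex = hindex,
                   seed = as.integer(seed)),
              class = "generator_spec")
  })
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("generator spec:", x$n_abstracts, "abstracts,",
      min(x$years), "-", max(x$years), ",",
      nrow(x$dictionary), "entities,",
      nrow(x$planted_pairs), "planted pairs,",
      nrow(x$planted_trends), "planted trends, seed", x$seed, "\n")
  invisible(x)
}

## per-entity inclusion probability in a given year
inclusion_prob <- function(spec, entity_id, year) {
  p <- spec$base_prob[entity_id]
  ti <- match(entity_id, spec$planted_trends$entity_id)
  tr <- !is.na(ti)
  if (any(tr)) {
    yrs <- year - spec$years[1]
    p[tr] <- pmin(1, spec$planted_trends$baseline[ti[tr]] +
                    spec$planted_trends$slope[ti[tr]] * yrs)
  }
  p
}

#' Closed-form expected weighted co-occurrence of a planted pair
#'
#' `E[C] = omega_a * n * pj + omega_s * n * pj * sentence_prob`, where pj
#' is the pair's joint-inclusion probability fixed in the spec.
#'
#' @param spec A [generator_spec()].
#' @param pair Character vector of the two entity ids (order-insensitive).
#' @param params [scoring_params()] supplying the weights.
#' @return Expected C (numeric).
#' @export
expected_C <- function(spec, pair, params = scoring_params()) {
  key <- pair_key(pair[1], pair[2])
  i <- match(key, pair_key(spec$planted_pairs$entity_a,
                           spec$planted_pairs$entity_b))
  if (is.na(i)) stop_("pair is not planted: ", pair[1], " / ", pair[2])
  pj <- spec$planted_pairs$joint_prob[i]
  sp <- spec$planted_pairs$sentence_prob[i]
  n <- spec$n_abstracts
  params$omega_a * n * pj + params$omega_s * n * pj * sp
}

sentence_frames <- c(
  "The relationship between %s was examined in this cohort.",
  "Our analysis indicates that %s show a robust association.",
  "We observed that %s were frequently reported together.",
  "Levels of %s were measured across all participants.",
  "These findings link %s in the studied population.")

filler_sentences <- c(
  "No further associations were observed.",
  "Additional replication will be required.",
  "The cohort was recruited prospectively.",
  "Limitations of the sampling design are discussed.",
  "Statistical analyses were performed as described previously.")

compose_sentence <- function(surfaces, frame_idx) {
  joined <- if (length(surfaces) == 1L) surfaces else
    paste(paste(surfaces[-length(surfaces)], collapse = ", "),
          surfaces[length(surfaces)], sep = " and ")
  sprintf(sentence_frames[frame_idx], joined)
}

#' Generate a synthetic corpus with ground truth
#'
#' Simulates abstracts year by year: baseline entities are included
#' independently with their Zipf probabilities, planted pairs through the
#' joint-inclusion mechanism described in the module header, and planted
#' trend entities with linearly increasing probability. Included entities
#' are embedded (as sampled synonyms) into neutral sentence frames. Fully
#' deterministic under the spec seed.
#'
#' @param spec A [generator_spec()].
#' @param dir Optional output directory; when given, writes
#'   `corpus.jsonl`, `corpus.xml`, `dictionary.tsv`, `hindex.tsv` and
#'   `ground_truth.json`.
#' @return List with `corpus` (a [corpus()]), `dictionary`, `hindex`
#'   (named vector) and `ground_truth` (list with `placements` data frame,
#'   `pair_ledger`, `trend_probs`).
#' @export
generate_corpus <- function(spec, dir = NULL) {
  d <- spec$dictionary
  ids <- d$entity_id
  pair_a <- spec$planted_pairs$entity_a
  pair_b <- spec$planted_pairs$entity_b
  pair_members <- c(pair_a, pair_b)
  if (anyDuplicated(pair_members)) {
    stop_("infeasible spec: planted pairs must be entity-disjoint")
  }
  baseline_ids <- setdiff(ids, pair_members)
  out <- with_seed(spec$seed + 1L, {
    years <- spec$years[sample.int(length(spec$years), spec$n_abstracts,
                                   replace = TRUE, prob = spec$yearly_weights)]
    abstracts <- vector("list", spec$n_abstracts)
    placements <- vector("list", spec$n_abstracts)
    joint_ab <- stats::setNames(vector("list", nrow(spec$planted_pairs)),
                                pair_key(pair_a, pair_b))
    joint_sent <- joint_ab
    for (k in seq_len(spec$n_abstracts)) {
      year <- years[k]
      aid <- sprintf("SYN%06d", k)
      p_base <- inclusion_prob(spec, baseline_ids, year)
      included <- baseline_ids[stats::runif(length(baseline_ids)) < p_base]
      same_sent_pairs <- list()
      diff_sent_pairs <- list()
      for (q in seq_len(nrow(spec$planted_pairs))) {
        pa <- spec$base_prob[pair_a[q]]
        pb <- spec$base_prob[pair_b[q]]
        pj <- spec$planted_pairs$joint_prob[q]
        u <- stats::runif(1)
        if (u < pj) {
          included <- c(included, pair_a[q], pair_b[q])
          key <- pair_key(pair_a[q], pair_b[q])
          joint_ab[[key]] <- c(joint_ab[[key]], aid)
          if (stats::runif(1) < spec$planted_pairs$sentence_prob[q]) {
            same_sent_pairs[[length(same_sent_pairs) + 1L]] <- c(pair_a[q], pair_b[q])
            joint_sent[[key]] <- c(joint_sent[[key]], aid)
          } else {
            diff_sent_pairs[[length(diff_sent_pairs) + 1L]] <- c(pair_a[q], pair_b[q])
          }
        } else {
          ## mutually exclusive remainder keeps the marginals exact
          v <- (u - pj) / (1 - pj)
          qa <- (pa - pj) / (1 - pj)
          qb <- (pb - pj) / (1 - pj)
          if (v < qa) included <- c(included, pair_a[q])
          else if (v < qa + qb) included <- c(included, pair_b[q])
        }
      }
      n_inc <- length(included)
      n_body <- max(3L, ceiling(n_inc / 2L) + 1L)
      sent_of <- stats::setNames(sample.int(n_body, n_inc, replace = TRUE),
                                 included)
      for (pr in same_sent_pairs) {
        s <- sample.int(n_body, 1L)
        sent_of[pr[1]] <- s
        sent_of[pr[2]] <- s
      }
      for (pr in diff_sent_pairs) {
        s <- sample.int(n_body, 2L, replace = FALSE)
        sent_of[pr[1]] <- s[1]
        sent_of[pr[2]] <- s[2]
      }
      surfaces <- vapply(included, function(e) {
        syns <- d$synonyms[[match(e, ids)]]
        syns[sample.int(length(syns), 1L)]
      }, "")
      body <- vapply(seq_len(n_body), function(s) {
        here <- included[sent_of == s]
        if (length(here)) {
          compose_sentence(surfaces[here],
                           sample.int(length(sentence_frames), 1L))
        } else {
          filler_sentences[sample.int(length(filler_sentences), 1L)]
        }
      }, "")
      journal <- sample(spec$journals, 1L)
      cites <- as.integer(round(stats::rlnorm(1, meanlog = 1.5, sdlog = 1)))
      abstracts[[k]] <- abstract(aid, sprintf("Synthetic record %06d", k),
                                 paste(body, collapse = " "),
                                 year = year, journal = journal,
                                 citation_count = cites)
      placements[[k]] <- if (n_inc) {
        data.frame(abstract_id = aid, entity_id = included,
                   sentence_index = unname(sent_of),  # body sentence, 1-based
                   surface = unname(surfaces), year = year,
                   stringsAsFactors = FALSE)
      } else NULL
    }
    list(abstracts = abstracts, placements = placements,
         joint_ab = joint_ab, joint_sent = joint_sent)
  })
  corp <- corpus(out$abstracts)
  placements <- do.call(rbind, out$placements[!vapply(out$placements, is.null,
                                                      logical(1))])
  trend_probs <- lapply(seq_len(nrow(spec$planted_trends)), function(i) {
    e <- spec$planted_trends$entity_id[i]
    list(entity_id = e, years = spec$years,
         inclusion_prob = as.numeric(inclusion_prob(spec, rep(e, length(spec$years)),
                                                    spec$years)))
  })
  ground_truth <- list(
    placements = placements,
    pair_ledger = lapply(seq_len(nrow(spec$planted_pairs)), function(q) {
      key <- pair_key(pair_a[q], pair_b[q])
      list(entity_a = pair_a[q], entity_b = pair_b[q],
           joint_abstracts = sort(out$joint_ab[[key]] %||% character(0)),
           joint_sentence_abstracts = sort(out$joint_sent[[key]] %||% character(0)))
    }),
    trend_probs = trend_probs)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_jsonl_corpus(corp, file.path(dir, "corpus.jsonl"))
    write_medline_xml(corp, file.path(dir, "corpus.xml"))
    write_dictionary(spec$dictionary, file.path(dir, "dictionary.tsv"))
    utils::write.table(data.frame(journal = names(spec$hindex),
                                  h_index = as.integer(spec$hindex)),
                       file.path(dir, "hindex.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(corpus = corp, dictionary = spec$dictionary, hindex = spec$hindex,
       ground_truth = ground_truth)
}

## inclusion_prob over years for trend entities uses vectorised year input
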