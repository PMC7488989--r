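## network_export: associative network over query results; JSON/CSV/GraphML
## export in a fixed schema.

type_palette <- function(types) {
  base <- c(gene = "#1f77b4", protein = "#ff7f0e", metabolite = "#2ca02c",
            microRNA = "#d62728", biological_process = "#9467bd",
            phenotype = "#8c564b", drug = "#e377c2", side_effect = "#7f7f7f",
            disease = "#bcbd22", cell = "#17becf", organism = "#aec7e8",
            pathway = "#ffbb78", tissue = "#98df8a")
  cols <- base[types]
  cols[is.na(cols)] <- "#cccccc"
  unname(cols)
}

node_size <- function(mention_count) 10 + 20 * log1p(mention_count)
edge_size <- function(pair_count) 1 + log1p(pair_count)

#' Build the associative network over a digest list
#'
#' One node per visible entity (query-matching entities of the result
#' abstracts, after any filtering); one undirected edge per entity pair
#' co-occurring in at least one result abstract. Mention and co-mention
#' counts are computed over the result set only; s-score, z and p are
#' copied from the corpus-wide score table. Node size grows strictly with
#' mention count, edge size with pair co-mention count.
#'
#' @param digests A [evaluate_query()] (optionally filtered) result.
#' @param ann The annotated corpus.
#' @param scores A [score_corpus()] table.
#' @param trends A [trend_table()] (per-node trend strength S).
#' @return List of class `"comention_network"` with data frames `nodes`
#'   (`id`, `label`, `synonyms`, `type`, `colour`, `size`,
#'   `trend_strength`, `mention_count`, `x`, `y`) and `edges` (`id`,
#'   `source`, `target`, `colour`, `size`, `s_score`, `z_score`,
#'   `p_value`, `template_flag`).
#' @export
build_network <- function(digests, ann, scores, trends) {
  matched <- attr(digests, "matched")
  entities <- sort(unique(unlist(matched, use.names = FALSE))) %||% character(0)
  result_ids <- digests$abstract_id
  sub <- ann$mentions[ann$mentions$abstract_id %in% result_ids &
                        ann$mentions$entity_id %in% entities, , drop = FALSE]
  mention_count <- vapply(entities, function(e) {
    length(unique(sub$abstract_id[sub$entity_id == e]))
  }, integer(1))
  d <- ann$dictionary
  di <- match(entities, d$entity_id)
  nodes <- data.frame(id = seq_along(entities),
                      label = d$canonical_name[di],
                      synonyms = vapply(d$synonyms[di], paste, "", collapse = "|"),
                      type = d$entity_type[di],
                      colour = type_palette(d$entity_type[di]),
                      size = node_size(unname(mention_count)),
                      trend_strength = trends$S_mk[match(entities, trends$entity_id)],
                      mention_count = unname(mention_count),
                      x = rep(NA_real_, length(entities)),
                      y = rep(NA_real_, length(entities)),
                      stringsAsFactors = FALSE)
  nodes$entity_id <- entities
  nodes$trend_strength[is.na(nodes$trend_strength)] <- 0L
  ## edges: pairs of visible entities sharing >= 1 result abstract
  pair_counts <- new.env(parent = emptyenv())
  for (id in result_ids) {
    ents <- sort(unique(sub$entity_id[sub$abstract_id == id]))
    if (length(ents) >= 2L) {
      cmb <- utils::combn(ents, 2L)
      for (k in seq_len(ncol(cmb))) {
        key <- paste(cmb[1L, k], cmb[2L, k], sep = "\r")
        pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- sort(ls(pair_counts))
  if (length(keys)) {
    parts <- split_pair_key(keys)
    cnt <- vapply(keys, function(k) pair_counts[[k]], integer(1))
    si <- match(keys, pair_key(scores$entity_a, scores$entity_b))
    edges <- data.frame(id = seq_along(keys),
                        source = match(parts$a, entities),
                        target = match(parts$b, entities),
                        colour = "#999999",
                        size = edge_size(unname(cnt)),
                        s_score = scores$S[si],
                        z_score = scores$z[si],
                        p_value = scores$p[si],
                        template_flag = scores$template_flag[si],
                        pair_count = unname(cnt),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(id = integer(0), source = integer(0),
                        target = integer(0), colour = character(0),
                        size = numeric(0), s_score = numeric(0),
                        z_score = numeric(0), p_value = numeric(0),
                        template_flag = logical(0), pair_count = integer(0),
                        stringsAsFactors = FALSE)
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "comention_network")
}

#' @export
print.comention_network <- function(x, ...) {
  cat("associative network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Assign node layout coordinates
#'
#' Default layout places nodes on the unit circle, ordered by type then by
#' decreasing mention count (deterministic). The seeded force-directed
#' option runs a small Fruchterman-Reingold loop initialised from the
#' circle; coordinates are always finite.
#'
#' @param network A [build_network()] result.
#' @param seed Integer seed (force-directed initialisation jitter).
#' @param method `"circle"` (default) or `"force"`.
#' @param iterations Force-directed iterations (default 50).
#' @return The network with `x`, `y` filled in.
#' @export
layout_nodes <- function(network, seed = 1L, method = c("circle", "force"),
                         iterations = 50L) {
  method <- match.arg(method)
  n <- nrow(network$nodes)
  if (n < 1L) stop_("layout requires at least one node")
  ord <- order(network$nodes$type, -network$nodes$mention_count,
               network$nodes$label)
  theta <- numeric(n)
  theta[ord] <- 2 * pi * (seq_len(n) - 1L) / n
  x <- cos(theta)
  y <- sin(theta)
  if (method == "force" && n > 1L) {
    jitter <- with_seed(seed, matrix(stats::runif(2L * n, -0.01, 0.01), ncol = 2L))
    pos <- cbind(x, y) + jitter
    k <- sqrt(4 / n)   # ideal spring length in a 2x2 canvas
    edges <- network$edges
    for (it in seq_len(iterations)) {
      disp <- matrix(0, n, 2L)
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          d <- pos[i, ] - pos[j, ]
          dist <- max(sqrt(sum(d^2)), 1e-6)
          rep_f <- k^2 / dist
          disp[i, ] <- disp[i, ] + d / dist * rep_f
          disp[j, ] <- disp[j, ] - d / dist * rep_f
        }
      }
      if (nrow(edges)) for (e in seq_len(nrow(edges))) {
        i <- edges$source[e]; j <- edges$target[e]
        d <- pos[i, ] - pos[j, ]
        dist <- max(sqrt(sum(d^2)), 1e-6)
        att <- dist^2 / k
        disp[i, ] <- disp[i, ] - d / dist * att
        disp[j, ] <- disp[j, ] + d / dist * att
      }
      temp <- 0.1 * (1 - it / (iterations + 1L))
      len <- pmax(sqrt(rowSums(disp^2)), 1e-9)
      pos <- pos + disp / len * pmin(len, temp)
    }
    x <- pos[, 1L]
    y <- pos[, 2L]
  }
  ## + 0 folds IEEE negative zero into +0 so JSON output is stable
  network$nodes$x <- round(x, 6) + 0
  network$nodes$y <- round(y, 6) + 0
  network
}

mapped_text <- function(ab, mentions) {
  sub <- mentions[mentions$abstract_id == ab$abstract_id, , drop = FALSE]
  if (!nrow(sub)) return(ab$text)
  ## merge identical spans (cross-type mentions), then resolve remaining
  ## overlaps leftmost-longest so inline tags never cross
  agg <- stats::aggregate(entity_id ~ start + end, data = sub,
                          FUN = function(x) paste(sort(unique(x)), collapse = ","))
  agg$entity_type <- "all"
  agg <- resolve_overlaps(agg)
  agg <- agg[order(-agg$start), , drop = FALSE]
  text <- ab$text
  for (i in seq_len(nrow(agg))) {
    s <- agg$start[i]; e <- agg$end[i]
    text <- paste0(substr(text, 1L, s),
                   "<e id=\"", agg$entity_id[i], "\">",
                   substring(text, s + 1L, e), "</e>",
                   substring(text, e + 1L))
  }
  text
}

digest_export_rows <- function(digests, ann) {
  lapply(seq_len(nrow(digests)), function(i) {
    id <- digests$abstract_id[i]
    ab <- Find(function(a) a$abstract_id == id, ann$corpus$abstracts)
    list(pmid = id,
         date = if (is.na(digests$year[i])) NA else digests$year[i],
         digest_score = digests$digest_score[i] %||% 0,
         citations = digests$citation_count[i],
         mapped_text = mapped_text(ab, ann$mentions))
  })
}

#' Export a digest table and network as JSON
#'
#' Top-level keys: `anddigest` (list of `{pmid, date, digest_score,
#' citations, mapped_text}`, with entity mentions marked inline as
#' `<e id="...">surface</e>`) and `network` (`{nodes, edges}` with the
#' [build_network()] fields). The file round-trips losslessly through
#' [import_network_json()].
#'
#' @param network A [build_network()] result (layout optional).
#' @param digests The digest list (with `digest_score` column if scored).
#' @param ann The annotated corpus.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_json <- function(network, digests, ann, path) {
  payload <- list(
    anddigest = digest_export_rows(digests, ann),
    network = list(
      nodes = network$nodes[, c("id", "label", "synonyms", "type", "colour",
                                "size", "trend_strength", "mention_count",
                                "x", "y")],
      edges = network$edges[, c("id", "source", "target", "colour", "size",
                                "s_score", "z_score", "p_value",
                                "template_flag")]))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Import a JSON export
#'
#' @param path File written by [export_json()].
#' @return List with `digests` (data frame) and `network` (nodes/edges
#'   data frames).
#' @export
import_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  dig <- obj$anddigest
  if (length(dig) == 0L) {
    dig <- data.frame(pmid = character(0), date = integer(0),
                      digest_score = numeric(0), citations = integer(0),
                      mapped_text = character(0), stringsAsFactors = FALSE)
  }
  list(digests = dig,
       network = structure(list(nodes = as.data.frame(obj$network$nodes),
                                edges = as.data.frame(obj$network$edges)),
                           class = "comention_network"))
}

#' Validate a JSON export against the shipped schema
#'
#' Checks the exported structure against the schema file bundled at
#' `inst/extdata/network_schema.json`: required top-level keys, required
#' fields and primitive types for digest entries, nodes and edges.
#'
#' @param path JSON export path.
#' @param schema_path Schema file (default: the bundled schema).
#' @return `TRUE` invisibly; errors describe every violation found.
#' @export
validate_export <- function(path,
                            schema_path = system.file("extdata",
                                                      "network_schema.json",
                                                      package = "comention")) {
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  problems <- character(0)
  req_top <- unlist(schema$required)
  miss_top <- setdiff(req_top, names(obj))
  if (length(miss_top)) {
    problems <- c(problems, paste("missing top-level key:", miss_top))
  }
  check_records <- function(records, spec, where) {
    req <- unlist(spec$required)
    types <- spec$properties
    unlist(lapply(seq_along(records), function(i) {
      rec <- records[[i]]
      miss <- setdiff(req, names(rec))
      errs <- if (length(miss)) paste0(where, "[", i, "]: missing ", miss) else character(0)
      for (f in intersect(names(types), names(rec))) {
        want <- types[[f]]$type
        v <- rec[[f]]
        ok <- is.null(v) || switch(want,
          string = is.character(v),
          number = is.numeric(v),
          integer = is.numeric(v) && (is.na(v) || v == round(v)),
          boolean = is.logical(v),
          TRUE)
        if (!ok) errs <- c(errs, paste0(where, "[", i, "].", f,
                                        ": expected ", want))
      }
      errs
    }))
  }
  if ("anddigest" %in% names(obj)) {
    problems <- c(problems,
                  check_records(obj$anddigest, schema$definitions$digest, "anddigest"))
  }
  if ("network" %in% names(obj)) {
    problems <- c(problems,
                  check_records(obj$network$nodes, schema$definitions$node,
                                "network.nodes"),
                  check_records(obj$network$edges, schema$definitions$edge,
                                "network.edges"))
  }
  if (length(problems)) stop_("export schema violations: ",
                              paste(problems, collapse = "; "))
  invisible(TRUE)
}

#' Export digests, nodes and edges as CSV
#'
#' Writes `digests.csv`, `nodes.csv` and `edges.csv` into `dir`. The CSV
#' form deliberately omits colours, sizes and spatial coordinates of nodes
#' and edges.
#'
#' @param network A [build_network()] result.
#' @param digests The digest list.
#' @param ann The annotated corpus.
#' @param dir Output directory (created if needed).
#' @return Character vector of the three file paths, invisibly.
#' @export
export_csv <- function(network, digests, ann, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- digest_export_rows(digests, ann)
  dig <- data.frame(pmid = vapply(rows, function(r) r$pmid, ""),
                    date = vapply(rows, function(r) ifelse(is.null(r$date) || is.na(r$date), NA_integer_, as.integer(r$date)), integer(1)),
                    digest_score = vapply(rows, function(r) as.numeric(r$digest_score), numeric(1)),
                    citations = vapply(rows, function(r) as.integer(r$citations), integer(1)),
                    mapped_text = vapply(rows, function(r) r$mapped_text, ""),
                    stringsAsFactors = FALSE)
  dig$digest_score <- sprintf("%.17g", dig$digest_score)
  nodes <- network$nodes[, c("id", "label", "synonyms", "type",
                             "trend_strength", "mention_count")]
  edges <- network$edges[, c("id", "source", "target", "s_score", "z_score",
                             "p_value", "template_flag")]
  ## full binary precision so score triples survive the text round trip
  for (col in c("s_score", "z_score", "p_value")) {
    edges[[col]] <- sprintf("%.17g", edges[[col]])
  }
  paths <- file.path(dir, c("digests.csv", "nodes.csv", "edges.csv"))
  utils::write.csv(dig, paths[1], row.names = FALSE)
  utils::write.csv(nodes, paths[2], row.names = FALSE)
  utils::write.csv(edges, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Export the network as GraphML (interchange extra)
#'
#' Requires the `igraph` package.
#'
#' @param network A [build_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop_("export_graphml requires the igraph package")
  }
  g <- igraph::graph_from_data_frame(
    d = transform(network$edges, from = source, to = target)[,
        c("from", "to", "s_score", "z_score", "p_value", "template_flag")],
    directed = FALSE,
    vertices = network$nodes[, c("id", "label", "type", "trend_strength",
                                 "mention_count")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
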