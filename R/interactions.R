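# Interaction scoring, threshold screening, network construction and
# per-group normalized heatmaps for phage-host protein pairs predicted by
# multimer structure prediction (ipTM / pTM confidences).

#' Combined interaction confidence score
#'
#' The model-ranking confidence of a predicted complex:
#' `0.8 * ipTM + 0.2 * pTM`. Both inputs must lie in \[0,1\].
#'
#' @param iptm Interface predicted TM confidence, in \[0,1\].
#' @param ptm Overall predicted TM confidence, in \[0,1\].
#' @return Numeric score in \[0,1\] (vectorized).
#' @export
interaction_score <- function(iptm, ptm) {
  bad <- which(is.na(iptm) | is.na(ptm) | iptm < 0 | iptm > 1 | ptm < 0 | ptm > 1)
  if (length(bad) > 0L) {
    ph_stop("ipTM/pTM value outside [0,1] at position %d", bad[1L])
  }
  0.8 * iptm + 0.2 * ptm
}

#' Score and screen predicted interactions
#'
#' Attaches the combined score to each (phage protein, host protein, ipTM,
#' pTM) record and keeps records whose screening value is strictly greater
#' than `threshold`. By default the weighted combined score is screened;
#' `score_mode = "sum"` instead screens the raw `ipTM + pTM` sum (the
#' reported `score` column is always the weighted combination).
#'
#' @param records Data frame with columns `phage_protein_id`,
#'   `host_protein_id`, `iptm`, `ptm`.
#' @param threshold Strict lower bound; conventional values are 0.5 for the
#'   network and 0.7 for a stringent candidate list.
#' @param score_mode `"weighted"` (default) or `"sum"`.
#' @return Data frame of retained records with an added `score` column.
#' @export
screen_interactions <- function(records, threshold = 0.5,
                                score_mode = c("weighted", "sum")) {
  score_mode <- match.arg(score_mode)
  stopifnot(threshold >= 0)
  score <- interaction_score(records$iptm, records$ptm)
  screen_value <- if (score_mode == "weighted") score else records$iptm + records$ptm
  out <- records[screen_value > threshold, , drop = FALSE]
  out$score <- score[screen_value > threshold]
  out <- out[order(out$phage_protein_id, out$host_protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a phage-host interaction network
#'
#' Phage nodes carry a size attribute (the number of proteins the
#' representative stands for); host nodes carry a degree attribute (the
#' number of phage proteins they interact with); edge weights are the
#' interaction scores. Duplicate (phage, host) pairs - e.g. multiple
#' predicted models per pair - are collapsed to their maximum score with a
#' message. Node and edge ordering is deterministic.
#'
#' @param screened Data frame from [screen_interactions()] (must carry a
#'   `score` column).
#' @param phage_rep_sizes Named integer vector: phage protein id -> number
#'   of proteins represented. Every phage node must have an entry.
#' @return Object of class `interaction_network`: list with data frames
#'   `phage_nodes` (`id`, `size`), `host_nodes` (`id`, `degree`) and `edges`
#'   (`phage_id`, `host_id`, `weight`).
#' @export
build_network <- function(screened, phage_rep_sizes) {
  if (nrow(screened) == 0L) {
    return(structure(list(
      phage_nodes = data.frame(id = character(), size = integer(),
                               stringsAsFactors = FALSE),
      host_nodes = data.frame(id = character(), degree = integer(),
                              stringsAsFactors = FALSE),
      edges = data.frame(phage_id = character(), host_id = character(),
                         weight = numeric(), stringsAsFactors = FALSE)),
      class = "interaction_network"))
  }
  stopifnot("score" %in% names(screened))
  key <- paste(screened$phage_protein_id, screened$host_protein_id, sep = "\r")
  if (anyDuplicated(key)) {
    message(sprintf("collapsing %d duplicate phage-host pair(s) to maximum score",
                    sum(duplicated(key))))
    best <- tapply(screened$score, key, max)
    parts <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
    screened <- data.frame(phage_protein_id = parts[, 1L],
                           host_protein_id = parts[, 2L],
                           score = as.numeric(best), stringsAsFactors = FALSE)
  }
  phage_ids <- sort(unique(screened$phage_protein_id))
  missing_size <- setdiff(phage_ids, names(phage_rep_sizes))
  if (length(missing_size) > 0L) {
    ph_stop("no representative size for phage node(s): %s",
            paste(head(missing_size, 5L), collapse = ", "))
  }
  host_ids <- sort(unique(screened$host_protein_id))
  degree <- vapply(host_ids, function(h) sum(screened$host_protein_id == h), 0L)
  edges <- data.frame(phage_id = screened$phage_protein_id,
                      host_id = screened$host_protein_id,
                      weight = screened$score, stringsAsFactors = FALSE)
  edges <- edges[order(edges$phage_id, edges$host_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    phage_nodes = data.frame(id = phage_ids,
                             size = as.integer(phage_rep_sizes[phage_ids]),
                             stringsAsFactors = FALSE, row.names = NULL),
    host_nodes = data.frame(id = host_ids, degree = as.integer(degree),
                            stringsAsFactors = FALSE, row.names = NULL),
    edges = edges), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d phage node(s), %d host node(s), %d edge(s)\n",
              nrow(x$phage_nodes), nrow(x$host_nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert an interaction network to an igraph object
#'
#' Bipartite graph with `kind` ("phage"/"host"), `size` and `degree_attr`
#' vertex attributes and `weight` edge attributes.
#'
#' @param network An [build_network()] object.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  vertices <- rbind(
    data.frame(name = network$phage_nodes$id, kind = "phage",
               size = network$phage_nodes$size, degree_attr = NA_integer_,
               stringsAsFactors = FALSE),
    data.frame(name = network$host_nodes$id, kind = "host",
               size = NA_integer_, degree_attr = network$host_nodes$degree,
               stringsAsFactors = FALSE))
  igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$phage_id, to = network$edges$host_id,
                   weight = network$edges$weight, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices)
}

#' Write an interaction network as GraphML and an edge-list TSV
#'
#' @param network An interaction network.
#' @param graphml_path Output GraphML path (skipped when `NULL`).
#' @param edges_path Output TSV path (`source`, `target`, `weight`; skipped
#'   when `NULL`).
#' @return Invisibly, the network.
#' @export
write_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(edges_path)) {
    edges <- network$edges
    names(edges) <- c("source", "target", "weight")
    write.table(edges, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    g <- as_igraph(network)
    if (igraph::vcount(g) > 0L) {
      igraph::write_graph(g, graphml_path, format = "graphml")
    } else {
      writeLines('<?xml version="1.0" encoding="UTF-8"?><graphml/>', graphml_path)
    }
  }
  invisible(network)
}

#' Per-group normalized hit-count heatmap
#'
#' Normalizes hit counts of each (category, phage group) cell by the number
#' of phages in the group, so groups of different sizes are comparable.
#' Cells with no hits are 0.
#'
#' @param counts Data frame with columns `category`, `group`, `count`.
#' @param phages_per_group Named integer vector: group -> number of phages
#'   (all strictly positive).
#' @return Numeric matrix (categories x groups) of counts per phage.
#' @export
normalized_cluster_heatmap <- function(counts, phages_per_group) {
  groups <- sort(unique(c(as.character(counts$group), names(phages_per_group))))
  missing_g <- setdiff(groups, names(phages_per_group))
  if (length(missing_g) > 0L) {
    ph_stop("no phage count for group(s): %s", paste(missing_g, collapse = ", "))
  }
  bad <- names(phages_per_group)[phages_per_group <= 0]
  if (length(bad) > 0L) {
    ph_stop("non-positive phage count for group(s): %s", paste(bad, collapse = ", "))
  }
  categories <- sort(unique(as.character(counts$category)))
  mat <- matrix(0, nrow = length(categories), ncol = length(groups),
                dimnames = list(categories, groups))
  for (i in seq_len(nrow(counts))) {
    cat_i <- as.character(counts$category[i])
    grp_i <- as.character(counts$group[i])
    mat[cat_i, grp_i] <- mat[cat_i, grp_i] + counts$count[i]
  }
  sweep(mat, 2L, phages_per_group[groups], "/")
}
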