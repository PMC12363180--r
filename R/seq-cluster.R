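# Desk-scale clustering semantics: thresholded similarity graph from
# precomputed pairwise alignments, greedy set-cover clustering, and a
# reassignment pass. Tie-breaking is lexicographic throughout so results are
# fully deterministic.

#' Construct a clustering object
#'
#' A clustering is a partition of protein ids into clusters, each with a
#' designated representative that belongs to its own cluster. Member sets
#' must be disjoint.
#'
#' @param clusters Named list: representative id -> character vector of
#'   member ids (the representative included).
#' @param provenance `"sequence"` or `"structure"`.
#' @return Object of class `phannot_clustering`.
#' @export
new_clustering <- function(clusters, provenance = c("sequence", "structure")) {
  provenance <- match.arg(provenance)
  stopifnot(is.list(clusters))
  if (length(clusters) > 0L && is.null(names(clusters))) {
    ph_stop("clusters must be a named list (representative -> members)")
  }
  clusters <- lapply(clusters, function(m) sort(unique(as.character(m))))
  obj <- structure(list(clusters = clusters, provenance = provenance),
                   class = "phannot_clustering")
  validate_clustering(obj)
  obj
}

#' @export
print.phannot_clustering <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<clustering> %d cluster(s), %d protein(s), provenance: %s\n",
              length(sizes), sum(sizes), x$provenance))
  invisible(x)
}

#' Validate the partition invariants of a clustering
#'
#' Checks that member sets are disjoint and that every representative is a
#' member of its own cluster.
#'
#' @param clustering A [new_clustering()] object.
#' @return The clustering, invisibly.
#' @export
validate_clustering <- function(clustering) {
  cl <- clustering$clusters
  if (length(cl) == 0L) return(invisible(clustering))
  reps <- names(cl)
  in_own <- vapply(reps, function(r) r %in% cl[[r]], TRUE)
  if (!all(in_own)) {
    ph_stop("representative(s) not member of own cluster: %s",
            paste(reps[!in_own], collapse = ", "))
  }
  all_members <- unlist(cl, use.names = FALSE)
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup) > 0L) {
    ph_stop("not a partition: member(s) in multiple clusters: %s",
            paste(head(dup, 5L), collapse = ", "))
  }
  invisible(clustering)
}

#' All protein ids covered by a clustering
#' @param clustering A clustering object.
#' @return Sorted character vector of member ids.
#' @export
clustering_members <- function(clustering) {
  sort(unlist(clustering$clusters, use.names = FALSE)) %||% character()
}

#' Map each member to its representative
#' @param clustering A clustering object.
#' @return Named character vector: member id -> representative id.
#' @export
member_to_rep <- function(clustering) {
  cl <- clustering$clusters
  reps <- rep(names(cl), lengths(cl))
  setNames(reps, unlist(cl, use.names = FALSE))
}

#' Build a threshold-filtered similarity graph from pairwise alignments
#'
#' A pair (query, target) becomes an undirected edge when at least one
#' alignment record reaches the identity threshold and satisfies the coverage
#' rule: in `bidirectional` mode both query and target coverage must reach
#' `min_coverage`; in `target` mode only target coverage is checked. All
#' thresholds are inclusive (>=), matching the MMseqs2/Foldseek convention.
#' Self-alignments are dropped (every node is implicitly similar to itself).
#'
#' @param alignments Alignment data frame (see [read_alignment_table()]).
#' @param min_identity Minimum sequence identity, default 0.5.
#' @param min_coverage Minimum alignment coverage, default 0.9.
#' @param coverage_mode `"bidirectional"` (default) or `"target"`.
#' @param node_ids Optional character vector of ids to include as nodes even
#'   when they appear in no qualifying alignment (e.g. the full protein set).
#' @return Object of class `similarity_graph`: list with sorted `nodes` and
#'   an `edges` data frame (`from` < `to` lexicographically).
#' @export
build_similarity_graph <- function(alignments, min_identity = 0.5,
                                   min_coverage = 0.9,
                                   coverage_mode = c("bidirectional", "target"),
                                   node_ids = NULL) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(min_identity >= 0, min_identity <= 1, min_coverage >= 0, min_coverage <= 1)
  validate_alignments(alignments)
  nodes <- sort(unique(c(alignments$query_id, alignments$target_id,
                         as.character(node_ids %||% character()))))
  if (nrow(alignments) == 0L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(), to = character(),
                                             stringsAsFactors = FALSE)),
                     class = "similarity_graph"))
  }
  cov_ok <- if (coverage_mode == "bidirectional") {
    alignments$query_cov >= min_coverage & alignments$target_cov >= min_coverage
  } else {
    alignments$target_cov >= min_coverage
  }
  pass <- !is.na(alignments$seq_identity) & alignments$seq_identity >= min_identity &
    !is.na(cov_ok) & cov_ok & alignments$query_id != alignments$target_id
  q <- alignments$query_id[pass]
  t <- alignments$target_id[pass]
  from <- pmin(q, t)
  to <- pmax(q, t)
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d node(s), %d edge(s)\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# adjacency as named list of sorted neighbor vectors
graph_adjacency <- function(graph) {
  adj <- setNames(vector("list", length(graph$nodes)), graph$nodes)
  for (i in seq_along(adj)) adj[[i]] <- character()
  if (nrow(graph$edges) > 0L) {
    s1 <- split(graph$edges$to, graph$edges$from)
    s2 <- split(graph$edges$from, graph$edges$to)
    for (v in names(s1)) adj[[v]] <- c(adj[[v]], s1[[v]])
    for (v in names(s2)) adj[[v]] <- c(adj[[v]], s2[[v]])
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

graph_edge_set <- function(graph) {
  if (nrow(graph$edges) == 0L) return(character())
  paste(graph$edges$from, graph$edges$to, sep = "\r")
}

has_edge <- function(edge_set, a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r") %in% edge_set
}

#' Greedy set-cover clustering of a similarity graph
#'
#' Repeatedly selects the node whose closed neighborhood covers the most
#' still-uncovered nodes (ties broken by lexicographically smallest id); the
#' selected node becomes a representative and it plus its currently
#' uncovered neighbors form a cluster. A node that is already covered can
#' still be selected when it covers uncovered neighbors; it then moves from
#' its previous cluster into the new one it represents, so the result is
#' always a partition. Iteration stops when every node is covered.
#'
#' @param graph A [build_similarity_graph()] object.
#' @return A [new_clustering()] object with provenance `"sequence"`.
#' @export
greedy_set_cover_cluster <- function(graph) {
  nodes <- graph$nodes  # sorted, so first argmax is the lexicographic winner
  n <- length(nodes)
  if (n == 0L) return(new_clustering(list(), provenance = "sequence"))
  adj <- graph_adjacency(graph)
  uncovered <- setNames(rep(TRUE, n), nodes)
  clusters <- list()
  assigned_to <- setNames(rep(NA_character_, n), nodes)  # member -> rep
  while (any(uncovered)) {
    gain <- vapply(nodes, function(v) sum(uncovered[c(v, adj[[v]])]), numeric(1))
    v <- nodes[which.max(gain)]
    new_members <- c(v, adj[[v]][uncovered[adj[[v]]]])
    new_members <- unique(new_members)
    # a previously covered selected node moves into the cluster it represents
    if (!uncovered[[v]]) {
      old <- assigned_to[[v]]
      clusters[[old]] <- setdiff(clusters[[old]], v)
    }
    clusters[[v]] <- sort(new_members)
    assigned_to[new_members] <- v
    uncovered[new_members] <- FALSE
  }
  clusters <- clusters[order(names(clusters))]
  new_clustering(clusters, provenance = "sequence")
}

#' Reassign cluster members lacking an edge to their representative
#'
#' After cascaded or incremental clustering, some members may no longer
#' satisfy the similarity criteria with their representative. Each
#' non-representative member without an edge to its representative is moved
#' to the lexicographically smallest other representative it has an edge to;
#' if none exists it becomes a new singleton cluster. Candidate targets are
#' the representatives of the input clustering. The operation is idempotent.
#'
#' @param clustering A clustering produced from `graph`.
#' @param graph The similarity graph the clustering was built from.
#' @return A new clustering in which every member has an edge to (or is) its
#'   representative.
#' @export
reassign_members <- function(clustering, graph) {
  stopifnot(inherits(clustering, "phannot_clustering"))
  edge_set <- graph_edge_set(graph)
  cl <- clustering$clusters
  reps <- sort(names(cl))
  adj <- graph_adjacency(graph)
  for (r in reps) {
    for (m in setdiff(cl[[r]], r)) {
      if (has_edge(edge_set, m, r)) next
      nb <- if (m %in% names(adj)) adj[[m]] else character()
      candidates <- sort(intersect(nb, setdiff(reps, r)))
      cl[[r]] <- setdiff(cl[[r]], m)
      if (length(candidates) > 0L) {
        cl[[candidates[1L]]] <- sort(c(cl[[candidates[1L]]], m))
      } else {
        cl[[m]] <- m
      }
    }
  }
  new_clustering(cl[order(names(cl))], provenance = clustering$provenance)
}

#' Summarize the cluster size distribution
#'
#' Counts clusters per size bin. Default bins follow the conventional
#' summary: 1, 2, 3-5, 6-10, 11-20, 21-50, 51-100, >100.
#'
#' @param clustering A clustering object.
#' @param bin_upper Increasing integer vector of bin upper bounds; the last
#'   bin is open-ended above the final bound.
#' @return Data frame with columns `bin` and `count`; counts sum to the
#'   number of clusters.
#' @export
cluster_size_summary <- function(clustering,
                                 bin_upper = c(1, 2, 5, 10, 20, 50, 100)) {
  stopifnot(all(diff(bin_upper) > 0))
  lower <- c(1, bin_upper[-length(bin_upper)] + 1)
  labels <- ifelse(lower == bin_upper, as.character(bin_upper),
                   paste0(lower, "-", bin_upper))
  labels <- c(labels, paste0(">", bin_upper[length(bin_upper)]))
  sizes <- lengths(clustering$clusters)
  counts <- integer(length(labels))
  if (length(sizes) > 0L) {
    bin_idx <- findInterval(sizes, c(lower, bin_upper[length(bin_upper)] + 1))
    tab <- table(factor(bin_idx, levels = seq_along(labels)))
    counts <- as.integer(tab)
  }
  data.frame(bin = labels, count = counts, stringsAsFactors = FALSE)
}

#' Screen clusters spanning temperate and lytic phages
#'
#' Restricts to clusters with at least two members, then returns the
#' representatives of clusters whose members come from at least one temperate
#' and at least one lytic phage.
#'
#' @param clustering A clustering object.
#' @param protein_to_phage Named character vector: protein id -> phage id.
#' @param metadata Data frame with columns `phage_id`, `group`, `lifestyle`
#'   (`temperate`, `lytic` or `unknown`).
#' @return Sorted character vector of representative ids.
#' @export
screen_mixed_lifestyle_clusters <- function(clustering, protein_to_phage, metadata) {
  stopifnot(inherits(clustering, "phannot_clustering"))
  members <- clustering_members(clustering)
  unmapped <- setdiff(members, names(protein_to_phage))
  if (length(unmapped) > 0L) {
    ph_stop("protein(s) without phage mapping: %s",
            paste(head(unmapped, 5L), collapse = ", "))
  }
  lifestyle <- setNames(as.character(metadata$lifestyle), metadata$phage_id)
  no_meta <- setdiff(unique(protein_to_phage[members]), names(lifestyle))
  if (length(no_meta) > 0L) {
    ph_stop("phage(s) without metadata: %s", paste(head(no_meta, 5L), collapse = ", "))
  }
  cl <- clustering$clusters
  cl <- cl[lengths(cl) >= 2L]
  hit <- vapply(cl, function(m) {
    ls <- lifestyle[protein_to_phage[m]]
    any(ls == "temperate") && any(ls == "lytic")
  }, TRUE)
  sort(names(cl)[hit])
}
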