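# Independent brute-force references used as oracles by the tests. These are
# deliberately coded from the definitions, not from the package internals.

# Build a similarity graph from bare edge pairs through the public API.
graph_from_pairs <- function(pairs, nodes = NULL) {
  if (length(pairs) == 0L) {
    aln <- data.frame(query_id = character(), target_id = character(),
                      seq_identity = numeric(), query_cov = numeric(),
                      target_cov = numeric(), evalue = numeric(),
                      tm_score = numeric(), lddt = numeric(),
                      target_name = character(), target_db = character(),
                      target_taxid = integer(), stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, pairs)
    aln <- data.frame(query_id = m[, 1L], target_id = m[, 2L],
                      seq_identity = 0.9, query_cov = 0.95, target_cov = 0.95,
                      evalue = 1e-10, tm_score = NA_real_, lddt = NA_real_,
                      target_name = NA_character_, target_db = NA_character_,
                      target_taxid = NA_integer_, stringsAsFactors = FALSE)
  }
  build_similarity_graph(aln, node_ids = nodes)
}

# Brute-force greedy set-cover reference: straight transcription of the rule.
# Each round, every node's gain is the number of uncovered nodes in its closed
# neighborhood; the smallest-id node among those with maximal positive gain is
# selected, and it plus its uncovered neighbors form (or move into) a cluster.
reference_greedy <- function(nodes, edge_pairs) {
  nodes <- sort(nodes)
  nbrs <- setNames(lapply(nodes, function(x) character()), nodes)
  for (p in edge_pairs) {
    a <- p[1L]; b <- p[2L]
    if (a == b) next
    nbrs[[a]] <- union(nbrs[[a]], b)
    nbrs[[b]] <- union(nbrs[[b]], a)
  }
  covered <- character()
  clusters <- list()
  home <- list()  # node -> rep of the cluster it currently sits in
  while (length(setdiff(nodes, covered)) > 0L) {
    best_node <- NULL
    best_gain <- 0L
    for (v in nodes) {  # nodes sorted: first strict improvement wins ties
      gain <- length(setdiff(c(v, nbrs[[v]]), covered))
      if (gain > best_gain) {
        best_gain <- gain
        best_node <- v
      }
    }
    v <- best_node
    members <- union(v, setdiff(nbrs[[v]], covered))
    if (v %in% covered) clusters[[home[[v]]]] <- setdiff(clusters[[home[[v]]]], v)
    clusters[[v]] <- sort(members)
    for (m in members) home[[m]] <- v
    covered <- union(covered, members)
  }
  clusters[order(names(clusters))]
}

random_graph_pairs <- function(n_nodes, edge_prob) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- list()
  if (n_nodes >= 2L) {
    cmb <- utils::combn(nodes, 2L)
    keep <- stats::runif(ncol(cmb)) < edge_prob
    pairs <- lapply(which(keep), function(i) cmb[, i])
  }
  list(nodes = nodes, pairs = pairs)
}

# Brute-force pairwise label-consistency enumerators.
reference_pfam <- function(sets) {
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) < 2L) return(NA_real_)
  total <- 0
  count <- 0L
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i == j) next
    total <- total + sum(sets[[i]] %in% sets[[j]]) / length(sets[[i]])
    count <- count + 1L
  }
  total / count
}

reference_ec <- function(codes, level) {
  codes <- codes[lengths(codes) == 1L]
  toks <- lapply(codes, function(c) strsplit(c[[1]], ".", fixed = TRUE)[[1]])
  toks <- toks[vapply(toks, function(t) !any(t[1:level] == "-"), TRUE)]
  if (length(toks) < 2L) return(NA_real_)
  pref <- vapply(toks, function(t) paste(t[1:level], collapse = "."), "")
  total <- 0
  count <- 0L
  for (i in seq_along(pref)) for (j in seq_along(pref)) {
    if (i == j) next
    total <- total + as.numeric(pref[i] == pref[j])
    count <- count + 1L
  }
  total / count
}

# Random rooted tree: node i's parent is uniform among nodes 1..(i-1).
random_tree <- function(n_nodes) {
  taxid <- seq_len(n_nodes)
  parent <- c(1L, vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), 1L))
  ranks <- c("no rank", sample(c("superkingdom", "phylum", "genus", "species"),
                               n_nodes - 1L, replace = TRUE))
  new_taxonomy_tree(taxid, parent, ranks, sprintf("node%d", taxid))
}

# Naive LCA oracle: intersect full ancestor sets, return the deepest element.
reference_lca <- function(tree, taxids) {
  anc <- function(t) {
    path <- t
    while (t != tree$root) {
      t <- tree$parent[match(t, tree$taxid)]
      path <- c(path, t)
    }
    path
  }
  common <- Reduce(intersect, lapply(unique(taxids), anc))
  common[which.max(tree$depth[match(common, tree$taxid)])]
}

make_alignment_rows <- function(query, target, tm = 0.8, qcov = 0.9,
                                tcov = 0.9, identity = 0.5, evalue = 1e-5,
                                lddt = NA_real_, name = NA_character_,
                                db = NA_character_, taxid = NA_integer_) {
  data.frame(query_id = query, target_id = target, seq_identity = identity,
             query_cov = qcov, target_cov = tcov, evalue = evalue,
             tm_score = tm, lddt = lddt, target_name = name, target_db = db,
             target_taxid = taxid, stringsAsFactors = FALSE)
}
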