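# Lowest-common-ancestor computation over a taxonomy tree and rank-level
# distribution summaries for structural-homolog hits.

#' Construct a taxonomy tree
#'
#' A rooted taxonomy: each node has a parent taxid, a rank and a name. The
#' root is the unique node whose parent is itself. The constructor validates
#' that every parent is present, that exactly one root exists, and that the
#' parent relation is acyclic.
#'
#' @param taxid Integer vector of node taxids (unique).
#' @param parent Integer vector of parent taxids (root points to itself).
#' @param rank Character vector of rank names (e.g. `"superkingdom"`).
#' @param name Character vector of scientific names.
#' @return Object of class `taxonomy_tree` with fields `taxid`, `parent`,
#'   `rank`, `name`, `root`, `depth` (root has depth 0).
#' @export
new_taxonomy_tree <- function(taxid, parent, rank, name) {
  stopifnot(length(taxid) == length(parent), length(taxid) == length(rank),
            length(taxid) == length(name))
  if (anyDuplicated(taxid)) {
    ph_stop("duplicate taxid(s): %s",
            paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  }
  orphan <- setdiff(parent, taxid)
  if (length(orphan) > 0L) {
    ph_stop("parent taxid(s) absent from tree: %s", paste(orphan, collapse = ", "))
  }
  roots <- taxid[parent == taxid]
  if (length(roots) != 1L) {
    ph_stop("expected exactly one self-parented root, found %d (%s)",
            length(roots), paste(roots, collapse = ", "))
  }
  # depths by iterative propagation; unresolved nodes indicate a cycle
  pidx <- match(parent, taxid)
  depth <- rep(NA_real_, length(taxid))
  depth[match(roots, taxid)] <- 0
  repeat {
    newd <- depth[pidx] + 1
    todo <- is.na(depth) & !is.na(newd)
    if (!any(todo)) break
    depth[todo] <- newd[todo]
  }
  if (anyNA(depth)) {
    ph_stop("cycle detected involving taxid(s): %s",
            paste(taxid[is.na(depth)], collapse = ", "))
  }
  structure(list(taxid = as.integer(taxid), parent = as.integer(parent),
                 rank = as.character(rank), name = as.character(name),
                 root = as.integer(roots), depth = as.integer(depth)),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d node(s), root %d (%s), max depth %d\n",
              length(x$taxid), x$root, x$name[match(x$root, x$taxid)],
              max(x$depth)))
  invisible(x)
}

# path from root down to taxid (inclusive)
root_path <- function(tree, taxid) {
  i <- match(taxid, tree$taxid)
  if (is.na(i)) ph_stop("unknown taxid: %s", taxid)
  path <- integer(tree$depth[i] + 1L)
  k <- length(path)
  repeat {
    path[k] <- tree$taxid[i]
    if (tree$taxid[i] == tree$root) break
    k <- k - 1L
    i <- match(tree$parent[i], tree$taxid)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node lying on the root path of every input taxid
#' (depth measured as root-path length). A single taxid is its own LCA.
#'
#' @param tree A [new_taxonomy_tree()] object.
#' @param taxids Non-empty vector of taxids, all present in the tree.
#' @return The LCA taxid (integer scalar).
#' @export
lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) ph_stop("lca of an empty taxid set is undefined")
  unknown <- setdiff(taxids, tree$taxid)
  if (length(unknown) > 0L) {
    ph_stop("unknown taxid(s): %s", paste(unknown, collapse = ", "))
  }
  paths <- lapply(taxids, function(t) root_path(tree, t))
  k <- min(lengths(paths))
  common <- 1L
  for (d in seq_len(k)) {
    node <- paths[[1L]][d]
    if (all(vapply(paths, function(p) p[d] == node, TRUE))) common <- d else break
  }
  paths[[1L]][common]
}

#' Per-query LCA of structural-homolog hits
#'
#' Groups hits by query and computes the LCA of each query's target taxids.
#' Hits without a taxid are skipped with a warning; queries left with no
#' taxid-bearing hits are omitted and counted in the `n_queries_dropped`
#' attribute.
#'
#' @param hits Alignment data frame carrying `query_id` and `target_taxid`.
#' @param tree A taxonomy tree.
#' @return Data frame with columns `query_id`, `lca_taxid`, `lca_rank`,
#'   `lca_name`, `n_hits`; attribute `n_queries_dropped`.
#' @export
per_query_lca <- function(hits, tree) {
  no_tax <- is.na(hits$target_taxid)
  if (any(no_tax)) {
    ph_warn("%d hit(s) without target taxid skipped", sum(no_tax))
  }
  usable <- hits[!no_tax, , drop = FALSE]
  all_queries <- unique(hits$query_id)
  groups <- split(usable$target_taxid, usable$query_id)
  rows <- lapply(sort(names(groups)), function(q) {
    t <- lca(tree, groups[[q]])
    i <- match(t, tree$taxid)
    data.frame(query_id = q, lca_taxid = t, lca_rank = tree$rank[i],
               lca_name = tree$name[i], n_hits = length(groups[[q]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(query_id = character(), lca_taxid = integer(),
               lca_rank = character(), lca_name = character(),
               n_hits = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_queries_dropped") <- length(all_queries) - nrow(out)
  out
}

# ancestor of taxid at the requested rank, or NA when the lineage has none
ancestor_at_rank <- function(tree, taxid, rank) {
  path <- root_path(tree, taxid)
  ranks <- tree$rank[match(path, tree$taxid)]
  hit <- which(ranks == rank)
  if (length(hit) == 0L) return(NA_integer_)
  path[hit[length(hit)]]
}

#' Distribution of taxa at a taxonomic rank
#'
#' Ascends each item (a taxid, or the `lca_taxid` column of a
#' [per_query_lca()] result) to its ancestor at the requested rank and
#' reports percentages. Items whose lineage carries no node at that rank
#' (e.g. an LCA at the root) fall into an `unassigned` bucket. Percentages
#' are over all items and sum to 100 up to rounding.
#'
#' @param x Integer vector of taxids, or a data frame with an `lca_taxid`
#'   column.
#' @param tree A taxonomy tree.
#' @param rank Rank name, default `"superkingdom"`.
#' @return Data frame with columns `name`, `n`, `percentage`, sorted by
#'   decreasing count (the `unassigned` bucket last).
#' @export
rank_distribution <- function(x, tree, rank = "superkingdom") {
  taxids <- if (is.data.frame(x)) x$lca_taxid else as.integer(x)
  if (length(taxids) == 0L) {
    return(data.frame(name = character(), n = integer(), percentage = numeric(),
                      stringsAsFactors = FALSE))
  }
  anc <- vapply(taxids, function(t) ancestor_at_rank(tree, t, rank), integer(1))
  nm <- ifelse(is.na(anc), "unassigned", tree$name[match(anc, tree$taxid)])
  tab <- table(nm)
  out <- data.frame(name = names(tab), n = as.integer(tab),
                    percentage = 100 * as.integer(tab) / length(taxids),
                    stringsAsFactors = FALSE)
  out <- out[order(out$name == "unassigned", -out$n, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-by-rank count table of lineages
#'
#' For each requested rank, counts how many items map to each taxon at that
#' rank and keeps the `top_k` largest (a flat-table replacement for a Sankey
#' view of the taxonomy).
#'
#' @param taxids Integer vector of taxids.
#' @param tree A taxonomy tree.
#' @param ranks Ranks to tabulate, shallowest first.
#' @param top_k Number of taxa kept per rank, default 8.
#' @return Data frame with columns `rank`, `name`, `n`.
#' @export
rank_breakdown <- function(taxids, tree,
                           ranks = c("superkingdom", "phylum", "genus", "species"),
                           top_k = 8L) {
  do.call(rbind, lapply(ranks, function(rk) {
    d <- rank_distribution(taxids, tree, rk)
    d <- d[d$name != "unassigned", , drop = FALSE]
    d <- head(d[order(-d$n), , drop = FALSE], top_k)
    if (nrow(d) == 0L) return(NULL)
    data.frame(rank = rk, name = d$name, n = d$n, stringsAsFactors = FALSE)
  }))
}
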