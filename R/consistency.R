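# Cluster-purity and annotation-consistency statistics: per-cluster LDDT/TM
# means, Pfam consistency, four-level EC consistency, EC prediction
# agreement, confidence gates, and the semantic-consistency check between
# structure- and sequence-based annotations.

#' Per-cluster structural purity from representative-vs-member alignments
#'
#' For each cluster, computes the arithmetic mean LDDT and TM-score over the
#' alignments of the representative against its members (self-alignments
#' excluded), plus the global medians of the per-cluster means. Clusters with
#' no non-self member alignments (e.g. singletons) are omitted with a
#' warning.
#'
#' @param clustering A clustering object.
#' @param alignments Alignment data frame of representative-vs-member rows
#'   carrying `lddt` and `tm_score` (either orientation accepted).
#' @return List with `per_cluster` (columns `representative_id`, `mean_lddt`,
#'   `mean_tm`, `n_members_aligned`) and `medians` (named vector `lddt`,
#'   `tm`).
#' @export
structural_purity <- function(clustering, alignments) {
  stopifnot(inherits(clustering, "phannot_clustering"))
  validate_alignments(alignments)
  m2r <- member_to_rep(clustering)
  reps <- sort(names(clustering$clusters))
  rows <- lapply(reps, function(r) {
    members <- setdiff(clustering$clusters[[r]], r)
    sel <- (alignments$query_id == r & alignments$target_id %in% members) |
           (alignments$target_id == r & alignments$query_id %in% members)
    sub <- alignments[sel & alignments$query_id != alignments$target_id, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    aligned <- unique(ifelse(sub$query_id == r, sub$target_id, sub$query_id))
    data.frame(representative_id = r,
               mean_lddt = mean(sub$lddt, na.rm = TRUE),
               mean_tm = mean(sub$tm_score, na.rm = TRUE),
               n_members_aligned = length(aligned),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped > 0L) {
    ph_warn("%d cluster(s) without member alignments omitted from purity", skipped)
  }
  per_cluster <- do.call(rbind, rows) %||%
    data.frame(representative_id = character(), mean_lddt = numeric(),
               mean_tm = numeric(), n_members_aligned = integer(),
               stringsAsFactors = FALSE)
  rownames(per_cluster) <- NULL
  medians <- c(lddt = median(per_cluster$mean_lddt),
               tm = median(per_cluster$mean_tm))
  list(per_cluster = per_cluster, medians = medians)
}

# mean over ordered pairs (ref, other) of |labels(ref) ∩ labels(other)| / |labels(ref)|
ordered_pair_consistency <- function(label_sets) {
  n <- length(label_sets)
  scores <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ref <- label_sets[[i]]
      scores <- c(scores, length(intersect(ref, label_sets[[j]])) / length(ref))
    }
  }
  mean(scores)
}

#' Pfam consistency of one cluster
#'
#' Over all ordered pairs (reference, other) of members with at least one
#' Pfam accession, the pair score is the fraction of the reference member's
#' accessions shared by the other member; the cluster score is the mean over
#' all ordered pairs. Both directions are averaged so the cluster score is
#' symmetric. Requires at least two annotated members.
#'
#' @param pfam_sets Named list: member id -> character vector of Pfam
#'   accessions (duplicates collapsed; empty vectors mark unannotated
#'   members).
#' @return Numeric score in \[0,1\], or `NA` when fewer than two members are
#'   annotated.
#' @export
pfam_consistency <- function(pfam_sets) {
  sets <- lapply(pfam_sets, function(s) unique(as.character(s)))
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) < 2L) return(NA_real_)
  ordered_pair_consistency(sets)
}

# split an EC string into its 4 tokens; error on malformed codes
parse_ec <- function(code) {
  tok <- strsplit(trimws(code), ".", fixed = TRUE)[[1]]
  if (length(tok) != 4L) ph_stop("malformed EC code '%s': expected 4 dot-separated tokens", code)
  tok
}

#' EC consistency of one cluster at a hierarchy level
#'
#' Members with exactly one EC code are considered (members with multiple
#' codes are excluded entirely). At level `level`, members whose code lacks a
#' concrete token anywhere in the first `level` positions (a `-`) are
#' disregarded. Remaining codes are truncated to their first `level` tokens
#' and compared pairwise: a pair scores 1 when the truncated codes are equal,
#' 0 otherwise; the cluster score is the mean over ordered pairs. Requires at
#' least two eligible members.
#'
#' @param ec_codes Named list: member id -> character vector of EC code
#'   strings (4 dot-separated tokens, `-` for unspecified levels).
#' @param level Hierarchy level, 1 to 4.
#' @return Numeric score in \[0,1\], or `NA` when fewer than two members are
#'   eligible.
#' @export
ec_consistency <- function(ec_codes, level) {
  stopifnot(level %in% 1:4)
  single <- ec_codes[lengths(ec_codes) == 1L]
  if (length(single) < 2L) return(NA_real_)
  toks <- lapply(single, function(code) parse_ec(code[[1]]))
  eligible <- vapply(toks, function(t) all(t[seq_len(level)] != "-"), TRUE)
  toks <- toks[eligible]
  if (length(toks) < 2L) return(NA_real_)
  truncated <- vapply(toks, function(t) paste(t[seq_len(level)], collapse = "."), "")
  ordered_pair_consistency(lapply(truncated, identity))
}

#' Per-cluster label consistency scores
#'
#' Applies [pfam_consistency()] or [ec_consistency()] to every cluster of a
#' clustering, skipping clusters with fewer than two annotated (or eligible)
#' members.
#'
#' @param clustering A clustering object.
#' @param labels Named list: protein id -> character vector of labels (Pfam
#'   accessions, or EC code strings).
#' @param kind `"pfam"` or `"ec"`.
#' @param level EC hierarchy level (ignored for Pfam).
#' @return Data frame with columns `representative_id`, `label_kind`,
#'   `score`, `n_annotated_members`.
#' @export
cluster_consistency <- function(clustering, labels, kind = c("pfam", "ec"),
                                level = 4L) {
  kind <- match.arg(kind)
  stopifnot(inherits(clustering, "phannot_clustering"))
  label_kind <- if (kind == "pfam") "pfam" else paste0("ec_level_", level)
  rows <- lapply(sort(names(clustering$clusters)), function(r) {
    members <- clustering$clusters[[r]]
    memb_labels <- labels[intersect(members, names(labels))]
    if (kind == "pfam") {
      n_ann <- sum(lengths(lapply(memb_labels, unique)) > 0L)
      score <- pfam_consistency(memb_labels)
    } else {
      n_ann <- sum(lengths(memb_labels) == 1L)
      score <- ec_consistency(memb_labels, level)
    }
    if (is.na(score)) return(NULL)
    data.frame(representative_id = r, label_kind = label_kind, score = score,
               n_annotated_members = n_ann, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(representative_id = character(), label_kind = character(),
               score = numeric(), n_annotated_members = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bin consistency scores by a per-cluster metric
#'
#' Assigns each scored cluster to a half-open bin `(lo, hi]` of a per-cluster
#' metric (typically the cluster's mean LDDT) and reports, per bin, the
#' fraction of clusters with a perfect score of 1.0 and the mean score.
#' Empty bins are reported with `NA` statistics.
#'
#' @param scores Data frame with `representative_id` and `score` columns.
#' @param metric Named numeric vector: representative id -> metric value.
#' @param bin_edges Increasing numeric vector of bin edges; bins are
#'   `(edges[i], edges[i+1]]`.
#' @return Data frame with columns `bin`, `lo`, `hi`, `n`, `frac_perfect`,
#'   `mean_score`.
#' @export
consistency_vs_metric_binning <- function(scores, metric,
                                          bin_edges = c(0, 0.65, 0.8, 0.9, 1)) {
  stopifnot(all(diff(bin_edges) > 0))
  missing_m <- setdiff(scores$representative_id, names(metric))
  if (length(missing_m) > 0L) {
    ph_stop("no metric value for cluster(s): %s",
            paste(head(missing_m, 5L), collapse = ", "))
  }
  m <- metric[scores$representative_id]
  outside <- which(m <= bin_edges[1L] | m > bin_edges[length(bin_edges)])
  if (length(outside) > 0L) {
    ph_stop("metric value %g for cluster %s outside all bins",
            m[outside[1L]], scores$representative_id[outside[1L]])
  }
  # (lo, hi]: right-closed intervals
  idx <- findInterval(m, bin_edges, left.open = TRUE, rightmost.closed = FALSE)
  n_bins <- length(bin_edges) - 1L
  do.call(rbind, lapply(seq_len(n_bins), function(b) {
    s <- scores$score[idx == b]
    data.frame(bin = sprintf("(%g, %g]", bin_edges[b], bin_edges[b + 1L]),
               lo = bin_edges[b], hi = bin_edges[b + 1L], n = length(s),
               frac_perfect = if (length(s)) mean(s == 1.0) else NA_real_,
               mean_score = if (length(s)) mean(s) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Agreement between predicted and reference EC numbers
#'
#' For proteins present in both maps, measures per-level agreement of the
#' first one, two and three EC hierarchy tokens. At each level only proteins
#' whose predicted and reference codes both carry concrete (non-`-`) tokens
#' through that level are counted. Level 4 is excluded because top-scoring
#' predictions typically leave it unspecified.
#'
#' @param predicted Named character vector: protein id -> predicted EC code.
#' @param reference Named character vector: protein id -> reference EC code.
#' @return Data frame with columns `level`, `n`, `agreement`.
#' @export
deepfri_ec_agreement <- function(predicted, reference) {
  shared <- intersect(names(predicted), names(reference))
  if (length(shared) == 0L) ph_stop("no proteins shared between predicted and reference maps")
  pt <- lapply(predicted[shared], parse_ec)
  rt <- lapply(reference[shared], parse_ec)
  do.call(rbind, lapply(1:3, function(level) {
    ok <- vapply(seq_along(shared), function(i) {
      all(pt[[i]][seq_len(level)] != "-") && all(rt[[i]][seq_len(level)] != "-")
    }, TRUE)
    agree <- vapply(which(ok), function(i) {
      all(pt[[i]][seq_len(level)] == rt[[i]][seq_len(level)])
    }, TRUE)
    data.frame(level = level, n = sum(ok),
               agreement = if (sum(ok)) mean(agree) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Gate predictions on a confidence score
#'
#' Keeps predictions with score strictly greater than `min_score`.
#'
#' @param predictions Data frame with a `score` column.
#' @param min_score Strict lower bound, default 0.8.
#' @return List with `data` (retained rows), `n_total`, `n_retained`.
#' @export
confidence_gate <- function(predictions, min_score = 0.8) {
  keep <- !is.na(predictions$score) & predictions$score > min_score
  out <- predictions[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(data = out, n_total = nrow(predictions), n_retained = nrow(out))
}

#' Gate proteins on mean model confidence
#'
#' Keeps proteins whose mean pLDDT is strictly greater than `min_plddt`
#' (default 90), the gate applied before trusting function predictions.
#'
#' @param mean_plddt Named numeric vector: protein id -> mean pLDDT.
#' @param min_plddt Strict lower bound, default 90.
#' @return List with `ids` (retained, sorted), `n_total`, `n_retained`.
#' @export
plddt_gate <- function(mean_plddt, min_plddt = 90) {
  keep <- !is.na(mean_plddt) & mean_plddt > min_plddt
  list(ids = sort(names(mean_plddt)[keep]), n_total = length(mean_plddt),
       n_retained = sum(keep))
}

#' Default ambiguous terms for the semantic-consistency filter
#' @return Character vector of terms that disqualify a representative's
#'   sequence annotation from the semantic comparison.
#' @export
default_ambiguous_terms <- function() {
  c("hypothetical", "membrane", "structural", "virion", "putative")
}

normalize_annotation <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

#' Read synonym groups from a YAML or JSON config
#'
#' The config is a list of groups, each a list/vector of annotation strings
#' judged biologically equivalent (e.g. "Phage tail protein" and "Minor tail
#' protein"). Matching is case- and whitespace-insensitive.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List of character vectors.
#' @export
read_synonym_groups <- function(path) {
  if (!file.exists(path)) ph_stop("synonym config not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) return(list())
  lapply(raw, function(g) as.character(unlist(g)))
}

#' Semantic consistency of structure- vs sequence-based annotations
#'
#' Mechanizes the two-step semantic check. First, clusters whose
#' representative's sequence annotation contains an ambiguous term
#' (default: hypothetical, membrane, structural, virion, putative) are
#' removed. Then, among members of the retained clusters, a member is
#' consistent when its transferred structural annotation and its sequence
#' annotation are identical (after case/whitespace normalization) or fall in
#' the same synonym group. The result is the fraction of consistent members
#' over all members in retained clusters.
#'
#' @param clustering A clustering object.
#' @param transferred Structural annotations ([transfer_annotations()]).
#' @param products Sequence products data frame (`protein_id`, `product`).
#' @param synonym_groups List of character vectors of equivalent annotation
#'   strings (see [read_synonym_groups()]). Required: pass `list()` for
#'   "identity only". `NULL` raises an error directing the user to provide a
#'   config.
#' @param ambiguous_terms Terms disqualifying a representative annotation,
#'   default [default_ambiguous_terms()].
#' @return List with `fraction`, `n_members`, `n_consistent`,
#'   `n_clusters_retained`, `n_clusters_removed`.
#' @export
semantic_consistency <- function(clustering, transferred, products,
                                 synonym_groups,
                                 ambiguous_terms = default_ambiguous_terms()) {
  stopifnot(inherits(clustering, "phannot_clustering"))
  if (is.null(synonym_groups)) {
    ph_stop(paste("no synonym configuration supplied; provide synonym_groups",
                  "(a list of equivalence classes, e.g. via read_synonym_groups()),",
                  "or list() for identity-only matching"))
  }
  group_id <- list()
  for (i in seq_along(synonym_groups)) {
    for (s in normalize_annotation(synonym_groups[[i]])) group_id[[s]] <- i
  }
  seq_prod <- setNames(products$product, products$protein_id)
  str_prod <- setNames(transferred$product, transferred$protein_id)
  reps <- sort(names(clustering$clusters))
  # only clusters that actually received a structural annotation participate
  reps <- reps[reps %in% names(str_prod)]
  rep_seq_ann <- seq_prod[reps]
  ambiguous <- is.na(rep_seq_ann) | contains_any_term(rep_seq_ann, ambiguous_terms)
  retained <- reps[!ambiguous]
  n_members <- 0L
  n_consistent <- 0L
  for (r in retained) {
    for (m in clustering$clusters[[r]]) {
      n_members <- n_members + 1L
      a <- normalize_annotation(if (m %in% names(str_prod)) str_prod[[m]] else NA_character_)
      b <- normalize_annotation(if (m %in% names(seq_prod)) seq_prod[[m]] else NA_character_)
      if (is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) next
      same <- identical(a, b) ||
        (!is.null(group_id[[a]]) && !is.null(group_id[[b]]) &&
           group_id[[a]] == group_id[[b]])
      if (same) n_consistent <- n_consistent + 1L
    }
  }
  list(fraction = if (n_members > 0L) n_consistent / n_members else NA_real_,
       n_members = n_members, n_consistent = n_consistent,
       n_clusters_retained = length(retained),
       n_clusters_removed = sum(ambiguous))
}
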