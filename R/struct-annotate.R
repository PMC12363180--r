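# Structure-hit filtering, best-hit selection, void-match classification,
# representative-to-member annotation transfer, and the two annotation-rate
# formulas:
#   sequence-based rate  = (n_all - n_unannotated) / n_all
#   structure-based rate = (n_match - n_void) / n_all

#' Default void terms for structural matches
#'
#' A structural hit whose target name contains any of these terms (as a
#' case-insensitive substring) is an uninformative "void" match and does not
#' count as an annotation.
#'
#' @return Character vector of void terms.
#' @export
default_void_terms <- function() {
  c("putative", "hypothetical", "uncharacterized", "domain of unknown function")
}

#' Filter structure-search hits by TM-score and coverage
#'
#' Keeps alignment records with `tm_score >= min_tm` that satisfy the
#' coverage rule (bidirectional by default; `target` mode supports local,
#' domain-level searches). Thresholds are inclusive, matching the search
#' tools' own flag semantics. Records lacking a TM-score are skipped with a
#' warning.
#'
#' @param alignments Alignment data frame.
#' @param min_tm Minimum TM-score, default 0.5.
#' @param min_coverage Minimum coverage, default 0.8.
#' @param coverage_mode `"bidirectional"` (default) or `"target"`.
#' @return Filtered alignment data frame.
#' @export
filter_structure_hits <- function(alignments, min_tm = 0.5, min_coverage = 0.8,
                                  coverage_mode = c("bidirectional", "target")) {
  coverage_mode <- match.arg(coverage_mode)
  validate_alignments(alignments)
  if (nrow(alignments) == 0L) return(alignments)
  no_tm <- is.na(alignments$tm_score)
  if (any(no_tm)) {
    ph_warn("%d alignment record(s) lack tm_score; skipped", sum(no_tm))
  }
  cov_ok <- if (coverage_mode == "bidirectional") {
    alignments$query_cov >= min_coverage & alignments$target_cov >= min_coverage
  } else {
    alignments$target_cov >= min_coverage
  }
  keep <- !no_tm & alignments$tm_score >= min_tm & !is.na(cov_ok) & cov_ok
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.db_precedence <- c(PDB = 1L, AFDB_SwissProt = 2L, AFDB = 3L,
                    counter_defense = 4L, other = 4L)

#' Select the best structural hit for one query
#'
#' Among already-filtered hits of a single query, the highest TM-score wins;
#' ties go to the lower E-value, then to database precedence
#' (PDB > AFDB_SwissProt > AFDB > other), then to the lexicographically
#' smallest target id.
#'
#' @param hits Alignment data frame for one query (may be empty).
#' @return A one-row data frame, or `NULL` when no hits survive.
#' @export
select_best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  if (length(unique(hits$query_id)) > 1L) {
    ph_stop("select_best_hit expects hits of a single query; got %d",
            length(unique(hits$query_id)))
  }
  prec <- .db_precedence[ifelse(is.na(hits$target_db), "other", hits$target_db)]
  prec[is.na(prec)] <- 4L
  ev <- ifelse(is.na(hits$evalue), Inf, hits$evalue)
  ord <- order(-hits$tm_score, ev, prec, hits$target_id)
  out <- hits[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best hit per query over a filtered hit table
#'
#' Applies [select_best_hit()] to every query in the table.
#'
#' @param alignments Filtered alignment data frame.
#' @return Data frame with one row per query that has at least one hit.
#' @export
best_hits_by_query <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  pieces <- split(alignments, alignments$query_id)
  out <- do.call(rbind, lapply(pieces[sort(names(pieces))], select_best_hit))
  rownames(out) <- NULL
  out
}

#' Classify a structural hit name as a void match
#'
#' `TRUE` when any void term occurs as a case-insensitive substring of the
#' target name, or when the name is absent or empty (an uninformative match).
#'
#' @param target_name Character vector of hit names.
#' @param void_terms Terms marking uninformative names; defaults to
#'   [default_void_terms()].
#' @return Logical vector.
#' @export
classify_void <- function(target_name, void_terms = default_void_terms()) {
  empty <- is.na(target_name) | !nzchar(trimws(target_name))
  empty | contains_any_term(target_name, void_terms)
}

#' Is a sequence-level product annotation uninformative?
#'
#' `TRUE` when the product contains "hypothetical protein" (case-insensitive)
#' or is empty/absent.
#'
#' @param product Character vector of GFF product strings.
#' @return Logical vector.
#' @export
is_sequence_unannotated <- function(product) {
  empty <- is.na(product) | !nzchar(trimws(product))
  empty | contains_any_term(product, "hypothetical protein")
}

#' Transfer representative best-hit annotations to all cluster members
#'
#' Every member of a cluster whose representative has a best structural hit
#' receives that hit's target name as its product, with source
#' `structure_transfer`. Clusters whose representative has no hit contribute
#' no records.
#'
#' @param clustering A clustering object.
#' @param rep_best_hits Data frame of best hits (one row per representative;
#'   columns `query_id`, `target_name`). Every `query_id` must be a
#'   representative in `clustering`.
#' @return Data frame with columns `protein_id`, `product`, `source`.
#' @export
transfer_annotations <- function(clustering, rep_best_hits) {
  stopifnot(inherits(clustering, "phannot_clustering"))
  reps <- names(clustering$clusters)
  if (is.null(rep_best_hits) || nrow(rep_best_hits) == 0L) {
    return(data.frame(protein_id = character(), product = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  bad <- setdiff(rep_best_hits$query_id, reps)
  if (length(bad) > 0L) {
    ph_stop("best-hit query id(s) not representatives: %s",
            paste(head(bad, 5L), collapse = ", "))
  }
  if (anyDuplicated(rep_best_hits$query_id)) {
    ph_stop("multiple best hits for representative(s): %s",
            paste(unique(rep_best_hits$query_id[duplicated(rep_best_hits$query_id)]),
                  collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(rep_best_hits)), function(i) {
    r <- rep_best_hits$query_id[i]
    data.frame(protein_id = clustering$clusters[[r]],
               product = rep_best_hits$target_name[i],
               source = "structure_transfer", stringsAsFactors = FALSE)
  }))
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sequence-based annotation rate
#'
#' Rate = (n_all - n_unannotated) / n_all, where a protein is unannotated
#' when its product field is empty or contains "hypothetical protein".
#'
#' @param products Data frame with columns `protein_id`, `product`.
#' @return List with `rate` and `tally` (n_all, n_unannotated, n_match,
#'   n_void; the latter two `NA` for the sequence formula).
#' @export
sequence_annotation_rate <- function(products) {
  n_all <- nrow(products)
  if (is.null(n_all) || n_all == 0L) ph_stop("undefined rate: empty protein set")
  n_unannotated <- sum(is_sequence_unannotated(products$product))
  list(rate = (n_all - n_unannotated) / n_all,
       tally = list(n_all = n_all, n_unannotated = n_unannotated,
                    n_match = NA_integer_, n_void = NA_integer_))
}

#' Structure-based annotation rate
#'
#' Rate = (n_match - n_void) / n_all, where n_all counts every protein in
#' the input set, n_match counts proteins that received a transferred
#' structural annotation, and n_void counts transferred annotations whose
#' target name is a void match.
#'
#' @param all_ids Character vector of all protein ids under consideration.
#' @param transferred Data frame from [transfer_annotations()].
#' @param void_terms Terms marking void matches; defaults to
#'   [default_void_terms()].
#' @return List with `rate` and `tally` (n_all, n_unannotated = NA, n_match,
#'   n_void).
#' @export
structure_annotation_rate <- function(all_ids, transferred,
                                      void_terms = default_void_terms()) {
  all_ids <- unique(as.character(all_ids))
  n_all <- length(all_ids)
  if (n_all == 0L) ph_stop("undefined rate: empty protein set")
  if (nrow(transferred) > 0L) {
    stray <- setdiff(transferred$protein_id, all_ids)
    if (length(stray) > 0L) {
      ph_stop("transferred annotation for unknown protein(s): %s",
              paste(head(stray, 5L), collapse = ", "))
    }
    if (anyDuplicated(transferred$protein_id)) {
      ph_stop("multiple transferred annotations for protein(s): %s",
              paste(unique(transferred$protein_id[duplicated(transferred$protein_id)]),
                    collapse = ", "))
    }
  }
  n_match <- nrow(transferred)
  n_void <- if (n_match > 0L) sum(classify_void(transferred$product, void_terms)) else 0L
  list(rate = (n_match - n_void) / n_all,
       tally = list(n_all = n_all, n_unannotated = NA_integer_,
                    n_match = n_match, n_void = n_void))
}

#' Annotation rates per phage and per phage group
#'
#' Computes the sequence- and structure-based rates for every phage, then
#' averages within each phage group and overall. Two variants are emitted:
#' `*_mean` (unweighted mean of per-phage rates, the "average per phage"
#' reading) and `*_pooled` (rates recomputed over all proteins of the group,
#' the "pooled denominator" reading).
#'
#' @param products Sequence products data frame (`protein_id`, `product`)
#'   covering every protein.
#' @param transferred Transferred structural annotations
#'   ([transfer_annotations()]).
#' @param protein_to_phage Named character vector: protein id -> phage id.
#' @param metadata Data frame with `phage_id`, `group`, `lifestyle`.
#' @param void_terms Void terms for the structure formula.
#' @return List with data frames `per_phage`, `per_group`, and a one-row
#'   `overall` data frame.
#' @export
per_group_rates <- function(products, transferred, protein_to_phage, metadata,
                            void_terms = default_void_terms()) {
  unmapped <- setdiff(products$protein_id, names(protein_to_phage))
  if (length(unmapped) > 0L) {
    ph_stop("protein(s) without phage mapping: %s",
            paste(head(unmapped, 5L), collapse = ", "))
  }
  phage <- protein_to_phage[products$protein_id]
  group_of <- setNames(as.character(metadata$group), metadata$phage_id)
  no_meta <- setdiff(unique(phage), names(group_of))
  if (length(no_meta) > 0L) {
    ph_stop("phage(s) without metadata: %s", paste(head(no_meta, 5L), collapse = ", "))
  }
  trans_prod <- setNames(transferred$product, transferred$protein_id)
  rate_pair <- function(ids) {
    seq_r <- sequence_annotation_rate(products[products$protein_id %in% ids, , drop = FALSE])$rate
    got <- intersect(ids, names(trans_prod))
    tr <- data.frame(protein_id = got, product = unname(trans_prod[got]),
                     stringsAsFactors = FALSE)
    str_r <- structure_annotation_rate(ids, tr, void_terms)$rate
    c(seq_r, str_r)
  }
  per_phage <- do.call(rbind, lapply(sort(unique(phage)), function(p) {
    ids <- products$protein_id[phage == p]
    r <- rate_pair(ids)
    data.frame(phage_id = p, group = unname(group_of[p]), n_proteins = length(ids),
               seq_rate = r[1], struct_rate = r[2], stringsAsFactors = FALSE)
  }))
  per_group <- do.call(rbind, lapply(sort(unique(per_phage$group)), function(g) {
    sub <- per_phage[per_phage$group == g, , drop = FALSE]
    ids <- products$protein_id[group_of[phage] == g]
    r <- rate_pair(ids)
    data.frame(group = g, n_phages = nrow(sub),
               seq_rate_mean = mean(sub$seq_rate),
               struct_rate_mean = mean(sub$struct_rate),
               seq_rate_pooled = r[1], struct_rate_pooled = r[2],
               stringsAsFactors = FALSE)
  }))
  r_all <- rate_pair(products$protein_id)
  overall <- data.frame(n_phages = nrow(per_phage),
                        seq_rate_mean = mean(per_phage$seq_rate),
                        struct_rate_mean = mean(per_phage$struct_rate),
                        seq_rate_pooled = r_all[1], struct_rate_pooled = r_all[2],
                        stringsAsFactors = FALSE)
  list(per_phage = per_phage, per_group = per_group, overall = overall)
}

#' Mean pLDDT of a structure model
#'
#' @param model A `structure_model` (see [read_plddt()]) or numeric vector of
#'   per-residue pLDDT values.
#' @return Arithmetic mean pLDDT in \[0,100\].
#' @export
mean_plddt <- function(model) {
  v <- if (inherits(model, "structure_model")) model$plddt else as.numeric(model)
  if (length(v) == 0L) ph_stop("empty structure model")
  mean(v)
}

#' Classify a model by mean pLDDT
#'
#' Models with mean pLDDT >= `high_cutoff` (default 70, inclusive) are
#' `High_pLDDT`; below, `Low_pLDDT`.
#'
#' @param mean_value Numeric vector of mean pLDDT values.
#' @param high_cutoff Inclusive cutoff, default 70.
#' @return Character vector of `"High_pLDDT"` / `"Low_pLDDT"`.
#' @export
classify_plddt <- function(mean_value, high_cutoff = 70) {
  ifelse(mean_value >= high_cutoff, "High_pLDDT", "Low_pLDDT")
}

#' Screen hits against a counter-defense protein library
#'
#' Keeps alignment records with TM-score strictly above the threshold
#' (default 0.6), the screen used to nominate phage counter-defense
#' candidates. Records lacking a TM-score are dropped.
#'
#' @param alignments Alignment data frame (hits vs the counter-defense
#'   library).
#' @param min_tm Strict lower bound on TM-score, default 0.6.
#' @return Filtered alignment data frame.
#' @export
counter_defense_screen <- function(alignments, min_tm = 0.6) {
  validate_alignments(alignments)
  keep <- !is.na(alignments$tm_score) & alignments$tm_score > min_tm
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
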