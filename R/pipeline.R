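# Orchestration: a validated configuration object, run_* stage functions
# writing their outputs plus a machine-readable manifest, and run_all()
# chaining the stages over a fixture-style input directory.

#' Pipeline configuration
#'
#' Collects every tunable threshold with the defaults used throughout the
#' workflow: clustering at 50% identity with 90% bidirectional coverage
#' (mirroring `--min-seq-id 0.5`, `-c 0.9`, `--cov-mode 0`), structural-hit
#' acceptance at TM-score 0.5 with 80% bidirectional coverage
#' (`--tmscore-threshold 0.5`, `-c 0.8`), the strict TM > 0.6
#' counter-defense screen, the pLDDT 70 high/low split and strict pLDDT > 90
#' prediction gate, the strict score > 0.8 confidence gate for EC
#' predictions, and the 0.5 / 0.7 interaction screening thresholds.
#'
#' @param input_dir Directory of input files (the layout written by
#'   [write_fixture_dir()]).
#' @param output_dir Directory for stage outputs.
#' @param min_identity,cluster_coverage,cluster_coverage_mode Clustering
#'   thresholds.
#' @param hit_tm,hit_coverage,hit_coverage_mode Structure-hit acceptance
#'   thresholds.
#' @param counter_defense_tm Strict TM-score bound of the counter-defense
#'   screen.
#' @param plddt_high Inclusive high/low mean-pLDDT split.
#' @param plddt_gate Strict mean-pLDDT gate for function predictions.
#' @param deepfri_score Strict confidence gate for EC predictions.
#' @param interaction_thresholds Strict interaction screening thresholds
#'   (network, stringent list).
#' @param interaction_score_mode `"weighted"` (0.8*ipTM + 0.2*pTM) or
#'   `"sum"` (raw ipTM + pTM) as the screened quantity.
#' @param void_terms,ambiguous_terms Term lists for void-match and
#'   ambiguous-annotation classification.
#' @param synonym_groups_path Optional path to a synonym-group YAML/JSON;
#'   `NULL` uses [default_synonym_groups()].
#' @param seed Seed for stages that simulate.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            min_identity = 0.5, cluster_coverage = 0.9,
                            cluster_coverage_mode = "bidirectional",
                            hit_tm = 0.5, hit_coverage = 0.8,
                            hit_coverage_mode = "bidirectional",
                            counter_defense_tm = 0.6,
                            plddt_high = 70, plddt_gate = 90,
                            deepfri_score = 0.8,
                            interaction_thresholds = c(0.5, 0.7),
                            interaction_score_mode = "weighted",
                            void_terms = default_void_terms(),
                            ambiguous_terms = default_ambiguous_terms(),
                            synonym_groups_path = NULL,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  chk01 <- c(min_identity = cfg$min_identity, cluster_coverage = cfg$cluster_coverage,
             hit_tm = cfg$hit_tm, hit_coverage = cfg$hit_coverage,
             counter_defense_tm = cfg$counter_defense_tm,
             deepfri_score = cfg$deepfri_score, cfg$interaction_thresholds)
  bad <- names(chk01)[chk01 < 0 | chk01 > 1]
  if (length(bad) > 0L) {
    ph_stop("config threshold(s) outside [0,1]: %s", paste(bad, collapse = ", "))
  }
  if (cfg$plddt_high < 0 || cfg$plddt_high > 100 ||
      cfg$plddt_gate < 0 || cfg$plddt_gate > 100) {
    ph_stop("pLDDT thresholds must lie in [0,100]")
  }
  if (!cfg$interaction_score_mode %in% c("weighted", "sum")) {
    ph_stop("interaction_score_mode must be 'weighted' or 'sum'")
  }
  if (!cfg$cluster_coverage_mode %in% c("bidirectional", "target") ||
      !cfg$hit_coverage_mode %in% c("bidirectional", "target")) {
    ph_stop("coverage modes must be 'bidirectional' or 'target'")
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML, with overrides
#'
#' Values in the YAML file override the package defaults; `...` overrides
#' both.
#'
#' @param path Path to a YAML config file (optional).
#' @param ... Named overrides of [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path = NULL, ...) {
  args <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) ph_stop("config file not found: %s", path)
    args <- yaml::read_yaml(path) %||% list()
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0L) {
    ph_stop("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, args)
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(cfg)[order(names(unclass(cfg)))], tf)
  unname(tools::md5sum(tf))
}

write_manifest <- function(cfg, stage, outputs, out_dir) {
  inputs <- list.files(cfg$input_dir %||% "", full.names = TRUE, recursive = TRUE)
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("phannot")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else list(),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

req_input <- function(cfg, name) {
  p <- file.path(cfg$input_dir, name)
  if (!file.exists(p)) ph_stop("missing input: %s", p)
  p
}

ensure_outdir <- function(cfg) {
  if (is.null(cfg$output_dir)) ph_stop("config lacks output_dir")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$output_dir
}

read_fixture_hits <- function(path) {
  read_alignment_table(path, column_map = fixture_hit_columns())
}

#' Generate a fixture input directory (simulate stage)
#'
#' @param cfg A [pipeline_config()]; `cfg$seed` seeds the generator and
#'   `cfg$input_dir` receives the files.
#' @param spec Optional [fixture_spec()] (its seed is replaced by
#'   `cfg$seed`).
#' @return The fixture bundle, invisibly.
#' @export
run_simulate <- function(cfg, spec = NULL) {
  if (is.null(cfg$input_dir)) ph_stop("config lacks input_dir")
  spec <- spec %||% fixture_spec(seed = cfg$seed)
  spec$seed <- cfg$seed
  bundle <- generate_fixtures(spec)
  write_fixture_dir(bundle, cfg$input_dir)
  invisible(bundle)
}

#' Cluster proteins from pairwise alignments (cluster stage)
#'
#' Builds the thresholded similarity graph over all proteins in
#' `proteins.fasta` (isolated proteins become singletons), runs greedy
#' set-cover clustering plus the reassignment pass, and writes
#' `clusters.tsv` and `cluster_sizes.tsv`.
#'
#' @param cfg A [pipeline_config()].
#' @return The clustering, invisibly.
#' @export
run_cluster <- function(cfg) {
  out <- ensure_outdir(cfg)
  seqs <- read_fasta(req_input(cfg, "proteins.fasta"))
  aln <- read_alignment_table(req_input(cfg, "cluster_alignments.tsv"))
  message(sprintf("cluster: %d alignment rows over %d proteins",
                  nrow(aln), nrow(seqs)))
  graph <- build_similarity_graph(aln, min_identity = cfg$min_identity,
                                  min_coverage = cfg$cluster_coverage,
                                  coverage_mode = cfg$cluster_coverage_mode,
                                  node_ids = seqs$protein_id)
  message(sprintf("cluster: %d qualifying edges", nrow(graph$edges)))
  clustering <- reassign_members(greedy_set_cover_cluster(graph), graph)
  write_cluster_tsv(clustering, file.path(out, "clusters.tsv"))
  sizes <- cluster_size_summary(clustering)
  write.table(sizes, file.path(out, "cluster_sizes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "cluster", c("clusters.tsv", "cluster_sizes.tsv"), out)
  invisible(clustering)
}

#' Transfer structural annotations and compute rates (annotate stage)
#'
#' Filters database hits at the TM/coverage thresholds, selects a best hit
#' per representative, transfers the best-hit names to all cluster members
#' and writes `annotations.tsv` (protein, product, source, void flag) plus
#' `rates.json` / `rates_per_group.tsv` with both annotation-rate formulas.
#'
#' @param cfg A [pipeline_config()].
#' @param clustering Optional clustering; defaults to `clusters.tsv` in the
#'   output directory (from [run_cluster()]).
#' @return List with the transferred annotations and rate reports,
#'   invisibly.
#' @export
run_annotate <- function(cfg, clustering = NULL) {
  out <- ensure_outdir(cfg)
  if (is.null(clustering)) {
    clustering <- read_cluster_tsv(file.path(out, "clusters.tsv"))
  }
  products <- read_products_from_gff(req_input(cfg, "products.gff"))
  if (nrow(products) == 0L) ph_stop("undefined rate: empty protein set")
  hits <- read_fixture_hits(req_input(cfg, "struct_hits.tsv"))
  db_hits <- hits[is.na(hits$target_db) | hits$target_db != "counter_defense", ,
                  drop = FALSE]
  message(sprintf("annotate: %d database hit rows", nrow(db_hits)))
  kept <- filter_structure_hits(db_hits, min_tm = cfg$hit_tm,
                                min_coverage = cfg$hit_coverage,
                                coverage_mode = cfg$hit_coverage_mode)
  message(sprintf("annotate: %d rows pass TM/coverage filter", nrow(kept)))
  best <- best_hits_by_query(kept)
  transferred <- transfer_annotations(clustering, best)
  message(sprintf("annotate: %d transferred annotations", nrow(transferred)))
  seq_rate <- sequence_annotation_rate(products)
  str_rate <- structure_annotation_rate(products$protein_id, transferred,
                                        cfg$void_terms)
  ann <- transferred
  ann$void <- classify_void(ann$product, cfg$void_terms)
  write.table(ann, file.path(out, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rates <- list(sequence = seq_rate, structure = str_rate)
  p2p_path <- file.path(cfg$input_dir, "protein_to_phage.tsv")
  md_path <- file.path(cfg$input_dir, "metadata.tsv")
  if (file.exists(p2p_path) && file.exists(md_path)) {
    p2p <- read.delim(p2p_path, stringsAsFactors = FALSE)
    metadata <- read.delim(md_path, stringsAsFactors = FALSE)
    grp <- per_group_rates(products, transferred,
                           setNames(p2p$phage_id, p2p$protein_id), metadata,
                           cfg$void_terms)
    write.table(grp$per_group, file.path(out, "rates_per_group.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rates$per_group <- grp
  }
  jsonlite::write_json(
    list(sequence_rate = seq_rate$rate, structure_rate = str_rate$rate,
         tally = c(seq_rate$tally[c("n_all", "n_unannotated")],
                   str_rate$tally[c("n_match", "n_void")])),
    file.path(out, "rates.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "annotate",
                 c("annotations.tsv", "rates.json", "rates_per_group.tsv"), out)
  invisible(list(transferred = transferred, rates = rates, best_hits = best))
}

#' Cluster purity and label consistency (purity stage)
#'
#' Computes per-cluster LDDT/TM means from the within-cluster alignment rows,
#' Pfam and four-level EC consistency from `labels.tsv`, the semantic
#' consistency between transferred and sequence annotations, and the
#' consistency-vs-LDDT binned summary. Writes `purity.tsv`,
#' `consistency.tsv`, `consistency_bins.tsv` and `consistency_report.json`.
#'
#' @param cfg A [pipeline_config()].
#' @param clustering Optional clustering (defaults to `clusters.tsv`).
#' @param transferred Optional transferred annotations (defaults to
#'   `annotations.tsv`).
#' @return List of reports, invisibly.
#' @export
run_purity <- function(cfg, clustering = NULL, transferred = NULL) {
  out <- ensure_outdir(cfg)
  if (is.null(clustering)) {
    clustering <- read_cluster_tsv(file.path(out, "clusters.tsv"))
  }
  aln <- read_alignment_table(req_input(cfg, "cluster_alignments.tsv"))
  purity <- suppressWarnings(structural_purity(clustering, aln))
  write.table(purity$per_cluster, file.path(out, "purity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  labels <- read.delim(req_input(cfg, "labels.tsv"), stringsAsFactors = FALSE)
  pfam <- setNames(strsplit(labels$pfam, ",", fixed = TRUE), labels$protein_id)
  ec <- setNames(strsplit(labels$ec, ",", fixed = TRUE), labels$protein_id)
  cons <- rbind(cluster_consistency(clustering, pfam, "pfam"),
                do.call(rbind, lapply(1:4, function(l) {
                  cluster_consistency(clustering, ec, "ec", level = l)
                })))
  write.table(cons, file.path(out, "consistency.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pf <- cons[cons$label_kind == "pfam", , drop = FALSE]
  metric <- setNames(purity$per_cluster$mean_lddt, purity$per_cluster$representative_id)
  bins <- NULL
  binnable <- pf[pf$representative_id %in% names(metric), , drop = FALSE]
  if (nrow(binnable) > 0L) {
    bins <- consistency_vs_metric_binning(binnable, metric)
    write.table(bins, file.path(out, "consistency_bins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (is.null(transferred)) {
    ann_path <- file.path(out, "annotations.tsv")
    transferred <- if (file.exists(ann_path)) {
      read.delim(ann_path, stringsAsFactors = FALSE)
    } else NULL
  }
  sem <- NULL
  if (!is.null(transferred) && nrow(transferred) > 0L) {
    products <- read_products_from_gff(req_input(cfg, "products.gff"))
    groups <- if (!is.null(cfg$synonym_groups_path)) {
      read_synonym_groups(cfg$synonym_groups_path)
    } else default_synonym_groups()
    sem <- semantic_consistency(clustering, transferred, products, groups,
                                cfg$ambiguous_terms)
  }
  report <- list(
    median_lddt = unname(purity$medians["lddt"]),
    median_tm = unname(purity$medians["tm"]),
    pfam_mean = if (nrow(pf)) mean(pf$score) else NA_real_,
    pfam_frac_perfect = if (nrow(pf)) mean(pf$score == 1.0) else NA_real_,
    semantic = sem)
  jsonlite::write_json(report, file.path(out, "consistency_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, "purity",
                 c("purity.tsv", "consistency.tsv", "consistency_report.json"), out)
  invisible(list(purity = purity, consistency = cons, bins = bins,
                 semantic = sem, report = report))
}

#' Taxonomy of structural homologs (lca stage)
#'
#' Reads the taxdump, computes a per-query LCA over database hits and the
#' superkingdom distributions of both per-query LCAs and raw best hits.
#' Writes `lca.tsv`, `superkingdoms.tsv` and `rank_breakdown.tsv`.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `lca`, `dist_best_hits`, `dist_lca`, invisibly.
#' @export
run_lca <- function(cfg) {
  out <- ensure_outdir(cfg)
  tree <- read_taxdump(req_input(cfg, file.path("taxdump", "nodes.dmp")),
                       req_input(cfg, file.path("taxdump", "names.dmp")))
  hits <- read_fixture_hits(req_input(cfg, "struct_hits.tsv"))
  db_hits <- hits[is.na(hits$target_db) | hits$target_db != "counter_defense", ,
                  drop = FALSE]
  kept <- filter_structure_hits(db_hits, min_tm = cfg$hit_tm,
                                min_coverage = cfg$hit_coverage,
                                coverage_mode = cfg$hit_coverage_mode)
  res <- suppressWarnings(per_query_lca(kept, tree))
  write.table(res, file.path(out, "lca.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  best <- best_hits_by_query(kept)
  best_tax <- best$target_taxid[!is.na(best$target_taxid)]
  dist_best <- rank_distribution(best_tax, tree, "superkingdom")
  dist_lca <- rank_distribution(res, tree, "superkingdom")
  write.table(dist_best, file.path(out, "superkingdoms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  brk <- rank_breakdown(best_tax, tree)
  if (!is.null(brk)) {
    write.table(brk, file.path(out, "rank_breakdown.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write_manifest(cfg, "lca", c("lca.tsv", "superkingdoms.tsv"), out)
  invisible(list(lca = res, dist_best_hits = dist_best, dist_lca = dist_lca))
}

#' Interaction screening, networks and heatmap (interactions stage)
#'
#' Scores the ipTM/pTM table, screens at both configured thresholds, builds
#' the phage-host network at the lower threshold (node sizes from cluster
#' sizes), screens counter-defense hits at the strict TM bound, and writes
#' the per-group normalized heatmap of counter-defense hit counts.
#'
#' @param cfg A [pipeline_config()].
#' @param clustering Optional clustering (defaults to `clusters.tsv`) used
#'   for phage node sizes.
#' @return List of results, invisibly.
#' @export
run_interactions <- function(cfg, clustering = NULL) {
  out <- ensure_outdir(cfg)
  if (is.null(clustering)) {
    clustering <- read_cluster_tsv(file.path(out, "clusters.tsv"))
  }
  records <- read.delim(req_input(cfg, "interactions.tsv"),
                        stringsAsFactors = FALSE)
  th <- sort(cfg$interaction_thresholds)
  screened <- lapply(th, function(t) {
    screen_interactions(records, t, cfg$interaction_score_mode)
  })
  names(screened) <- sprintf("t%g", th)
  for (i in seq_along(th)) {
    write.table(screened[[i]],
                file.path(out, sprintf("interactions_screened_%g.tsv", th[i])),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  message(sprintf("interactions: %d/%d records pass threshold %g",
                  nrow(screened[[1L]]), nrow(records), th[1L]))
  sizes <- setNames(lengths(clustering$clusters), names(clustering$clusters))
  present <- unique(screened[[1L]]$phage_protein_id)
  sizes_full <- setNames(rep(1L, length(present)), present)
  sizes_full[intersect(present, names(sizes))] <-
    sizes[intersect(present, names(sizes))]
  net <- build_network(screened[[1L]], sizes_full)
  write_network(net, graphml_path = file.path(out, "network.graphml"),
                edges_path = file.path(out, "network_edges.tsv"))
  # counter-defense screen and per-group normalized heatmap
  heat <- NULL
  cd <- NULL
  hits_path <- file.path(cfg$input_dir, "struct_hits.tsv")
  p2p_path <- file.path(cfg$input_dir, "protein_to_phage.tsv")
  md_path <- file.path(cfg$input_dir, "metadata.tsv")
  if (file.exists(hits_path) && file.exists(p2p_path) && file.exists(md_path)) {
    hits <- read_fixture_hits(hits_path)
    cd <- counter_defense_screen(
      hits[!is.na(hits$target_db) & hits$target_db == "counter_defense", ,
           drop = FALSE],
      cfg$counter_defense_tm)
    p2p <- read.delim(p2p_path, stringsAsFactors = FALSE)
    md <- read.delim(md_path, stringsAsFactors = FALSE)
    if (nrow(cd) > 0L) {
      phage_of <- setNames(p2p$phage_id, p2p$protein_id)
      group_of <- setNames(md$group, md$phage_id)
      counts <- as.data.frame(table(
        category = cd$target_name,
        group = group_of[phage_of[cd$query_id]]), stringsAsFactors = FALSE)
      names(counts)[3] <- "count"
      per_group <- table(factor(md$group, levels = sort(unique(md$group))))
      heat <- normalized_cluster_heatmap(counts,
                                         setNames(as.integer(per_group),
                                                  names(per_group)))
      write.table(heat, file.path(out, "counter_defense_heatmap.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
    }
  }
  write_manifest(cfg, "interactions",
                 c("network_edges.tsv", "network.graphml"), out)
  invisible(list(screened = screened, network = net, counter_defense = cd,
                 heatmap = heat))
}

#' Run the full workflow end to end
#'
#' Chains cluster, annotate, purity, lca and interactions over the input
#' directory and writes a combined `report.json`.
#'
#' @param cfg A [pipeline_config()].
#' @return List with every stage's results, invisibly.
#' @export
run_all <- function(cfg) {
  out <- ensure_outdir(cfg)
  clustering <- run_cluster(cfg)
  ann <- run_annotate(cfg, clustering = clustering)
  pur <- run_purity(cfg, clustering = clustering,
                    transferred = ann$transferred)
  lc <- run_lca(cfg)
  intr <- run_interactions(cfg, clustering = clustering)
  report <- list(
    n_clusters = length(clustering$clusters),
    sequence_rate = ann$rates$sequence$rate,
    structure_rate = ann$rates$structure$rate,
    median_lddt = pur$report$median_lddt,
    median_tm = pur$report$median_tm,
    pfam_frac_perfect = pur$report$pfam_frac_perfect,
    superkingdoms = lc$dist_best_hits,
    n_screened = vapply(intr$screened, nrow, 1L))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(clustering = clustering, annotate = ann, purity = pur,
                 lca = lc, interactions = intr, report = report))
}
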