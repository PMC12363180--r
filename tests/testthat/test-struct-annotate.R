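test_that("structure-hit filtering applies TM and coverage rules", {
  aln <- rbind(
    make_alignment_rows("q1", "t1", tm = 0.62, qcov = 0.85, tcov = 0.83),
    make_alignment_rows("q2", "t2", tm = 0.45, qcov = 0.95, tcov = 0.95),
    make_alignment_rows("q3", "t3", tm = 0.62, qcov = 0.75, tcov = 0.95),
    make_alignment_rows("q4", "t4", tm = 0.50, qcov = 0.80, tcov = 0.80))
  kept <- filter_structure_hits(aln)
  expect_setequal(kept$query_id, c("q1", "q4"))  # thresholds inclusive
  # target-only mode admits the low-query-coverage record
  kept_t <- filter_structure_hits(aln, coverage_mode = "target")
  expect_true("q3" %in% kept_t$query_id)
  # records lacking tm_score are skipped with a warning
  aln$tm_score[1] <- NA
  expect_warning(kept2 <- filter_structure_hits(aln), "lack tm_score")
  expect_false("q1" %in% kept2$query_id)
})

test_that("best-hit selection ranks by TM, then E-value, then database, then id", {
  h <- rbind(
    make_alignment_rows("q", "tA", tm = 0.7, evalue = 1e-3, db = "AFDB"),
    make_alignment_rows("q", "tB", tm = 0.9, evalue = 1e-3, db = "AFDB"))
  expect_equal(select_best_hit(h)$target_id, "tB")

  h2 <- rbind(
    make_alignment_rows("q", "tA", tm = 0.9, evalue = 1e-3, db = "AFDB"),
    make_alignment_rows("q", "tB", tm = 0.9, evalue = 1e-8, db = "AFDB"))
  expect_equal(select_best_hit(h2)$target_id, "tB")

  h3 <- rbind(
    make_alignment_rows("q", "tA", tm = 0.9, evalue = 1e-8, db = "AFDB"),
    make_alignment_rows("q", "tB", tm = 0.9, evalue = 1e-8, db = "PDB"))
  expect_equal(select_best_hit(h3)$target_id, "tB")

  h4 <- rbind(
    make_alignment_rows("q", "tB", tm = 0.9, evalue = 1e-8, db = "PDB"),
    make_alignment_rows("q", "tA", tm = 0.9, evalue = 1e-8, db = "PDB"))
  expect_equal(select_best_hit(h4)$target_id, "tA")

  expect_null(select_best_hit(h[0, ]))
  expect_error(select_best_hit(rbind(h, make_alignment_rows("q2", "t"))), "single query")
})

test_that("void classification is substring-based, case-insensitive, empty-true", {
  expect_true(classify_void("Putative DNA-binding protein"))
  expect_false(classify_void("Major capsid protein"))
  expect_true(classify_void(""))
  expect_true(classify_void(NA_character_))
  expect_true(classify_void("Domain of Unknown Function DUF4011"))
  expect_equal(classify_void(c("putative x", "capsid")), c(TRUE, FALSE))
  # custom term list
  expect_true(classify_void("probable kinase", void_terms = "probable"))
  expect_false(classify_void("putative kinase", void_terms = "probable"))
})

test_that("sequence unannotated rule matches 'hypothetical protein' and empties", {
  expect_true(is_sequence_unannotated("hypothetical protein"))
  expect_false(is_sequence_unannotated("terminase large subunit"))
  expect_true(is_sequence_unannotated("Hypothetical Protein gp42"))
  expect_true(is_sequence_unannotated(""))
})

test_that("annotation transfer copies the best-hit name to all members", {
  cl <- new_clustering(list(r = c("r", "a", "b"), s = c("s", "x")))
  best <- data.frame(query_id = "r", target_name = "terminase",
                     stringsAsFactors = FALSE)
  tr <- transfer_annotations(cl, best)
  expect_equal(nrow(tr), 3L)
  expect_true(all(tr$product == "terminase"))
  expect_true(all(tr$source == "structure_transfer"))
  expect_setequal(tr$protein_id, c("r", "a", "b"))
  # conservation: transferred rows = sum of sizes of clusters with a hit
  best2 <- rbind(best, data.frame(query_id = "s", target_name = "portal",
                                  stringsAsFactors = FALSE))
  expect_equal(nrow(transfer_annotations(cl, best2)), 5L)
  expect_error(transfer_annotations(cl, data.frame(query_id = "zz",
                                                   target_name = "x")),
               "not representatives")
})

test_that("annotation-rate formulas match their definitions", {
  prods <- data.frame(protein_id = sprintf("p%d", 1:10),
                      product = c(rep("hypothetical protein", 4),
                                  rep("tail protein", 6)),
                      stringsAsFactors = FALSE)
  sr <- sequence_annotation_rate(prods)
  expect_equal(sr$rate, 0.6)
  expect_equal(sr$tally$n_unannotated, 4L)

  all_hyp <- data.frame(protein_id = "p", product = "hypothetical protein")
  expect_equal(sequence_annotation_rate(all_hyp)$rate, 0)
  expect_error(sequence_annotation_rate(prods[0, ]), "undefined rate")

  ids <- sprintf("p%d", 1:10)
  tr <- data.frame(protein_id = ids[1:8],
                   product = c(rep("putative protein", 3), rep("capsid", 5)),
                   stringsAsFactors = FALSE)
  st <- structure_annotation_rate(ids, tr)
  expect_equal(st$tally$n_match, 8L)
  expect_equal(st$tally$n_void, 3L)
  expect_equal(st$rate, 0.5)
  expect_equal(structure_annotation_rate(ids, tr[0, ])$rate, 0)
  expect_error(structure_annotation_rate(ids[1:3], tr), "unknown protein")
})

test_that("structure rate never increases as void terms grow", {
  ids <- sprintf("p%d", 1:6)
  tr <- data.frame(protein_id = ids,
                   product = c("putative x", "probable y", "capsid",
                               "tail", "DUF21 domain of unknown function", "portal"),
                   stringsAsFactors = FALSE)
  r1 <- structure_annotation_rate(ids, tr, void_terms = "putative")$rate
  r2 <- structure_annotation_rate(ids, tr, void_terms = c("putative", "probable"))$rate
  r3 <- structure_annotation_rate(ids, tr, void_terms = default_void_terms())$rate
  expect_true(r2 <= r1)
  expect_true(r3 <= r2)
})

test_that("per-group rates average per-phage rates within groups", {
  prods <- data.frame(
    protein_id = sprintf("p%d", 1:10),
    product = c(rep("hypothetical protein", 3), rep("capsid", 2),   # phage A1: 0.4
                rep("hypothetical protein", 2), rep("capsid", 3)),  # phage A2: 0.6
    stringsAsFactors = FALSE)
  p2p <- setNames(rep(c("phA1", "phA2"), each = 5), prods$protein_id)
  metadata <- data.frame(phage_id = c("phA1", "phA2"), group = "A",
                         lifestyle = "temperate", stringsAsFactors = FALSE)
  tr <- data.frame(protein_id = character(), product = character(),
                   stringsAsFactors = FALSE)
  out <- per_group_rates(prods, tr, p2p, metadata)
  expect_equal(out$per_phage$seq_rate, c(0.4, 0.6))
  expect_equal(out$per_group$seq_rate_mean, 0.5)
  expect_equal(out$per_group$seq_rate_pooled, 0.5)
  expect_equal(out$overall$seq_rate_mean, 0.5)
  expect_error(per_group_rates(prods, tr, p2p[-1], metadata), "mapping")
})

test_that("mean pLDDT classification uses an inclusive 70 cutoff", {
  expect_equal(mean_plddt(c(70, 80, 90)), 80)
  expect_equal(classify_plddt(80), "High_pLDDT")
  expect_equal(classify_plddt(69.9), "Low_pLDDT")
  expect_equal(classify_plddt(70), "High_pLDDT")
  expect_error(mean_plddt(numeric()), "empty")
})

test_that("counter-defense screen is strictly above 0.6", {
  aln <- rbind(make_alignment_rows("q1", "t1", tm = 0.61),
               make_alignment_rows("q2", "t2", tm = 0.60),
               make_alignment_rows("q3", "t3", tm = NA_real_))
  kept <- counter_defense_screen(aln)
  expect_equal(kept$query_id, "q1")
  expect_equal(nrow(counter_defense_screen(aln[0, ])), 0L)
})
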