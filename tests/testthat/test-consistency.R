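test_that("structural purity averages rep-vs-member rows and reports medians", {
  cl <- new_clustering(list(r1 = c("r1", "a", "b"), r2 = c("r2", "c"),
                            s = "s"))
  aln <- rbind(
    make_alignment_rows("r1", "a", tm = 0.9, lddt = 0.8),
    make_alignment_rows("r1", "b", tm = 0.7, lddt = 1.0),
    make_alignment_rows("c", "r2", tm = 0.6, lddt = 0.5),   # reversed orientation
    make_alignment_rows("r1", "r1", tm = 1.0, lddt = 1.0))  # self: excluded
  expect_warning(p <- structural_purity(cl, aln), "omitted")  # singleton s
  expect_equal(p$per_cluster$mean_lddt[p$per_cluster$representative_id == "r1"], 0.9)
  expect_equal(p$per_cluster$mean_tm[p$per_cluster$representative_id == "r1"], 0.8)
  expect_equal(p$per_cluster$n_members_aligned, c(2L, 1L))
  expect_equal(unname(p$medians["lddt"]), median(c(0.9, 0.5)))
  expect_equal(unname(p$medians["tm"]), median(c(0.8, 0.6)))
})

test_that("Pfam consistency averages ordered-pair overlap fractions", {
  expect_equal(pfam_consistency(list(a = "PF00001", b = "PF00001")), 1.0)
  # A={PF1,PF2}, B={PF1}: A->B gives 1/2, B->A gives 1/1
  expect_equal(pfam_consistency(list(a = c("PF1", "PF2"), b = "PF1")), 0.75)
  expect_equal(pfam_consistency(list(a = "PF1", b = "PF2")), 0.0)
  # unannotated members excluded; < 2 annotated -> NA
  expect_equal(pfam_consistency(list(a = "PF1", b = character(), c = "PF1")), 1.0)
  expect_true(is.na(pfam_consistency(list(a = "PF1", b = character()))))
  # duplicate accessions collapse to a set
  expect_equal(pfam_consistency(list(a = c("PF1", "PF1"), b = "PF1")), 1.0)
})

test_that("EC consistency truncates codes per level and applies exclusions", {
  two <- list(a = "1.2.3.4", b = "1.2.3.5")
  expect_equal(ec_consistency(two, 3), 1.0)
  expect_equal(ec_consistency(two, 4), 0.0)
  # members with multiple EC numbers are excluded entirely
  multi <- list(a = c("1.1.1.1", "2.7.7.7"), b = "1.1.1.1", c = "1.1.1.1")
  expect_equal(ec_consistency(multi, 4), 1.0)
  expect_true(is.na(ec_consistency(list(a = c("1.1.1.1", "2.7.7.7"),
                                        b = "1.1.1.1"), 4)))
  # codes lacking a concrete token at the level are disregarded there
  dashed <- list(a = "1.2.-.-", b = "1.2.3.4")
  expect_equal(ec_consistency(dashed, 2), 1.0)
  expect_true(is.na(ec_consistency(dashed, 3)))
  expect_error(ec_consistency(list(a = "1.2.3", b = "1.2.3.4"), 1), "4 dot")
})

test_that("consistency scores match the brute-force enumerator on random clusters", {
  set.seed(99)
  pool <- sprintf("PF%03d", 1:6)
  for (i in 1:60) {
    k <- sample(2:8, 1L)
    sets <- lapply(seq_len(k), function(j) sample(pool, sample(0:3, 1L)))
    names(sets) <- sprintf("m%d", seq_len(k))
    expect_equal(pfam_consistency(sets), reference_pfam(sets))
    codes <- lapply(seq_len(k), function(j) {
      sprintf("%d.%d.%d.%d", sample(1:2, 1), sample(1:2, 1),
              sample(1:2, 1), sample(1:2, 1))
    })
    names(codes) <- names(sets)
    for (l in 1:4) expect_equal(ec_consistency(codes, l), reference_ec(codes, l))
  }
})

test_that("per-cluster consistency table skips unscorable clusters", {
  cl <- new_clustering(list(r1 = c("r1", "a"), r2 = c("r2", "b"), s = "s"))
  labels <- list(r1 = "PF1", a = "PF1", r2 = "PF2", b = character(), s = "PF9")
  out <- cluster_consistency(cl, labels, "pfam")
  expect_equal(out$representative_id, "r1")
  expect_equal(out$score, 1.0)
  expect_equal(out$n_annotated_members, 2L)
})

test_that("binned consistency summaries use half-open (lo, hi] bins", {
  scores <- data.frame(representative_id = c("r1", "r2", "r3"),
                       score = c(1.0, 0.5, 1.0), stringsAsFactors = FALSE)
  metric <- c(r1 = 0.5, r2 = 0.65, r3 = 0.9)   # 0.65 lands in (0, 0.65]
  b <- consistency_vs_metric_binning(scores, metric,
                                     bin_edges = c(0, 0.65, 0.8, 1))
  expect_equal(b$n, c(2L, 0L, 1L))
  expect_equal(b$frac_perfect[1], 0.5)
  expect_true(is.na(b$frac_perfect[2]))
  expect_equal(b$mean_score[3], 1.0)
  expect_error(consistency_vs_metric_binning(scores, c(r1 = 0, r2 = 0.65, r3 = 0.9),
                                             bin_edges = c(0, 0.65, 0.8, 1)),
               "outside")
})

test_that("EC prediction agreement compares the first three levels", {
  pred <- c(p1 = "3.6.1.1", p2 = "2.7.7.7", p3 = "3.6.1.5", p4 = "3.6.2.1")
  ref <- c(p1 = "3.6.1.5", p2 = "3.6.1.5", p3 = "3.6.1.5", p4 = "3.6.1.5")
  out <- deepfri_ec_agreement(pred, ref)
  expect_equal(out$level, 1:3)
  expect_equal(out$agreement[1], 0.75)          # p2 disagrees at level 1
  expect_equal(out$agreement[2], 0.75)
  expect_equal(out$agreement[3], 0.5)           # p4 also out at level 3
  # dash-bearing predictions drop out of deeper levels
  out2 <- deepfri_ec_agreement(c(p1 = "3.6.-.-"), c(p1 = "3.6.1.5"))
  expect_equal(out2$n, c(1L, 1L, 0L))
  expect_error(deepfri_ec_agreement(c(x = "1.1.1.1"), c(y = "1.1.1.1")), "shared")
})

test_that("confidence and pLDDT gates are strict", {
  preds <- data.frame(protein_id = c("a", "b", "c"),
                      score = c(0.81, 0.80, 0.95), stringsAsFactors = FALSE)
  g <- confidence_gate(preds, 0.8)
  expect_equal(g$data$protein_id, c("a", "c"))
  expect_equal(g$n_retained, 2L)
  expect_equal(confidence_gate(preds[0, ], 0.8)$n_total, 0L)

  pl <- c(a = 90.0, b = 90.1, c = 50)
  g2 <- plddt_gate(pl, 90)
  expect_equal(g2$ids, "b")   # 90.0 exactly is dropped
  expect_equal(g2$n_total, 3L)
})

test_that("semantic consistency removes ambiguous clusters and honors synonyms", {
  cl <- new_clustering(list(r1 = c("r1", "a"), r2 = c("r2", "b"),
                            r3 = c("r3", "c")))
  products <- data.frame(
    protein_id = c("r1", "a", "r2", "b", "r3", "c"),
    product = c("Minor tail protein", "Minor tail protein",
                "hypothetical protein", "capsid",    # ambiguous rep: removed
                "portal protein", "integrase"),
    stringsAsFactors = FALSE)
  transferred <- data.frame(
    protein_id = c("r1", "a", "r2", "b", "r3", "c"),
    product = c("Phage tail protein", "Phage tail protein",
                "capsid", "capsid", "portal  protein", "portal protein"),
    stringsAsFactors = FALSE)
  groups <- list(c("phage tail protein", "minor tail protein"))
  out <- semantic_consistency(cl, transferred, products, groups)
  expect_equal(out$n_clusters_removed, 1L)
  expect_equal(out$n_clusters_retained, 2L)
  expect_equal(out$n_members, 4L)
  # r1/a consistent via synonym group; r3 consistent via normalized identity;
  # c ("integrase" vs "portal protein") inconsistent
  expect_equal(out$n_consistent, 3L)
  expect_equal(out$fraction, 0.75)
  expect_error(semantic_consistency(cl, transferred, products, NULL), "synonym")
})
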