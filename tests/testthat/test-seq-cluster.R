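test_that("similarity edges require identity and coverage thresholds (inclusive)", {
  aln <- rbind(
    make_alignment_rows("a", "b", identity = 0.6, qcov = 0.95, tcov = 0.92),
    make_alignment_rows("a", "c", identity = 0.6, qcov = 0.85, tcov = 0.95),
    make_alignment_rows("a", "d", identity = 0.5, qcov = 0.90, tcov = 0.90),
    make_alignment_rows("a", "e", identity = 0.49, qcov = 0.95, tcov = 0.95))
  g <- build_similarity_graph(aln)
  expect_equal(nrow(g$edges), 2L)  # a-b and the exactly-at-threshold a-d
  expect_true(all(c("a-b", "a-d") %in% paste(g$edges$from, g$edges$to, sep = "-")))

  # target-only coverage mode admits the low-query-coverage pair
  g2 <- build_similarity_graph(aln, coverage_mode = "target")
  expect_equal(nrow(g2$edges), 3L)
})

test_that("self-alignments never create edges and isolated ids become nodes", {
  aln <- make_alignment_rows("a", "a", identity = 0.9, qcov = 1, tcov = 1)
  g <- build_similarity_graph(aln, node_ids = c("a", "z"))
  expect_equal(nrow(g$edges), 0L)
  expect_equal(g$nodes, c("a", "z"))
})

test_that("greedy set cover handles the canonical small graphs", {
  # edgeless graph: all singletons
  g <- graph_from_pairs(list(), nodes = c("a", "b", "c", "d", "e"))
  cl <- greedy_set_cover_cluster(g)
  expect_equal(lengths(cl$clusters), setNames(rep(1L, 5), c("a", "b", "c", "d", "e")))

  # star: the hub covers everything
  g <- graph_from_pairs(list(c("a", "b"), c("a", "c"), c("a", "d")))
  cl <- greedy_set_cover_cluster(g)
  expect_equal(names(cl$clusters), "a")
  expect_setequal(cl$clusters[["a"]], c("a", "b", "c", "d"))

  # path a-b-c: the middle node has the largest closed neighborhood
  g <- graph_from_pairs(list(c("a", "b"), c("b", "c")))
  cl <- greedy_set_cover_cluster(g)
  expect_equal(names(cl$clusters), "b")
  expect_setequal(cl$clusters[["b"]], c("a", "b", "c"))
})

test_that("greedy set cover matches the brute-force reference on random graphs", {
  set.seed(42)
  for (i in 1:50) {
    rg <- random_graph_pairs(sample(2:8, 1L), runif(1, 0.1, 0.8))
    g <- graph_from_pairs(rg$pairs, nodes = rg$nodes)
    got <- greedy_set_cover_cluster(g)
    expect_equal(got$clusters, reference_greedy(rg$nodes, rg$pairs))
    validate_clustering(got)
    expect_setequal(clustering_members(got), rg$nodes)
  }
})

test_that("reassignment moves stranded members and is a fixed point otherwise", {
  g <- graph_from_pairs(list(c("m", "r2"), c("r1", "x")))
  # m parked under r1 without an m-r1 edge, but with an m-r2 edge
  cl <- new_clustering(list(r1 = c("r1", "m", "x"), r2 = "r2"))
  out <- reassign_members(cl, g)
  expect_setequal(out$clusters[["r2"]], c("m", "r2"))
  expect_setequal(out$clusters[["r1"]], c("r1", "x"))

  # member with no edge to any representative becomes a singleton
  g2 <- graph_from_pairs(list(c("r1", "x")))
  cl2 <- new_clustering(list(r1 = c("r1", "x", "lost")))
  out2 <- reassign_members(cl2, g2)
  expect_equal(out2$clusters[["lost"]], "lost")

  # clustering already consistent with the graph is returned unchanged
  g3 <- graph_from_pairs(list(c("r1", "x")))
  cl3 <- new_clustering(list(r1 = c("r1", "x")))
  expect_equal(reassign_members(cl3, g3)$clusters, cl3$clusters)
})

test_that("cluster size summary bins counts that sum to the cluster count", {
  cl <- new_clustering(list(a = "a", b = "b", c = "c", d = c("d", "e")))
  s <- cluster_size_summary(cl)
  expect_equal(s$count[s$bin == "1"], 3L)
  expect_equal(s$count[s$bin == "2"], 1L)
  expect_equal(sum(s$count), 4L)

  empty <- cluster_size_summary(new_clustering(list()))
  expect_true(all(empty$count == 0L))

  set.seed(7)
  sizes <- sample(1:200, 30, replace = TRUE)
  ids <- sprintf("p%04d", seq_len(sum(sizes)))
  groups <- split(ids, rep(seq_along(sizes), sizes))
  cl2 <- new_clustering(setNames(groups, vapply(groups, `[[`, "", 1L)))
  expect_equal(sum(cluster_size_summary(cl2)$count), 30L)
})

test_that("mixed-lifestyle screening needs both lifestyles and >= 2 members", {
  metadata <- data.frame(phage_id = c("pT", "pL", "pT2"),
                         group = c("A", "B", "A"),
                         lifestyle = c("temperate", "lytic", "temperate"),
                         stringsAsFactors = FALSE)
  p2p <- c(a = "pT", b = "pL", c = "pT", d = "pT2", e = "pT")
  cl <- new_clustering(list(a = c("a", "b"),    # temperate + lytic -> selected
                            c = c("c", "d"),    # two temperate -> no
                            e = "e"))           # singleton -> no
  expect_equal(screen_mixed_lifestyle_clusters(cl, p2p, metadata), "a")
  expect_error(screen_mixed_lifestyle_clusters(cl, p2p[-1], metadata), "mapping")
})

test_that("raising the identity threshold never adds edges or merges clusters", {
  set.seed(11)
  aln <- do.call(rbind, lapply(1:60, function(i) {
    make_alignment_rows(sprintf("p%02d", sample(12, 1)), sprintf("p%02d", sample(12, 1)),
                        identity = runif(1), qcov = runif(1, 0.8, 1),
                        tcov = runif(1, 0.8, 1))
  }))
  nodes <- sprintf("p%02d", 1:12)
  thresholds <- c(0.2, 0.4, 0.6, 0.8)
  graphs <- lapply(thresholds, function(t) {
    build_similarity_graph(aln, min_identity = t, node_ids = nodes)
  })
  n_edges <- vapply(graphs, function(g) nrow(g$edges), 1L)
  expect_true(all(diff(n_edges) <= 0))
  n_clusters <- vapply(graphs, function(g) length(greedy_set_cover_cluster(g)$clusters), 1L)
  expect_true(all(diff(n_clusters) >= 0))
})
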