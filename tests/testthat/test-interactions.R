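random_interactions <- function(n) {
  data.frame(phage_protein_id = sprintf("ph%02d", sample(8, n, replace = TRUE)),
             host_protein_id = sprintf("h%02d", sample(6, n, replace = TRUE)),
             iptm = runif(n), ptm = runif(n), stringsAsFactors = FALSE)
}

test_that("interaction score is the 0.8/0.2 weighted combination", {
  expect_equal(interaction_score(0.8, 0.6), 0.76)
  x <- c(0, 0.3, 1)
  expect_equal(interaction_score(x, x), x)    # convexity identity
  expect_equal(interaction_score(0, 0), 0)
  expect_error(interaction_score(1.2, 0.5), "outside")
  expect_error(interaction_score(0.5, -0.1), "outside")
})

test_that("interaction screening is strict and monotone in the threshold", {
  rec <- data.frame(phage_protein_id = c("p1", "p2"), host_protein_id = c("h", "h"),
                    iptm = c(0.51, 0.50), ptm = c(0.51, 0.50),
                    stringsAsFactors = FALSE)
  out <- screen_interactions(rec, 0.5)
  expect_equal(out$phage_protein_id, "p1")    # score 0.51 kept, 0.50 dropped
  expect_equal(out$score, 0.51)

  set.seed(21)
  tab <- random_interactions(300)
  prev <- screen_interactions(tab, 0)
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- screen_interactions(tab, th)
    key <- function(d) paste(d$phage_protein_id, d$host_protein_id, d$score)
    expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
})

test_that("raw-sum screening mode uses ipTM + pTM as the screened quantity", {
  rec <- data.frame(phage_protein_id = "p", host_protein_id = "h",
                    iptm = 0.2, ptm = 0.4, stringsAsFactors = FALSE)
  # weighted score 0.24 fails 0.5, but the raw sum 0.6 passes
  expect_equal(nrow(screen_interactions(rec, 0.5, "weighted")), 0L)
  out <- screen_interactions(rec, 0.5, "sum")
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 0.24)   # reported score stays the weighted one
})

test_that("network node attributes follow the size/degree rules", {
  screened <- data.frame(
    phage_protein_id = c("p1", "p2"), host_protein_id = c("h1", "h1"),
    iptm = c(0.9, 0.8), ptm = c(0.9, 0.8),
    score = c(0.9, 0.8), stringsAsFactors = FALSE)
  net <- build_network(screened, c(p1 = 5L, p2 = 2L))
  expect_equal(net$host_nodes$degree, 2L)  # shared host target
  expect_equal(net$phage_nodes$size, c(5L, 2L))
  expect_equal(nrow(net$edges), 2L)
  expect_error(build_network(screened, c(p1 = 5L)), "size")

  empty <- build_network(screened[0, ], c(p1 = 5L))
  expect_equal(nrow(empty$edges), 0L)
})

test_that("duplicate phage-host pairs collapse to their maximum score", {
  screened <- data.frame(
    phage_protein_id = c("p1", "p1"), host_protein_id = c("h1", "h1"),
    iptm = c(0.9, 0.7), ptm = c(0.9, 0.7), score = c(0.9, 0.7),
    stringsAsFactors = FALSE)
  expect_message(net <- build_network(screened, c(p1 = 1L)), "collapsing")
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 0.9)
  expect_equal(net$host_nodes$degree, 1L)
})

test_that("network degrees equal recomputed degrees on random tables", {
  set.seed(31)
  scr <- screen_interactions(random_interactions(200), 0.3)
  sizes <- setNames(sample(1:10, length(unique(scr$phage_protein_id)), replace = TRUE),
                    unique(scr$phage_protein_id))
  net <- suppressMessages(build_network(scr, sizes))
  recomputed <- table(net$edges$host_id)
  expect_equal(net$host_nodes$degree,
               as.integer(recomputed[net$host_nodes$id]))
  expect_equal(nrow(net$edges),
               nrow(unique(scr[c("phage_protein_id", "host_protein_id")])))
})

test_that("networks export to edge-list TSV and GraphML", {
  screened <- data.frame(phage_protein_id = "p1", host_protein_id = "h1",
                         iptm = 0.9, ptm = 0.9, score = 0.9,
                         stringsAsFactors = FALSE)
  net <- build_network(screened, c(p1 = 3L))
  d <- withr::local_tempdir()
  write_network(net, graphml_path = file.path(d, "net.graphml"),
                edges_path = file.path(d, "edges.tsv"))
  edges <- read.delim(file.path(d, "edges.tsv"))
  expect_equal(edges$source, "p1")
  expect_equal(edges$weight, 0.9)
  g <- igraph::read_graph(file.path(d, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
})

test_that("heatmap cells are per-phage ratios, linear in counts", {
  counts <- data.frame(category = c("Acr", "Acr", "antitoxin"),
                       group = c("A", "B", "A"), count = c(5L, 2L, 1L),
                       stringsAsFactors = FALSE)
  per_group <- c(A = 10L, B = 4L)
  h <- normalized_cluster_heatmap(counts, per_group)
  expect_equal(h["Acr", "A"], 0.5)
  expect_equal(h["Acr", "B"], 0.5)
  expect_equal(h["antitoxin", "B"], 0)
  counts2 <- counts
  counts2$count <- counts2$count * 2L
  expect_equal(normalized_cluster_heatmap(counts2, per_group), 2 * h)
  expect_error(normalized_cluster_heatmap(counts, c(A = 10L, B = 0L)),
               "non-positive")
  expect_error(normalized_cluster_heatmap(counts, c(A = 10L)), "no phage count")
})
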