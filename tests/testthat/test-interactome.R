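test_that("combine_scores implements capped noisy-OR", {
  expect_equal(combine_scores(0.8), 0.8)
  expect_equal(combine_scores(c(0.8, 0.6)), 1 - 0.2 * 0.4)
  # a single source can never exceed the 0.9 cap
  expect_equal(combine_scores(0.95), 0.9)
  expect_equal(combine_scores(1), 0.9)
  expect_equal(combine_scores(numeric(0)), 0)
  expect_error(combine_scores(1.2), "\\[0, 1\\]")
})

test_that("combine_scores is monotone, order-invariant, and >= any capped input", {
  set.seed(7)
  for (i in 1:50) {
    s <- runif(sample(1:4, 1))
    c0 <- combine_scores(s)
    expect_equal(combine_scores(sample(s)), c0)
    expect_gte(c0 + 1e-12, max(pmin(s, 0.9)))
    expect_lte(c0, 1)
    # raising any one channel never lowers the combination
    j <- sample(seq_along(s), 1)
    s2 <- s; s2[j] <- min(1, s2[j] + runif(1, 0, 1 - s2[j]))
    expect_gte(combine_scores(s2) + 1e-12, c0)
  }
})

test_that("prior correction reduces to plain noisy-OR at prior 0 and stays in range", {
  s <- c(0.8, 0.6, 0.3)
  expect_equal(combine_scores(s, prior = 0), combine_scores(s))
  withp <- combine_scores(s, prior = 0.041)
  expect_gte(withp, 0.041)
  expect_lte(withp, 1)
  # channels at the prior contribute nothing
  expect_equal(combine_scores(c(0.041, 0.8), prior = 0.041),
               combine_scores(c(0.8), prior = 0.041))
})

test_that("scored_interactions canonicalizes and deduplicates unordered pairs", {
  df <- data.frame(gene_a = c("B", "A", "C"), gene_b = c("A", "B", "C"),
                   combined_score = c(0.91, 0.95, 0.5))
  expect_error(scored_interactions(df, recompute = FALSE), "self-interactions")
  df <- df[df$gene_a != df$gene_b, ]
  si <- scored_interactions(df, recompute = FALSE)
  expect_equal(nrow(si), 1)
  expect_identical(si$gene_a, "A")
  expect_identical(si$gene_b, "B")
  expect_equal(si$combined_score, 0.95)
})

test_that("filtering keeps curated edges and thresholds scored edges inclusively", {
  df <- data.frame(
    gene_a = c("A", "A", "A", "A"), gene_b = c("B", "C", "D", "E"),
    database = c("scored", "scored", "curated", "scored"),
    combined_score = c(0.89, 0.92, NA, 0.90))
  f <- filter_interactions(scored_interactions(df, recompute = FALSE))
  expect_setequal(f$gene_b, c("C", "D", "E"))  # 0.89 out, 0.90 & 0.92 in
  strict <- filter_interactions(scored_interactions(df, recompute = FALSE),
                                strict = TRUE)
  expect_setequal(strict$gene_b, c("C", "E"))
})

test_that("combined scores are recomputed from score_ columns", {
  df <- data.frame(gene_a = "A", gene_b = "B",
                   score_x = 0.8, score_y = 0.6)
  si <- scored_interactions(df)
  expect_equal(si$combined_score, 0.92)
})

test_that("induced network keeps all universe genes and only internal edges", {
  edges <- scored_interactions(
    data.frame(gene_a = c("A", "B"), gene_b = c("B", "D"),
               combined_score = 0.95), recompute = FALSE)
  g <- induce_network(gene_set(c("A", "B", "C")), edges)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(unname(compute_degree(g)["C"]), 0L)

  empty <- induce_network(gene_set(character()), edges)
  expect_equal(igraph::vcount(empty), 0)
})

test_that("filter-then-induce commutes with induce-then-filter", {
  set.seed(11)
  for (i in 1:10) {
    genes <- paste0("G", 1:12)
    df <- data.frame(gene_a = sample(genes, 30, TRUE),
                     gene_b = sample(genes, 30, TRUE),
                     combined_score = runif(30))
    df <- df[df$gene_a != df$gene_b, ]
    si <- scored_interactions(df, recompute = FALSE)
    universe <- gene_set(sample(genes, 8))
    g1 <- induce_network(universe, filter_interactions(si, 0.5))
    pre <- si[si$gene_a %in% universe$genes & si$gene_b %in% universe$genes, ]
    g2 <- induce_network(universe, filter_interactions(pre, 0.5))
    expect_true(igraph::identical_graphs(g1, g2) ||
                  (setequal(igraph::V(g1)$name, igraph::V(g2)$name) &&
                     igraph::ecount(g1) == igraph::ecount(g2)))
  }
})

test_that("degree satisfies the handshake identity on random graphs", {
  set.seed(3)
  for (i in 1:20) {
    g <- graph_from_adjacency(random_adj(sample(2:20, 1), runif(1)))
    expect_equal(sum(compute_degree(g)), 2 * igraph::ecount(g))
  }
  star <- graph_from_adjacency(rbind(c(0, 1, 1, 1, 1),
                                     cbind(1, matrix(0, 4, 4))))
  expect_equal(unname(compute_degree(star)), c(4L, 1L, 1L, 1L, 1L))
})

test_that("betweenness matches hand-derived values on canonical graphs", {
  path3 <- graph_from_adjacency(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
                                labels = c("a", "b", "c"))
  expect_equal(compute_betweenness(path3), c(a = 0, b = 1, c = 0))

  star <- graph_from_adjacency(rbind(c(0, 1, 1, 1, 1),
                                     cbind(1, matrix(0, 4, 4))))
  expect_equal(unname(compute_betweenness(star)), c(choose(4, 2), 0, 0, 0, 0))

  cyc4 <- graph_from_adjacency(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0),
                                     c(0, 1, 0, 1), c(1, 0, 1, 0)))
  expect_equal(unname(compute_betweenness(cyc4)), rep(0.5, 4))

  # degree <= 1 nodes have betweenness 0
  expect_equal(unname(compute_betweenness(path3)[c(1, 3)]), c(0, 0))
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  # all labeled graphs on up to 4 nodes
  for (n in 2:4) {
    for (bits in 0:(2^choose(n, 2) - 1)) {
      adj <- labeled_graph_adj(n, bits)
      g <- graph_from_adjacency(adj)
      expect_equal(unname(compute_betweenness(g)), brute_betweenness(adj),
                   tolerance = 1e-10)
    }
  }
  # random labeled graphs on 5-8 nodes across densities
  set.seed(99)
  for (i in 1:120) {
    n <- sample(5:8, 1)
    adj <- random_adj(n, runif(1, 0.1, 0.9))
    expect_equal(unname(compute_betweenness(graph_from_adjacency(adj))),
                 brute_betweenness(adj), tolerance = 1e-10)
  }
})

test_that("network summary reports the published mean-interaction convention", {
  # two disjoint edges: LCC covers half the nodes and half the edges
  g <- graph_from_adjacency(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                                  c(0, 0, 0, 1), c(0, 0, 1, 0)))
  s <- summarize_network(g)
  expect_equal(s$lcc_node_fraction, 0.5)
  expect_equal(s$lcc_edge_fraction, 0.5)
  expect_equal(s$n_two_node_islets, 2L)
  expect_equal(s$mean_interactions_per_node, 2 / 4)

  single <- induce_network(gene_set("A"), NULL)
  ss <- summarize_network(single)
  expect_equal(ss$mean_interactions_per_node, 0)
  expect_equal(ss$lcc_node_fraction, 1)
  expect_equal(ss$lcc_edge_fraction, 1)

  empty <- summarize_network(induce_network(gene_set(character()), NULL))
  expect_equal(empty$n_nodes, 0L)
})

test_that("edge-list TSV round-trips through the '#'-header format", {
  df <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                   database = c("scored", "curated"),
                   combined_score = c(0.92, NA),
                   score_src1 = c(0.8, NA), score_src2 = c(0.6, NA))
  si <- scored_interactions(df, recompute = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(si, path)
  expect_match(readLines(path, n = 1), "^#gene_a\t")
  back <- read_interactions(path)
  expect_equal(back$combined_score, si$combined_score)
  expect_identical(back$gene_a, si$gene_a)
  expect_identical(back$database, si$database)
})
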