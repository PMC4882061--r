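# toy_background(): A-C-B, A-D, islet E-F, 4-cycle P-Q-R-S

test_that("common-neighbor bridging adds exactly the shared neighbors", {
  bg <- toy_background()
  # A and B share only C; D touches A alone and must stay out
  sn <- build_bridged_subnetwork(c("A", "B"), bg)
  expect_setequal(igraph::V(sn$graph)$name, c("A", "B", "C"))
  expect_identical(unname(sn$roles[c("A", "B", "C")]),
                   c("seed", "seed", "bridge"))
  # adjacent seeds need no bridge
  sn2 <- build_bridged_subnetwork(c("A", "C"), bg)
  expect_setequal(igraph::V(sn2$graph)$name, c("A", "C"))
  expect_equal(igraph::ecount(sn2$graph), 1)
  # empty seed set -> empty subnetwork
  expect_equal(igraph::vcount(build_bridged_subnetwork(character(), bg)$graph),
               0)
  # seeds not in the background are dropped and reported
  sn3 <- build_bridged_subnetwork(c("A", "B", "ZZ"), bg)
  expect_identical(sn3$dropped_seeds, "ZZ")
})

test_that("common-neighbor bridging is superset-monotone in the seeds", {
  s <- generate_synthetic_study(small_synth_config(seed = 3))
  bg <- s$background_network
  seeds <- c(s$planted$up, s$planted$down)
  small <- build_bridged_subnetwork(seeds[1:3], bg)
  large <- build_bridged_subnetwork(seeds, bg)
  expect_true(all(igraph::V(small$graph)$name %in%
                    igraph::V(large$graph)$name))
})

test_that("steiner-greedy connects connectable seed pairs through shortest paths", {
  bg <- toy_background()
  sn <- build_bridged_subnetwork(c("B", "D"), bg, policy = "steiner_greedy")
  # B-C-A-D is the only route
  expect_setequal(igraph::V(sn$graph)$name, c("A", "B", "C", "D"))
  d <- igraph::distances(sn$graph, v = "B", to = "D")
  expect_true(is.finite(d[1, 1]))
  # seeds in different components stay apart and are flagged isolated
  sn2 <- build_bridged_subnetwork(c("B", "E"), bg, policy = "steiner_greedy")
  expect_setequal(igraph::V(sn2$graph)$name, c("B", "E"))
  expect_setequal(sn2$isolated_seeds, c("B", "E"))
})

test_that("subnetwork edges are exactly the background-induced edges", {
  s <- generate_synthetic_study(small_synth_config(seed = 5))
  bg <- s$background_network
  for (policy in c("common_neighbors", "steiner_greedy")) {
    sn <- build_bridged_subnetwork(c(s$planted$up, s$planted$down), bg,
                                   policy = policy)
    nodes <- igraph::V(sn$graph)$name
    ref <- igraph::induced_subgraph(bg, nodes)
    expect_equal(igraph::ecount(sn$graph), igraph::ecount(ref))
    # every bridge touches >= 2 seeds (common-neighbor policy only)
    if (policy == "common_neighbors") {
      seeds <- names(sn$roles)[startsWith(sn$roles, "seed")]
      bridges <- names(sn$roles)[sn$roles == "bridge"]
      for (b in bridges) {
        nb <- igraph::neighbors(bg, b)$name
        expect_gte(length(intersect(nb, seeds)), 2)
      }
    }
  }
})

test_that("candidate-to-known-gene linkage flags roles and keeps direct edges", {
  bg <- toy_background()
  dgm <- disease_gene_map(list(ph1 = c("C"), ph2 = c("F")))
  ln <- link_to_disease_genes(c("A", "E"), dgm, bg)
  roles <- ln$roles
  expect_identical(unname(roles["A"]), "candidate")
  expect_identical(unname(roles["C"]), "known")
  # candidate directly interacting with a known gene keeps the edge
  expect_true(igraph::are_adjacent(ln$graph, "A", "C"))
  expect_true(igraph::are_adjacent(ln$graph, "E", "F"))
  # a gene that is both candidate and known is flagged as such
  ln2 <- link_to_disease_genes(c("C"), dgm, bg)
  expect_identical(unname(ln2$roles["C"]), "candidate_known")
})

test_that("shortest paths are verified shortest with lexicographic tie-break", {
  bg <- toy_background()
  sp <- shortest_path_links(c("A", "B", "E"), bg)
  ab <- sp[sp$from == "A" & sp$to == "B", ]
  expect_equal(ab$length, 2L)
  expect_identical(ab$path[[1]], c("A", "C", "B"))
  # unreachable pair reported as such
  ae <- sp[sp$from == "A" & sp$to == "E", ]
  expect_true(is.na(ae$length))
  # 4-cycle distance-2 pair: P-Q-R beats P-S-R lexicographically
  sp2 <- shortest_path_links(c("P", "R"), bg)
  expect_identical(sp2$path[[1]], c("P", "Q", "R"))
  # adjacent pair: path of length 1
  sp3 <- shortest_path_links(c("P", "Q"), bg)
  expect_equal(sp3$length, 1L)
})

test_that("every reported path is shortest by independent BFS distance", {
  s <- generate_synthetic_study(small_synth_config(seed = 6))
  bg <- s$background_network
  genes <- c(s$planted$up, s$planted$down)[1:5]
  sp <- shortest_path_links(genes, bg)
  D <- igraph::distances(bg, v = genes, to = genes, weights = NA)
  for (i in seq_len(nrow(sp))) {
    expected <- D[sp$from[i], sp$to[i]]
    if (is.finite(expected)) {
      expect_equal(sp$length[i], unname(expected))
      # consecutive path nodes are adjacent in the background
      p <- sp$path[[i]]
      for (j in seq_len(length(p) - 1)) {
        expect_true(igraph::are_adjacent(bg, p[j], p[j + 1]))
      }
    } else {
      expect_true(is.na(sp$length[i]))
    }
  }
})

test_that("disease-gene maps validate and round-trip through TSV", {
  expect_error(disease_gene_map(list(ph1 = character())), "at least one")
  dgm <- disease_gene_map(list(ph2 = c("B", "A"), ph1 = "C"))
  expect_identical(dgm$genes$ph2, c("A", "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(phenotype_id = c("p1", "p1", "p2"),
                         phenotype_name = c("one", "one", "two"),
                         gene = c("A", "B", "C")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_disease_gene_map(path)
  expect_identical(back$genes$p1, c("A", "B"))
  expect_identical(back$metadata$phenotype_name, c("one", "two"))
})
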