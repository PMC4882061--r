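test_that("config validation rejects impossible studies", {
  expect_error(small_synth_config(n_planted_consistent_down = 100L),
               "planted")
  expect_error(synthetic_config(n_annotation = 10L, n_genes = 5L),
               "n_annotation")
  expect_error(synthetic_config(n_core = 3000L), "n_core")
  expect_error(small_synth_config(enrichment_core_counts = c(70L, 25L, 30L)),
               "core counts")
  # a single disease cannot host direction-inconsistent decoys
  expect_error(synthetic_config(n_diseases = 1L, disease_names = "FSGS",
                                n_planted_inconsistent = 4L),
               "single disease")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- small_synth_config(seed = 21)
  s1 <- generate_synthetic_study(cfg)
  s2 <- generate_synthetic_study(cfg)
  expect_identical(s1$universe$genes, s2$universe$genes)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$disease_tables, s2$disease_tables)
  expect_identical(unclass(s1$similarity), unclass(s2$similarity))
  expect_identical(s1$modules, s2$modules)
  # a different seed changes the draw
  s3 <- generate_synthetic_study(small_synth_config(seed = 22))
  expect_false(identical(s1$edges, s3$edges))
})

test_that("universe construction nails set sizes and the planted intersection", {
  cfg <- small_synth_config(seed = 2)
  u <- generate_universe(cfg)
  expect_length(u$annotation_set$genes, cfg$n_annotation)
  sizes <- vapply(u$enrichment_sets, function(s) length(s$genes), integer(1))
  expect_equal(sizes, unname(cfg$enrichment_set_sizes))
  # mouse sets carry mouse ids and map back completely
  mouse <- u$enrichment_sets[[cfg$mouse_datasets[1]]]
  expect_identical(mouse$species, "mouse")
  mapped <- map_orthologs(mouse, u$ortholog_map)
  expect_identical(attr(mapped, "n_unmapped"), 0L)
  # intersection of annotation with the enrichment union is the core
  human_sets <- lapply(u$enrichment_sets, function(s) {
    if (s$species == "mouse") map_orthologs(s, u$ortholog_map) else s
  })
  enriched <- union_gene_sets(human_sets)
  core <- intersect_universe(u$annotation_set, enriched)
  expect_setequal(core$genes, u$core$genes)
  expect_length(core$genes, cfg$n_core)
  # per-dataset annotation overlap matches the configured counts
  for (j in seq_along(human_sets)) {
    ov <- overlap_report(u$annotation_set, human_sets[[j]])
    expect_equal(ov$n_intersect, unname(cfg$enrichment_core_counts[j]))
  }
})

test_that("an empty annotation set gives an empty intersection", {
  cfg <- synthetic_config(seed = 1, n_genes = 100L, n_annotation = 0L,
                          n_core = 0L, n_enriched_datasets = 2L,
                          enrichment_set_sizes = c(20L, 30L),
                          enrichment_core_counts = c(0L, 0L),
                          mouse_datasets = integer(),
                          n_planted_consistent_up = 0L,
                          n_planted_consistent_down = 0L,
                          n_planted_inconsistent = 0L)
  u <- generate_universe(cfg)
  expect_length(u$annotation_set$genes, 0)
  expect_length(u$core$genes, 0)
})

test_that("generated interactomes are simple graphs with valid scores", {
  cfg <- small_synth_config(seed = 13)
  u <- generate_universe(cfg)
  e <- generate_interactome(cfg, u$universe, core = u$core)
  expect_true(all(e$gene_a < e$gene_b))          # canonical, no self-loops
  expect_false(any(duplicated(paste(e$gene_a, e$gene_b))))
  sc <- as.matrix(e[, grep("^score_", names(e))])
  expect_true(all(is.na(sc) | (sc >= 0 & sc <= 1)))
  scored <- e$database == "scored"
  expect_true(all(e$combined_score[scored] >= 0 &
                    e$combined_score[scored] <= 1))
  # zero edge-generation parameters give an empty edge list
  cfg0 <- small_synth_config(pa_edges_per_node = 0L, core_edges_per_node = 0L,
                             uniform_edge_fraction = 0,
                             candidate_pair_fraction = 0)
  e0 <- generate_interactome(cfg0, u$universe)
  expect_equal(nrow(e0), 0)
})

test_that("guarantee fraction 1 yields all candidate pairs above threshold", {
  cfg <- small_synth_config(seed = 17, candidate_pair_fraction = 1)
  u <- generate_universe(cfg)
  planted <- sort(u$core$genes[1:5])
  e <- generate_interactome(cfg, u$universe, core = u$core,
                            guarantee_genes = planted)
  kept <- filter_interactions(e, 0.9)
  inside <- kept[kept$gene_a %in% planted & kept$gene_b %in% planted, ]
  expect_equal(nrow(inside), choose(5, 2))
  expect_true(all(inside$combined_score >= 0.9 |
                    inside$database == "curated"))
})

test_that("disease tables plant exact all-disease strata", {
  s <- generate_synthetic_study(small_synth_config(seed = 30))
  ct <- build_consistency_table(s$restricted_network, s$disease_tables)
  all_k <- ct$strata[nrow(ct$strata), ]
  cfg <- s$config
  expect_equal(all_k$up, cfg$n_planted_consistent_up)
  expect_equal(all_k$down, cfg$n_planted_consistent_down)
  expect_equal(all_k$inconsistent, cfg$n_planted_inconsistent)
  expect_equal(all_k$total, cfg$n_planted_consistent_up +
                 cfg$n_planted_consistent_down + cfg$n_planted_inconsistent)
  # planted p-values honor the threshold strictly
  for (t in s$disease_tables) {
    planted_rows <- t[t$gene %in% unlist(s$planted), ]
    expect_true(all(planted_rows$p_value < cfg$deg_p_threshold))
  }
  expect_error(
    generate_disease_tables(cfg, s$planted$up, s$planted$up,
                            character(), s$universe),
    "disjoint")
})

test_that("background all-disease DE count matches the truncated-binomial form", {
  # background genes draw K ~ min(Binom(n_diseases, q), n_diseases - 1)
  # diseases, so the expected count DE in >= (K-1) diseases is
  # N * (P(Binom = K-1) + P(Binom = K)); check within 3 binomial sigma
  cfg <- synthetic_config(seed = 41, n_genes = 1000L, n_annotation = 50L,
                          n_core = 30L, n_enriched_datasets = 2L,
                          enrichment_set_sizes = c(40L, 50L),
                          enrichment_core_counts = c(20L, 15L),
                          mouse_datasets = integer(),
                          n_planted_consistent_up = 0L,
                          n_planted_consistent_down = 0L,
                          n_planted_inconsistent = 0L,
                          background_de_prob = 0.3)
  u <- generate_universe(cfg)
  tabs <- generate_disease_tables(cfg, character(), character(), character(),
                                  u$universe)
  prof <- classify_genes(u$universe$genes, tabs,
                         p_threshold = cfg$deg_p_threshold)
  K <- cfg$n_diseases
  q <- cfg$background_de_prob
  p_top <- dbinom(K - 1, K, q) + dbinom(K, K, q)
  n <- length(u$universe$genes)
  observed <- sum(prof$n_diseases_de == K - 1)
  expect_lt(abs(observed - n * p_top), 3 * sqrt(n * p_top * (1 - p_top)) + 1)
  # truncation: no background gene is DE in all diseases
  expect_equal(sum(prof$n_diseases_de == K), 0)
})

test_that("phenotype data yields valid similarity and connected modules", {
  s <- generate_synthetic_study(small_synth_config(seed = 19))
  S <- unclass(s$similarity)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_true(all(S >= 0 & S <= 1))
  net <- s$background_network
  for (p in names(s$modules)) {
    mod <- s$modules[[p]]
    sub <- igraph::induced_subgraph(net, mod$module)
    expect_equal(igraph::components(sub)$no, 1)       # connected module
    expect_setequal(c(mod$known, mod$held_out), mod$module)
    expect_length(intersect(mod$known, mod$held_out), 0)
    # every held-out gene is adjacent to a known gene of its phenotype
    for (g in mod$held_out) {
      nb <- igraph::neighbors(net, g)$name
      expect_gte(length(intersect(nb, mod$known)), 1)
    }
  }
  expect_error(generate_phenotype_data(
    small_synth_config(n_phenotypes = 2L), s$background_network),
    "at least 3")
})

test_that("planted module genes are closer to their known genes than random genes", {
  s <- generate_synthetic_study(small_synth_config(seed = 23))
  net <- s$background_network
  set.seed(1)
  rand <- sample(setdiff(igraph::V(net)$name,
                         unlist(lapply(s$modules, `[[`, "module"))), 40)
  mean_dist <- function(genes, known) {
    d <- igraph::distances(net, v = genes, to = known, weights = NA)
    mean(apply(d, 1, min)[is.finite(apply(d, 1, min))])
  }
  planted_d <- mean(vapply(names(s$modules), function(p)
    mean_dist(s$modules[[p]]$held_out, s$modules[[p]]$known), numeric(1)))
  random_d <- mean(vapply(names(s$modules), function(p)
    mean_dist(rand, s$modules[[p]]$known), numeric(1)))
  expect_lt(planted_d, random_d)
})
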