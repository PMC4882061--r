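#' Configuration of the synthetic study generator
#'
#' Defines the statistical shape of a fully synthetic study with planted
#' ground truth: an annotation (cytoskeleton-style) gene set, nine
#' tissue-enrichment datasets whose sizes and annotation-overlap counts
#' default to the published nine glomerular expression profiles, a
#' sparse scale-free-like scored interactome, five disease
#' differential-expression tables with planted direction-consistent
#' candidates and inconsistent decoys, and clustered phenotype modules
#' with a similarity matrix.
#'
#' Background genes are differentially expressed in at most
#' `n_diseases - 1` diseases, so the all-disease stratum of the
#' consistency table contains exactly the planted genes — the generator's
#' ground truth is recoverable by construction.
#'
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical outputs.
#' @param n_genes gene-universe size.
#' @param n_annotation annotation-set size (default 2030).
#' @param n_core size of the annotation-by-enrichment intersection the
#'   generator constructs — the node universe of the restricted network
#'   (default 426).
#' @param n_enriched_datasets number of enrichment datasets (default 9).
#' @param enrichment_set_sizes per-dataset gene counts (defaults: 148,
#'   102, 310, 165, 914, 130, 202, 675, 1890).
#' @param enrichment_core_counts per-dataset count of annotation-overlap
#'   genes (defaults: 32, 28, 53, 32, 118, 25, 23, 138, 299).
#' @param mouse_datasets indices of datasets issued with mouse
#'   identifiers and routed through the ortholog map (default 3, 4, 5).
#' @param n_sources number of interaction evidence channels (default 3).
#' @param pa_edges_per_node preferential-attachment edges per node for
#'   the background interactome (0 disables background edges).
#' @param uniform_edge_fraction extra uniform-random edges, as a fraction
#'   of the preferential-attachment edge count.
#' @param core_edges_per_node preferential-attachment edges per node for
#'   the denser interactome among core genes.
#' @param core_connected_fraction fraction of core genes covered by the
#'   dense core layer; the remainder stay isolated unless background
#'   edges reach them, giving the restricted network its realistic
#'   disconnected-node fraction.
#' @param background_high_conf_prob,core_high_conf_prob probability that
#'   an edge carries one high-confidence channel (>= 0.9 before capping),
#'   i.e. survives the 0.9 combined-score threshold.
#' @param curated_fraction fraction of edges tagged as curated
#'   literature edges (no channel scores).
#' @param candidate_pair_fraction fraction of planted-candidate pairs
#'   guaranteed an edge with combined score >= 0.9.
#' @param n_diseases number of disease tables (default 5).
#' @param disease_names disease labels.
#' @param n_planted_consistent_up,n_planted_consistent_down,n_planted_inconsistent
#'   planted gene counts (defaults 3 / 18 / 16, the published all-disease
#'   stratum).
#' @param background_de_prob per-disease DE probability of a background
#'   gene.
#' @param deg_p_threshold DE p-value threshold the tables are generated
#'   around (default 0.05).
#' @param n_phenotypes number of phenotypes (>= 3; default 6).
#' @param n_phenotype_clusters phenotype clusters sharing module
#'   neighborhoods.
#' @param module_size genes per planted phenotype module.
#' @param within_cluster_similarity,between_cluster_similarity off-diagonal
#'   similarity values inside / across phenotype clusters.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 5000L,
                             n_annotation = 2030L,
                             n_core = 426L,
                             n_enriched_datasets = 9L,
                             enrichment_set_sizes = c(148L, 102L, 310L, 165L,
                                                      914L, 130L, 202L, 675L,
                                                      1890L),
                             enrichment_core_counts = c(32L, 28L, 53L, 32L,
                                                        118L, 25L, 23L, 138L,
                                                        299L),
                             mouse_datasets = c(3L, 4L, 5L),
                             n_sources = 3L,
                             pa_edges_per_node = 2L,
                             uniform_edge_fraction = 0.1,
                             core_edges_per_node = 2L,
                             core_connected_fraction = 0.7,
                             background_high_conf_prob = 0.25,
                             core_high_conf_prob = 0.75,
                             curated_fraction = 0.03,
                             candidate_pair_fraction = 0.3,
                             n_diseases = 5L,
                             disease_names = c("FSGS", "MN", "MCD", "DN",
                                               "IgA"),
                             n_planted_consistent_up = 3L,
                             n_planted_consistent_down = 18L,
                             n_planted_inconsistent = 16L,
                             background_de_prob = 0.35,
                             deg_p_threshold = 0.05,
                             n_phenotypes = 6L,
                             n_phenotype_clusters = 3L,
                             module_size = 8L,
                             within_cluster_similarity = 0.8,
                             between_cluster_similarity = 0.2) {
  cfg <- list(
    seed = assert_count(seed, "seed"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_annotation = assert_count(n_annotation, "n_annotation"),
    n_core = assert_count(n_core, "n_core"),
    n_enriched_datasets = assert_count(n_enriched_datasets,
                                       "n_enriched_datasets"),
    enrichment_set_sizes = assert_count(enrichment_set_sizes,
                                        "enrichment_set_sizes"),
    enrichment_core_counts = assert_count(enrichment_core_counts,
                                          "enrichment_core_counts"),
    mouse_datasets = as.integer(mouse_datasets),
    n_sources = assert_count(n_sources, "n_sources", min = 1L),
    pa_edges_per_node = assert_count(pa_edges_per_node, "pa_edges_per_node"),
    uniform_edge_fraction = uniform_edge_fraction,
    core_edges_per_node = assert_count(core_edges_per_node,
                                       "core_edges_per_node"),
    core_connected_fraction = assert_probability(core_connected_fraction,
                                                 "core_connected_fraction"),
    background_high_conf_prob =
      assert_probability(background_high_conf_prob,
                         "background_high_conf_prob"),
    core_high_conf_prob = assert_probability(core_high_conf_prob,
                                             "core_high_conf_prob"),
    curated_fraction = assert_probability(curated_fraction,
                                          "curated_fraction"),
    candidate_pair_fraction = assert_probability(candidate_pair_fraction,
                                                 "candidate_pair_fraction"),
    n_diseases = assert_count(n_diseases, "n_diseases", min = 1L),
    disease_names = as.character(disease_names),
    n_planted_consistent_up = assert_count(n_planted_consistent_up,
                                           "n_planted_consistent_up"),
    n_planted_consistent_down = assert_count(n_planted_consistent_down,
                                             "n_planted_consistent_down"),
    n_planted_inconsistent = assert_count(n_planted_inconsistent,
                                          "n_planted_inconsistent"),
    background_de_prob = assert_probability(background_de_prob,
                                            "background_de_prob"),
    deg_p_threshold = assert_probability(deg_p_threshold, "deg_p_threshold"),
    n_phenotypes = assert_count(n_phenotypes, "n_phenotypes"),
    n_phenotype_clusters = assert_count(n_phenotype_clusters,
                                        "n_phenotype_clusters", min = 1L),
    module_size = assert_count(module_size, "module_size", min = 2L),
    within_cluster_similarity = assert_probability(within_cluster_similarity,
                                                   "within_cluster_similarity"),
    between_cluster_similarity =
      assert_probability(between_cluster_similarity,
                         "between_cluster_similarity")
  )
  with(cfg, {
    if (n_annotation > n_genes) {
      stop("n_annotation cannot exceed n_genes", call. = FALSE)
    }
    if (n_core > n_annotation) {
      stop("n_core cannot exceed n_annotation", call. = FALSE)
    }
    if (length(enrichment_set_sizes) != n_enriched_datasets ||
        length(enrichment_core_counts) != n_enriched_datasets) {
      stop("enrichment sizes/core counts must have n_enriched_datasets ",
           "entries", call. = FALSE)
    }
    if (any(enrichment_core_counts > enrichment_set_sizes)) {
      stop("per-dataset core counts cannot exceed dataset sizes",
           call. = FALSE)
    }
    if (any(enrichment_core_counts > n_core)) {
      stop("per-dataset core counts cannot exceed n_core", call. = FALSE)
    }
    if (n_core > 0L && sum(enrichment_core_counts) < n_core) {
      stop("core slots across datasets (sum of enrichment_core_counts) ",
           "cannot cover n_core genes", call. = FALSE)
    }
    if (any(enrichment_set_sizes - enrichment_core_counts >
            n_genes - n_annotation)) {
      stop("dataset fill exceeds the non-annotation gene pool",
           call. = FALSE)
    }
    n_planted <- n_planted_consistent_up + n_planted_consistent_down +
      n_planted_inconsistent
    if (n_planted > n_core) {
      stop("planted gene counts exceed the constructed intersection ",
           "(n_core)", call. = FALSE)
    }
    if (n_diseases < 2L && n_planted_inconsistent > 0L) {
      stop("direction inconsistency is impossible with a single disease",
           call. = FALSE)
    }
    if (length(disease_names) != n_diseases) {
      stop("disease_names must have n_diseases entries", call. = FALSE)
    }
    if (any(mouse_datasets < 1L | mouse_datasets > n_enriched_datasets)) {
      stop("mouse_datasets indices out of range", call. = FALSE)
    }
  })
  structure(cfg, class = "synthetic_config")
}

mouse_id <- function(gene) paste0("m", gene)

#' Generate the synthetic gene universe and input gene sets
#'
#' Draws the gene universe, the annotation set, and the enrichment
#' datasets.  A fixed "core" subset of the annotation set (size
#' `n_core`) is distributed across the enrichment datasets with exactly
#' the configured per-dataset overlap counts (every core gene appears in
#' at least one dataset), while the rest of each dataset is filled from
#' non-annotation genes — so the intersection of the annotation set with
#' the enrichment union is the core, exactly.  Mouse-tagged datasets are
#' issued with mouse identifiers plus a complete one-to-one ortholog map
#' back to human.
#'
#' @param config a [synthetic_config()].
#' @return List with `universe`, `annotation_set`, `enrichment_sets`
#'   (list of [gene_set()]s, some mouse), `ortholog_map`, and the planted
#'   `core` intersection.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(sub_seed(config$seed, 11L))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  universe <- gene_set(genes, name = "universe",
                       provenance = "synthetic gene universe")
  annotation <- sample(genes, config$n_annotation)
  core <- if (config$n_core) sample(annotation, config$n_core) else character()
  pool <- setdiff(genes, annotation)
  J <- config$n_enriched_datasets
  sizes <- config$enrichment_set_sizes
  core_counts <- config$enrichment_core_counts
  # assign every core gene to >= 1 dataset, respecting per-dataset quotas
  members <- replicate(J, character(), simplify = FALSE)
  if (length(core)) {
    remaining <- core_counts
    for (g in sample(core)) {
      open <- which(remaining > 0L)
      j <- if (length(open) == 1L) open else
        sample(open, 1L, prob = remaining[open])
      members[[j]] <- c(members[[j]], g)
      remaining[j] <- remaining[j] - 1L
    }
    # fill leftover quota with additional core genes (no within-set dups)
    for (j in seq_len(J)) {
      if (remaining[j] > 0L) {
        extra <- sample(setdiff(core, members[[j]]), remaining[j])
        members[[j]] <- c(members[[j]], extra)
      }
    }
  }
  mouse_pairs_src <- character()
  enrichment_sets <- lapply(seq_len(J), function(j) {
    fill <- if (sizes[j] > core_counts[j])
      sample(pool, sizes[j] - core_counts[j]) else character()
    set_genes <- c(members[[j]], fill)
    if (j %in% config$mouse_datasets) {
      gene_set(mouse_id(set_genes), name = sprintf("enriched_%02d", j),
               species = "mouse",
               provenance = sprintf("synthetic enrichment dataset %d (mouse)",
                                    j))
    } else {
      gene_set(set_genes, name = sprintf("enriched_%02d", j),
               provenance = sprintf("synthetic enrichment dataset %d", j))
    }
  })
  mouse_src <- unique(unlist(lapply(config$mouse_datasets, function(j)
    enrichment_sets[[j]]$genes), use.names = FALSE))
  omap <- ortholog_map(source = mouse_src, target = sub("^m", "", mouse_src))
  list(universe = universe,
       annotation_set = gene_set(annotation, name = "annotation",
                                 provenance = "synthetic annotation set"),
       enrichment_sets = enrichment_sets,
       ortholog_map = omap,
       core = gene_set(core, name = "core",
                       provenance = "planted annotation ∩ enrichment"))
}

# score channels for n edges; each edge gets 1..n_sources active channels;
# high-confidence edges get one channel drawn in [0.9, 1]
draw_edge_scores <- function(n, n_sources, high_conf) {
  S <- matrix(NA_real_, nrow = n, ncol = n_sources,
              dimnames = list(NULL, paste0("score_src", seq_len(n_sources))))
  if (!n) return(S)
  n_active <- sample.int(n_sources, n, replace = TRUE)
  for (i in seq_len(n)) {
    ch <- sample.int(n_sources, n_active[i])
    S[i, ch] <- runif(n_active[i], 0.05, 0.85)
  }
  hi <- which(high_conf)
  if (length(hi)) {
    ch <- sample.int(n_sources, length(hi), replace = TRUE)
    S[cbind(hi, ch)] <- runif(length(hi), 0.9, 1)
  }
  S
}

pa_edge_list <- function(n, m, labels) {
  if (n < 2L || m < 1L) return(NULL)
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  e <- igraph::as_edgelist(g, names = FALSE)
  perm <- sample(labels)
  data.frame(gene_a = perm[e[, 1]], gene_b = perm[e[, 2]],
             stringsAsFactors = FALSE)
}

#' Generate the synthetic scored interactome
#'
#' Edges come from three layers: a preferential-attachment background
#' over the whole universe (heavy-tailed degree profile) plus a uniform
#' random-edge fraction; a denser preferential-attachment layer among
#' the core genes with a higher high-confidence rate (so the restricted
#' network is connected at realistic density); and guaranteed
#' high-confidence edges over a configurable fraction of planted
#' candidate pairs.  Every edge carries per-source channel scores in
#' [0, 1] and a noisy-OR combined score; a small fraction is tagged as
#' curated literature edges without channel scores.
#'
#' @param config a [synthetic_config()].
#' @param universe [gene_set()] of all genes (non-empty).
#' @param core optional [gene_set()] of core genes for the dense layer.
#' @param guarantee_genes optional character vector of planted candidate
#'   genes whose pairs get guaranteed combined score >= 0.9 (fraction
#'   `candidate_pair_fraction` of all pairs).
#' @return A [scored_interactions()] table.
#' @export
generate_interactome <- function(config, universe, core = NULL,
                                 guarantee_genes = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- as_gene_vector(universe)
  if (!length(genes)) stop("universe is empty", call. = FALSE)
  set.seed(sub_seed(config$seed, 23L))
  parts <- list()
  bg <- pa_edge_list(length(genes), config$pa_edges_per_node, genes)
  if (!is.null(bg)) {
    n_unif <- round(config$uniform_edge_fraction * nrow(bg))
    if (n_unif > 0L && length(genes) >= 2L) {
      ua <- sample(genes, n_unif, replace = TRUE)
      ub <- sample(genes, n_unif, replace = TRUE)
      keep <- ua != ub
      bg <- rbind(bg, data.frame(gene_a = ua[keep], gene_b = ub[keep],
                                 stringsAsFactors = FALSE))
    }
    bg$high <- runif(nrow(bg)) < config$background_high_conf_prob
    parts$background <- bg
  }
  core_genes <- if (is.null(core)) character() else as_gene_vector(core)
  if (length(core_genes)) {
    core_genes <- sample(core_genes,
                         round(config$core_connected_fraction *
                                 length(core_genes)))
  }
  ce <- pa_edge_list(length(core_genes), config$core_edges_per_node,
                     core_genes)
  if (!is.null(ce)) {
    ce$high <- runif(nrow(ce)) < config$core_high_conf_prob
    parts$core <- ce
  }
  gg <- sort(unique(as.character(guarantee_genes %||% character())))
  if (length(gg) >= 2L && config$candidate_pair_fraction > 0) {
    pairs <- t(combn(gg, 2L))
    n_take <- ceiling(config$candidate_pair_fraction * nrow(pairs))
    take <- sort(sample.int(nrow(pairs), n_take))
    parts$guaranteed <- data.frame(gene_a = pairs[take, 1],
                                   gene_b = pairs[take, 2],
                                   high = TRUE, stringsAsFactors = FALSE)
  }
  if (!length(parts)) {
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        database = character(), combined_score = numeric(),
                        stringsAsFactors = FALSE)
    class(empty) <- c("scored_interactions", "data.frame")
    return(empty)
  }
  edges <- do.call(rbind, unname(parts))
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  scores <- draw_edge_scores(nrow(edges), config$n_sources, edges$high)
  curated <- runif(nrow(edges)) < config$curated_fraction & !edges$high
  scores[curated, ] <- NA_real_
  df <- cbind(data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                         database = ifelse(curated, "curated", "scored"),
                         stringsAsFactors = FALSE),
              as.data.frame(scores))
  scored_interactions(df)
}

#' Generate synthetic per-disease differential-expression tables
#'
#' Every universe gene appears in every disease table with a synthetic
#' log-fold-change and p-value.  Planted consistent-up genes are DE
#' (`p < deg_p_threshold`) with positive sign in all diseases;
#' consistent-down genes analogously negative; planted inconsistent
#' decoys are DE in all diseases with mixed signs.  Background genes are
#' DE in a random subset of at most `n_diseases - 1` diseases with random
#' signs; their DE p-values are uniform below the threshold and non-DE
#' p-values uniform above it.
#'
#' @param config a [synthetic_config()].
#' @param candidates_up,candidates_down,decoys disjoint [gene_set()]s (or
#'   character vectors) of planted genes.
#' @param universe [gene_set()] of all genes in the tables.
#' @return Named list of [disease_table()]s, one per disease.
#' @export
generate_disease_tables <- function(config, candidates_up, candidates_down,
                                    decoys, universe) {
  stopifnot(inherits(config, "synthetic_config"))
  up <- as_gene_vector(candidates_up)
  down <- as_gene_vector(candidates_down)
  dec <- as_gene_vector(decoys)
  if (length(intersect(up, down)) || length(intersect(up, dec)) ||
      length(intersect(down, dec))) {
    stop("planted gene sets must be disjoint", call. = FALSE)
  }
  K <- config$n_diseases
  if (K < 2L && length(dec)) {
    stop("direction inconsistency is impossible with a single disease",
         call. = FALSE)
  }
  genes <- as_gene_vector(universe)
  stopifnot(all(c(up, down, dec) %in% genes))
  set.seed(sub_seed(config$seed, 37L))
  n <- length(genes)
  thr <- config$deg_p_threshold
  # per-gene x disease DE indicator and sign
  de <- matrix(FALSE, n, K, dimnames = list(genes, config$disease_names))
  sgn <- matrix(sample(c(-1L, 1L), n * K, replace = TRUE), n, K,
                dimnames = dimnames(de))
  background <- setdiff(genes, c(up, down, dec))
  k_bg <- pmin(rbinom(length(background), K, config$background_de_prob),
               K - 1L)
  for (i in seq_along(background)) {
    if (k_bg[i] > 0L) de[background[i], sample.int(K, k_bg[i])] <- TRUE
  }
  de[up, ] <- TRUE;   sgn[up, ] <- 1L
  de[down, ] <- TRUE; sgn[down, ] <- -1L
  de[dec, ] <- TRUE
  for (g in dec) {
    s <- sample(c(-1L, 1L), K, replace = TRUE)
    if (length(unique(s)) == 1L) s[sample.int(K, 1L)] <- -s[1L]
    sgn[g, ] <- s
  }
  tables <- lapply(seq_len(K), function(k) {
    p <- ifelse(de[, k], runif(n, 0, 1) * thr,
                thr + runif(n, 0, 1) * (1 - thr))
    # p must stay strictly below / at-or-above the threshold
    p[de[, k]] <- pmax(p[de[, k]], .Machine$double.xmin)
    p[de[, k] & p >= thr] <- thr / 2
    lfc <- sgn[, k] * (0.2 + abs(stats::rnorm(n)))
    disease_table(data.frame(gene = genes, log_fold_change = lfc,
                             p_value = p, stringsAsFactors = FALSE),
                  disease = config$disease_names[k])
  })
  names(tables) <- config$disease_names
  tables
}

#' Generate phenotype similarity and known-gene modules
#'
#' Phenotypes are grouped into clusters.  Each phenotype is assigned a
#' connected module of `module_size` genes grown by breadth-first search
#' inside the network's largest connected component; phenotypes of one
#' cluster grow their modules from the same anchor region, so similar
#' phenotypes share module neighborhoods.  Half of each module
#' (alternating along the BFS order) becomes the phenotype's known
#' disease genes; the other half is held out as recoverable ground
#' truth.  The similarity matrix has unit diagonal,
#' `within_cluster_similarity` inside clusters and
#' `between_cluster_similarity` across.
#'
#' @param config a [synthetic_config()].
#' @param network the interaction network (igraph, non-empty, with an
#'   LCC of at least `module_size` nodes).
#' @return List with `similarity` ([phenotype_similarity()]),
#'   `disease_gene_map` ([disease_gene_map()] of known genes), and
#'   `modules`: per-phenotype list with `module`, `known`, `held_out`,
#'   `cluster`.
#' @export
generate_phenotype_data <- function(config, network) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_phenotypes < 3L) {
    stop("need at least 3 phenotypes for concordance scoring",
         call. = FALSE)
  }
  if (igraph::vcount(network) == 0L) stop("network is empty", call. = FALSE)
  comp <- igraph::components(network)
  lcc <- igraph::V(network)$name[comp$membership == which.max(comp$csize)]
  if (length(lcc) < config$module_size) {
    stop("largest connected component smaller than module_size",
         call. = FALSE)
  }
  set.seed(sub_seed(config$seed, 53L))
  P <- config$n_phenotypes
  phenos <- sprintf("PH%02d", seq_len(P))
  cluster <- rep(seq_len(config$n_phenotype_clusters), length.out = P)
  anchors <- sample(lcc, config$n_phenotype_clusters,
                    replace = config$n_phenotype_clusters > length(lcc))
  grow_module <- function(start) {
    # randomized BFS restricted to the LCC, tracking depth; splitting the
    # module by depth parity guarantees every held-out gene is adjacent
    # to a known gene of its own phenotype
    mod <- start
    depth <- setNames(0L, start)
    frontier <- start
    while (length(mod) < config$module_size && length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(v)
        igraph::neighbors(network, v)$name), use.names = FALSE))
      nb <- setdiff(intersect(nb, lcc), mod)
      if (!length(nb)) break
      nb <- sample(nb)
      take <- utils::head(nb, config$module_size - length(mod))
      depth[take] <- depth[frontier[1]] + 1L
      mod <- c(mod, take)
      frontier <- take
    }
    list(genes = mod, depth = depth[mod])
  }
  modules <- lapply(seq_len(P), function(i) {
    anchor <- anchors[cluster[i]]
    # later phenotypes of a cluster start from a neighbor of the anchor
    nb <- igraph::neighbors(network, anchor)$name
    start <- if (i > match(cluster[i], cluster) && length(nb))
      sample(nb, 1L) else anchor
    mod <- grow_module(start)
    even <- mod$depth %% 2L == 0L
    list(module = mod$genes,
         known = mod$genes[even],
         held_out = mod$genes[!even],
         cluster = cluster[i])
  })
  names(modules) <- phenos
  S <- matrix(config$between_cluster_similarity, P, P,
              dimnames = list(phenos, phenos))
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    S[idx, idx] <- config$within_cluster_similarity
  }
  diag(S) <- 1
  list(similarity = phenotype_similarity(S),
       disease_gene_map = disease_gene_map(lapply(modules, `[[`, "known")),
       modules = modules)
}

#' Generate a complete synthetic study
#'
#' Orchestrates the generators into one coherent study with planted
#' ground truth: universe and gene sets, planted candidates and decoys
#' drawn from the core intersection, the scored interactome (with
#' guaranteed candidate edges), the integrated filtered network and the
#' restricted network induced on the core, the disease tables, and the
#' phenotype data grown on the integrated network.
#'
#' @param config a [synthetic_config()].
#' @param score_threshold combined-score threshold for the integrated
#'   network (default 0.9).
#' @return List of class `synthetic_study` with elements `config`,
#'   `universe`, `annotation_set`, `enrichment_sets`, `ortholog_map`,
#'   `core`, `planted` (list `up`, `down`, `inconsistent`), `edges`
#'   (all scored interactions), `filtered_edges`, `background_network`
#'   (all universe genes, filtered edges), `restricted_network` (induced
#'   on the core), `disease_tables`, `similarity`, `disease_gene_map`,
#'   `modules`.
#' @export
generate_synthetic_study <- function(config = synthetic_config(),
                                     score_threshold = 0.9) {
  stopifnot(inherits(config, "synthetic_config"))
  uni <- generate_universe(config)
  set.seed(sub_seed(config$seed, 7L))
  n_up <- config$n_planted_consistent_up
  n_down <- config$n_planted_consistent_down
  n_dec <- config$n_planted_inconsistent
  picked <- sample(uni$core$genes, n_up + n_down + n_dec)
  planted <- list(up = sort(picked[seq_len(n_up)]),
                  down = sort(picked[n_up + seq_len(n_down)]),
                  inconsistent = sort(picked[n_up + n_down + seq_len(n_dec)]))
  edges <- generate_interactome(config, uni$universe, core = uni$core,
                                guarantee_genes = c(planted$up, planted$down))
  filtered <- filter_interactions(edges, threshold = score_threshold)
  background <- induce_network(uni$universe, filtered)
  restricted <- induce_network(uni$core, filtered)
  tables <- generate_disease_tables(config, planted$up, planted$down,
                                    planted$inconsistent, uni$universe)
  pheno <- generate_phenotype_data(config, background)
  structure(c(uni, list(
    config = config,
    planted = planted,
    edges = edges,
    filtered_edges = filtered,
    background_network = background,
    restricted_network = restricted,
    disease_tables = tables,
    similarity = pheno$similarity,
    disease_gene_map = pheno$disease_gene_map,
    modules = pheno$modules
  )), class = "synthetic_study")
}
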