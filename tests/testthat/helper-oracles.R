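# Independent oracles and small-graph utilities shared across tests.

# Brute-force betweenness from first principles, independent of igraph:
# Floyd-Warshall distances on the adjacency matrix, shortest-path counts
# via powers of A (walks of minimal length are exactly the shortest
# paths), and CB(v) = sum over unordered pairs {s,t}, v not in {s,t}, of
# sigma_st(v) / sigma_st with sigma_st(v) = sigma_sv * sigma_vt when
# d(s,v) + d(v,t) = d(s,t).
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(numeric(0))
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  maxd <- max(D[is.finite(D)])
  pow <- vector("list", max(maxd, 1))
  P <- adj
  pow[[1]] <- P
  if (maxd >= 2) {
    for (d in 2:maxd) {
      P <- P %*% adj
      pow[[d]] <- P
    }
  }
  sigma <- function(i, j) {
    if (i == j) return(1)
    d <- D[i, j]
    if (!is.finite(d)) return(0)
    pow[[d]][i, j]
  }
  cb <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    sst <- sigma(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        cb[v] <- cb[v] + sigma(s, v) * sigma(v, t) / sst
      }
    }
  }
  cb
}

graph_from_adjacency <- function(adj, labels = NULL) {
  labels <- labels %||% paste0("n", seq_len(nrow(adj)))
  dimnames(adj) <- list(labels, labels)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# adjacency matrix of the i-th labeled graph on n nodes (i indexes the
# edge bitmask, 0 .. 2^choose(n,2) - 1)
labeled_graph_adj <- function(n, bitmask) {
  adj <- matrix(0L, n, n)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  on <- bitwAnd(bitmask, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) != 0L
  adj[pairs[on, , drop = FALSE]] <- 1L
  adj + t(adj)
}

random_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  on <- stats::runif(nrow(pairs)) < p
  adj[pairs[on, , drop = FALSE]] <- 1L
  adj + t(adj)
}

# a small deterministic toy background used by subnetwork / path tests:
#   A - C - B,  A - D,  E - F (separate islet), plus 4-cycle P-Q-R-S
toy_background <- function() {
  edges <- data.frame(
    gene_a = c("A", "C", "A", "E", "P", "Q", "R", "S"),
    gene_b = c("C", "B", "D", "F", "Q", "R", "S", "P"),
    database = "scored", combined_score = 0.95,
    stringsAsFactors = FALSE
  )
  induce_network(unique(c(edges$gene_a, edges$gene_b)),
                 scored_interactions(edges, recompute = FALSE))
}

small_synth_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed,
    n_genes = 400L, n_annotation = 150L, n_core = 60L,
    n_enriched_datasets = 3L,
    enrichment_set_sizes = c(60L, 90L, 120L),
    enrichment_core_counts = c(20L, 25L, 30L),
    mouse_datasets = 2L,
    n_planted_consistent_up = 2L, n_planted_consistent_down = 4L,
    n_planted_inconsistent = 3L,
    n_phenotypes = 4L, n_phenotype_clusters = 2L, module_size = 6L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}
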