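#' Known disease-gene map
#'
#' Phenotype -> known disease genes, the OMIM-style input behind both the
#' candidate/known-gene linkage network and the prioritization step.
#'
#' @param genes named list: phenotype id -> character vector of genes
#'   (each non-empty).
#' @param metadata optional data.frame with columns `phenotype_id` and
#'   `phenotype_name`.
#' @return An object of class `disease_gene_map`.
#' @export
disease_gene_map <- function(genes, metadata = NULL) {
  stopifnot(is.list(genes), !is.null(names(genes)), all(nzchar(names(genes))))
  genes <- lapply(genes, function(g) sort(unique(as.character(g))))
  if (any(!vapply(genes, length, integer(1)))) {
    stop("every phenotype needs at least one known gene", call. = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- data.frame(phenotype_id = names(genes),
                           phenotype_name = names(genes),
                           stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, metadata = metadata),
            class = "disease_gene_map")
}

#' Read a phenotype-gene association TSV
#'
#' One row per (phenotype, gene) association: columns `phenotype_id`,
#' `phenotype_name`, `gene`.
#'
#' @param path file path.
#' @return A [disease_gene_map()].
#' @export
read_disease_gene_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("phenotype_id", "gene") %in% names(df)))
  if (is.null(df$phenotype_name)) df$phenotype_name <- df$phenotype_id
  genes <- split(as.character(df$gene), df$phenotype_id)
  meta <- unique(df[, c("phenotype_id", "phenotype_name")])
  disease_gene_map(genes, metadata = meta[order(meta$phenotype_id), ])
}

new_bridged_subnetwork <- function(graph, roles, dropped = character(),
                                   isolated = character(), policy = NA) {
  structure(list(graph = graph, roles = roles, dropped_seeds = dropped,
                 isolated_seeds = isolated, policy = policy),
            class = "bridged_subnetwork")
}

#' @export
print.bridged_subnetwork <- function(x, ...) {
  tab <- table(x$roles)
  cat(sprintf("<bridged_subnetwork> (%s policy) %d nodes, %d edges\n",
              x$policy, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(x$dropped_seeds)) {
    cat("  dropped (not in background):",
        paste(x$dropped_seeds, collapse = ", "), "\n")
  }
  invisible(x)
}

# deterministic lexicographically-smallest shortest path between two
# vertices of an unweighted graph; NULL when unreachable
lex_shortest_path <- function(graph, from, to) {
  if (from == to) return(from)
  d <- igraph::distances(graph, v = to, weights = NA)[1, ]
  if (!is.finite(d[from])) return(NULL)
  path <- from
  cur <- from
  while (cur != to) {
    nb <- igraph::neighbors(graph, cur)$name
    nxt <- sort(nb[d[nb] == d[cur] - 1])[1]
    path <- c(path, nxt)
    cur <- nxt
  }
  path
}

#' Reconstruct a bridged subnetwork around seed genes
#'
#' The candidate genes are sparsely connected among themselves in the
#' integrated interaction network, so a connected view is reconstructed
#' by adding non-seed "bridge" nodes.  Two deterministic policies:
#'
#' * `common_neighbors` (default): add every background node adjacent to
#'   at least two seeds (the "common first-order neighbor" rule).
#' * `steiner_greedy`: walk seed pairs in order of background distance
#'   (ties lexicographic) and add the nodes of the lexicographically
#'   smallest shortest path whenever the pair is not yet connected inside
#'   the growing subnetwork — a compact greedy Steiner-style connector.
#'
#' Edges are always the background edges induced on the retained nodes;
#' no edge is invented.
#'
#' @param seeds a [gene_set()] or character vector of seed genes; seeds
#'   absent from the background are dropped (and reported).
#' @param background the integrated interaction network (igraph).
#' @param policy bridging policy.
#' @param seed_roles optional named character vector labelling seeds
#'   (e.g. `"seed_up"` / `"seed_down"`); default role is `"seed"`.
#' @return A `bridged_subnetwork`: list with the induced `graph`, named
#'   `roles` vector (`seed*` / `bridge`), `dropped_seeds`, and
#'   `isolated_seeds` (seeds with no connection inside the subnetwork).
#' @export
build_bridged_subnetwork <- function(seeds, background,
                                     policy = c("common_neighbors",
                                                "steiner_greedy"),
                                     seed_roles = NULL) {
  policy <- match.arg(policy)
  seeds <- as_gene_vector(seeds)
  bg_nodes <- igraph::V(background)$name
  dropped <- setdiff(seeds, bg_nodes)
  seeds <- intersect(seeds, bg_nodes)
  if (!length(seeds)) {
    return(new_bridged_subnetwork(igraph::make_empty_graph(0, FALSE),
                                  setNames(character(0), character(0)),
                                  dropped = dropped, policy = policy))
  }
  if (policy == "common_neighbors") {
    # count, for every background node, how many seeds it touches
    inc <- igraph::adjacent_vertices(background, seeds)
    nb_all <- unlist(lapply(inc, function(v) v$name), use.names = FALSE)
    tab <- table(nb_all)
    bridges <- setdiff(names(tab)[tab >= 2L], seeds)
  } else {
    d <- igraph::distances(background, v = seeds, to = seeds, weights = NA)
    pairs <- which(upper.tri(d) & is.finite(d), arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(d[pairs], seeds[pairs[, 1]], seeds[pairs[, 2]])
      pairs <- pairs[ord, , drop = FALSE]
    }
    nodes <- seeds
    for (i in seq_len(nrow(pairs))) {
      s1 <- seeds[pairs[i, 1]]; s2 <- seeds[pairs[i, 2]]
      sub <- igraph::induced_subgraph(background, nodes)
      already <- is.finite(igraph::distances(sub, v = s1, to = s2,
                                             weights = NA)[1, 1])
      if (!already) {
        nodes <- union(nodes, lex_shortest_path(background, s1, s2))
      }
    }
    bridges <- setdiff(nodes, seeds)
  }
  keep <- sort(union(seeds, bridges))
  sub <- igraph::induced_subgraph(background, keep)
  roles <- setNames(rep("bridge", length(keep)), keep)
  roles[seeds] <- "seed"
  if (!is.null(seed_roles)) {
    hit <- intersect(names(seed_roles), seeds)
    roles[hit] <- seed_roles[hit]
  }
  deg <- igraph::degree(sub)
  new_bridged_subnetwork(sub, roles[igraph::V(sub)$name], dropped = dropped,
                         isolated = intersect(names(deg)[deg == 0L], seeds),
                         policy = policy)
}

#' Link candidate genes to known disease genes
#'
#' Builds the candidate-by-known-disease-gene interaction view: seeds are
#' the candidates plus every known disease gene, bridged with the chosen
#' policy over the integrated network.  Node roles distinguish
#' `candidate`, `known`, `candidate_known` (both), and `bridge`;
#' candidates with no connection in the resulting subnetwork are flagged
#' isolated.
#'
#' @param candidates a [gene_set()] or character vector of candidates.
#' @param dgm a [disease_gene_map()].
#' @param background the integrated interaction network (igraph).
#' @param policy bridging policy, as in [build_bridged_subnetwork()].
#' @return A `bridged_subnetwork` with the roles above.
#' @export
link_to_disease_genes <- function(candidates, dgm, background,
                                  policy = c("common_neighbors",
                                             "steiner_greedy")) {
  stopifnot(inherits(dgm, "disease_gene_map"))
  policy <- match.arg(policy)
  candidates <- as_gene_vector(candidates)
  known <- sort(unique(unlist(dgm$genes, use.names = FALSE)))
  roles <- setNames(rep("candidate", length(candidates)), candidates)
  roles[known] <- "known"
  both <- intersect(candidates, known)
  roles[both] <- "candidate_known"
  build_bridged_subnetwork(union(candidates, known), background,
                           policy = policy, seed_roles = roles)
}

#' Deterministic shortest paths among a gene set
#'
#' For every unordered pair of the given genes that lies in one connected
#' component of the background network, reports one shortest path with a
#' deterministic tie-break (the lexicographically smallest node sequence,
#' walked from the lexicographically smaller endpoint).  Unreachable
#' pairs are reported with `length = NA` and an empty path.
#'
#' @param genes a [gene_set()] or character vector (genes absent from the
#'   background are dropped).
#' @param background the interaction network (igraph).
#' @return data.frame with columns `from`, `to`, `length`, `path`
#'   (a list-column of node sequences).
#' @export
shortest_path_links <- function(genes, background) {
  genes <- sort(intersect(as_gene_vector(genes),
                          igraph::V(background)$name))
  if (length(genes) < 2L) {
    return(data.frame(from = character(), to = character(),
                      length = integer(), path = I(list())))
  }
  pairs <- combn(genes, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    p <- lex_shortest_path(background, pairs[1, i], pairs[2, i])
    list(from = pairs[1, i], to = pairs[2, i],
         length = if (is.null(p)) NA_integer_ else length(p) - 1L,
         path = if (is.null(p)) character(0) else p)
  })
  data.frame(from = vapply(res, `[[`, character(1), "from"),
             to = vapply(res, `[[`, character(1), "to"),
             length = vapply(res, `[[`, integer(1), "length"),
             path = I(lapply(res, `[[`, "path")),
             stringsAsFactors = FALSE)
}
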