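#' Standardize a per-disease differential-expression table
#'
#' Normalizes one disease's differential-expression results to columns
#' `gene`, `direction` (+1 / -1), `log_fold_change`, `p_value`.  Direction
#' is taken strictly as the sign of the fold change; a zero fold change is
#' rejected.  Duplicate gene rows are collapsed deterministically to the
#' minimum p-value (with a warning), ties broken by larger absolute fold
#' change then row order.
#'
#' @param df data.frame with columns `gene`, `p_value`, and either
#'   `log_fold_change` (numeric, nonzero) or `direction` (`"up"`/`"down"`
#'   or +1/-1).
#' @param disease disease label (e.g. `"FSGS"`).
#' @return Standardized data.frame of class `disease_table` with
#'   attribute `"disease"`.
#' @export
disease_table <- function(df, disease) {
  stopifnot(is.data.frame(df), "gene" %in% names(df), "p_value" %in% names(df))
  gene <- as.character(df$gene)
  p <- as.numeric(df$p_value)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("[%s] p_value must be in [0, 1]", disease), call. = FALSE)
  }
  if (!is.null(df$log_fold_change)) {
    lfc <- as.numeric(df$log_fold_change)
    if (anyNA(lfc) || any(lfc == 0)) {
      stop(sprintf("[%s] log_fold_change must be nonzero", disease),
           call. = FALSE)
    }
  } else if (!is.null(df$direction)) {
    dirc <- df$direction
    if (is.character(dirc)) {
      dirc <- c(up = 1, down = -1)[tolower(dirc)]
    }
    dirc <- as.numeric(dirc)
    if (anyNA(dirc) || any(dirc == 0)) {
      stop(sprintf("[%s] direction must be up/down or +1/-1", disease),
           call. = FALSE)
    }
    lfc <- sign(dirc)
  } else {
    stop(sprintf("[%s] need a log_fold_change or direction column", disease),
         call. = FALSE)
  }
  out <- data.frame(gene = gene, direction = as.integer(sign(lfc)),
                    log_fold_change = lfc, p_value = p,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) {
    warning(sprintf("[%s] duplicate gene rows collapsed to minimum p-value",
                    disease), call. = FALSE)
    ord <- order(out$gene, out$p_value, -abs(out$log_fold_change))
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(out$gene), , drop = FALSE]
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "disease") <- disease
  class(out) <- c("disease_table", "data.frame")
  out
}

#' Read a disease differential-expression TSV
#'
#' Expects tab-separated columns `gene`, `p_value`, and
#' `log_fold_change` or `direction`.
#'
#' @param path file path.
#' @param disease disease label; defaults to the file name stem.
#' @return A [disease_table()].
#' @export
read_disease_table <- function(path, disease = NULL) {
  disease <- disease %||% sub("\\.[^.]*$", "", basename(path))
  disease_table(read.delim(path, stringsAsFactors = FALSE), disease)
}

disease_labels <- function(tables) {
  labs <- names(tables)
  from_attr <- vapply(tables, function(t) attr(t, "disease") %||% NA_character_,
                      character(1))
  if (is.null(labs)) labs <- from_attr
  labs[is.na(labs) | !nzchar(labs)] <-
    paste0("disease_", which(is.na(labs) | !nzchar(labs)))
  labs
}

# genes x diseases matrix of DE signs: +1 / -1 where p < threshold, 0 otherwise
de_sign_matrix <- function(genes, tables, p_threshold = 0.05) {
  K <- length(tables)
  M <- matrix(0L, nrow = length(genes), ncol = K,
              dimnames = list(genes, disease_labels(tables)))
  for (k in seq_len(K)) {
    t <- tables[[k]]
    de <- t[t$p_value < p_threshold, , drop = FALSE]
    hit <- de$gene %in% genes
    M[de$gene[hit], k] <- de$direction[hit]
  }
  M
}

#' Classify genes by cross-disease differential-expression consistency
#'
#' A gene is differentially expressed (DE) in a disease when it appears in
#' that disease's table with `p < p_threshold`; a gene absent from a table
#' is treated as not DE there.  From the sign pattern over its DE diseases
#' the gene is classed as `none` (DE nowhere), `consistent_up`,
#' `consistent_down`, or `inconsistent` (both signs present).  Candidates
#' are the direction-consistent genes DE in *all* diseases.
#'
#' @param genes character vector of genes to classify (normally the
#'   network's node set).
#' @param tables list of [disease_table()]s, one per disease.
#' @param p_threshold DE p-value cutoff (default 0.05, no multiplicity
#'   correction, matching the upstream selection rule).
#' @return data.frame with columns `gene`, `n_diseases_de`, `n_up`,
#'   `n_down`, `class`, `candidate`, plus the per-disease sign matrix as
#'   attribute `"signs"`.
#' @export
classify_genes <- function(genes, tables, p_threshold = 0.05) {
  stopifnot(length(tables) >= 1L)
  genes <- as_gene_vector(genes)
  M <- de_sign_matrix(genes, tables, p_threshold)
  K <- ncol(M)
  n_up <- rowSums(M > 0L)
  n_down <- rowSums(M < 0L)
  n_de <- n_up + n_down
  cls <- rep("none", length(genes))
  cls[n_up > 0L & n_down == 0L] <- "consistent_up"
  cls[n_down > 0L & n_up == 0L] <- "consistent_down"
  cls[n_up > 0L & n_down > 0L] <- "inconsistent"
  out <- data.frame(
    gene = genes,
    n_diseases_de = as.integer(n_de),
    n_up = as.integer(n_up),
    n_down = as.integer(n_down),
    class = cls,
    candidate = cls %in% c("consistent_up", "consistent_down") & n_de == K,
    stringsAsFactors = FALSE
  )
  attr(out, "signs") <- M
  out
}

#' @rdname classify_genes
#' @param gene a single gene identifier.
#' @return `classify_gene()` returns the one-row profile for `gene`.
#' @export
classify_gene <- function(gene, tables, p_threshold = 0.05) {
  classify_genes(gene, tables, p_threshold)
}

#' Cross-disease consistency and per-disease DE summary tables
#'
#' Builds the two summary tables of the analysis: (i) strata counts of
#' network genes by the number of diseases in which they are DE
#' (k = 0..K), split into consistently up, consistently down, and
#' direction-inconsistent; (ii) per-disease counts of up-/down-regulated
#' genes genome-wide and within the network, with the network percentage
#' displayed at one decimal (half-up).
#'
#' @param network an undirected igraph whose vertex names are genes.
#' @param tables list of [disease_table()]s.
#' @param p_threshold DE p-value cutoff.
#' @return A list of class `consistency_table` with data.frames `strata`
#'   (columns `n_diseases`, `up`, `down`, `inconsistent`, `total`) and
#'   `per_disease` (columns `disease`, `n_up_genome`, `n_up_network`,
#'   `n_down_genome`, `n_down_network`, `n_de_network`, `pct_network`),
#'   plus the underlying `profiles`.
#' @export
build_consistency_table <- function(network, tables, p_threshold = 0.05) {
  genes <- if (igraph::vcount(network)) igraph::V(network)$name else character()
  K <- length(tables)
  prof <- if (length(genes)) classify_genes(genes, tables, p_threshold) else
    classify_genes(character(), tables, p_threshold)
  strata <- do.call(rbind, lapply(0:K, function(k) {
    at_k <- prof[prof$n_diseases_de == k, , drop = FALSE]
    data.frame(n_diseases = k,
               up = sum(at_k$class == "consistent_up"),
               down = sum(at_k$class == "consistent_down"),
               inconsistent = sum(at_k$class == "inconsistent"),
               total = nrow(at_k))
  }))
  labs <- disease_labels(tables)
  per_disease <- do.call(rbind, lapply(seq_len(K), function(k) {
    t <- tables[[k]]
    de <- t[t$p_value < p_threshold, , drop = FALSE]
    up <- de$gene[de$direction > 0L]
    down <- de$gene[de$direction < 0L]
    n_up_net <- sum(up %in% genes)
    n_down_net <- sum(down %in% genes)
    data.frame(disease = labs[k],
               n_up_genome = length(unique(up)),
               n_up_network = n_up_net,
               n_down_genome = length(unique(down)),
               n_down_network = n_down_net,
               n_de_network = n_up_net + n_down_net,
               pct_network = if (length(genes))
                 round_half_up(100 * (n_up_net + n_down_net) / length(genes), 1)
               else 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(strata = strata, per_disease = per_disease,
                 profiles = prof, p_threshold = p_threshold),
            class = "consistency_table")
}

#' @export
print.consistency_table <- function(x, ...) {
  cat("<consistency_table>\n\nStrata (genes by number of diseases DE):\n")
  print(x$strata, row.names = FALSE)
  cat("\nPer-disease DE counts:\n")
  print(x$per_disease, row.names = FALSE)
  invisible(x)
}

#' Select direction-consistent all-disease candidate genes
#'
#' Genes of the network that are DE in every disease with one consistent
#' direction of regulation, partitioned into up- and down-regulated
#' subsets.
#'
#' @inheritParams build_consistency_table
#' @return A list of class `candidate_set` with [gene_set()]s `up`,
#'   `down`, and `all`.
#' @export
select_candidates <- function(network, tables, p_threshold = 0.05) {
  genes <- if (igraph::vcount(network)) igraph::V(network)$name else character()
  prof <- classify_genes(genes, tables, p_threshold)
  cand <- prof[prof$candidate, , drop = FALSE]
  up <- cand$gene[cand$class == "consistent_up"]
  down <- cand$gene[cand$class == "consistent_down"]
  structure(list(
    up = gene_set(up, name = "candidates_up",
                  provenance = "DE in all diseases, consistently up"),
    down = gene_set(down, name = "candidates_down",
                    provenance = "DE in all diseases, consistently down"),
    all = gene_set(c(up, down), name = "candidates",
                   provenance = "direction-consistent all-disease DE genes")
  ), class = "candidate_set")
}

#' Permutation null for the all-disease consistent-candidate count
#'
#' Permutes gene labels within each disease table independently and
#' recounts direction-consistent all-disease candidates, giving an
#' empirical null distribution for the observed candidate count.
#'
#' @inheritParams build_consistency_table
#' @param n_permutations number of label permutations.
#' @param seed RNG seed.
#' @return A list with `observed`, numeric vector `null`, and the
#'   empirical p-value `(1 + #(null >= observed)) / (n_permutations + 1)`.
#' @export
consistency_null <- function(network, tables, n_permutations = 1000L,
                             p_threshold = 0.05, seed = 1L) {
  assert_count(n_permutations, "n_permutations", min = 1L)
  genes <- if (igraph::vcount(network)) igraph::V(network)$name else character()
  K <- length(tables)
  count_candidates <- function(M) {
    n_up <- rowSums(M > 0L); n_down <- rowSums(M < 0L)
    sum((n_up == K & n_down == 0L) | (n_down == K & n_up == 0L))
  }
  observed <- count_candidates(de_sign_matrix(genes, tables, p_threshold))
  # per-table DE sign vectors over that table's own gene list
  per_table <- lapply(tables, function(t) {
    s <- integer(nrow(t))
    de <- t$p_value < p_threshold
    s[de] <- t$direction[de]
    list(genes = t$gene, signs = s)
  })
  set.seed(seed)
  null <- vapply(seq_len(n_permutations), function(b) {
    M <- matrix(0L, nrow = length(genes), ncol = K,
                dimnames = list(genes, NULL))
    for (k in seq_len(K)) {
      pt <- per_table[[k]]
      perm_genes <- sample(pt$genes)
      hit <- perm_genes %in% genes
      M[perm_genes[hit], k] <- pt$signs[hit]
    }
    count_candidates(M)
  }, numeric(1))
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (n_permutations + 1))
}
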