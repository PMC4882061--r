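#' Phenotype-phenotype similarity matrix
#'
#' Validates a square symmetric similarity matrix with unit diagonal and
#' entries in [0, 1], the phenotype-side input of the concordance score.
#' At least three phenotypes are required downstream (a Pearson
#' correlation over fewer profiles is degenerate).
#'
#' @param mat numeric matrix with identical row/column phenotype names.
#' @param tol symmetry tolerance.
#' @return The validated matrix with class `phenotype_similarity`.
#' @export
phenotype_similarity <- function(mat, tol = 1e-8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("similarity matrix must be square",
                                   call. = FALSE)
  if (is.null(rownames(mat)) || is.null(colnames(mat)) ||
      !identical(rownames(mat), colnames(mat))) {
    stop("similarity matrix needs matching phenotype row/column names",
         call. = FALSE)
  }
  assert_probability(c(mat), "similarity entries")
  if (max(abs(mat - t(mat))) > tol) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(mat) - 1)) > tol) {
    stop("similarity matrix must have unit diagonal", call. = FALSE)
  }
  structure(mat, class = c("phenotype_similarity", class(mat)))
}

#' Read / write a phenotype similarity TSV
#'
#' Square tab-separated matrix with phenotype ids as header and first
#' column.
#'
#' @param path file path.
#' @return `read_phenotype_similarity()` returns a
#'   [phenotype_similarity()] matrix.
#' @export
read_phenotype_similarity <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE,
                   stringsAsFactors = FALSE)
  phenotype_similarity(as.matrix(df))
}

#' @rdname read_phenotype_similarity
#' @param similarity matrix to write.
#' @export
write_phenotype_similarity <- function(similarity, path) {
  df <- data.frame(phenotype = rownames(similarity),
                   as.data.frame(unclass(similarity), check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Network closeness profile of genes to phenotypes
#'
#' For gene `g` and phenotype `p`, the closeness is
#' `Phi(g, p) = sum over known genes g' of p of exp(-L(g, g')^2)`, with
#' `L` the unweighted shortest-path length in the network, `L(g, g) = 0`,
#' and disconnected pairs contributing 0.  A phenotype none of whose
#' known genes is in the network contributes a zero column (with a
#' warning).
#'
#' @param network the interaction network (igraph) used for distances —
#'   conventionally the full integrated network, not the
#'   tissue-restricted one.
#' @param dgm a [disease_gene_map()].
#' @param genes genes to profile; default all network nodes.
#' @return Numeric matrix, genes x phenotypes.
#' @export
closeness_profile <- function(network, dgm, genes = NULL) {
  stopifnot(inherits(dgm, "disease_gene_map"))
  if (igraph::vcount(network) == 0L) stop("network is empty", call. = FALSE)
  nodes <- igraph::V(network)$name
  genes <- if (is.null(genes)) nodes else
    intersect(as_gene_vector(genes), nodes)
  phenos <- names(dgm$genes)
  known_in <- lapply(dgm$genes, intersect, nodes)
  missing <- phenos[!vapply(known_in, length, integer(1))]
  if (length(missing)) {
    warning("phenotype(s) with no known gene in the network score 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  targets <- sort(unique(unlist(known_in, use.names = FALSE)))
  Phi <- matrix(0, nrow = length(genes), ncol = length(phenos),
                dimnames = list(genes, phenos))
  if (!length(targets)) return(Phi)
  L <- igraph::distances(network, v = genes, to = targets, weights = NA)
  K <- exp(-L^2)
  K[!is.finite(L)] <- 0
  for (p in phenos) {
    tg <- known_in[[p]]
    if (length(tg)) Phi[, p] <- rowSums(K[, tg, drop = FALSE])
  }
  Phi
}

#' Concordance score between genes and phenotypes
#'
#' The prioritization score of gene `g` for phenotype `p` is the Pearson
#' correlation, across all phenotypes `p'`, between the phenotype
#' similarity row `S[p, ]` and the gene's closeness profile
#' `Phi(g, )` — high when the gene is topologically close to the known
#' genes of exactly the phenotypes that resemble `p`.  Zero-variance
#' profiles (e.g. a gene disconnected from every known gene) are scored
#' 0 and flagged.
#'
#' @param network integrated interaction network (igraph).
#' @param similarity a [phenotype_similarity()] matrix (>= 3 phenotypes).
#' @param dgm a [disease_gene_map()]; phenotype ids must match the
#'   similarity matrix.
#' @param genes genes to score; default all network nodes.
#' @return Numeric matrix of scores (genes x phenotypes) in [-1, 1], with
#'   a logical attribute `"zero_variance"` marking flagged entries and
#'   the closeness profile as attribute `"profile"`.
#' @export
cipher_score <- function(network, similarity, dgm, genes = NULL) {
  similarity <- phenotype_similarity(unclass(similarity))
  phenos <- rownames(similarity)
  if (length(phenos) < 3L) {
    stop("concordance scoring needs at least 3 phenotypes", call. = FALSE)
  }
  if (!setequal(phenos, names(dgm$genes))) {
    stop("similarity phenotypes and disease-gene map phenotypes differ",
         call. = FALSE)
  }
  Phi <- closeness_profile(network, dgm, genes)[, phenos, drop = FALSE]
  # cor of columns: t(Phi) has genes as columns, t(S) phenotypes as columns
  sd_g <- apply(Phi, 1L, stats::sd)
  sd_p <- apply(similarity, 1L, stats::sd)
  scores <- suppressWarnings(cor(t(Phi), t(unclass(similarity))))
  zero_var <- outer(sd_g == 0, sd_p == 0, `|`)
  scores[zero_var | is.na(scores)] <- 0
  dimnames(scores) <- list(rownames(Phi), phenos)
  attr(scores, "zero_variance") <- zero_var | is.na(scores)
  attr(scores, "profile") <- Phi
  scores
}

#' Rank scores per phenotype and call top-N predictions
#'
#' Per phenotype, genes are sorted by descending score with ties broken
#' lexicographically by gene name; the top `n` per phenotype are called
#' predicted (the published analysis used the top 1000 genes per
#' phenotype).
#'
#' @param scores genes x phenotypes score matrix from [cipher_score()].
#' @param n top-N call threshold.
#' @return data.frame with columns `gene`, `phenotype`, `score`, `rank`,
#'   `predicted`, ordered by phenotype then rank.
#' @export
rank_and_call <- function(scores, n = 1000L) {
  assert_count(n, "n", min = 1L)
  genes <- rownames(scores)
  out <- do.call(rbind, lapply(colnames(scores), function(p) {
    ord <- order(-scores[, p], genes)
    data.frame(gene = genes[ord], phenotype = p,
               score = scores[ord, p], rank = seq_along(genes),
               predicted = seq_along(genes) <= n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
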