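#' Combine per-source interaction confidence scores
#'
#' Noisy-OR integration of evidence-channel confidences into one combined
#' score, STRING-style: each channel is capped (a single evidence source
#' can contribute at most `cap`, 0.9 by default, so a single-source edge
#' can never exceed 0.9), and the capped channels are combined as
#' `1 - prod(1 - s_i)`.  With `prior > 0` each channel is first corrected
#' for the random-expectation prior (`(s - prior) / (1 - prior)`, floored
#' at 0), combined, and the prior is re-added.
#'
#' @param scores numeric vector of per-source scores in `[0, 1]` (names,
#'   if any, identify the evidence channels and are ignored by the
#'   arithmetic).
#' @param cap per-source maximum contribution.
#' @param prior prior probability removed from / re-added to each channel;
#'   `0` (default) disables prior correction.
#' @return A single combined score in `[0, 1]`; `0` for an empty input.
#' @examples
#' combine_scores(c(0.8))            # single source below the cap: 0.8
#' combine_scores(c(0.8, 0.6))       # 1 - 0.2 * 0.4 = 0.92
#' combine_scores(c(0.95))           # capped at 0.9
#' @export
combine_scores <- function(scores, cap = 0.9, prior = 0) {
  if (is.list(scores)) scores <- unlist(scores, use.names = FALSE)
  if (!length(scores)) return(0)
  assert_probability(scores, "source scores")
  assert_probability(cap, "cap")
  assert_probability(prior, "prior")
  s <- pmin(scores, cap)
  if (prior > 0) {
    s <- pmax(s - prior, 0) / (1 - prior)
    (1 - prod(1 - s)) * (1 - prior) + prior
  } else {
    1 - prod(1 - s)
  }
}

score_columns <- function(df) grep("^score_", names(df), value = TRUE)

#' Build a canonical scored-interaction table
#'
#' Normalizes an undirected edge list of protein-protein interactions:
#' endpoints are put in canonical (lexicographic) order, self-loops are
#' rejected, per-source score columns (named `score_*`) are validated,
#' and the combined score is (re)computed with [combine_scores()] for
#' edges of the `"scored"` database class.  `"curated"` edges (literature
#' databases without channel scores) keep `NA` scores.
#'
#' @param df data.frame with columns `gene_a`, `gene_b`, optionally
#'   `database` (`"scored"` or `"curated"`, default `"scored"`),
#'   optionally `combined_score`, plus any number of `score_*` columns.
#' @param cap,prior passed to [combine_scores()].
#' @param recompute if `TRUE` (default) the combined score of scored
#'   edges is recomputed from the `score_*` columns when present.
#' @return The canonicalized data.frame (class `scored_interactions`),
#'   deduplicated on the unordered pair keeping the maximum combined
#'   score.
#' @export
scored_interactions <- function(df, cap = 0.9, prior = 0, recompute = TRUE) {
  stopifnot(is.data.frame(df), all(c("gene_a", "gene_b") %in% names(df)))
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  if (any(df$gene_a == df$gene_b)) {
    stop("self-interactions are not allowed", call. = FALSE)
  }
  if (is.null(df$database)) df$database <- "scored"
  if (!all(df$database %in% c("scored", "curated"))) {
    stop("database must be 'scored' or 'curated'", call. = FALSE)
  }
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]
  df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  sc <- score_columns(df)
  for (col in sc) assert_probability(df[[col]][!is.na(df[[col]])], col)
  scored <- df$database == "scored"
  if (is.null(df$combined_score)) df$combined_score <- NA_real_
  if (recompute && length(sc)) {
    df$combined_score[scored] <- vapply(which(scored), function(i) {
      s <- unlist(df[i, sc], use.names = FALSE)
      combine_scores(s[!is.na(s)], cap = cap, prior = prior)
    }, numeric(1))
  }
  if (any(scored & is.na(df$combined_score))) {
    stop("scored edges need a combined_score or score_* columns",
         call. = FALSE)
  }
  # dedup unordered pairs: keep the row with the highest combined score,
  # but a pair reported curated by any record stays curated
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  comb_filled <- ifelse(is.na(df$combined_score), -1, df$combined_score)
  curated_keys <- unique(key[df$database == "curated"])
  ord <- order(key, -comb_filled)
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(key[ord])
  df <- df[!dup, , drop = FALSE]
  df$database[paste(df$gene_a, df$gene_b, sep = "\r") %in% curated_keys] <-
    "curated"
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scored_interactions", "data.frame")
  df
}

#' Filter interactions at a combined-score threshold
#'
#' Keeps scored edges whose combined confidence is at least `threshold`
#' (inclusive, so a single maximally-supported source at the 0.9 cap
#' qualifies), and keeps curated literature edges unconditionally unless
#' `strict = TRUE`.  Unordered duplicates are collapsed to the maximum
#' combined score.
#'
#' @param edges a [scored_interactions()] table (or coercible data.frame).
#' @param threshold minimum combined score for scored edges.
#' @param strict if `TRUE`, curated edges are thresholded too (curated
#'   edges without a combined score are then dropped).
#' @return The filtered `scored_interactions` table.
#' @export
filter_interactions <- function(edges, threshold = 0.9, strict = FALSE) {
  if (!inherits(edges, "scored_interactions")) {
    edges <- scored_interactions(edges, recompute = FALSE)
  }
  assert_probability(threshold, "threshold")
  pass <- !is.na(edges$combined_score) & edges$combined_score >= threshold
  keep <- if (strict) pass else pass | edges$database == "curated"
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a scored edge-list TSV
#'
#' The on-disk format is a tab-separated table whose header line is
#' prefixed with `#`: columns `gene_a`, `gene_b`, `database`,
#' `combined_score`, plus optional per-source `score_*` columns.
#'
#' @param path file path.
#' @return `read_interactions()` returns a [scored_interactions()] table.
#' @export
read_interactions <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  df <- read.delim(path, skip = 1L, header = FALSE, col.names = cols,
                   stringsAsFactors = FALSE)
  scored_interactions(df, recompute = FALSE)
}

#' @rdname read_interactions
#' @param edges a `scored_interactions` table to write.
#' @export
write_interactions <- function(edges, path) {
  stopifnot(is.data.frame(edges))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(edges), collapse = "\t")), con)
  write.table(edges, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
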