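#' Create a gene set
#'
#' A `gene_set` is the unit of annotation and tissue-enrichment input: a
#' named, species-tagged collection of unique gene identifiers with
#' free-text provenance (source, year, selection criterion).  Identifiers
#' within one set live in a single namespace; mixed-species collections
#' must be reconciled with [map_orthologs()] before set algebra.
#'
#' @param genes character vector of gene identifiers; duplicates are
#'   collapsed and the result is stored sorted for determinism.
#' @param name short label for the set.
#' @param species `"human"` or `"mouse"`.
#' @param provenance free-text description of where the set came from.
#' @return An object of class `gene_set`.
#' @examples
#' gene_set(c("ACTN4", "SYNPO", "MYO1E"), name = "podocyte_actin")
#' @export
gene_set <- function(genes = character(), name = "gene_set",
                     species = c("human", "mouse"),
                     provenance = NA_character_) {
  species <- match.arg(species)
  genes <- as.character(genes)
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop("gene identifiers must be non-empty strings", call. = FALSE)
  }
  structure(
    list(name = name, species = species,
         genes = sort(unique(genes)), provenance = provenance),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s]: %d genes\n", x$name, x$species,
              length(x$genes)))
  if (length(x$genes)) {
    shown <- utils::head(x$genes, 6L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$genes) > 6L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

as_gene_vector <- function(x) {
  if (inherits(x, "gene_set")) x$genes else sort(unique(as.character(x)))
}

#' Union of gene sets
#'
#' Exact set-theoretic union of same-species gene sets, as used to merge
#' the three cytoskeleton annotation term lists and the nine
#' glomerulus-enriched expression datasets.  Which input sets contributed
#' each gene is recorded in the `"membership"` attribute.
#'
#' @param sets list of [gene_set()] objects sharing one species.
#' @param name name for the result.
#' @return A `gene_set`; attribute `"membership"` is a data.frame with
#'   columns `gene` and `set`.
#' @export
union_gene_sets <- function(sets, name = "union") {
  stopifnot(is.list(sets), all(vapply(sets, inherits, logical(1), "gene_set")))
  if (!length(sets)) return(gene_set(name = name))
  species <- unique(vapply(sets, `[[`, character(1), "species"))
  if (length(species) > 1L) {
    stop("gene sets mix species (", paste(species, collapse = ", "),
         "); run map_orthologs() first", call. = FALSE)
  }
  membership <- do.call(rbind, lapply(sets, function(s) {
    if (!length(s$genes)) return(NULL)
    data.frame(gene = s$genes, set = s$name, stringsAsFactors = FALSE)
  }))
  out <- gene_set(unlist(lapply(sets, `[[`, "genes"), use.names = FALSE),
                  name = name, species = species,
                  provenance = paste("union of",
                                     paste(vapply(sets, `[[`, character(1),
                                                  "name"), collapse = " + ")))
  attr(out, "membership") <- membership
  out
}

#' Create an ortholog map
#'
#' Pairs of (source identifier, target identifier), e.g. mouse symbols to
#' human symbols.  A source identifier may map to several targets; the
#' keep-all versus drop-ambiguous policy is chosen in [map_orthologs()].
#'
#' @param source,target equal-length character vectors of identifiers.
#' @param source_species,target_species species tags of the two columns.
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(source = character(), target = character(),
                         source_species = "mouse",
                         target_species = "human") {
  stopifnot(length(source) == length(target))
  pairs <- unique(data.frame(source = as.character(source),
                             target = as.character(target),
                             stringsAsFactors = FALSE))
  if (nrow(pairs) && (anyNA(pairs) || any(!nzchar(pairs$source)) ||
                      any(!nzchar(pairs$target)))) {
    stop("ortholog identifiers must be non-empty strings", call. = FALSE)
  }
  structure(list(pairs = pairs, source_species = source_species,
                 target_species = target_species),
            class = "ortholog_map")
}

#' Map a gene set to another species
#'
#' Translates every identifier through the ortholog map.  Unmapped inputs
#' are dropped and tallied; one-to-many sources either expand to all
#' targets (default, `ambiguous = "keep_all"`) or are dropped entirely.
#'
#' @param set a [gene_set()] whose species matches `map$source_species`.
#' @param map an [ortholog_map()].
#' @param ambiguous policy for sources with several targets.
#' @return A `gene_set` in the target species.  Attributes `"n_unmapped"`
#'   and `"unmapped"` report inputs without any ortholog; with
#'   `ambiguous = "drop"`, `"n_ambiguous"` counts dropped multi-target
#'   sources.
#' @export
map_orthologs <- function(set, map, ambiguous = c("keep_all", "drop")) {
  stopifnot(inherits(set, "gene_set"), inherits(map, "ortholog_map"))
  ambiguous <- match.arg(ambiguous)
  if (set$species != map$source_species) {
    stop(sprintf("set species '%s' does not match map source species '%s'",
                 set$species, map$source_species), call. = FALSE)
  }
  pairs <- map$pairs[map$pairs$source %in% set$genes, , drop = FALSE]
  n_amb <- 0L
  if (ambiguous == "drop" && nrow(pairs)) {
    multi <- names(which(table(pairs$source) > 1L))
    n_amb <- length(multi)
    pairs <- pairs[!pairs$source %in% multi, , drop = FALSE]
  }
  unmapped <- setdiff(set$genes, map$pairs$source)
  out <- gene_set(pairs$target, name = set$name,
                  species = map$target_species,
                  provenance = paste0(set$provenance %||% "",
                                      " [ortholog-mapped from ",
                                      set$species, "]"))
  attr(out, "n_unmapped") <- length(unmapped)
  attr(out, "unmapped") <- unmapped
  if (ambiguous == "drop") attr(out, "n_ambiguous") <- n_amb
  out
}

#' Overlap report between two gene sets
#'
#' Exact intersection counts with display proportions, the shape used to
#' report what fraction of each glomerulus-enriched dataset carries a
#' cytoskeleton annotation, and to compare the tissue-restricted gene
#' list with neuronal and muscle gene lists.
#'
#' @param a,b [gene_set()] objects in the same namespace.
#' @return A one-row data.frame of class `overlap_report` with columns
#'   `set_a`, `set_b`, `n_a`, `n_b`, `n_intersect`, `prop_of_a`,
#'   `prop_of_b`, and the display percentages `pct_of_a` / `pct_of_b`
#'   rounded half-up to two decimals.
#' @export
overlap_report <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  if (a$species != b$species) {
    stop("overlap requires one namespace; map orthologs first", call. = FALSE)
  }
  n_int <- length(intersect(a$genes, b$genes))
  prop_a <- if (length(a$genes)) n_int / length(a$genes) else NA_real_
  prop_b <- if (length(b$genes)) n_int / length(b$genes) else NA_real_
  structure(
    data.frame(set_a = a$name, set_b = b$name,
               n_a = length(a$genes), n_b = length(b$genes),
               n_intersect = n_int,
               prop_of_a = prop_a, prop_of_b = prop_b,
               pct_of_a = round_half_up(100 * prop_a, 2),
               pct_of_b = round_half_up(100 * prop_b, 2),
               stringsAsFactors = FALSE),
    class = c("overlap_report", "data.frame")
  )
}

#' Intersect two gene sets into a tissue-restricted universe
#'
#' The intersection of the annotation universe (cytoskeleton genes) with
#' the tissue-enrichment union defines the node universe of the
#' restricted interaction network.
#'
#' @param cytoskeleton,enriched [gene_set()] objects in the same namespace.
#' @param name name for the result.
#' @return A `gene_set` holding the exact intersection.
#' @export
intersect_universe <- function(cytoskeleton, enriched, name = "intersection") {
  stopifnot(inherits(cytoskeleton, "gene_set"), inherits(enriched, "gene_set"))
  if (cytoskeleton$species != enriched$species) {
    stop("intersection requires one namespace; map orthologs first",
         call. = FALSE)
  }
  gene_set(intersect(cytoskeleton$genes, enriched$genes), name = name,
           species = cytoskeleton$species,
           provenance = paste(cytoskeleton$name, "∩", enriched$name))
}
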