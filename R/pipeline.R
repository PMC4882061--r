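#' Pipeline configuration
#'
#' One object that drives the whole analysis end-to-end, either in
#' synthetic mode (everything generated with planted ground truth) or in
#' file mode (inputs read from disk).
#'
#' File-mode `paths` is a list with entries:
#' * `annotation_sets`: character vector of gene-list TSVs (column
#'   `gene`) forming the annotation universe;
#' * `enrichment_sets`: named character vector of gene-list TSVs; names
#'   ending in `".mouse"` mark mouse-identifier sets;
#' * `ortholog_map`: TSV with columns `source`, `target` (needed when any
#'   enrichment set is mouse);
#' * `interactions`: scored edge-list TSV (see [read_interactions()]);
#' * `disease_tables`: manifest TSV with columns `disease`, `path`;
#' * optional `disease_genes` (see [read_disease_gene_map()]) and
#'   `similarity` (see [read_phenotype_similarity()]).
#'
#' @param synthetic a [synthetic_config()], or `NULL` for file mode.
#' @param paths file-mode input paths (see Details).
#' @param p_threshold DE p-value cutoff (default 0.05).
#' @param score_threshold combined-score threshold (default 0.9).
#' @param per_source_cap per-channel score cap (default 0.9).
#' @param prior prior for score combination (default 0).
#' @param bridge_policy `"common_neighbors"` or `"steiner_greedy"`.
#' @param top_n top-N call threshold for prioritization (default 1000).
#' @param seed seed for the permutation null and synthetic generation.
#' @param out_dir optional output directory for intermediate TSVs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            p_threshold = 0.05, score_threshold = 0.9,
                            per_source_cap = 0.9, prior = 0,
                            bridge_policy = c("common_neighbors",
                                              "steiner_greedy"),
                            top_n = 1000L, seed = 1L, out_dir = NULL) {
  if (is.null(synthetic) && is.null(paths)) {
    stop("provide either a synthetic config or input paths", call. = FALSE)
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(
    synthetic = synthetic, paths = paths,
    p_threshold = assert_probability(p_threshold, "p_threshold"),
    score_threshold = assert_probability(score_threshold, "score_threshold"),
    per_source_cap = assert_probability(per_source_cap, "per_source_cap"),
    prior = assert_probability(prior, "prior"),
    bridge_policy = match.arg(bridge_policy),
    top_n = assert_count(top_n, "top_n", min = 1L),
    seed = assert_count(seed, "seed"),
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Schema checks on every configured input: file existence, mandatory
#' columns, p-values in [0, 1], nonzero fold changes, duplicate gene
#' rows (warning — collapsed deterministically to the minimum p-value at
#' load time), similarity-matrix shape.  Issues are returned rather than
#' thrown, each tagged `"fatal"` or `"warning"`.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns `input`, `severity`, `message`;
#'   zero rows when everything checks out.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- list()
  note <- function(input, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      input = input, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  if (!is.null(config$synthetic)) {
    # synthetic_config() already validated on construction
    return(data.frame(input = character(), severity = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  p <- config$paths
  check_exists <- function(path, input) {
    ok <- is.character(path) && length(path) == 1L && file.exists(path)
    if (!ok) note(input, "fatal", sprintf("file not found: %s", path))
    ok
  }
  for (nm in c("annotation_sets", "enrichment_sets")) {
    for (f in p[[nm]]) {
      if (check_exists(f, nm)) {
        df <- try(read.delim(f, stringsAsFactors = FALSE), silent = TRUE)
        if (inherits(df, "try-error") || !"gene" %in% names(df)) {
          note(nm, "fatal", sprintf("%s: needs a 'gene' column", f))
        }
      }
    }
  }
  if (!is.null(p$interactions) && check_exists(p$interactions,
                                               "interactions")) {
    e <- try(read_interactions(p$interactions), silent = TRUE)
    if (inherits(e, "try-error")) {
      note("interactions", "fatal", attr(e, "condition")$message)
    }
  }
  if (!is.null(p$disease_tables) && check_exists(p$disease_tables,
                                                 "disease_tables")) {
    man <- read.delim(p$disease_tables, stringsAsFactors = FALSE)
    if (!all(c("disease", "path") %in% names(man))) {
      note("disease_tables", "fatal",
           "manifest needs 'disease' and 'path' columns")
    } else {
      for (i in seq_len(nrow(man))) {
        f <- man$path[i]
        if (!check_exists(f, "disease_tables")) next
        raw <- read.delim(f, stringsAsFactors = FALSE)
        t <- withCallingHandlers(
          try(disease_table(raw, man$disease[i]), silent = TRUE),
          warning = function(w) {
            note("disease_tables", "warning",
                 sprintf("%s: %s", f, conditionMessage(w)))
            invokeRestart("muffleWarning")
          })
        if (inherits(t, "try-error")) {
          note("disease_tables", "fatal",
               sprintf("%s: %s", f, attr(t, "condition")$message))
        }
      }
    }
  }
  if (!is.null(p$similarity) && check_exists(p$similarity, "similarity")) {
    s <- try(read_phenotype_similarity(p$similarity), silent = TRUE)
    if (inherits(s, "try-error")) {
      note("similarity", "fatal", attr(s, "condition")$message)
    }
  }
  if (!is.null(p$disease_genes) && check_exists(p$disease_genes,
                                                "disease_genes")) {
    d <- try(read_disease_gene_map(p$disease_genes), silent = TRUE)
    if (inherits(d, "try-error")) {
      note("disease_genes", "fatal", attr(d, "condition")$message)
    }
  }
  if (!length(issues)) {
    return(data.frame(input = character(), severity = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

read_gene_list <- function(path, name, species = "human") {
  gene_set(read.delim(path, stringsAsFactors = FALSE)$gene,
           name = name, species = species, provenance = path)
}

load_file_inputs <- function(paths) {
  ann_sets <- lapply(seq_along(paths$annotation_sets), function(i)
    read_gene_list(paths$annotation_sets[i], sprintf("annotation_%d", i)))
  enr_names <- names(paths$enrichment_sets) %||%
    sprintf("enriched_%02d", seq_along(paths$enrichment_sets))
  enr_sets <- lapply(seq_along(paths$enrichment_sets), function(i) {
    mouse <- grepl("\\.mouse$", enr_names[i])
    read_gene_list(paths$enrichment_sets[i],
                   sub("\\.mouse$", "", enr_names[i]),
                   species = if (mouse) "mouse" else "human")
  })
  omap <- if (!is.null(paths$ortholog_map)) {
    df <- read.delim(paths$ortholog_map, stringsAsFactors = FALSE)
    ortholog_map(df$source, df$target)
  }
  edges <- read_interactions(paths$interactions)
  man <- read.delim(paths$disease_tables, stringsAsFactors = FALSE)
  tables <- setNames(lapply(seq_len(nrow(man)), function(i)
    read_disease_table(man$path[i], man$disease[i])), man$disease)
  list(annotation_sets = ann_sets, enrichment_sets = enr_sets,
       ortholog_map = omap, edges = edges, disease_tables = tables,
       disease_gene_map = if (!is.null(paths$disease_genes))
         read_disease_gene_map(paths$disease_genes),
       similarity = if (!is.null(paths$similarity))
         read_phenotype_similarity(paths$similarity))
}

#' Run the whole analysis pipeline
#'
#' Executes every stage in order: gene-set assembly (ortholog mapping,
#' enrichment union, annotation union, intersection into the restricted
#' node universe), interactome integration (score filtering, induced
#' networks, topology), cross-disease consistency classification and
#' candidate selection, bridged-subnetwork reconstruction (candidates
#' among themselves and against known disease genes), and
#' phenotype-concordance prioritization with top-N calls.  In synthetic
#' mode the run is reproducible end-to-end from the seed.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `run_report` with elements `network_summary`,
#'   `consistency`, `candidates`, `subnetwork` (+ `linkage` when disease
#'   genes are supplied), `prioritization` (+ `top_n_counts`),
#'   `assembly` (gene-set sizes and overlap), `provenance` (seed, config
#'   hash, timestamp), and — in synthetic mode — the generated `study`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- validate_inputs(config)
  if (any(issues$severity == "fatal")) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s", issues$input, issues$message),
               collapse = "\n"), call. = FALSE)
  }
  if (!is.null(config$synthetic)) {
    study <- generate_synthetic_study(config$synthetic,
                                      score_threshold =
                                        config$score_threshold)
    ann_sets <- list(study$annotation_set)
    enr_sets <- study$enrichment_sets
    omap <- study$ortholog_map
    edges <- study$edges
    tables <- study$disease_tables
    dgm <- study$disease_gene_map
    similarity <- study$similarity
  } else {
    inp <- load_file_inputs(config$paths)
    study <- NULL
    ann_sets <- inp$annotation_sets
    enr_sets <- inp$enrichment_sets
    omap <- inp$ortholog_map
    edges <- inp$edges
    tables <- inp$disease_tables
    dgm <- inp$disease_gene_map
    similarity <- inp$similarity
  }

  # --- gene-set assembly -------------------------------------------------
  enr_human <- lapply(enr_sets, function(s) {
    if (s$species == "mouse") {
      if (is.null(omap)) stop("mouse enrichment set but no ortholog map",
                              call. = FALSE)
      map_orthologs(s, omap)
    } else s
  })
  annotation <- union_gene_sets(ann_sets, name = "annotation")
  enriched <- union_gene_sets(enr_human, name = "enriched")
  core <- intersect_universe(annotation, enriched, name = "node_universe")
  assembly <- list(
    n_annotation = length(annotation$genes),
    n_enriched = length(enriched$genes),
    n_core = length(core$genes),
    overlap = overlap_report(annotation, enriched)
  )

  # --- interactome -------------------------------------------------------
  filtered <- filter_interactions(edges, threshold = config$score_threshold)
  all_genes <- union(union(unique(c(filtered$gene_a, filtered$gene_b)),
                           core$genes), annotation$genes)
  background <- induce_network(gene_set(all_genes, name = "integrated"),
                               filtered)
  network <- induce_network(core, filtered)
  summary <- summarize_network(network)

  # --- disease consistency ----------------------------------------------
  consistency <- build_consistency_table(network, tables,
                                         p_threshold = config$p_threshold)
  candidates <- select_candidates(network, tables,
                                  p_threshold = config$p_threshold)

  # --- subnetworks -------------------------------------------------------
  seed_roles <- setNames(
    c(rep("seed_up", length(candidates$up$genes)),
      rep("seed_down", length(candidates$down$genes))),
    c(candidates$up$genes, candidates$down$genes))
  subnetwork <- build_bridged_subnetwork(candidates$all, background,
                                         policy = config$bridge_policy,
                                         seed_roles = seed_roles)
  linkage <- if (!is.null(dgm)) {
    link_to_disease_genes(candidates$all, dgm, background,
                          policy = config$bridge_policy)
  }

  # --- prioritization ----------------------------------------------------
  prioritization <- NULL
  top_n_counts <- NULL
  if (!is.null(similarity) && !is.null(dgm) &&
      nrow(similarity) >= 3L) {
    scores <- cipher_score(background, similarity, dgm)
    prioritization <- rank_and_call(scores, n = config$top_n)
    top_n_counts <- tapply(prioritization$predicted,
                           prioritization$phenotype, sum)
  } else if (!is.null(dgm)) {
    message("prioritization skipped: no similarity matrix ",
            "(or fewer than 3 phenotypes)")
  }

  report <- structure(list(
    assembly = assembly,
    network = network,
    background_network = background,
    network_summary = summary,
    consistency = consistency,
    candidates = candidates,
    subnetwork = subnetwork,
    linkage = linkage,
    prioritization = prioritization,
    top_n_counts = top_n_counts,
    study = study,
    provenance = list(
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  node universe: %d genes (annotation %d ∩ enriched %d)\n",
              x$assembly$n_core, x$assembly$n_annotation,
              x$assembly$n_enriched))
  print(x$network_summary)
  all5 <- x$consistency$strata[nrow(x$consistency$strata), ]
  cat(sprintf("  all-disease stratum: %d up / %d down / %d inconsistent (total %d)\n",
              all5$up, all5$down, all5$inconsistent, all5$total))
  cat(sprintf("  candidates: %d (%d up, %d down)\n",
              length(x$candidates$all$genes), length(x$candidates$up$genes),
              length(x$candidates$down$genes)))
  cat(sprintf("  bridged subnetwork: %d nodes, %d edges (%s policy)\n",
              igraph::vcount(x$subnetwork$graph),
              igraph::ecount(x$subnetwork$graph), x$subnetwork$policy))
  if (!is.null(x$top_n_counts)) {
    cat("  predicted per phenotype:",
        paste(names(x$top_n_counts), x$top_n_counts, sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write the report's intermediate tables to a directory
#'
#' @param report a `run_report`.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  export_network(report$network, file.path(dir, "restricted_network"))
  write.table(report$consistency$strata,
              file.path(dir, "consistency_strata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$consistency$per_disease,
              file.path(dir, "per_disease_de.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- report$consistency$profiles
  write.table(cand[cand$candidate, , drop = FALSE],
              file.path(dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$prioritization)) {
    write.table(report$prioritization,
                file.path(dir, "prioritization.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(sprintf("seed: %s\nconfig_hash: %s\ntimestamp: %s",
                     report$provenance$seed, report$provenance$config_hash,
                     report$provenance$timestamp),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
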