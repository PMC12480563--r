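## End-to-end orchestration: configuration, per-tree classification with
## skip-and-log error policy, report writing and the run manifest.

#' Build a pipeline run configuration
#'
#' @param trees Directory of newick files (or character vector of paths),
#'   one tree per orthogroup; file basenames become orthogroup ids.
#' @param taxonomy Path to the taxonomy map TSV.
#' @param out_dir Output directory for reports (created if needed).
#' @param og_table,contig_lengths Optional paths to an orthogroup membership
#'   table and a gene-to-contig length table.
#' @param params A `walk_params`.
#' @param on_missing Passed to [annotate_tree()]; default
#'   `"outgroup_unknown"` tolerates leaves absent from the map, as expected
#'   for corpus-scale inputs.
#' @param min_trees_enrichment Minimum usable trees per lineage for the
#'   enrichment test.
#' @return An object of class `run_config`.
#' @export
run_config <- function(trees, taxonomy, out_dir,
                       og_table = NULL, contig_lengths = NULL,
                       params = walk_params(),
                       on_missing = c("outgroup_unknown", "error", "drop"),
                       min_trees_enrichment = 2L) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(params, "walk_params"))
  if (length(trees) == 1L && !dir.exists(trees) && !file.exists(trees))
    stop("trees path does not exist: ", trees)
  if (!file.exists(taxonomy)) stop("taxonomy map not found: ", taxonomy)
  for (p in c(og_table, contig_lengths))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  structure(list(trees = trees, taxonomy = taxonomy, out_dir = out_dir,
                 og_table = og_table, contig_lengths = contig_lengths,
                 params = params, on_missing = on_missing,
                 min_trees_enrichment = as.integer(min_trees_enrichment)),
            class = "run_config")
}

#' Run the full HGT-detection pipeline
#'
#' Executes annotate, root, collapse, walk, direction, event aggregation and
#' enrichment over a corpus of gene trees, and writes four tab-separated
#' reports (`classifications.tsv`, `events.tsv`, `enrichment.tsv`,
#' `summary.tsv`) plus a machine-readable `manifest.txt` (parameters, input
#' checksums, per-category counts, skip counts). Trees failing parsing or
#' annotation are logged to stderr, skipped and counted in the manifest.
#' Re-running on identical inputs yields byte-identical reports; only the
#' manifest's timestamp line differs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `calls`, `events`, `enrichment`,
#'   `summary`, `manifest` and `scans`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  map <- load_taxonomy_map(config$taxonomy)
  paths <- config$trees
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.(nwk|newick|tre|tree)$",
                             full.names = TRUE))
  if (!length(paths)) stop("no tree files found under ", config$trees)

  annotated <- list()
  skipped <- character(0)
  for (p in paths) {
    og <- sub("\\.[^.]*$", "", basename(p))
    at <- tryCatch({
      tr <- parse_gene_tree(paste(readLines(p, warn = FALSE), collapse = ""))
      suppressWarnings(annotate_tree(tr, map, og_id = og,
                                     on_missing = config$on_missing))
    }, error = function(e) {
      message(sprintf("[hgtscan] skipping %s: %s", og, conditionMessage(e)))
      NULL
    })
    if (is.null(at)) { skipped <- c(skipped, og); next }
    annotated[[og]] <- at
  }
  if (!length(annotated)) stop("zero parseable trees; nothing to do")

  scan <- classify_corpus(annotated, config$params)
  no_query <- scan$per_tree$og_id[is.na(scan$per_tree$category)]

  enr <- tryCatch(
    lineage_enrichment(scan$events, scan$trees,
                       min_trees = config$min_trees_enrichment),
    error = function(e) {
      message("[hgtscan] enrichment not computed: ", conditionMessage(e))
      NULL
    })

  cat_counts <- table(factor(scan$calls$category, levels = .CATEGORIES))
  summary_df <- data.frame(category = names(cat_counts),
                           n_queries = as.integer(cat_counts),
                           stringsAsFactors = FALSE)

  ev_out <- scan$events
  ev_out$stop_clade_leaves <- vapply(ev_out$clade_leaves, paste,
                                     character(1), collapse = ",")
  ev_out$clade_leaves <- NULL

  .write_report(scan$calls, file.path(config$out_dir, "classifications.tsv"))
  .write_report(ev_out, file.path(config$out_dir, "events.tsv"))
  if (!is.null(enr))
    .write_report(as.data.frame(enr), file.path(config$out_dir, "enrichment.tsv"))
  .write_report(summary_df, file.path(config$out_dir, "summary.tsv"))

  manifest <- c(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    hgtscan_version = as.character(utils::packageVersion("hgtscan")),
    taxonomy_md5 = unname(tools::md5sum(config$taxonomy)),
    n_tree_files = length(paths),
    n_trees_classified = length(annotated) - length(no_query),
    n_trees_skipped = length(skipped),
    n_trees_no_query = length(no_query),
    skipped_og_ids = paste(skipped, collapse = ","),
    n_queries_processed = nrow(scan$calls),
    n_events = nrow(scan$events),
    n_hgt_genes = sum(scan$events$n_genes),
    support_threshold = config$params$support_threshold,
    min_sisters = config$params$min_sisters,
    min_outgroup_per_lineage = config$params$min_outgroup_per_lineage,
    rooting_strategy = config$params$rooting_strategy,
    strict_greater = config$params$strict_greater,
    single_lineage_rule = config$params$single_lineage_rule,
    event_key = config$params$event_key,
    stats::setNames(as.integer(cat_counts), paste0("n_", names(cat_counts))))
  writeLines(paste(names(manifest), unname(manifest), sep = "\t"),
             file.path(config$out_dir, "manifest.txt"))

  invisible(list(calls = scan$calls, events = scan$events, enrichment = enr,
                 summary = summary_df, manifest = manifest, scans = scan))
}

.write_report <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
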