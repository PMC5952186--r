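# Report writers share one deterministic TSV dialect: tab-separated, no
# quoting, fixed numeric formats (avg_sp-like columns to 6 decimal places,
# p-values/proportions to 6 significant digits) so re-runs are byte-identical.

format_report_column <- function(x, name) {
  if (name %in% c("avg_sp", "avg_sp_diseases", "avg_sp_symptoms",
                  "mean_avg_sp")) {
    return(ifelse(is.na(x), "NA", sprintf("%.6f", x)))
  }
  if (name %in% c("p_value", "p_adjusted", "proportion")) {
    return(ifelse(is.na(x), "NA", sprintf("%.6g", x)))
  }
  if (is.logical(x)) return(ifelse(x, "TRUE", "FALSE"))
  as.character(x)
}

write_report_tsv <- function(df, path) {
  out <- df
  for (nm in names(out)) out[[nm]] <- format_report_column(out[[nm]], nm)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write and read enrichment / path-summary reports
#'
#' TSV mirrors of the pipeline's two central tables: the module-enrichment
#' report (one row per module x seed group: overlap `k`, `p_value`, fold
#' `proportion`, `positive`) and the shortest-path report (one row per
#' target x group: `min_sp`, `max_sp`, `avg_sp` to 6 decimal places,
#' reachability counts). The readers invert the writers; numeric values
#' round-trip to the printed precision.
#'
#' @param records data frame of enrichment records or path summaries/calls.
#' @param path TSV file.
#' @return the path (writers) or the data frame (readers), invisibly for
#'   writers.
#' @export
write_enrichment_report <- function(records, path) {
  if (inherits(records, "enrichment_result")) records <- records$records
  write_report_tsv(records, path)
}

#' @rdname write_enrichment_report
#' @export
read_enrichment_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_enrichment_report
#' @export
write_path_report <- function(records, path) {
  write_report_tsv(as.data.frame(records), path)
}

#' @rdname write_enrichment_report
#' @export
read_path_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

pipeline_defaults <- function() {
  list(
    format = "tsv", alpha = 0.05, threshold = 3, method = "greedy-modularity",
    seed = 1L, min_size = 3L, selection_rule = "top_n", selection_param = 2L,
    correction = "none", skip_bad_lines = FALSE
  )
}

#' Run the full network-pharmacology pipeline
#'
#' Chains every stage: read the PPI network, phenotype seed sets and
#' herb-ingredient-target table; detect topological modules; Fisher-enrich
#' every seed group (phenotype sets, per-herb sets, aggregates) against every
#' module; select key modules by positivity count; compute shortest-path
#' summaries of every herb target against the key-module gene sets and the
#' aggregate disease/symptom groups; intersect the key calls into candidate
#' targets; and, when a GMT collection is configured, count per-pathway
#' module-gene and key-protein overlaps for each key module. All reports are
#' written as deterministic TSVs plus a YAML run manifest; re-running with
#' the same configuration and seed reproduces byte-identical files.
#'
#' @param config path to a YAML file or a named list. Required keys:
#'   `network`, `seed_sets`, `herb_table`. Optional: `gmt`, `format`
#'   (`"tsv"`/`"sif"`), `alpha` (0.05), `threshold` (3), `method`
#'   (`"greedy-modularity"`), `seed` (1), `min_size` (3), `selection_rule`
#'   (`"top_n"`), `selection_param` (2), `correction` (`"none"`),
#'   `skip_bad_lines` (FALSE), `out_dir`.
#' @param out_dir output directory (overrides `config$out_dir`); created if
#'   needed.
#' @return invisibly, the report bundle: list with `network`, `seeds`,
#'   `herb_records`, `partition`, `enrichment`, `selection`, `calls`,
#'   `candidates`, `pathway_overlap` (or `NULL`), `manifest`, `files`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults(), config)
  for (key in c("network", "seed_sets", "herb_table")) {
    if (is.null(cfg[[key]])) {
      stop("pipeline config is missing '", key, "'", call. = FALSE)
    }
  }
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  network <- stage("read", read_network(cfg$network, format = cfg$format,
                                        skip_bad_lines = cfg$skip_bad_lines))
  seeds <- stage("read", read_seed_sets(cfg$seed_sets, network))
  herb_records <- stage("read", read_herb_table(cfg$herb_table))
  herb_sets <- stage("read", herb_seed_sets(herb_records, network))
  annotations <- if (!is.null(cfg$gmt)) stage("read", read_gmt(cfg$gmt))

  partition <- stage("detect",
    detect_modules(network, method = cfg$method, seed = cfg$seed,
                   min_size = cfg$min_size))

  # herb-table sets take their place beside the phenotype sets; if the seed
  # TSV also carried herb-category rows, the phenotype file wins on a clash
  extra <- setdiff(names(herb_sets$sets), names(seeds$sets))
  groups <- seed_collection(c(seeds$sets, herb_sets$sets[extra]))
  enrichment <- stage("enrich",
    enrich_all(partition, groups, alpha = cfg$alpha,
               correction = cfg$correction))
  selection <- stage("prioritize",
    select_key_modules(enrichment, rule = cfg$selection_rule,
                       param = cfg$selection_param))

  targets <- sort(unique(herb_records$target))
  path_groups <- lapply(selection$selected, function(lab) {
    seed_set(lab, "module", module_genes(partition, lab))
  })
  for (nm in c("Diseases", "Symptoms")) {
    if (!is.null(seeds$sets[[nm]])) {
      path_groups <- c(path_groups, list(seeds$sets[[nm]]))
    }
  }
  calls <- stage("paths",
    call_key_targets(network, targets, path_groups, threshold = cfg$threshold))
  candidates <- stage("prioritize", intersect_key_targets(calls, selection))

  pathway_overlap <- NULL
  if (!is.null(annotations)) {
    pathway_overlap <- do.call(rbind, lapply(selection$selected, function(lab) {
      keys <- unique(calls$source[calls$group_name == lab & calls$is_key])
      cbind(module_label = lab,
            pathway_key_overlap(annotations, module_genes(partition, lab),
                                keys))
    }))
  }

  files <- c(
    partition = file.path(out_dir, "partition.tsv"),
    partition_summary = file.path(out_dir, "partition_summary.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv"),
    positivity = file.path(out_dir, "positivity.tsv"),
    path_summaries = file.path(out_dir, "path_summaries.tsv"),
    candidates = file.path(out_dir, "candidates.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_partition(partition, files[["partition"]])
  partition_summary(partition, files[["partition_summary"]])
  write_enrichment_report(enrichment, files[["enrichment"]])
  write_report_tsv(enrichment$positivity, files[["positivity"]])
  write_path_report(calls, files[["path_summaries"]])
  write_report_tsv(as.data.frame(candidates), files[["candidates"]])
  if (!is.null(pathway_overlap)) {
    files <- c(files, pathway_overlap = file.path(out_dir, "pathway_overlap.tsv"))
    write_report_tsv(pathway_overlap, files[["pathway_overlap"]])
  }

  manifest <- list(
    package = list(name = "netpharm",
                   version = as.character(utils::packageVersion("netpharm"))),
    inputs = list(network = cfg$network, seed_sets = cfg$seed_sets,
                  herb_table = cfg$herb_table,
                  gmt = if (is.null(cfg$gmt)) NA else cfg$gmt),
    parameters = cfg[c("format", "alpha", "threshold", "method", "seed",
                       "min_size", "selection_rule", "selection_param",
                       "correction")],
    network_report = network$report,
    seed_set_log = if (!is.null(seeds$log)) {
      lapply(seq_len(nrow(seeds$log)), function(i) as.list(seeds$log[i, ]))
    },
    herb_duplicates_collapsed = attr(herb_records, "n_duplicates"),
    targets_dropped = as.list(attr(calls, "dropped_targets")),
    n_modules = length(partition$labels),
    modularity = partition$modularity_score,
    selected_modules = as.list(selection$selected),
    n_candidates = nrow(candidates)
  )
  yaml::write_yaml(manifest, files[["manifest"]])

  invisible(list(
    network = network, seeds = seeds, herb_records = herb_records,
    partition = partition, enrichment = enrichment, selection = selection,
    calls = calls, candidates = candidates,
    pathway_overlap = pathway_overlap, manifest = manifest, files = files
  ))
}
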