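#' Select key modules from positivity counts
#'
#' Ranks modules by the number of seed gene groups significantly enriched in
#' them and selects either the `param` top-ranked modules (`rule = "top_n"`)
#' or all modules with at least `param` positive results
#' (`rule = "min_positive"`). Ordering is deterministic: decreasing
#' `n_positive`, ties by module number.
#'
#' @param counts a data frame (`module_label`, `n_positive`) or an
#'   `enrichment_result` (its `$positivity` is used).
#' @param rule `"top_n"` (default) or `"min_positive"`.
#' @param param rank cutoff or minimum positivity count (default 2).
#' @return object of class `key_module_selection`: list with `selected`
#'   (ordered labels), `rule`, `param`, `table` (ordered positivity table).
#' @export
select_key_modules <- function(counts, rule = c("top_n", "min_positive"),
                               param = 2L) {
  rule <- match.arg(rule)
  stopifnot(param >= 1L)
  if (inherits(counts, "enrichment_result")) counts <- counts$positivity
  stopifnot(is.data.frame(counts),
            all(c("module_label", "n_positive") %in% names(counts)),
            nrow(counts) > 0L)
  num <- suppressWarnings(as.integer(sub("^M", "", counts$module_label)))
  ord <- order(-counts$n_positive,
               ifelse(is.na(num), .Machine$integer.max, num),
               counts$module_label)
  tab <- counts[ord, , drop = FALSE]
  rownames(tab) <- NULL
  selected <- switch(rule,
    top_n = utils::head(tab$module_label[tab$n_positive > 0L], param),
    min_positive = tab$module_label[tab$n_positive >= param]
  )
  if (length(selected) == 0L) {
    warning("no module qualifies under rule ", rule, "(", param, ")",
            call. = FALSE)
  }
  structure(list(selected = selected, rule = rule, param = as.integer(param),
                 table = tab),
            class = "key_module_selection")
}

#' @export
print.key_module_selection <- function(x, ...) {
  cat(sprintf("<key_module_selection> %s(%d): %s\n", x$rule, x$param,
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Intersect key-target calls across module and phenotype groups
#'
#' A protein is a candidate target when it is key (average shortest path
#' below threshold) simultaneously for at least one selected key module, for
#' the aggregate co-morbid disease group, and for the aggregate co-morbid
#' symptom group. Candidates are ranked by the mean of their supporting
#' `avg_sp` values, ascending (closer is stronger).
#'
#' @param calls a `key_target_calls` data frame (or any data frame with
#'   columns `source`, `group_name`, `group_category`, `avg_sp`, `is_key`);
#'   must contain rows for the `aggregate-diseases` and `aggregate-symptoms`
#'   groups.
#' @param selection a `key_module_selection`; its `selected` labels are
#'   matched against `group_name`.
#' @return object of class `candidate_targets`: data frame with one row per
#'   candidate (`gene`, `modules_hit`, `avg_sp_modules`, `avg_sp_diseases`,
#'   `avg_sp_symptoms`, `mean_avg_sp`), sorted by `mean_avg_sp`.
#' @export
intersect_key_targets <- function(calls, selection) {
  stopifnot(inherits(selection, "key_module_selection"), is.data.frame(calls))
  need <- c("source", "group_name", "group_category", "avg_sp", "is_key")
  stopifnot(all(need %in% names(calls)))
  if (!any(calls$group_category == "aggregate-diseases") ||
      !any(calls$group_category == "aggregate-symptoms")) {
    stop("calls must include the aggregate-diseases and aggregate-symptoms groups",
         call. = FALSE)
  }
  sel <- selection$selected
  rows <- list()
  for (src in unique(calls$source)) {
    cc <- calls[calls$source == src, , drop = FALSE]
    mod <- cc[cc$group_name %in% sel & cc$is_key, , drop = FALSE]
    dis <- cc[cc$group_category == "aggregate-diseases", , drop = FALSE]
    sym <- cc[cc$group_category == "aggregate-symptoms", , drop = FALSE]
    if (nrow(mod) == 0L || nrow(dis) == 0L || nrow(sym) == 0L) next
    if (!all(dis$is_key) || !all(sym$is_key)) next
    support <- c(mod$avg_sp, dis$avg_sp, sym$avg_sp)
    rows[[src]] <- data.frame(
      gene = src,
      modules_hit = paste(sort(mod$group_name), collapse = ";"),
      avg_sp_modules = paste(sprintf("%.6f", mod$avg_sp[order(mod$group_name)]),
                             collapse = ";"),
      avg_sp_diseases = dis$avg_sp[1L],
      avg_sp_symptoms = sym$avg_sp[1L],
      mean_avg_sp = mean(support),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(gene = character(), modules_hit = character(),
               avg_sp_modules = character(), avg_sp_diseases = numeric(),
               avg_sp_symptoms = numeric(), mean_avg_sp = numeric(),
               stringsAsFactors = FALSE)
  out <- out[order(out$mean_avg_sp, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_targets", "data.frame")
  out
}

#' Per-pathway overlap with module genes and key proteins
#'
#' For each annotation set, counts the module genes it contains
#' (`n_pathway_gene`) and how many of those are also key drug targets
#' (`n_key_protein`); the latter never exceeds the former.
#'
#' @param annotations an `annotation_collection`.
#' @param module_genes character vector of one module's genes.
#' @param key_targets character vector of key drug target genes.
#' @return data frame (`set_name`, `n_pathway_gene`, `n_key_protein`), one
#'   row per annotation set in collection order.
#' @export
pathway_key_overlap <- function(annotations, module_genes, key_targets) {
  stopifnot(inherits(annotations, "annotation_collection"))
  module_genes <- unique(normalize_gene(module_genes))
  key_targets <- if (length(key_targets)) unique(normalize_gene(key_targets))
                 else character()
  n_path <- vapply(annotations$sets,
                   function(s) length(intersect(s, module_genes)), 0L)
  n_key <- vapply(annotations$sets, function(s) {
    length(intersect(intersect(s, module_genes), key_targets))
  }, 0L)
  data.frame(set_name = names(annotations$sets),
             n_pathway_gene = as.integer(n_path),
             n_key_protein = as.integer(n_key),
             stringsAsFactors = FALSE, row.names = NULL)
}
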