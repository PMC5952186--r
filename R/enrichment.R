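#' One-sided Fisher exact (hypergeometric tail) p-value
#'
#' Probability of observing at least `k` genes shared between a module of
#' `module_size` genes and a group of `group_size` genes when the group is
#' drawn uniformly from a universe of `universe_size` genes — the enrichment
#' tail of Fisher's exact test on the 2x2 table
#' `[[k, group-k], [module-k, rest]]`. Vectorized over all arguments.
#'
#' @param k overlap count(s).
#' @param module_size,group_size,universe_size 2x2 table margins.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' fisher_p(5, 5, 5, 10) # == 1 / choose(10, 5)
#' @export
fisher_p <- function(k, module_size, group_size, universe_size) {
  stopifnot(all(k >= 0), all(module_size >= 0), all(group_size >= 0),
            all(universe_size >= 1),
            all(module_size <= universe_size),
            all(group_size <= universe_size),
            all(k <= pmin(module_size, group_size)))
  stats::phyper(k - 1, group_size, universe_size - group_size, module_size,
                lower.tail = FALSE)
}

#' Fisher enrichment of one seed gene group in one module
#'
#' Tests whether the group over-represents the module's genes relative to
#' uniform placement in the universe. `proportion` is the fold enrichment
#' `(k / module_size) / (group_size / universe_size)`, reported as 0 when the
#' overlap is empty so the record stays total.
#'
#' @param module_genes character vector of the module's genes (subset of
#'   `universe`, non-empty).
#' @param group a [seed_set()] (a plain character vector is wrapped as an
#'   ad-hoc `annotation` set named `"query"`).
#' @param universe background gene universe (character vector, non-empty).
#' @param alpha positivity threshold on the raw p-value (default 0.05),
#'   strict: `positive` iff `p_value < alpha`.
#' @param module_label label stored in the record.
#' @return one-row data frame: `module_label`, `group_name`,
#'   `group_category`, `k`, `module_size`, `group_size`, `universe_size`,
#'   `p_value`, `proportion`, `positive`.
#' @export
fisher_enrichment <- function(module_genes, group, universe, alpha = 0.05,
                              module_label = NA_character_) {
  if (is.character(group)) group <- seed_set("query", "annotation", group)
  stopifnot(inherits(group, "seed_set"), alpha > 0, alpha < 1)
  universe <- unique(normalize_gene(universe))
  module_genes <- unique(normalize_gene(module_genes))
  if (length(module_genes) == 0L) stop("empty module gene set", call. = FALSE)
  if (!all(module_genes %in% universe)) {
    stop("module genes outside the universe", call. = FALSE)
  }
  if (!all(group$genes %in% universe)) {
    stop("group '", group$name, "' has genes outside the universe",
         call. = FALSE)
  }
  k <- length(intersect(module_genes, group$genes))
  m <- length(module_genes)
  g <- length(group$genes)
  n <- length(universe)
  p <- fisher_p(k, m, g, n)
  prop <- if (k > 0L) (k / m) / (g / n) else 0
  data.frame(
    module_label = module_label, group_name = group$name,
    group_category = group$category, k = k, module_size = m,
    group_size = g, universe_size = n, p_value = p, proportion = prop,
    positive = p < alpha, stringsAsFactors = FALSE
  )
}

#' Module enrichment of every seed gene group
#'
#' Scores each (module, group) pair with [fisher_enrichment()] and tallies
#' per-module positivity counts. The reserved `M0` pool of sub-threshold
#' modules is skipped. Records are ordered by module label and, within a
#' module, by increasing p-value.
#'
#' @param partition a `module_partition` from [detect_modules()].
#' @param groups a `seed_collection` or list of [seed_set()] objects; every
#'   group must lie inside the universe (readers filter to the network).
#' @param universe background gene universe; defaults to all genes of the
#'   partitioned network.
#' @param alpha positivity threshold (default 0.05).
#' @param correction `"none"` (default; the positivity rule is applied to raw
#'   p-values) or `"bh"` (Benjamini-Hochberg across all records; positivity
#'   then uses the adjusted values, kept in column `p_adjusted`).
#' @return object of class `enrichment_result`: list with `records` (data
#'   frame of enrichment records), `positivity` (data frame `module_label`,
#'   `n_positive`), `alpha`, `correction`.
#' @export
enrich_all <- function(partition, groups, universe = NULL, alpha = 0.05,
                       correction = c("none", "bh")) {
  stopifnot(inherits(partition, "module_partition"))
  correction <- match.arg(correction)
  groups <- as_seed_list(groups)
  if (is.null(universe)) universe <- names(partition$membership)
  universe <- unique(normalize_gene(universe))
  labels <- partition$labels
  if (length(labels) == 0L || length(groups) == 0L) {
    stop("no testable (module, group) pairs", call. = FALSE)
  }
  recs <- vector("list", length(labels) * length(groups))
  i <- 0L
  for (lab in labels) {
    mg <- module_genes(partition, lab)
    for (grp in groups) {
      i <- i + 1L
      recs[[i]] <- fisher_enrichment(mg, grp, universe, alpha = alpha,
                                     module_label = lab)
    }
  }
  records <- do.call(rbind, recs)
  if (correction == "bh") {
    records$p_adjusted <- stats::p.adjust(records$p_value, method = "BH")
    records$positive <- records$p_adjusted < alpha
  }
  ord <- order(match(records$module_label, labels), records$p_value,
               records$group_name)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  pos <- tapply(records$positive, factor(records$module_label, levels = labels),
                sum)
  positivity <- data.frame(module_label = labels,
                           n_positive = as.integer(pos),
                           stringsAsFactors = FALSE)
  structure(list(records = records, positivity = positivity,
                 alpha = alpha, correction = correction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d records over %d modules (alpha=%g, correction=%s)\n",
              nrow(x$records), nrow(x$positivity), x$alpha, x$correction))
  print(x$positivity)
  invisible(x)
}

#' Over-representation analysis against a GMT collection
#'
#' Generic replacement for platform-specific functional enrichment: tests a
#' query gene list against every annotation set with the same one-sided
#' Fisher machinery. Annotation sets are intersected with the universe
#' first; sets with no universe overlap are skipped and reported in the
#' `skipped` attribute.
#'
#' @param query non-empty character vector of genes, inside `universe`.
#' @param annotations an `annotation_collection` from [read_gmt()].
#' @param universe background gene universe.
#' @param alpha positivity threshold (default 0.05).
#' @return data frame of enrichment records (one per tested set, set name in
#'   `group_name`, `module_label = "query"`), ordered by increasing p-value;
#'   attribute `skipped` names sets without universe overlap.
#' @export
ora <- function(query, annotations, universe, alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_collection"))
  universe <- unique(normalize_gene(universe))
  query <- unique(normalize_gene(query))
  if (length(query) == 0L) stop("empty query gene set", call. = FALSE)
  if (!all(query %in% universe)) {
    stop("query genes outside the universe", call. = FALSE)
  }
  recs <- list()
  skipped <- character()
  for (nm in names(annotations$sets)) {
    genes <- intersect(annotations$sets[[nm]], universe)
    if (length(genes) == 0L) {
      skipped <- c(skipped, nm)
      next
    }
    grp <- seed_set(nm, "annotation", genes)
    recs[[nm]] <- fisher_enrichment(query, grp, universe, alpha = alpha,
                                    module_label = "query")
  }
  if (length(skipped)) {
    message("skipped ", length(skipped),
            " annotation set(s) with no universe overlap")
  }
  if (length(recs) == 0L) stop("no testable annotation set", call. = FALSE)
  out <- do.call(rbind, unname(recs))
  out <- out[order(out$p_value, out$group_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
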