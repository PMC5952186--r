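#' Normalize gene symbols
#'
#' Canonical form used throughout the pipeline: surrounding whitespace is
#' stripped and the symbol is upper-cased. Normalization is idempotent. No
#' alias or ortholog mapping is attempted; symbols are taken as curated.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_gene(c(" crh", "Nppa "))
#' @export
normalize_gene <- function(x) {
  if (!is.character(x)) stop("gene symbols must be character", call. = FALSE)
  out <- toupper(trimws(x))
  bad <- !nzchar(out) | is.na(out)
  if (any(bad)) {
    stop("empty or missing gene symbol at position(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  ws <- grepl("[[:space:]]", out)
  if (any(ws)) {
    stop("gene symbol contains internal whitespace: ",
         paste(utils::head(out[ws], 5), collapse = ", "), call. = FALSE)
  }
  out
}

#' Construct a seed gene set
#'
#' A named group of genes with a category tag: a curated `disease`, `symptom`
#' or `herb` set, one of the `aggregate-*` unions, a `module` gene group, or
#' an `annotation` (GMT) set.
#'
#' @param name label, unique within a run.
#' @param category one of `disease`, `symptom`, `herb`, `aggregate-diseases`,
#'   `aggregate-symptoms`, `aggregate-herbs`, `module`, `annotation`.
#' @param genes character vector of gene symbols (normalized on construction).
#' @return object of class `seed_set` with elements `name`, `category`,
#'   `genes` (sorted, unique).
#' @export
seed_set <- function(name, category, genes) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  category <- match.arg(category, SEED_CATEGORIES)
  genes <- sort(unique(normalize_gene(genes)))
  if (length(genes) == 0L) stop("seed set '", name, "' is empty", call. = FALSE)
  structure(list(name = name, category = category, genes = genes),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %s [%s]: %d genes\n", x$name, x$category,
              length(x$genes)))
  invisible(x)
}

# Coerce a list of seed_set objects into a named collection, checking name
# uniqueness. `log` carries per-set filtering counts when built by a reader.
seed_collection <- function(sets, log = NULL) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, TRUE, "seed_set")))
  nm <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate seed set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nm
  structure(list(sets = sets, log = log), class = "seed_collection")
}

#' @export
print.seed_collection <- function(x, ...) {
  cat(sprintf("<seed_collection> %d sets\n", length(x$sets)))
  for (s in x$sets) {
    cat(sprintf("  %-28s %-20s %5d genes\n", s$name, s$category,
                length(s$genes)))
  }
  invisible(x)
}

# Pull a plain list of seed_set out of either a seed_collection or a list.
as_seed_list <- function(groups) {
  if (inherits(groups, "seed_collection")) return(groups$sets)
  if (inherits(groups, "seed_set")) return(stats::setNames(list(groups), groups$name))
  stopifnot(is.list(groups), all(vapply(groups, inherits, TRUE, "seed_set")))
  stats::setNames(groups, vapply(groups, `[[`, "", "name"))
}
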