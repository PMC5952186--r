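#' Read phenotype/herb seed gene sets and build aggregates
#'
#' Reads a header-bearing TSV with columns `name`, `category`, `gene` (one
#' gene per row; `category` is `disease`, `symptom` or `herb`). Genes absent
#' from the network are dropped and logged per set; sets left empty are
#' excluded and logged (curated phenotypes with no network gene cannot be
#' tested). Aggregate union sets are appended: `Diseases`
#' (category `aggregate-diseases`), `Symptoms` and `Herbs`, each present only
#' when at least one member set survived filtering.
#'
#' @param path TSV file.
#' @param network a [ppi_network()]; defines the admissible gene universe.
#' @return a `seed_collection`; `$log` is a data frame with one row per input
#'   set (`name`, `category`, `n_input`, `n_kept`, `n_dropped`, `kept`).
#' @export
read_seed_sets <- function(path, network) {
  stopifnot(inherits(network, "ppi_network"))
  tab <- read_required_tsv(path, c("name", "category", "gene"))
  bad <- setdiff(unique(tab$category), INPUT_CATEGORIES)
  if (length(bad)) {
    stop("unknown seed set category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab$gene <- normalize_gene(tab$gene)
  nodes <- network_nodes(network)
  sets <- list()
  log <- list()
  for (nm in unique(tab$name)) {
    rows <- tab[tab$name == nm, , drop = FALSE]
    cat_ <- unique(rows$category)
    if (length(cat_) != 1L) {
      stop("seed set '", nm, "' spans multiple categories", call. = FALSE)
    }
    genes <- unique(rows$gene)
    kept <- intersect(genes, nodes)
    log[[nm]] <- data.frame(
      name = nm, category = cat_, n_input = length(genes),
      n_kept = length(kept), n_dropped = length(genes) - length(kept),
      kept = length(kept) > 0L, stringsAsFactors = FALSE
    )
    if (length(kept) == 0L) {
      message("seed set '", nm, "' has no gene in the network; excluded")
      next
    }
    sets[[nm]] <- seed_set(nm, cat_, kept)
  }
  if (length(sets) == 0L) {
    stop("all seed sets are empty after network filtering", call. = FALSE)
  }
  sets <- c(sets, aggregate_seed_sets(sets))
  seed_collection(sets, log = do.call(rbind, unname(log)))
}

# Union aggregates over member sets of each input category.
aggregate_seed_sets <- function(sets) {
  spec <- list(
    disease = c("Diseases", "aggregate-diseases"),
    symptom = c("Symptoms", "aggregate-symptoms"),
    herb = c("Herbs", "aggregate-herbs")
  )
  out <- list()
  cats <- vapply(sets, `[[`, "", "category")
  for (cat_ in names(spec)) {
    members <- sets[cats == cat_]
    if (length(members) == 0L) next
    genes <- sort(unique(unlist(lapply(members, `[[`, "genes"))))
    nm <- spec[[cat_]][1L]
    out[[nm]] <- seed_set(nm, spec[[cat_]][2L], genes)
  }
  out
}

#' Read a herb-ingredient-target table
#'
#' Reads a header-bearing TSV with columns `herb`, `ingredient`, `target` and
#' optionally `source` (provenance tag, defaults to `""`). Rows duplicating
#' the same (herb, ingredient, target) triple are collapsed to the first
#' occurrence; the number collapsed is kept in the `n_duplicates` attribute.
#'
#' @param path TSV file.
#' @return data frame of records (`herb`, `ingredient`, `target`, `source`)
#'   with normalized targets, attribute `n_duplicates`.
#' @export
read_herb_table <- function(path) {
  tab <- read_required_tsv(path, c("herb", "ingredient", "target"))
  if (!"source" %in% names(tab)) tab$source <- ""
  tab <- tab[, c("herb", "ingredient", "target", "source")]
  empty <- !nzchar(trimws(tab$herb)) | !nzchar(trimws(tab$ingredient)) |
    !nzchar(trimws(tab$target))
  if (any(empty)) {
    stop("herb table row(s) with empty herb/ingredient/target: ",
         paste(utils::head(which(empty), 5), collapse = ", "), call. = FALSE)
  }
  tab$herb <- trimws(tab$herb)
  tab$ingredient <- trimws(tab$ingredient)
  tab$target <- normalize_gene(tab$target)
  key <- paste(tab$herb, tab$ingredient, tab$target, sep = "\r")
  dup <- duplicated(key)
  out <- tab[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Derive per-herb seed gene sets from herb records
#'
#' Groups the targets of each herb into a `herb`-category [seed_set()] and
#' appends the `Herbs` aggregate union. When a network is supplied, targets
#' outside it are dropped and herbs left without in-network targets are
#' excluded (with a message).
#'
#' @param records data frame from [read_herb_table()].
#' @param network optional [ppi_network()] used to filter targets.
#' @return a `seed_collection`.
#' @export
herb_seed_sets <- function(records, network = NULL) {
  stopifnot(all(c("herb", "target") %in% names(records)))
  nodes <- if (is.null(network)) NULL else network_nodes(network)
  sets <- list()
  for (h in unique(records$herb)) {
    genes <- unique(records$target[records$herb == h])
    if (!is.null(nodes)) genes <- intersect(genes, nodes)
    if (length(genes) == 0L) {
      message("herb '", h, "' has no target in the network; excluded")
      next
    }
    sets[[h]] <- seed_set(h, "herb", genes)
  }
  if (length(sets) == 0L) stop("no herb has in-network targets", call. = FALSE)
  sets <- c(sets, aggregate_seed_sets(sets))
  seed_collection(sets)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: each line `set name<TAB>description<TAB>gene...`.
#' Set names must be unique and every set must carry at least one gene.
#'
#' @param path GMT file.
#' @return object of class `annotation_collection`: list with `sets` (named
#'   list of normalized gene vectors) and `description` (named character).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop(sprintf("parse error at GMT line %d: fewer than 3 columns",
                 which(short)[1]), call. = FALSE)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate GMT set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) sort(unique(normalize_gene(f[-(1:2)]))))
  names(sets) <- nm
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), nm)
  structure(list(sets = sets, description = desc),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("<annotation_collection> %d sets (%d genes total)\n",
              length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Write an annotation collection to GMT
#'
#' @param annotations an `annotation_collection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_collection"))
  lines <- vapply(names(annotations$sets), function(nm) {
    paste(c(nm, annotations$description[[nm]], annotations$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Shared TSV reader: header required, named columns mandatory.
read_required_tsv <- function(path, required) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  tab <- read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}
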