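#' Construct an undirected PPI network from gene pairs
#'
#' Builds a simple undirected graph over normalized gene symbols. Self-loops
#' and duplicate edges (in either orientation) are dropped and counted in the
#' load report. Endpoint genes of dropped self-loops are retained as nodes.
#'
#' @param from,to character vectors of interacting gene symbols (same length).
#' @param nodes optional extra node symbols (e.g. isolated proteins).
#' @param report optional list of reader-side counts merged into the load
#'   report (`n_malformed`, `n_comment`).
#' @return object of class `ppi_network`: list with `graph` (an
#'   \pkg{igraph} graph with sorted vertex names) and `report` (counts:
#'   `n_pairs`, `n_kept`, `n_self_loops`, `n_duplicates`, plus reader counts).
#' @examples
#' net <- ppi_network(c("a", "B"), c("b", "C"))
#' network_nodes(net)
#' @export
ppi_network <- function(from, to, nodes = NULL, report = NULL) {
  stopifnot(length(from) == length(to))
  n_pairs <- length(from)
  if (n_pairs > 0L) {
    from <- normalize_gene(from)
    to <- normalize_gene(to)
  }
  self <- from == to
  a <- pmin(from[!self], to[!self])
  b <- pmax(from[!self], to[!self])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  a <- a[!dup]
  b <- b[!dup]
  vs <- sort(unique(c(from, to, if (!is.null(nodes)) normalize_gene(nodes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vs
  )
  rep_out <- list(
    n_pairs = n_pairs,
    n_kept = length(a),
    n_self_loops = sum(self),
    n_duplicates = sum(dup)
  )
  structure(list(graph = g, report = c(rep_out, report)),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  r <- x$report
  cat(sprintf("  load: %d pairs read, %d kept, %d self-loops, %d duplicates dropped\n",
              r$n_pairs, r$n_kept, r$n_self_loops, r$n_duplicates))
  invisible(x)
}

#' Network accessors
#'
#' @param network a `ppi_network`.
#' @return `network_nodes()`: sorted character vector of gene symbols;
#'   `network_edges()`: two-column data frame (`from`, `to`) with
#'   `from < to` lexicographically, sorted; `load_report()`: the list of
#'   load counts recorded when the network was read.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  igraph::V(network$graph)$name
}

#' @rdname network_nodes
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  el <- igraph::as_edgelist(network$graph)
  if (nrow(el) == 0L) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(from = pmin(el[, 1], el[, 2]),
                   to = pmax(el[, 1], el[, 2]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname network_nodes
#' @export
load_report <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  network$report
}

#' Read a PPI network from an edge-list or SIF file
#'
#' Edge-list format (`tsv`): two or more whitespace/tab-separated columns per
#' line, first two taken as interacting gene symbols; no header. SIF format:
#' `nodeA<TAB>relation<TAB>nodeB[<TAB>nodeB2 ...]`, the relation column is
#' ignored. Lines starting with `#` and blank lines are skipped in both
#' formats. Symbols are normalized; self-loops and duplicate edges are
#' dropped and counted in the load report. The result is independent of
#' input line order.
#'
#' @param path input file.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param skip_bad_lines if `FALSE` (default) a malformed line (too few
#'   columns) is a fatal parse error naming the line number; if `TRUE` such
#'   lines are dropped and counted as `n_malformed` in the load report.
#' @return a [ppi_network()].
#' @export
read_network <- function(path, format = c("tsv", "sif"),
                         skip_bad_lines = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read network file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # "#node<TAB>SYMBOL" directive lines declare isolated nodes (written by
  # write_network so edge lists round-trip); all other "#" lines are comments.
  iso_lines <- grepl("^#node[ \t]", lines)
  iso_nodes <- if (any(iso_lines)) {
    vapply(strsplit(lines[iso_lines], "[ \t]+"), `[[`, "", 2L)
  } else NULL
  keep <- !grepl("^\\s*(#|$)", lines)
  n_comment <- sum(!keep)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "[ \t]+")
  min_cols <- if (format == "tsv") 2L else 3L
  ok <- lengths(fields) >= min_cols
  if (any(!ok)) {
    if (!skip_bad_lines) {
      stop(sprintf("parse error at line %d: fewer than %d columns",
                   idx[which(!ok)[1]], min_cols), call. = FALSE)
    }
    fields <- fields[ok]
  }
  n_malformed <- sum(!ok)
  if (format == "tsv") {
    from <- vapply(fields, `[[`, "", 1L)
    to <- vapply(fields, `[[`, "", 2L)
  } else {
    # SIF: one source, one or more targets from column 3 onwards
    from <- unlist(lapply(fields, function(f) rep(f[1L], length(f) - 2L)))
    to <- unlist(lapply(fields, function(f) f[-(1:2)]))
    if (is.null(from)) from <- character()
    if (is.null(to)) to <- character()
  }
  ppi_network(from, to, nodes = iso_nodes,
              report = list(n_malformed = n_malformed, n_comment = n_comment))
}

#' Write a network as a two-column edge-list TSV
#'
#' Writes edges in canonical sorted order (each pair with the
#' lexicographically smaller gene first). Re-reading with [read_network()]
#' yields an identical node and edge set; isolated nodes, which a bare edge
#' list cannot carry, are written as `#node` directive lines that
#' [read_network()] understands.
#'
#' @param network a `ppi_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  ed <- network_edges(network)
  iso <- setdiff(network_nodes(network), unique(c(ed$from, ed$to)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(iso)) writeLines(paste0("#node\t", iso), con)
  write.table(ed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
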