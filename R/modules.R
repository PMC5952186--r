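#' Partition a PPI network into topological modules
#'
#' Runs modularity-based community detection and labels the resulting
#' communities `M1..Mk` in order of decreasing size, ties broken by the
#' lexicographically smallest member gene. Communities smaller than
#' `min_size` are pooled under the reserved label `M0` (unassigned), which
#' downstream enrichment skips: one- and two-gene modules cannot support a
#' meaningful Fisher test.
#'
#' Detection is delegated to \pkg{igraph}: greedy modularity maximization
#' (Clauset-Newman-Moore agglomeration, deterministic) or asynchronous label
#' propagation (stochastic; made reproducible by seeding R's RNG).
#'
#' @param network a [ppi_network()], non-empty.
#' @param method `"greedy-modularity"` (default) or `"label-propagation"`.
#' @param seed integer RNG seed; with a fixed seed the partition is identical
#'   across runs.
#' @param min_size minimum module size retained (default 3).
#' @return object of class `module_partition`: list with `membership` (named
#'   character vector, gene -> label), `labels` (ordered `M1..Mk`, excluding
#'   `M0`), `sizes` (named integer, including `M0` when present),
#'   `modularity_score` (Q of the final labeled partition), and the call
#'   parameters.
#' @export
detect_modules <- function(network,
                           method = c("greedy-modularity", "label-propagation"),
                           seed = 1L, min_size = 3L) {
  stopifnot(inherits(network, "ppi_network"))
  method <- match.arg(method)
  if (igraph::vcount(network$graph) == 0L) {
    stop("cannot detect modules in an empty network", call. = FALSE)
  }
  stopifnot(min_size >= 1L)
  g <- network$graph
  set.seed(as.integer(seed))
  if (igraph::ecount(g) == 0L) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
  } else if (method == "greedy-modularity") {
    comm <- igraph::cluster_fast_greedy(g)
    # cut the agglomeration dendrogram exactly at the modularity maximum
    memb <- igraph::cut_at(comm, steps = which.max(comm$modularity) - 1L)
    names(memb) <- igraph::V(g)$name
  } else {
    comm <- igraph::cluster_label_prop(g)
    memb <- igraph::membership(comm)
  }
  genes <- igraph::V(g)$name
  raw <- split(genes, as.integer(memb))
  raw <- lapply(raw, sort)
  sizes <- lengths(raw)
  small <- sizes < min_size
  kept <- raw[!small]
  if (length(kept)) {
    # decreasing size, ties by lexicographically smallest member gene
    ord <- order(-lengths(kept), vapply(kept, `[[`, "", 1L))
    kept <- kept[ord]
    labels <- paste0("M", seq_along(kept))
  } else {
    labels <- character()
  }
  assignment <- stats::setNames(rep("M0", length(genes)), genes)
  for (i in seq_along(kept)) assignment[kept[[i]]] <- labels[i]
  assignment <- assignment[order(names(assignment))]
  size_tab <- stats::setNames(lengths(kept), labels)
  if (any(small)) size_tab <- c(size_tab, M0 = sum(sizes[small]))
  q <- if (igraph::ecount(g) > 0L) modularity_score(network, assignment) else NA_real_
  structure(list(
    membership = assignment, labels = labels, sizes = size_tab,
    modularity_score = q, method = method, seed = as.integer(seed),
    min_size = as.integer(min_size)
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules over %d genes (method=%s, Q=%.4f)\n",
              length(x$labels), length(x$membership), x$method,
              x$modularity_score))
  show <- utils::head(x$sizes, 10)
  cat("  sizes:", paste(sprintf("%s=%d", names(show), show), collapse = " "),
      if (length(x$sizes) > 10) "...\n" else "\n")
  invisible(x)
}

#' Newman modularity of a labeled partition
#'
#' Computes `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `m` is the total edge
#' count, `e_c` the number of edges internal to community `c` and `d_c` the
#' total degree of its members. `Q` lies in `[-0.5, 1]`; the trivial
#' one-community partition scores 0.
#'
#' @param network a [ppi_network()] with at least one edge.
#' @param partition a `module_partition` or a named character/factor vector
#'   assigning every network node to a community label.
#' @return the modularity score (numeric scalar).
#' @export
modularity_score <- function(network, partition) {
  stopifnot(inherits(network, "ppi_network"))
  memb <- if (inherits(partition, "module_partition")) partition$membership
          else partition
  genes <- network_nodes(network)
  if (!all(genes %in% names(memb))) {
    stop("partition does not cover the network: missing ",
         paste(utils::head(setdiff(genes, names(memb)), 5), collapse = ", "),
         call. = FALSE)
  }
  memb <- as.character(memb[genes])
  names(memb) <- genes
  m <- igraph::ecount(network$graph)
  if (m == 0L) stop("modularity is undefined for an edgeless network",
                    call. = FALSE)
  el <- igraph::as_edgelist(network$graph)
  intra <- memb[el[, 1]] == memb[el[, 2]]
  deg <- igraph::degree(network$graph)
  d_c <- tapply(deg, memb[names(deg)], sum)
  e_c <- stats::setNames(rep(0, length(d_c)), names(d_c))
  if (any(intra)) {
    tab <- table(memb[el[intra, 1]])
    e_c[names(tab)] <- as.numeric(tab)
  }
  sum(e_c / m - (d_c / (2 * m))^2)
}

#' Genes belonging to one module
#'
#' @param partition a `module_partition`.
#' @param label module label, e.g. `"M1"`.
#' @return sorted character vector of member genes.
#' @export
module_genes <- function(partition, label) {
  stopifnot(inherits(partition, "module_partition"))
  if (!label %in% c(partition$labels, "M0")) {
    stop("unknown module label: ", label, call. = FALSE)
  }
  sort(names(partition$membership)[partition$membership == label])
}

#' Write partition tables
#'
#' `write_partition()` writes the gene-to-module assignment
#' (`gene`, `module_label`); `partition_summary()` returns and optionally
#' writes the per-module size table (`module_label`, `size`).
#'
#' @param partition a `module_partition`.
#' @param path output TSV path (for `partition_summary`, optional).
#' @return the written path (or the summary data frame), invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "module_partition"))
  df <- data.frame(gene = names(partition$membership),
                   module_label = unname(partition$membership),
                   stringsAsFactors = FALSE)
  write_report_tsv(df, path)
}

#' @rdname write_partition
#' @export
partition_summary <- function(partition, path = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  df <- data.frame(module_label = names(partition$sizes),
                   size = as.integer(partition$sizes),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) write_report_tsv(df, path)
  invisible(df)
}
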