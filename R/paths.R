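#' Single-source shortest-path distances
#'
#' Exact shortest-path distances from one source protein to every network
#' node, computed by Dijkstra's algorithm with unit edge weights (the PPI
#' network is unweighted, so the result coincides with breadth-first search;
#' the test suite verifies this equivalence). Nodes in other connected
#' components are marked unreachable (`Inf`).
#'
#' @param network a [ppi_network()].
#' @param source gene symbol, must be a network node.
#' @return object of class `distance_profile`: list with `source` and
#'   `distances` (named numeric vector over all nodes, `Inf` = unreachable).
#' @export
single_source_distances <- function(network, source) {
  stopifnot(inherits(network, "ppi_network"))
  source <- normalize_gene(source)
  stopifnot(length(source) == 1L)
  if (!source %in% network_nodes(network)) {
    stop("source '", source, "' is not a network node", call. = FALSE)
  }
  g <- network$graph
  d <- igraph::distances(g, v = source, to = igraph::V(g),
                         algorithm = "dijkstra",
                         weights = rep(1, igraph::ecount(g)))
  structure(list(source = source,
                 distances = stats::setNames(as.numeric(d[1L, ]),
                                             colnames(d))),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  fin <- is.finite(x$distances)
  cat(sprintf("<distance_profile> source %s: %d/%d nodes reachable (max %s)\n",
              x$source, sum(fin), length(x$distances),
              if (any(fin)) max(x$distances[fin]) else NA))
  invisible(x)
}

#' Summarize a source's distance profile against a gene group
#'
#' Min/max/average shortest-path distance from the profile's source to the
#' members of a gene group. Unreachable members are excluded from all three
#' statistics and accounted for via `n_reachable` / `n_total`; when the
#' source belongs to the group its self-distance 0 is included (hence
#' `min_sp = 0` for sources inside the group). A group with no reachable
#' member yields `NA` statistics and is excluded from key-target calling.
#'
#' @param profile a `distance_profile` from [single_source_distances()].
#' @param group a [seed_set()] (or character vector, wrapped as an `annotation`
#'   set named `"group"`); group genes must be network nodes.
#' @return one-row data frame: `source`, `group_name`, `group_category`,
#'   `min_sp`, `max_sp`, `avg_sp`, `n_reachable`, `n_total`.
#' @export
summarize_to_group <- function(profile, group) {
  stopifnot(inherits(profile, "distance_profile"))
  if (is.character(group)) group <- seed_set("group", "annotation", group)
  stopifnot(inherits(group, "seed_set"))
  missing <- setdiff(group$genes, names(profile$distances))
  if (length(missing)) {
    stop("group '", group$name, "' has genes outside the network: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  d <- profile$distances[group$genes]
  fin <- is.finite(d)
  n_reach <- sum(fin)
  if (n_reach == 0L) {
    min_sp <- max_sp <- NA_integer_
    avg_sp <- NA_real_
  } else {
    min_sp <- as.integer(min(d[fin]))
    max_sp <- as.integer(max(d[fin]))
    avg_sp <- mean(d[fin])
  }
  data.frame(
    source = profile$source, group_name = group$name,
    group_category = group$category, min_sp = min_sp, max_sp = max_sp,
    avg_sp = avg_sp, n_reachable = n_reach, n_total = length(d),
    stringsAsFactors = FALSE
  )
}

#' Call key drug targets by average shortest-path proximity
#'
#' For every (target, group) pair, summarizes the target's shortest-path
#' distance profile against the group and flags the target as key for that
#' group when its average distance is strictly below `threshold` ("strongly
#' connecting"; default 3). Targets absent from the network are dropped with
#' a message and recorded in the `dropped_targets` attribute. Groups whose
#' members are all unreachable from a target yield `is_key = FALSE` with
#' `NA` statistics.
#'
#' @param network a [ppi_network()].
#' @param targets character vector of drug target genes.
#' @param groups a `seed_collection`, list of [seed_set()], or single set;
#'   typical groups are key-module gene sets and the aggregate disease and
#'   symptom sets.
#' @param threshold strict upper bound on `avg_sp` (default 3).
#' @return object of class `key_target_calls`: data frame with the
#'   [summarize_to_group()] columns plus `is_key` and `threshold`, one row
#'   per (target, group); attribute `dropped_targets`.
#' @export
call_key_targets <- function(network, targets, groups, threshold = 3) {
  stopifnot(inherits(network, "ppi_network"), threshold > 0)
  targets <- unique(normalize_gene(targets))
  groups <- as_seed_list(groups)
  stopifnot(length(groups) > 0L)
  nodes <- network_nodes(network)
  dropped <- setdiff(targets, nodes)
  targets <- intersect(targets, nodes)
  if (length(dropped)) {
    message(length(dropped), " target(s) not in the network; dropped")
  }
  if (length(targets) == 0L) {
    stop("no target is a network node", call. = FALSE)
  }
  rows <- vector("list", length(targets) * length(groups))
  i <- 0L
  for (tg in targets) {
    prof <- single_source_distances(network, tg)
    for (grp in groups) {
      i <- i + 1L
      rows[[i]] <- summarize_to_group(prof, grp)
    }
  }
  out <- do.call(rbind, rows)
  out$is_key <- !is.na(out$avg_sp) & out$avg_sp < threshold
  out$threshold <- threshold
  rownames(out) <- NULL
  class(out) <- c("key_target_calls", "data.frame")
  attr(out, "dropped_targets") <- dropped
  out
}
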