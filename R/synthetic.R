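#' Specification for synthetic benchmark inputs
#'
#' Describes a planted-partition (stochastic block model) network with a
#' designated planted module, a seed gene group with controlled fold
#' enrichment in that module, and a drug target wired at controlled proximity
#' to it. Defaults describe the benchmark conditions used throughout the test
#' suite: 120 proteins in 4 communities with strong contrast (within-community
#' edge probability 0.3 vs 0.01 between), a 15-gene seed group at fold 4 in a
#' 30-gene module, and a target attached to half the module.
#'
#' @param n_nodes number of proteins (default 120).
#' @param n_communities number of planted communities (default 4); nodes are
#'   split as evenly as possible.
#' @param p_in,p_out within/between-community edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param planted_module index (1-based) of the community carrying the
#'   planted enrichment and proximity signal.
#' @param group_size size of the planted seed gene group (default 15).
#' @param fold target fold enrichment of the planted group in the planted
#'   module (>= 1; default 4).
#' @param attach_fraction fraction of planted-module nodes wired to the
#'   planted target (in (0, 1]; default 0.5).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_spec` (validated list of the above).
#' @export
synthetic_spec <- function(n_nodes = 120L, n_communities = 4L, p_in = 0.3,
                           p_out = 0.01, planted_module = 1L, group_size = 15L,
                           fold = 4, attach_fraction = 0.5, seed = 1L) {
  stopifnot(n_nodes >= 2L, n_communities >= 1L, n_communities <= n_nodes,
            p_out >= 0, p_out < p_in, p_in <= 1,
            planted_module >= 1L, planted_module <= n_communities,
            group_size >= 1L, group_size <= n_nodes,
            fold >= 1, attach_fraction > 0, attach_fraction <= 1)
  structure(list(
    n_nodes = as.integer(n_nodes), n_communities = as.integer(n_communities),
    p_in = p_in, p_out = p_out, planted_module = as.integer(planted_module),
    group_size = as.integer(group_size), fold = fold,
    attach_fraction = attach_fraction, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Community sizes: as even as possible, remainder to the first communities.
planted_sizes <- function(spec) {
  base <- spec$n_nodes %/% spec$n_communities
  sizes <- rep(base, spec$n_communities)
  extra <- spec$n_nodes - base * spec$n_communities
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

synthetic_gene_names <- function(n) sprintf("G%06d", seq_len(n))

#' Generate a planted-partition PPI network
#'
#' Samples a stochastic block model with the spec's community sizes and
#' edge probabilities, over synthetic gene names `G000001...`. Seeded and
#' reproducible: the same spec always yields the same edge set.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (a [ppi_network()]) and `labels` (named
#'   integer vector, gene -> planted community index).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sizes <- planted_sizes(spec)
  pref <- matrix(spec$p_out, spec$n_communities, spec$n_communities)
  diag(pref) <- spec$p_in
  set.seed(spec$seed)
  g <- igraph::sample_sbm(spec$n_nodes, pref.matrix = pref,
                          block.sizes = sizes, directed = FALSE)
  genes <- synthetic_gene_names(spec$n_nodes)
  el <- igraph::as_edgelist(g)
  network <- ppi_network(genes[el[, 1]], genes[el[, 2]], nodes = genes)
  labels <- stats::setNames(rep(seq_len(spec$n_communities), sizes), genes)
  list(network = network, labels = labels)
}

#' Generate a seed gene group with controlled module enrichment
#'
#' Draws a `group_size` gene set whose expected overlap with the planted
#' module is `fold x (module_size / n_nodes) x group_size`: each member is
#' placed inside the module with probability `fold x module_size / n_nodes`
#' (binomial in-module count, clamped to the feasible range), then sampled
#' without replacement inside and outside the module. `fold = 1` reproduces
#' uniform sampling in expectation; the maximal fold
#' `n_nodes / module_size` places the whole group inside the module.
#'
#' @param labels planted labels from [generate_network()].
#' @param spec a [synthetic_spec()].
#' @param name,category label and category of the returned [seed_set()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return a [seed_set()].
#' @export
generate_seed_group <- function(labels, spec, name = "planted-group",
                                category = "disease", seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  inside <- names(labels)[labels == spec$planted_module]
  outside <- names(labels)[labels != spec$planted_module]
  n <- length(labels)
  p <- spec$fold * length(inside) / n
  if (p > 1 + 1e-9) {
    stop(sprintf("infeasible fold %g: maximum feasible fold is %g",
                 spec$fold, n / length(inside)), call. = FALSE)
  }
  p <- min(p, 1)
  expected <- spec$group_size * p
  if (expected > length(inside) + 1e-9) {
    stop(sprintf(
      "infeasible fold %g: expected in-module count %.2f exceeds module size %d (max feasible fold %g)",
      spec$fold, expected, length(inside), n / spec$group_size), call. = FALSE)
  }
  set.seed(as.integer(seed))
  k_in <- rbinom(1L, spec$group_size, p)
  k_in <- max(min(k_in, length(inside)),
              spec$group_size - length(outside), 0L)
  genes <- c(if (k_in > 0) sample(inside, k_in),
             if (spec$group_size - k_in > 0)
               sample(outside, spec$group_size - k_in))
  seed_set(name, category, genes)
}

#' Plant a proximal drug target
#'
#' Adds one new node wired to `ceiling(attach_fraction x module_size)`
#' distinct planted-module nodes chosen uniformly (seeded). Emulates a drug
#' target protein interacting densely with one disease module.
#'
#' @param network a [ppi_network()].
#' @param labels planted labels from [generate_network()].
#' @param spec a [synthetic_spec()].
#' @param name symbol of the new target node (default `"TGT1"`).
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list with `network` (augmented) and `target` (the new symbol).
#' @export
plant_proximal_target <- function(network, labels, spec, name = "TGT1",
                                  seed = spec$seed) {
  stopifnot(inherits(network, "ppi_network"), inherits(spec, "synthetic_spec"))
  module_nodes <- names(labels)[labels == spec$planted_module]
  if (length(module_nodes) == 0L) stop("planted module is empty", call. = FALSE)
  n_attach <- ceiling(spec$attach_fraction * length(module_nodes))
  if (n_attach < 1L) stop("attach count is zero", call. = FALSE)
  set.seed(as.integer(seed))
  attach_to <- sample(module_nodes, n_attach)
  attach_target(network, name, attach_to)
}

#' Plant a randomly wired control target
#'
#' Degree-matched null for [plant_proximal_target()]: adds one node wired to
#' `n_edges` nodes chosen uniformly from the whole network (optionally
#' excluding some), irrespective of community structure.
#'
#' @param network a [ppi_network()].
#' @param n_edges number of attachment edges.
#' @param name symbol of the new node (default `"CTL1"`).
#' @param seed RNG seed.
#' @param exclude node symbols not eligible for attachment.
#' @return list with `network` (augmented) and `target` (the new symbol).
#' @export
plant_control_target <- function(network, n_edges, name = "CTL1", seed = 1L,
                                 exclude = character()) {
  stopifnot(inherits(network, "ppi_network"), n_edges >= 1L)
  pool <- setdiff(network_nodes(network), normalize_gene(c(name, exclude)))
  stopifnot(n_edges <= length(pool))
  set.seed(as.integer(seed))
  attach_to <- sample(pool, n_edges)
  attach_target(network, name, attach_to)
}

attach_target <- function(network, name, attach_to) {
  name <- normalize_gene(name)
  if (name %in% network_nodes(network)) {
    stop("target symbol '", name, "' already in the network", call. = FALSE)
  }
  ed <- network_edges(network)
  out <- ppi_network(c(ed$from, rep(name, length(attach_to))),
                     c(ed$to, attach_to),
                     nodes = network_nodes(network))
  list(network = out, target = name)
}

#' Write a complete synthetic input bundle
#'
#' Emits every file [run_pipeline()] consumes, built from one spec: the
#' planted-partition network augmented with the planted proximal target
#' `TGT1` (edge list TSV), a seed-set TSV with one enriched disease group
#' and one enriched symptom group, a herb table whose targets are `TGT1`
#' (two ingredients of one synthetic herb), a GMT collection (the planted
#' module's genes plus a uniform decoy set), and the spec itself as YAML.
#' The planted target is the construction's intended sole candidate: it is
#' the only drug target, it sits at distance 1 from half the planted module,
#' and both phenotype groups are enriched in that module.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (`network`, `seed_sets`, `herb_table`,
#'   `gmt`, `spec`) plus `target` (the planted symbol) and `labels`.
#' @export
generate_input_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_network(spec)
  dis <- generate_seed_group(gen$labels, spec, name = "Planted disease",
                             category = "disease", seed = spec$seed + 1L)
  sym <- generate_seed_group(gen$labels, spec, name = "Planted symptom",
                             category = "symptom", seed = spec$seed + 2L)
  planted <- plant_proximal_target(gen$network, gen$labels, spec,
                                   seed = spec$seed + 3L)

  paths <- list(
    network = file.path(dir, "edges.tsv"),
    seed_sets = file.path(dir, "seed_sets.tsv"),
    herb_table = file.path(dir, "herb_table.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    spec = file.path(dir, "spec.yaml")
  )
  write_network(planted$network, paths$network)

  seed_df <- rbind(
    data.frame(name = dis$name, category = dis$category, gene = dis$genes,
               stringsAsFactors = FALSE),
    data.frame(name = sym$name, category = sym$category, gene = sym$genes,
               stringsAsFactors = FALSE)
  )
  write.table(seed_df, paths$seed_sets, sep = "\t", quote = FALSE,
              row.names = FALSE)

  herb_df <- data.frame(
    herb = "Synthetic herb A",
    ingredient = c("ingredient-1", "ingredient-2"),
    target = planted$target,
    source = "synthetic",
    stringsAsFactors = FALSE
  )
  write.table(herb_df, paths$herb_table, sep = "\t", quote = FALSE,
              row.names = FALSE)

  module_nodes <- names(gen$labels)[gen$labels == spec$planted_module]
  set.seed(spec$seed + 4L)
  decoy <- sort(sample(names(gen$labels), min(20L, spec$n_nodes)))
  ann <- structure(list(
    sets = list("planted-module-pathway" = sort(module_nodes),
                "uniform-decoy-pathway" = decoy),
    description = c("planted-module-pathway" = "genes of the planted community",
                    "uniform-decoy-pathway" = "uniform random gene set")
  ), class = "annotation_collection")
  write_gmt(ann, paths$gmt)

  yaml::write_yaml(unclass(spec), paths$spec)
  c(paths, list(target = planted$target, labels = gen$labels))
}
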