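# Independent oracles used across the suite. Deliberately naive and written
# against base R only, so they share no code path with the implementation.

# Erdos-Renyi edge list over integer node ids, via base R RNG only.
random_edge_pairs <- function(n, p, seed) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- stats::runif(nrow(idx)) < p
  idx[pick, , drop = FALSE]
}

gene_name <- function(i) sprintf("N%04d", i)

# ppi_network over n named nodes from an integer pair matrix.
network_from_pairs <- function(pairs, n) {
  ppi_network(gene_name(pairs[, 1]), gene_name(pairs[, 2]),
              nodes = gene_name(seq_len(n)))
}

# Adjacency list (integer vectors, 1..n) from a ppi_network, using the
# node order of network_nodes().
oracle_adjacency <- function(network) {
  nodes <- network_nodes(network)
  ed <- network_edges(network)
  i <- match(ed$from, nodes)
  j <- match(ed$to, nodes)
  adj <- vector("list", length(nodes))
  for (v in seq_along(nodes)) adj[[v]] <- integer()
  for (e in seq_along(i)) {
    adj[[i[e]]] <- c(adj[[i[e]]], j[e])
    adj[[j[e]]] <- c(adj[[j[e]]], i[e])
  }
  adj
}

# Textbook queue-based breadth-first search.
oracle_bfs <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s
  head <- 1L
  while (head <= length(queue)) {
    u <- queue[head]
    head <- head + 1L
    for (v in adj[[u]]) {
      if (!is.finite(d[v])) {
        d[v] <- d[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  d
}

# Floyd-Warshall all-pairs matrix (vectorized inner update).
oracle_floyd_warshall <- function(network) {
  nodes <- network_nodes(network)
  n <- length(nodes)
  ed <- network_edges(network)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  i <- match(ed$from, nodes)
  j <- match(ed$to, nodes)
  D[cbind(i, j)] <- 1
  D[cbind(j, i)] <- 1
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Exhaustive hypergeometric upper-tail sum via choose(); the brute-force
# reference for the one-sided Fisher p-value.
oracle_hyper_tail <- function(k, m, g, N) {
  lo <- max(0L, m + g - N)
  hi <- min(m, g)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(exp(lchoose(g, i) + lchoose(N - g, m - i) - lchoose(N, m)))
}

adjusted_agreement <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small two-clique "barbell": two 5-cliques joined by one bridge edge.
barbell_network <- function() {
  cl <- function(genes) t(utils::combn(genes, 2))
  a <- cl(paste0("A", 1:5))
  b <- cl(paste0("B", 1:5))
  ed <- rbind(a, b, c("A1", "B1"))
  ppi_network(ed[, 1], ed[, 2])
}

# Path graph over the given gene names, in order.
chain_network <- function(genes) {
  ppi_network(genes[-length(genes)], genes[-1])
}
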