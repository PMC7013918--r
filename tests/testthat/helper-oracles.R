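# Independent, deliberately naive reference implementations used to check
# the package. None of them share code with the implementation: statistics
# are computed from an adjacency matrix with BFS and triangle counting, and
# hypergeometric tails by explicit enumeration of the sampling formula.

oracle_stats <- function(edges, node_ids) {
  n <- length(node_ids)
  adj <- matrix(FALSE, n, n, dimnames = list(node_ids, node_ids))
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a <- edges$id_a[r]; b <- edges$id_b[r]
      adj[a, b] <- TRUE; adj[b, a] <- TRUE
    }
  }
  deg <- rowSums(adj)

  # mean local clustering, degree-<2 nodes contributing 0
  cc <- 0
  if (n > 0) {
    local <- numeric(n)
    for (i in seq_len(n)) {
      if (deg[i] >= 2) {
        nb <- which(adj[i, ])
        links <- sum(adj[nb, nb, drop = FALSE]) / 2
        local[i] <- 2 * links / (deg[i] * (deg[i] - 1))
      }
    }
    cc <- mean(local)
  }

  # components and all-pairs shortest paths by BFS
  comp <- rep(NA_integer_, n)
  nc <- 0L
  diam <- 0L
  for (s in seq_len(n)) {
    if (is.na(comp[s])) {
      nc <- nc + 1L
      queue <- s
      comp[s] <- nc
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        for (w in which(adj[v, ])) {
          if (is.na(comp[w])) { comp[w] <- nc; queue <- c(queue, w) }
        }
      }
    }
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ])) {
        if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
      }
    }
    diam <- max(diam, max(dist, na.rm = TRUE))
  }
  list(n_nodes = n, n_edges = if (nrow(edges) > 0) sum(adj) / 2 else 0,
       clustering_coefficient = cc,
       n_components = nc, diameter = diam, n_isolated = sum(deg == 0))
}

oracle_hypergeom <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Erdos-Renyi edge table over named nodes, generated without igraph
random_edges <- function(n, p, prefix = "V") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hit <- runif(nrow(pairs)) < p
  tibble::tibble(id_a = ids[pairs[hit, 1]], id_b = ids[pairs[hit, 2]])
}

random_network <- function(n, p, prefix = "V", label = "random") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  ppi_network(random_edges(n, p, prefix),
              nodes = tibble::tibble(gene_id = ids), label = label)
}
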