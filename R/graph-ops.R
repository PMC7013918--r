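#' Tabular views of a PPI network
#'
#' `net_edges()` returns the canonical (lexicographically oriented) edge
#' table; `net_nodes()` the node table with attributes.
#'
#' @param g A PPI network.
#' @return A tibble.
#' @export
net_edges <- function(g) {
  e <- igraph::as_data_frame(g, what = "edges")
  if (nrow(e) == 0) {
    return(tibble(id_a = character(), id_b = character(),
                  score = numeric(), evidence = character()))
  }
  out <- tibble(id_a = pmin(e$from, e$to), id_b = pmax(e$from, e$to),
                score = e$score %||% NA_real_,
                evidence = e$evidence %||% NA_character_)
  arrange(out, .data$id_a, .data$id_b)
}

#' @rdname net_edges
#' @export
net_nodes <- function(g) {
  v <- igraph::as_data_frame(g, what = "vertices")
  tibble(gene_id = as.character(v$name),
         gene_symbol = if ("symbol" %in% names(v)) v$symbol else NA_character_,
         is_seed = if ("is_seed" %in% names(v)) isTRUE_vec(v$is_seed)
                   else FALSE) |>
    arrange(.data$gene_id)
}

edge_keys <- function(g) {
  e <- net_edges(g)
  paste(e$id_a, e$id_b, sep = "\r")
}

#' Intersection of PPI networks
#'
#' With `mode = "node_edge"` (Cytoscape-style merge, the default) the result
#' keeps the nodes present in every input and the edges present — as
#' unordered pairs — in every input. With `mode = "node"` the edges are the
#' induced subgraph of the first input on the common node set. Node and edge
#' attributes are taken from the first input.
#'
#' @param networks List of at least two PPI networks.
#' @param mode `"node_edge"` or `"node"`.
#' @param label Label of the result.
#' @return A PPI network.
#' @export
intersect_networks <- function(networks, mode = c("node_edge", "node"),
                               label = "merged_intersection") {
  mode <- match.arg(mode)
  if (length(networks) < 2) abort("need at least two networks to intersect")
  common_nodes <- Reduce(intersect, map(networks, ~ net_nodes(.x)$gene_id))
  e1 <- net_edges(networks[[1]])
  keys1 <- paste(e1$id_a, e1$id_b, sep = "\r")
  keep <- e1$id_a %in% common_nodes & e1$id_b %in% common_nodes
  if (mode == "node_edge") {
    common_keys <- Reduce(intersect, map(networks, edge_keys))
    keep <- keep & keys1 %in% common_keys
  }
  nodes1 <- net_nodes(networks[[1]])
  ppi_network(e1[keep, , drop = FALSE],
              nodes1[nodes1$gene_id %in% common_nodes, , drop = FALSE],
              label = label)
}

#' Union of PPI networks
#'
#' Node and edge set unions; conflicting scores for the same edge are
#' resolved by keeping the maximum, seed flags are OR-ed, and the first
#' non-missing symbol wins.
#'
#' @param networks List of PPI networks.
#' @param label Label of the result.
#' @return A PPI network.
#' @export
union_networks <- function(networks, label = "merged_union") {
  if (length(networks) < 2) abort("need at least two networks to union")
  edges <- bind_rows(map(networks, net_edges))
  nodes <- bind_rows(map(networks, net_nodes)) |>
    group_by(.data$gene_id) |>
    summarise(gene_symbol = first(.data$gene_symbol[!is.na(.data$gene_symbol)],
                                  default = NA_character_),
              is_seed = any(.data$is_seed), .groups = "drop")
  ppi_network(edges, nodes, label = label)
}

#' Unique difference network
#'
#' Subtracts the `reference` network (typically the merged intersection of
#' all disease-specific networks) node-wise: the result is the induced
#' subgraph of `g` on `nodes(g) \ nodes(reference)`. With `mode = "edge"`
#' the node set is kept and only the edges present in `reference` are
#' removed.
#'
#' @param g A PPI network.
#' @param reference Network to subtract.
#' @param mode `"node"` (default) or `"edge"`.
#' @return A PPI network labelled `"<label of g>_unique"`.
#' @export
difference_network <- function(g, reference, mode = c("node", "edge")) {
  mode <- match.arg(mode)
  label <- paste0(igraph::graph_attr(g, "label") %||% "network", "_unique")
  e <- net_edges(g)
  nodes <- net_nodes(g)
  if (mode == "node") {
    drop_nodes <- net_nodes(reference)$gene_id
    nodes <- nodes[!nodes$gene_id %in% drop_nodes, , drop = FALSE]
    e <- e[e$id_a %in% nodes$gene_id & e$id_b %in% nodes$gene_id, ,
           drop = FALSE]
  } else {
    keys <- paste(e$id_a, e$id_b, sep = "\r")
    e <- e[!keys %in% edge_keys(reference), , drop = FALSE]
  }
  ppi_network(e, nodes, label = label)
}

#' Topology statistics of a PPI network
#'
#' The six per-network quantities used throughout the package to summarise a
#' network: node and edge counts, mean local clustering coefficient (nodes
#' of degree < 2 contribute 0 and are included in the mean, unless
#' `include_low_degree = FALSE`), number of connected components (isolated
#' nodes count as components), network diameter (the maximum shortest-path
#' length over connected node pairs, i.e. the largest component diameter;
#' 0 for an edgeless graph) and the number of isolated (degree-0) nodes.
#'
#' @param g A PPI network.
#' @param include_low_degree Include degree-<2 nodes (as zeros) in the mean
#'   clustering coefficient. Default `TRUE`.
#' @return A one-row tibble with columns `n_nodes`, `n_edges`,
#'   `clustering_coefficient`, `n_components`, `diameter`, `n_isolated`.
#' @export
compute_stats <- function(g, include_low_degree = TRUE) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  cc_local <- if (n == 0) numeric() else {
    igraph::transitivity(g, type = "local", isolates = "zero")
  }
  cc_local[is.na(cc_local)] <- 0
  cc <- if (n == 0) 0 else if (include_low_degree) {
    mean(cc_local)
  } else if (any(deg >= 2)) {
    mean(cc_local[deg >= 2])
  } else 0
  diam <- if (igraph::ecount(g) == 0) 0 else {
    igraph::diameter(g, unconnected = TRUE, weights = NA)
  }
  tibble(n_nodes = n,
         n_edges = igraph::ecount(g),
         clustering_coefficient = cc,
         n_components = if (n == 0) 0L else igraph::count_components(g),
         diameter = as.integer(diam),
         n_isolated = sum(deg == 0))
}

#' Top hub nodes by degree
#'
#' Ranks nodes by decreasing degree, ties broken by lexicographic gene id,
#' and returns the first `k` (all nodes if the graph has fewer).
#'
#' @param g A PPI network.
#' @param k Number of hubs (default 10).
#' @return A tibble of class `hub_list` with columns `rank`, `gene_id`,
#'   `gene_symbol`, `degree`.
#' @export
top_hubs <- function(g, k = 10) {
  if (k < 1) abort("k must be at least 1")
  nodes <- net_nodes(g)
  deg <- igraph::degree(g)
  nodes$degree <- as.integer(deg[nodes$gene_id])
  nodes <- arrange(nodes, desc(.data$degree), .data$gene_id)
  out <- slice_head(nodes, n = k)
  out <- mutate(out, rank = row_number())
  out <- out[c("rank", "gene_id", "gene_symbol", "degree")]
  class(out) <- unique(c("hub_list", class(out)))
  out
}

#' Isolated nodes of a network
#'
#' Degree-0 nodes: typically seed genes none of whose interactions survived
#' the confidence/taxonomy filters.
#'
#' @param g A PPI network.
#' @param id_space Identifier space of the network's node names.
#' @return A [gene_set()].
#' @export
isolated_nodes <- function(g, id_space = "ensembl_gene") {
  deg <- igraph::degree(g)
  ids <- names(deg)[deg == 0]
  nodes <- net_nodes(g)
  idx <- match(ids, nodes$gene_id)
  gene_set(ids, id_space = id_space, symbols = nodes$gene_symbol[idx])
}
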