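#' Consensus of two hub lists across databases
#'
#' Maps both hub lists into a common identifier space (Ensembl gene by
#' default; symbol-space comparison is available for diagnostics but tends
#' to over-match because symbol conventions differ between databases) and
#' intersects them. Hubs that cannot be mapped are reported, never silently
#' dropped.
#'
#' @param hubs_a,hubs_b `hub_list` tibbles from [top_hubs()].
#' @param idmap An [id_map()]; may be `NULL` when both lists already live in
#'   `target` space.
#' @param space_a,space_b Id spaces of the two lists.
#' @param target Common id space for the comparison.
#' @return A list with `matched` (a [gene_set()] of shared hubs in the
#'   target space), `match_count`, and `unmapped_a` / `unmapped_b`.
#' @export
hub_consensus <- function(hubs_a, hubs_b, idmap = NULL,
                          space_a = "ensembl_gene", space_b = "ensembl_gene",
                          target = "ensembl_gene") {
  if (nrow(hubs_a) == 0 || nrow(hubs_b) == 0) {
    abort("hub lists must be non-empty")
  }
  to_target <- function(hubs, space) {
    gs <- gene_set(hubs$gene_id, id_space = space,
                   symbols = hubs$gene_symbol)
    if (space == target) return(list(mapped = gs, unmapped = character()))
    if (is.null(idmap)) {
      abort(sprintf("an id map is required to map %s hubs into %s space",
                    space, target))
    }
    res <- map_ids(gs, idmap, target)
    list(mapped = res$mapped, unmapped = res$unmapped)
  }
  a <- to_target(hubs_a, space_a)
  b <- to_target(hubs_b, space_b)
  matched <- gene_set(intersect(a$mapped$gene_id, b$mapped$gene_id),
                      id_space = target)
  list(matched = matched, match_count = nrow(matched),
       unmapped_a = a$unmapped, unmapped_b = b$unmapped)
}

#' Genes isolated in every network
#'
#' The intersection of the isolated (degree-0) node sets of the networks:
#' seed genes that stay unconnected in every disease-specific network are
#' candidates for under-studied but disease-relevant genes.
#'
#' @param networks List of at least two PPI networks.
#' @param id_space Identifier space of the node names.
#' @return A [gene_set()].
#' @export
common_isolated <- function(networks, id_space = "ensembl_gene") {
  if (length(networks) < 2) abort("need at least two networks")
  iso <- map(networks, ~ isolated_nodes(.x, id_space = id_space)$gene_id)
  gene_set(Reduce(intersect, iso), id_space = id_space)
}

#' Cross-database merge report
#'
#' Maps the node sets of two database-specific networks for the same
#' disease into Ensembl gene space, then reports the intersecting and union
#' node counts, plus the number of intersecting nodes that have no shared
#' edge in both inputs (`unconnected_in_intersection`: degree-0 nodes of the
#' edge-intersection graph restricted to the common node set).
#'
#' @param g_a,g_b PPI networks.
#' @param idmap An [id_map()], or `NULL` when both networks are already
#'   keyed by `target` ids.
#' @param space_a,space_b Id spaces of the two networks' node names.
#' @param target Common id space.
#' @return A one-row tibble with `intersecting_nodes`, `union_nodes` and
#'   `unconnected_in_intersection`.
#' @export
cross_db_merge <- function(g_a, g_b, idmap = NULL,
                           space_a = "ensembl_gene",
                           space_b = "ensembl_gene",
                           target = "ensembl_gene") {
  map_net <- function(g, space) {
    ids <- net_nodes(g)$gene_id
    e <- net_edges(g)
    if (space == target) {
      return(list(nodes = ids, edges = e))
    }
    if (is.null(idmap)) abort("an id map is required for cross-space merges")
    res <- map_ids(gene_set(ids, id_space = space), idmap, target)
    if (nrow(res$mapped) == 0) {
      abort("no network node could be mapped into the target id space")
    }
    lut <- attr(res$mapped, "mapping")
    lut_v <- setNames(lut$target_id, lut$source_id)
    e$id_a <- unname(lut_v[e$id_a])
    e$id_b <- unname(lut_v[e$id_b])
    e <- filter(e, !is.na(.data$id_a), !is.na(.data$id_b))
    list(nodes = res$mapped$gene_id, edges = e)
  }
  a <- map_net(g_a, space_a)
  b <- map_net(g_b, space_b)
  common <- intersect(a$nodes, b$nodes)
  uni <- union(a$nodes, b$nodes)
  key <- function(e) paste(pmin(e$id_a, e$id_b), pmax(e$id_a, e$id_b),
                           sep = "\r")
  shared_edges <- intersect(key(a$edges), key(b$edges))
  touched <- unique(unlist(strsplit(shared_edges, "\r", fixed = TRUE)))
  tibble(intersecting_nodes = length(common),
         union_nodes = length(uni),
         unconnected_in_intersection = sum(!common %in% touched))
}

#' Side-by-side network statistics table
#'
#' One row of topology statistics per network, followed by rows for the
#' merged intersection and merged union of all of them, using the standard
#' column order Nodes, Edges, Clustering Coefficient, Connected Components,
#' Network Diameter, Isolated Nodes.
#'
#' @param networks Named list of PPI networks (names become the `Samples`
#'   column).
#' @return A tibble with `length(networks) + 2` rows.
#' @export
compare_stats_table <- function(networks) {
  if (is.null(names(networks))) {
    names(networks) <- map_chr(networks, function(g) {
      lbl <- igraph::graph_attr(g, "label")
      if (is.null(lbl) || !nzchar(lbl)) "network" else lbl
    })
  }
  all_nets <- c(networks,
                list(`merged intersection` = intersect_networks(networks),
                     `merged union` = union_networks(networks)))
  rows <- imap(all_nets, function(g, nm) {
    s <- compute_stats(g)
    tibble(Samples = nm,
           Nodes = s$n_nodes, Edges = s$n_edges,
           `Clustering Coefficient` = s$clustering_coefficient,
           `Connected Components` = s$n_components,
           `Network Diameter` = s$diameter,
           `Isolated Nodes` = s$n_isolated)
  })
  bind_rows(rows)
}
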