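#' Export a PPI network
#'
#' `write_network_graphml()` writes GraphML with all vertex/edge attributes
#' preserved (attribute names: `symbol`, `is_seed`, `score`, `evidence`).
#' `write_network_sif()` writes a Cytoscape SIF file using node symbols when
#' available (falling back to ids); connected nodes appear as
#' `A<tab>pp<tab>B` lines, isolated nodes as bare single-token lines.
#' `write_network_edgelist()` writes the canonical edge table as TSV.
#'
#' @param g A PPI network.
#' @param path Output path.
#' @return `g`, invisibly.
#' @export
write_network_graphml <- function(g, path) {
  gg <- g
  # graphml cannot carry logical attributes portably; encode as 0/1
  if ("is_seed" %in% igraph::vertex_attr_names(gg)) {
    igraph::V(gg)$is_seed <- as.integer(isTRUE_vec(igraph::V(gg)$is_seed))
  }
  if ("symbol" %in% igraph::vertex_attr_names(gg)) {
    sym <- igraph::V(gg)$symbol
    igraph::V(gg)$symbol <- ifelse(is.na(sym), "", sym)
  }
  if ("evidence" %in% igraph::edge_attr_names(gg)) {
    ev <- igraph::E(gg)$evidence
    igraph::E(gg)$evidence <- ifelse(is.na(ev), "", ev)
  }
  igraph::write_graph(gg, path, format = "graphml")
  invisible(g)
}

#' @rdname write_network_graphml
#' @export
write_network_sif <- function(g, path) {
  nodes <- net_nodes(g)
  disp <- ifelse(is.na(nodes$gene_symbol), nodes$gene_id, nodes$gene_symbol)
  names(disp) <- nodes$gene_id
  e <- net_edges(g)
  lines <- character()
  if (nrow(e) > 0) {
    lines <- paste(disp[e$id_a], "pp", disp[e$id_b], sep = "\t")
  }
  iso <- isolated_nodes(g)$gene_id
  lines <- c(lines, unname(disp[iso]))
  writeLines(lines, path)
  invisible(g)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(g, path) {
  readr::write_tsv(net_edges(g), path)
  invisible(g)
}

#' Read a PPI network from GraphML
#'
#' Inverse of [write_network_graphml()]; restores the `is_seed` logical and
#' `NA` conventions.
#'
#' @param path GraphML file written by this package.
#' @return A PPI network.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if ("is_seed" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$is_seed <- as.logical(as.numeric(igraph::V(g)$is_seed))
  }
  if ("symbol" %in% igraph::vertex_attr_names(g)) {
    sym <- igraph::V(g)$symbol
    igraph::V(g)$symbol <- ifelse(nzchar(sym), sym, NA_character_)
  }
  if ("evidence" %in% igraph::edge_attr_names(g)) {
    ev <- igraph::E(g)$evidence
    igraph::E(g)$evidence <- ifelse(nzchar(ev), ev, NA_character_)
  }
  if ("score" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$score[is.nan(igraph::E(g)$score)] <- NA_real_
  }
  g
}

#' Write interaction records in a given dialect
#'
#' Used by the synthetic generator to emit files bit-compatible with
#' [parse_interactions()].
#'
#' @param records Interaction tibble.
#' @param path Output path.
#' @param dialect `"biogrid_tab"` or `"string_links"`.
#' @return `records`, invisibly.
#' @export
write_interactions <- function(records, path,
                               dialect = c("biogrid_tab", "string_links")) {
  dialect <- match.arg(dialect)
  if (dialect == "biogrid_tab") {
    readr::write_tsv(records[c("id_a", "id_b", "symbol_a", "symbol_b",
                               "taxon_a", "taxon_b", "evidence")], path)
  } else {
    tbl <- tibble(protein1 = records$id_a, protein2 = records$id_b,
                  combined_score = as.integer(round(records$score * 1000)))
    writeLines(c("protein1 protein2 combined_score",
                 paste(tbl$protein1, tbl$protein2, tbl$combined_score)),
               path)
  }
  invisible(records)
}
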