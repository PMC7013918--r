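hub_tbl <- function(ids, space = "ensembl_gene") {
  structure(tibble::tibble(rank = seq_along(ids), gene_id = ids,
                           gene_symbol = NA_character_,
                           degree = rev(seq_along(ids))),
            class = c("hub_list", class(tibble::tibble())))
}

test_that("hub consensus counts cross-database matches after mapping", {
  im <- id_map(tibble::tibble(symbol = sprintf("SYM%02d", 1:10),
                              ensembl_gene = sprintf("ENSG%02d", 1:10)),
               provenance = "toy")
  hubs_symbol <- hub_tbl(sprintf("SYM%02d", 1:10))
  hubs_ensembl <- hub_tbl(c(sprintf("ENSG%02d", 1:6),
                            sprintf("ENSX%02d", 7:10)))
  hc <- hub_consensus(hubs_symbol, hubs_ensembl, im, space_a = "symbol")
  expect_equal(hc$match_count, 6)  # two ten-gene lists sharing six
  expect_setequal(hc$matched$gene_id, sprintf("ENSG%02d", 1:6))
  # identical lists -> full match; disjoint -> empty
  full <- hub_consensus(hubs_ensembl, hubs_ensembl)
  expect_equal(full$match_count, nrow(hubs_ensembl))
  none <- hub_consensus(hub_tbl("ENSG01"), hub_tbl("ENSG99"))
  expect_equal(none$match_count, 0)
  expect_error(hub_consensus(hub_tbl(character()), hubs_ensembl),
               "non-empty")
})

test_that("unmappable hubs are reported rather than dropped", {
  im <- id_map(tibble::tibble(symbol = "SYM01", ensembl_gene = "ENSG01"),
               provenance = "toy")
  hc <- hub_consensus(hub_tbl(c("SYM01", "LOST"), "symbol"),
                      hub_tbl("ENSG01"), im, space_a = "symbol")
  expect_equal(hc$unmapped_a, "LOST")
  expect_equal(hc$match_count, 1)
})

test_that("common isolated genes are the intersection of isolated sets", {
  g1 <- net_from_pairs("A-B", extra_nodes = c("X", "Y", "P1"))
  g2 <- net_from_pairs("A-C", extra_nodes = c("X", "Y", "P2"))
  g3 <- net_from_pairs("B-C", extra_nodes = c("X", "Y"))
  ci <- common_isolated(list(g1, g2, g3))
  expect_setequal(ci$gene_id, c("X", "Y"))
  for (g in list(g1, g2, g3)) {
    expect_true(all(ci$gene_id %in% isolated_nodes(g)$gene_id))
  }
  connected <- net_from_pairs(c("X-Y", "A-B"))
  expect_equal(nrow(common_isolated(list(g1, connected))), 0)
  expect_error(common_isolated(list(g1)), "two")
})

test_that("cross-database merge counts obey inclusion-exclusion", {
  g_a <- net_from_pairs(c("N1-N2", "N2-N3"),
                        extra_nodes = c("N4", "N5", "N6"))  # 6 nodes
  g_b <- net_from_pairs(c("N1-N2", "N7-N8"), extra_nodes = "N3")  # 5 nodes
  rep <- cross_db_merge(g_a, g_b)
  expect_equal(rep$intersecting_nodes, 3)
  expect_equal(rep$union_nodes, 8)
  expect_equal(rep$intersecting_nodes + rep$union_nodes,
               igraph::vcount(g_a) + igraph::vcount(g_b))
  # shared edge N1-N2 connects those two; N3 shares no edge
  expect_equal(rep$unconnected_in_intersection, 1)

  same <- cross_db_merge(g_a, g_a)
  expect_equal(same$intersecting_nodes, same$union_nodes)
  expect_equal(same$unconnected_in_intersection, 3)  # N4..N6 edgeless

  # shared nodes but edge-disjoint graphs: all intersecting unconnected
  e_a <- net_from_pairs(c("M1-M2"))
  e_b <- net_from_pairs(c("M1-M3", "M2-M3"))
  rep2 <- cross_db_merge(e_a, e_b)
  expect_equal(rep2$unconnected_in_intersection, rep2$intersecting_nodes)
})

test_that("merging across id spaces goes through the id map", {
  im <- id_map(tibble::tibble(symbol = c("S1", "S2"),
                              ensembl_gene = c("ENSG01", "ENSG02")),
               provenance = "toy")
  g_sym <- net_from_pairs("S1-S2")
  g_ens <- net_from_pairs("ENSG01-ENSG02")
  rep <- cross_db_merge(g_sym, g_ens, im, space_a = "symbol")
  expect_equal(rep$intersecting_nodes, 2)
  expect_equal(rep$unconnected_in_intersection, 0)
  g_lost <- net_from_pairs("Q1-Q2")
  expect_error(cross_db_merge(g_lost, g_ens, im, space_a = "symbol"),
               "mapped")
})

test_that("the comparison table has the canonical shape and bounds", {
  nets <- list(glioma = net_from_pairs(c("A-B", "B-C")),
               gbm = net_from_pairs(c("A-B", "C-D")),
               astro = net_from_pairs(c("A-B", "B-C", "A-C")))
  tbl <- compare_stats_table(nets)
  expect_equal(nrow(tbl), 5)  # 3 networks + intersection + union
  expect_equal(names(tbl),
               c("Samples", "Nodes", "Edges", "Clustering Coefficient",
                 "Connected Components", "Network Diameter",
                 "Isolated Nodes"))
  inter <- tbl$Nodes[tbl$Samples == "merged intersection"]
  expect_true(all(inter <= tbl$Nodes[1:3]))
  uni <- tbl$Nodes[tbl$Samples == "merged union"]
  expect_true(all(uni >= tbl$Nodes[1:3]))
})
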