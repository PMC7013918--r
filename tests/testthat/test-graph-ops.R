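test_that("network intersection keeps shared nodes and shared edges", {
  g1 <- net_from_pairs(c("A-B", "B-C"))
  g2 <- net_from_pairs(c("B-C", "C-D"))
  gi <- intersect_networks(list(g1, g2))
  expect_setequal(igraph::V(gi)$name, c("B", "C"))
  expect_equal(nrow(net_edges(gi)), 1)
  # idempotence and disjoint inputs
  gii <- intersect_networks(list(g1, g1))
  expect_equal(net_edges(gii), net_edges(g1))
  gd <- intersect_networks(list(g1, net_from_pairs("X-Y")))
  expect_equal(igraph::vcount(gd), 0)
  expect_error(intersect_networks(list(g1)), "two")
})

test_that("node-mode intersection induces edges from the first input", {
  g1 <- net_from_pairs(c("A-B", "B-C"))
  g2 <- net_from_pairs(c("A-C", "C-B"))  # same nodes, different edges
  gi <- intersect_networks(list(g1, g2), mode = "node")
  expect_setequal(igraph::V(gi)$name, c("A", "B", "C"))
  expect_equal(nrow(net_edges(gi)), 2)  # A-B and B-C survive from g1
})

test_that("network union merges nodes and edges, max score wins", {
  tri <- net_from_pairs(c("A-B", "B-C", "A-C"))
  pair <- net_from_pairs("D-E")
  gu <- union_networks(list(tri, pair))
  expect_equal(igraph::vcount(gu), 5)
  expect_equal(igraph::ecount(gu), 4)
  expect_gte(igraph::vcount(gu), igraph::vcount(tri))
  expect_equal(net_edges(union_networks(list(tri, tri))), net_edges(tri))
  s1 <- net_from_pairs("A-B", scores = 0.91)
  s2 <- net_from_pairs("A-B", scores = 0.95)
  expect_equal(net_edges(union_networks(list(s1, s2)))$score, 0.95)
})

test_that("difference subtracts nodes and induces the remaining subgraph", {
  tri <- net_from_pairs(c("A-B", "B-C", "A-C"), label = "tri")
  ref <- net_from_pairs(character(), extra_nodes = "C")
  gd <- difference_network(tri, ref)
  expect_setequal(igraph::V(gd)$name, c("A", "B"))
  expect_equal(nrow(net_edges(gd)), 1)
  expect_equal(igraph::graph_attr(gd, "label"), "tri_unique")
  expect_equal(igraph::vcount(difference_network(tri, tri)), 0)
  empty_ref <- ppi_network()
  expect_equal(net_edges(difference_network(tri, empty_ref)),
               net_edges(tri))
})

test_that("closed-form statistics hold for cliques, paths, stars, mixtures", {
  clique4 <- net_from_pairs(c("A-B", "A-C", "A-D", "B-C", "B-D", "C-D"))
  s <- compute_stats(clique4)
  expect_equal(s$clustering_coefficient, 1)
  expect_equal(s$diameter, 1L)
  expect_equal(s$n_components, 1L)
  expect_equal(s$n_isolated, 0L)

  path4 <- net_from_pairs(c("A-B", "B-C", "C-D"))
  s <- compute_stats(path4)
  expect_equal(s$clustering_coefficient, 0)
  expect_equal(s$diameter, 3L)

  mix <- net_from_pairs(c("A-B", "B-C", "A-C"),
                        extra_nodes = c("X", "Y", "Z"))
  s <- compute_stats(mix)
  expect_equal(s$n_components, 4L)
  expect_equal(s$n_isolated, 3L)
  expect_equal(s$diameter, 1L)
  expect_equal(s$clustering_coefficient, 0.5)  # three 1s, three 0s

  edgeless <- ppi_network(nodes = tibble::tibble(gene_id = c("A", "B")))
  s <- compute_stats(edgeless)
  expect_equal(s$diameter, 0L)
  expect_equal(s$n_components, 2L)

  star <- net_from_pairs(paste0("H-", sprintf("L%d", 1:9)))
  expect_equal(compute_stats(star)$diameter, 2L)
  expect_equal(top_hubs(star, k = 1)$gene_id, "H")
  expect_equal(top_hubs(star, k = 1)$degree, 9L)
})

test_that("statistics agree with the naive BFS/triangle oracle", {
  set.seed(5)
  for (rep in 1:12) {
    n <- sample(4:40, 1)
    g <- random_network(n, runif(1, 0.05, 0.3))
    got <- compute_stats(g)
    want <- oracle_stats(net_edges(g), net_nodes(g)$gene_id)
    expect_equal(got$n_nodes, want$n_nodes)
    expect_equal(got$n_edges, want$n_edges)
    expect_equal(got$clustering_coefficient, want$clustering_coefficient,
                 tolerance = 1e-12)
    expect_equal(got$n_components, want$n_components)
    expect_equal(got$diameter, want$diameter)
    expect_equal(got$n_isolated, want$n_isolated)
  }
})

test_that("hub ranking is deterministic with documented tie-breaks", {
  # two nodes tied at the k boundary: smaller id included
  g <- net_from_pairs(c("Z-A", "Z-B", "Y-A", "Y-B", "X-A"))
  hubs <- top_hubs(g, k = 3)
  # A has degree 3; B, Y, Z are tied at 2 and the k boundary cuts the tie
  # lexicographically: B and Y enter, Z does not
  expect_equal(hubs$gene_id, c("A", "B", "Y"))
  expect_equal(top_hubs(g, k = 100)$gene_id,
               top_hubs(g, k = igraph::vcount(g))$gene_id)
  expect_identical(top_hubs(g, 3), top_hubs(g, 3))
  expect_error(top_hubs(g, k = 0), "at least 1")
})

test_that("isolated node extraction matches degree zero", {
  g <- net_from_pairs(c("A-B", "B-C", "A-C"), extra_nodes = "X")
  expect_equal(isolated_nodes(g)$gene_id, "X")
  expect_equal(nrow(isolated_nodes(net_from_pairs(c("A-B")))), 0)
})

test_that("networks round-trip through GraphML with attributes", {
  rec <- tibble::tibble(
    id_a = c("A", "B"), id_b = c("B", "C"),
    symbol_a = c("SA", "SB"), symbol_b = c("SB", "SC"),
    taxon_a = 9606L, taxon_b = 9606L,
    score = c(0.95, NA), evidence = c("Two-hybrid", NA))
  g <- build_first_order_network(rec, gene_set(c("A", "B", "Q")),
                                 label = "rt")
  path <- tempfile(fileext = ".graphml")
  write_network_graphml(g, path)
  g2 <- read_network_graphml(path)
  expect_equal(net_edges(g2), net_edges(g))
  expect_equal(net_nodes(g2), net_nodes(g))
  # SIF and edge-list exports are well-formed
  sif <- tempfile(fileext = ".sif")
  write_network_sif(g, sif)
  lines <- readLines(sif)
  expect_true(any(grepl("\tpp\t", lines)))
  expect_true("Q" %in% lines)  # isolated node as a bare line
})
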