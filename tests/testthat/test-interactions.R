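write_string_fixture <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 combined_score", lines), path)
  path
}

write_biogrid_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(paste("id_a", "id_b", "symbol_a", "symbol_b",
                     "taxon_a", "taxon_b", "evidence", sep = "\t"), lines),
             path)
  path
}

test_that("string_links scores are rescaled from the native 0-1000 scale", {
  path <- write_string_fixture(c("P1 P2 950", "P2 P3 899"))
  rec <- parse_interactions(path, "string_links")
  expect_equal(rec$score, c(0.95, 0.899))
  expect_true(all(rec$taxon_a == 9606L))
  expect_equal(attr(rec, "dialect"), "string_links")
  # empty file with a valid header parses to zero records
  expect_equal(nrow(parse_interactions(write_string_fixture(character()),
                                       "string_links")), 0)
  expect_error(parse_interactions(write_string_fixture("P1 P2 weird"),
                                  "string_links"), "line 2")
})

test_that("biogrid_tab rows carry both taxa and no score", {
  path <- write_biogrid_fixture("E1\tE2\tA\tB\t9606\t10090\tTwo-hybrid")
  rec <- parse_interactions(path, "biogrid_tab")
  expect_equal(rec$taxon_a, 9606L)
  expect_equal(rec$taxon_b, 10090L)
  expect_true(is.na(rec$score))
  bad <- write_biogrid_fixture("E1\tE2\tA\tB\tnot-a-taxon\t9606\tx")
  expect_error(parse_interactions(bad, "biogrid_tab"), "line 2")
})

test_that("first-order construction applies score, taxon and seed predicates", {
  rec <- tibble::tibble(
    id_a = c("A", "B", "A"), id_b = c("B", "C", "D"),
    symbol_a = NA_character_, symbol_b = NA_character_,
    taxon_a = 9606L, taxon_b = 9606L,
    score = c(0.95, 0.99, 0.50), evidence = NA_character_)
  g <- build_first_order_network(rec, gene_set("A"), min_score = 0.9)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  ed <- net_edges(g)
  expect_equal(nrow(ed), 1)
  expect_equal(c(ed$id_a, ed$id_b), c("A", "B"))
})

test_that("seeds with no surviving records stay as isolated nodes", {
  rec <- tibble::tibble(id_a = "X", id_b = "Y",
                        symbol_a = NA_character_, symbol_b = NA_character_,
                        taxon_a = 9606L, taxon_b = 9606L,
                        score = 0.99, evidence = NA_character_)
  g <- build_first_order_network(rec, gene_set(c("X", "E")))
  expect_true("E" %in% igraph::V(g)$name)
  expect_equal(isolated_nodes(g)$gene_id, "E")
  expect_setequal(network_seeds(g), c("X", "E"))
})

test_that("taxonomy filtering requires both interactors to match", {
  rec <- tibble::tibble(
    id_a = c("S", "S"), id_b = c("H", "M"),
    symbol_a = NA_character_, symbol_b = NA_character_,
    taxon_a = c(9606L, 9606L), taxon_b = c(9606L, 10090L),
    score = NA_real_, evidence = NA_character_)
  g <- build_first_order_network(rec, gene_set("S"), taxon = 9606)
  expect_setequal(igraph::V(g)$name, c("S", "H"))
  unfiltered <- build_first_order_network(rec, gene_set("S"))
  expect_gt(igraph::vcount(unfiltered), igraph::vcount(g))
})

test_that("duplicate records collapse to one edge keeping the best score", {
  rec <- tibble::tibble(
    id_a = c("A", "B"), id_b = c("B", "A"),
    symbol_a = NA_character_, symbol_b = NA_character_,
    taxon_a = 9606L, taxon_b = 9606L,
    score = c(0.91, 0.95), evidence = NA_character_)
  g <- build_first_order_network(rec, gene_set("A"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$score, 0.95)
})

test_that("raising min_score only ever shrinks the network", {
  set.seed(11)
  rec <- tibble::tibble(
    id_a = sample(sprintf("G%02d", 1:12), 60, replace = TRUE),
    id_b = sample(sprintf("G%02d", 1:12), 60, replace = TRUE),
    symbol_a = NA_character_, symbol_b = NA_character_,
    taxon_a = 9606L, taxon_b = 9606L,
    score = runif(60), evidence = NA_character_)
  rec <- rec[rec$id_a != rec$id_b, ]
  seeds <- gene_set(c("G01", "G02", "G03"))
  prev_nodes <- Inf; prev_edges <- Inf
  for (ms in c(0, 0.3, 0.6, 0.9)) {
    g <- build_first_order_network(rec, seeds, min_score = ms)
    expect_lte(igraph::vcount(g), prev_nodes)
    expect_lte(igraph::ecount(g), prev_edges)
    # first-order property: every edge touches a seed
    ed <- net_edges(g)
    expect_true(all(ed$id_a %in% seeds$gene_id |
                      ed$id_b %in% seeds$gene_id))
    # seeds always present; graph simple
    expect_true(all(seeds$gene_id %in% igraph::V(g)$name))
    expect_false(igraph::any_multiple(g))
    expect_false(any(igraph::which_loop(g)))
    prev_nodes <- igraph::vcount(g); prev_edges <- igraph::ecount(g)
  }
  expect_error(build_first_order_network(rec, seeds, min_score = 1.2),
               "0, 1")
})

test_that("rebuilding a network from its own edge list is idempotent", {
  set.seed(3)
  g <- random_network(20, 0.2)
  g2 <- ppi_network(net_edges(g), net_nodes(g))
  expect_equal(net_edges(g2), net_edges(g))
  expect_equal(net_nodes(g2), net_nodes(g))
})
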