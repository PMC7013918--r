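test_that("map_ids resolves what it can and reports the rest", {
  im <- toy_idmap()
  # 10 symbols, 8 resolvable: the classic >80% mapping experience
  genes <- gene_set(c(sprintf("SYM%02d", 1:8), "NOPE1", "NOPE2"),
                    id_space = "symbol")
  res <- map_ids(genes, im, "ensembl_gene")
  expect_equal(nrow(res$mapped), 8)
  expect_setequal(res$unmapped, c("NOPE1", "NOPE2"))
  # conservation: every input id accounted for exactly once
  mapping <- attr(res$mapped, "mapping")
  expect_equal(sum(!is.na(mapping$target_id)) + length(res$unmapped),
               nrow(genes))
})

test_that("symbol lookups are case-insensitive and whitespace-tolerant", {
  im <- toy_idmap()
  res <- map_ids(gene_set(c("sym01", " Sym02 "), id_space = "symbol"),
                 im, "ensembl_gene")
  expect_setequal(res$mapped$gene_id, c("ENSG01", "ENSG02"))
})

test_that("mapping to the source space is an error; empty map maps nothing", {
  im <- toy_idmap()
  genes <- gene_set("SYM01", id_space = "symbol")
  expect_error(map_ids(genes, im, "symbol"), "source")
  empty <- id_map(tibble::tibble(symbol = character()))
  res <- map_ids(genes, empty, "ensembl_gene")
  expect_equal(nrow(res$mapped), 0)
  expect_equal(res$unmapped, "SYM01")
})

test_that("ambiguous resolutions use precedence then smallest target, logged", {
  im <- id_map(tibble::tibble(symbol = c("DUP", "DUP"),
                              ensembl_gene = c("ENSG09", "ENSG02")),
               provenance = "one")
  res <- map_ids(gene_set("DUP", id_space = "symbol"), im, "ensembl_gene")
  expect_equal(res$mapped$gene_id, "ENSG02")
  expect_equal(nrow(res$ambiguous), 1)
})

test_that("merging disjoint partial maps adds their coverage", {
  universe <- sprintf("SYM%02d", 1:20)
  map_a <- id_map(tibble::tibble(symbol = universe[1:8],
                                 ensembl_gene = sprintf("ENSG%02d", 1:8)),
                  provenance = "a")
  map_b <- id_map(tibble::tibble(symbol = universe[9:17],
                                 ensembl_gene = sprintf("ENSG%02d", 9:17)),
                  provenance = "b")
  merged <- merge_idmaps(list(map_a, map_b))
  res <- map_ids(gene_set(universe, id_space = "symbol"),
                 merged, "ensembl_gene")
  expect_equal(nrow(res$mapped), 17)  # 40% + disjoint 45% -> 85%
  # resolution rate of a merge is never below the best input
  res_a <- map_ids(gene_set(universe, id_space = "symbol"),
                   map_a, "ensembl_gene")
  expect_gte(nrow(res$mapped), nrow(res_a$mapped))
  # merging a map with itself changes nothing
  expect_equal(nrow(merge_idmaps(list(map_a, map_a))), nrow(map_a))
})

test_that("merge conflicts resolve to the first-listed source and are logged", {
  map_a <- id_map(tibble::tibble(symbol = "TP53", ensembl_gene = "ENSG01"),
                  provenance = "first")
  map_b <- id_map(tibble::tibble(symbol = "TP53", ensembl_gene = "ENSG99"),
                  provenance = "second")
  merged <- merge_idmaps(list(map_a, map_b))
  res <- map_ids(gene_set("TP53", id_space = "symbol"),
                 merged, "ensembl_gene")
  expect_equal(res$mapped$gene_id, "ENSG01")
  conflicts <- attr(merged, "conflicts")
  expect_equal(conflicts$kept, "ENSG01")
  expect_equal(conflicts$dropped, "ENSG99")
})

test_that("manual patches fill holes, take precedence, and log overrides", {
  holes <- id_map(tibble::tibble(
    symbol = sprintf("SYM%02d", 1:40),
    ensembl_gene = c(sprintf("ENSG%02d", 1:10), rep(NA, 30))),
    provenance = "auto")
  genes <- gene_set(sprintf("SYM%02d", 1:40), id_space = "symbol")
  before <- map_ids(genes, holes, "ensembl_gene")
  expect_equal(length(before$unmapped), 30)
  patches <- tibble::tibble(symbol = sprintf("SYM%02d", 11:40),
                            ensembl_gene = sprintf("ENSG%02d", 11:40))
  patched <- manual_patch(holes, patches)
  after <- map_ids(genes, patched, "ensembl_gene")
  expect_equal(length(after$unmapped), 0)
  expect_true(all(patched$provenance[seq_len(30)] == "manual"))

  # identity on empty patch list
  expect_identical(manual_patch(holes, tibble::tibble()), holes)
  # an override wins and is logged
  over <- manual_patch(holes, tibble::tibble(symbol = "SYM01",
                                             ensembl_gene = "ENSG77"))
  res <- map_ids(gene_set("SYM01", id_space = "symbol"),
                 over, "ensembl_gene")
  expect_equal(res$mapped$gene_id, "ENSG77")
  expect_true("SYM01" %in% attr(over, "overrides")$key)
  # malformed patch rows are rejected
  expect_error(manual_patch(holes, tibble::tibble(symbol = "X")),
               "malformed patch")
})

test_that("round trips through unambiguous maps restore the original ids", {
  im <- toy_idmap()
  genes <- gene_set(sprintf("SYM%02d", 1:8), id_space = "symbol")
  fwd <- map_ids(genes, im, "ensembl_gene")
  back <- map_ids(fwd$mapped, im, "symbol")
  expect_setequal(back$mapped$gene_id, genes$gene_id)
})
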