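# Small fixtures built in code at test time.

write_expr_fixture <- function(rows, dir = tempfile("expr")) {
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "expr.tsv")
  writeLines(c("Gene ID\tGene Name\tglioma", rows), path)
  path
}

toy_annotations <- function() {
  annotation_table(
    entries = tibble::tribble(
      ~gene_id, ~accession,
      "G1", "GO:0000001",
      "G2", "GO:0000001",
      "G3", "GO:0000002",
      "G4", "GO:0000003",
      "G2", "GO:0000002"),
    terms = tibble::tribble(
      ~accession, ~name, ~namespace,
      "GO:0000001", "positive regulation of cell proliferation",
      "biological_process",
      "GO:0000002", "apoptotic process", "biological_process",
      "GO:0000003", "Proliferation of glial cells", "biological_process"))
}

# path A-B-C-D etc. from a compact spec like c("A-B", "B-C")
net_from_pairs <- function(pairs, extra_nodes = character(), label = "toy",
                           scores = NULL) {
  sp <- strsplit(pairs, "-", fixed = TRUE)
  edges <- tibble::tibble(id_a = vapply(sp, `[`, "", 1),
                          id_b = vapply(sp, `[`, "", 2))
  if (!is.null(scores)) edges$score <- scores
  nodes <- tibble::tibble(gene_id = unique(c(edges$id_a, edges$id_b,
                                             extra_nodes)))
  ppi_network(edges, nodes, label = label)
}

toy_idmap <- function() {
  id_map(tibble::tibble(
    ensembl_gene = sprintf("ENSG%02d", 1:8),
    ensembl_protein = sprintf("ENSP%02d", 1:8),
    entrez = as.character(101:108),
    symbol = sprintf("SYM%02d", 1:8)),
    provenance = "toy")
}
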