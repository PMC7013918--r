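#' Read a gene expression table
#'
#' Reads an Expression Atlas style TSV: one row per gene, a gene-id column,
#' a gene-symbol column, and one numeric FPKM column per condition. Blank
#' cells become `NA` (explicitly missing, never zero), so that genes without
#' an observed value can never pass an expression cutoff.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param id_col,symbol_col Names of the gene-id and gene-symbol columns.
#' @param conditions Optional character vector naming the condition columns to
#'   keep; by default every column other than `id_col`/`symbol_col` is treated
#'   as a condition.
#'
#' @return A tibble with columns `gene_id`, `gene_symbol` and one numeric
#'   column per condition, carrying attribute `conditions`.
#' @export
read_expression_table <- function(path, id_col = "Gene ID",
                                  symbol_col = "Gene Name",
                                  conditions = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  for (col in c(id_col, symbol_col)) {
    if (!col %in% names(tbl)) {
      abort(sprintf("expression table %s has no column '%s'", path, col))
    }
  }
  cond_cols <- conditions %||% setdiff(names(tbl), c(id_col, symbol_col))
  missing_cond <- setdiff(cond_cols, names(tbl))
  if (length(missing_cond) > 0) {
    abort(sprintf("expression table %s has no condition column '%s'",
                  path, missing_cond[1]))
  }
  if (length(cond_cols) == 0) {
    abort(sprintf("expression table %s has no condition columns", path))
  }
  out <- tibble(gene_id = tbl[[id_col]], gene_symbol = tbl[[symbol_col]])
  if (anyNA(out$gene_id)) abort(sprintf("empty gene id in %s", path))
  dup <- unique(out$gene_id[duplicated(out$gene_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated gene_id rows in %s: %s", path,
                  paste(head(dup, 5), collapse = ", ")))
  }
  for (col in cond_cols) {
    vals <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(!is.na(tbl[[col]]) & is.na(vals))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric expression value in column '%s', row %d",
                    col, bad[1]))
    }
    neg <- which(!is.na(vals) & vals < 0)
    if (length(neg) > 0) {
      abort(sprintf("negative expression value in column '%s', row %d",
                    col, neg[1]))
    }
    out[[col]] <- vals
  }
  attr(out, "conditions") <- cond_cols
  out
}

#' Filter genes by an expression cutoff
#'
#' Keeps genes whose expression under `condition` is at least `cutoff` FPKM.
#' Values strictly below the cutoff are removed (so a gene at exactly the
#' cutoff is kept), and missing values never pass. The default of 3 FPKM
#' corresponds to roughly 10 TPM.
#'
#' @param tbl An expression table from [read_expression_table()].
#' @param condition Name of the condition column to filter on.
#' @param cutoff Minimum FPKM retained (default 3).
#' @param id_space Identifier space of the table's `gene_id` column.
#' @return A [gene_set()] of the retained genes.
#' @export
filter_by_cutoff <- function(tbl, condition, cutoff = 3,
                             id_space = "ensembl_gene") {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0) {
    abort("cutoff must be a single non-negative number")
  }
  if (!condition %in% names(tbl)) {
    abort(sprintf("unknown condition column '%s'", condition))
  }
  vals <- tbl[[condition]]
  keep <- !is.na(vals) & vals >= cutoff
  gene_set(tbl$gene_id[keep], id_space = id_space,
           symbols = tbl$gene_symbol[keep])
}

#' Read a differentially-expressed-genes table
#'
#' Reads a DEG table (one row per gene with a log2 fold change and a raw
#' p-value), the form in which IDH-mutant versus wild-type comparisons are
#' distributed.
#'
#' @param path Tab-separated file with a header row.
#' @param id_col,symbol_col,lfc_col,p_col Column names.
#' @return A tibble with columns `gene_id`, `gene_symbol`, `log2_fold_change`
#'   and `p_value`.
#' @export
read_deg_table <- function(path, id_col = "Gene ID", symbol_col = "Gene Name",
                           lfc_col = "log2foldchange", p_col = "p-value") {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  for (col in c(id_col, symbol_col, lfc_col, p_col)) {
    if (!col %in% names(tbl)) {
      abort(sprintf("DEG table %s has no column '%s'", path, col))
    }
  }
  out <- tibble(gene_id = tbl[[id_col]],
                gene_symbol = tbl[[symbol_col]],
                log2_fold_change = as.numeric(tbl[[lfc_col]]),
                p_value = as.numeric(tbl[[p_col]]))
  bad <- which(!is.na(out$p_value) & (out$p_value < 0 | out$p_value > 1))
  if (length(bad) > 0) {
    abort(sprintf("p-value outside [0, 1] in %s, row %d", path, bad[1]))
  }
  out
}

#' Filter a DEG table to significantly upregulated genes
#'
#' Keeps genes with `p_value < p_max` and `log2_fold_change >= lfc_min`.
#' The p-value comparison is strict and the fold-change comparison inclusive,
#' matching the common DESeq reporting convention (p < 0.05, log2FC cutoff 1,
#' upregulated only — the sign of the fold change matters).
#'
#' @param tbl A DEG tibble from [read_deg_table()].
#' @param p_max Exclusive upper bound on the p-value (default 0.05).
#' @param lfc_min Inclusive lower bound on log2 fold change (default 1).
#' @param id_space Identifier space of `gene_id`.
#' @return A [gene_set()] of upregulated genes.
#' @export
filter_upregulated <- function(tbl, p_max = 0.05, lfc_min = 1,
                               id_space = "ensembl_gene") {
  if (!is.finite(p_max) || !is.finite(lfc_min)) {
    abort("p_max and lfc_min must be finite")
  }
  keep <- !is.na(tbl$p_value) & !is.na(tbl$log2_fold_change) &
    tbl$p_value < p_max & tbl$log2_fold_change >= lfc_min
  gene_set(tbl$gene_id[keep], id_space = id_space,
           symbols = tbl$gene_symbol[keep])
}

#' Filter a gene set by a GO term-name keyword
#'
#' Keeps a gene if it is annotated to at least one GO term whose *name*
#' contains `keyword` as a case-insensitive substring. Filtering is by a word
#' (e.g. "proliferation"), not by a GO accession, so related terms such as
#' "positive regulation of cell population proliferation" all match.
#'
#' @param genes A [gene_set()].
#' @param annotations An [annotation_table()] covering the gene set's id
#'   space.
#' @param keyword Non-empty keyword (default `"proliferation"`).
#' @return A [gene_set()] restricted to genes with a matching annotation.
#' @export
filter_by_go_keyword <- function(genes, annotations,
                                 keyword = "proliferation") {
  if (!is.character(keyword) || length(keyword) != 1 || !nzchar(keyword)) {
    abort("keyword must be a single non-empty string")
  }
  hit_terms <- annotations$terms$accession[
    stringr::str_detect(annotations$terms$name,
                        stringr::fixed(keyword, ignore_case = TRUE))]
  hit_genes <- unique(annotations$entries$gene_id[
    annotations$entries$accession %in% hit_terms])
  keep <- genes$gene_id %in% hit_genes
  new_gene_set(genes[keep, , drop = FALSE], id_space(genes))
}
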