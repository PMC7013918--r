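#' Gene sets
#'
#' A gene set is a tibble with a `gene_id` column (and optionally
#' `gene_symbol`), carrying an `id_space` attribute naming the identifier
#' space of its members: one of `"ensembl_gene"`, `"ensembl_protein"`,
#' `"entrez"` or `"symbol"`. Gene sets are what the filtering stages emit and
#' what network construction consumes as seeds.
#'
#' @param ids Character vector of gene identifiers (duplicates are collapsed).
#' @param id_space Identifier space of the members.
#' @param symbols Optional character vector of human-readable symbols,
#'   parallel to `ids`.
#'
#' @return A tibble of class `gene_set` with columns `gene_id` and (if
#'   supplied) `gene_symbol`, sorted by `gene_id`.
#' @export
#' @examples
#' gene_set(c("ENSG00000141510", "ENSG00000012048"))
gene_set <- function(ids, id_space = "ensembl_gene", symbols = NULL) {
  id_space <- match.arg(id_space, c("ensembl_gene", "ensembl_protein",
                                    "entrez", "symbol"))
  ids <- as.character(ids)
  if (anyNA(ids)) abort("gene_set ids must not contain NA")
  out <- tibble(gene_id = ids)
  if (!is.null(symbols)) out$gene_symbol <- as.character(symbols)
  out <- distinct(out, .data$gene_id, .keep_all = TRUE)
  out <- arrange(out, .data$gene_id)
  new_gene_set(out, id_space)
}

new_gene_set <- function(tbl, id_space) {
  attr(tbl, "id_space") <- id_space
  class(tbl) <- unique(c("gene_set", class(tbl)))
  tbl
}

#' @export
print.gene_set <- function(x, ...) {
  cat("# Gene set:", nrow(x), "genes in id space", id_space(x), "\n")
  NextMethod()
}

#' Identifier space of a gene set
#' @param x A `gene_set`.
#' @return A string naming the id space.
#' @export
id_space <- function(x) attr(x, "id_space") %||% "ensembl_gene"

#' Write a gene set as plain text
#'
#' Writes the one-gene-per-line seed list used as input for network
#' construction, and optionally a two-column (id, symbol) TSV.
#'
#' @param x A `gene_set`.
#' @param path Output path for the one-id-per-line list.
#' @param tsv_path Optional path for a two-column `gene_id`/`gene_symbol` TSV.
#' @return `x`, invisibly.
#' @export
write_gene_set <- function(x, path, tsv_path = NULL) {
  writeLines(x$gene_id, path)
  if (!is.null(tsv_path)) {
    tbl <- tibble(gene_id = x$gene_id,
                  gene_symbol = if ("gene_symbol" %in% names(x))
                    x$gene_symbol else NA_character_)
    readr::write_tsv(tbl, tsv_path)
  }
  invisible(x)
}
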