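#' Gene Ontology annotation tables
#'
#' An annotation table pairs genes with GO terms. It is a list of two
#' tibbles: `entries` with columns `gene_id` and `accession` (unique pairs),
#' and `terms` with columns `accession`, `name` and `namespace`
#' (`biological_process`, `molecular_function` or `cellular_component`).
#' Only direct annotations are stored; no propagation along the GO graph is
#' performed anywhere in the package.
#'
#' @param entries Tibble/data frame with `gene_id` and `accession`.
#' @param terms Tibble/data frame with `accession`, `name`, `namespace`.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(entries, terms) {
  entries <- distinct(as_tibble(entries)[c("gene_id", "accession")])
  terms <- distinct(as_tibble(terms)[c("accession", "name", "namespace")],
                    .data$accession, .keep_all = TRUE)
  bad_acc <- terms$accession[!grepl("^GO:\\d{7}$", terms$accession)]
  if (length(bad_acc) > 0) {
    abort(sprintf("malformed GO accession: %s", bad_acc[1]))
  }
  if (any(!nzchar(terms$name))) abort("GO term names must be non-empty")
  ns_ok <- terms$namespace %in% c("biological_process",
                                  "molecular_function",
                                  "cellular_component")
  if (!all(ns_ok)) {
    abort(sprintf("unknown GO namespace '%s'", terms$namespace[!ns_ok][1]))
  }
  orphan <- setdiff(entries$accession, terms$accession)
  if (length(orphan) > 0) {
    abort(sprintf("annotation entry references unknown term %s", orphan[1]))
  }
  structure(list(entries = entries, terms = terms),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("# GO annotation table:", nrow(x$entries), "gene-term pairs,",
      nrow(x$terms), "terms\n")
  invisible(x)
}

#' Read GO annotations
#'
#' Two dialects are supported. The two-file pair dialect takes a gene-to-term
#' TSV (columns `gene_id`, `accession`) plus a term-metadata TSV (columns
#' `accession`, `name`, `namespace`). The GMT dialect takes a single file
#' with one term per line: accession, tab, description, tab, then the
#' annotated gene ids tab-separated; GMT carries no namespace so all terms
#' are recorded as `biological_process`.
#'
#' @param path Gene-to-term TSV, or GMT file when `dialect = "gmt"`.
#' @param terms_path Term metadata TSV (pair dialect only).
#' @param dialect `"pair"` or `"gmt"`.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, terms_path = NULL,
                             dialect = c("pair", "gmt")) {
  dialect <- match.arg(dialect)
  if (dialect == "pair") {
    if (is.null(terms_path)) abort("pair dialect needs terms_path")
    entries <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
    terms <- readr::read_tsv(terms_path, col_types = "ccc", progress = FALSE)
    annotation_table(entries, terms)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3)
    if (length(short) > 0) {
      abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
    }
    terms <- tibble(accession = map_chr(parts, 1),
                    name = map_chr(parts, 2),
                    namespace = "biological_process")
    entries <- tibble(
      accession = rep(terms$accession, lengths(parts) - 2L),
      gene_id = unlist(map(parts, ~ .x[-(1:2)])))
    annotation_table(entries[c("gene_id", "accession")], terms)
  }
}

#' Write an annotation table in the two-file pair dialect
#' @param x An [annotation_table()].
#' @param path,terms_path Output TSV paths for entries and term metadata.
#' @return `x`, invisibly.
#' @export
write_annotations <- function(x, path, terms_path) {
  readr::write_tsv(x$entries, path)
  readr::write_tsv(x$terms, terms_path)
  invisible(x)
}
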