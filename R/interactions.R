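#' Parse an interaction table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`biogrid_tab`}{Tab-separated with header columns `id_a`, `id_b`,
#'     `symbol_a`, `symbol_b`, `taxon_a`, `taxon_b` (NCBI taxonomy integers)
#'     and `evidence` (experimental system). This dialect carries no
#'     confidence score: `score` is `NA` on every record.}
#'   \item{`string_links`}{Whitespace-separated with header columns
#'     `protein1`, `protein2`, `combined_score`. The combined score is on the
#'     native integer 0--1000 scale and is rescaled to `[0, 1]` by dividing
#'     by 1000; both taxa default to the file-level `organism`.}
#' }
#'
#' @param path Input file.
#' @param dialect `"biogrid_tab"` or `"string_links"`.
#' @param organism File-level NCBI taxon for `string_links` (default 9606,
#'   human).
#' @return A tibble of interaction records with columns `id_a`, `id_b`,
#'   `symbol_a`, `symbol_b`, `taxon_a`, `taxon_b`, `score`, `evidence`.
#' @export
parse_interactions <- function(path, dialect = c("biogrid_tab",
                                                 "string_links"),
                               organism = 9606L) {
  dialect <- match.arg(dialect)
  if (dialect == "biogrid_tab") {
    tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE)
    need <- c("id_a", "id_b", "symbol_a", "symbol_b",
              "taxon_a", "taxon_b", "evidence")
    missing_col <- setdiff(need, names(tbl))
    if (length(missing_col) > 0) {
      abort(sprintf("biogrid_tab file %s lacks column '%s'",
                    path, missing_col[1]))
    }
    taxon_a <- suppressWarnings(as.integer(tbl$taxon_a))
    taxon_b <- suppressWarnings(as.integer(tbl$taxon_b))
    bad <- which(is.na(tbl$id_a) | is.na(tbl$id_b) |
                   is.na(taxon_a) | is.na(taxon_b))
    if (length(bad) > 0) {
      abort(sprintf("malformed biogrid_tab row at line %d of %s",
                    bad[1] + 1L, path))
    }
    out <- tibble(id_a = tbl$id_a, id_b = tbl$id_b,
                  symbol_a = tbl$symbol_a, symbol_b = tbl$symbol_b,
                  taxon_a = taxon_a, taxon_b = taxon_b,
                  score = NA_real_, evidence = tbl$evidence)
  } else {
    tbl <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                             na = c("", "NA"), progress = FALSE)
    need <- c("protein1", "protein2", "combined_score")
    missing_col <- setdiff(need, names(tbl))
    if (length(missing_col) > 0) {
      abort(sprintf("string_links file %s lacks column '%s'",
                    path, missing_col[1]))
    }
    raw <- suppressWarnings(as.numeric(tbl$combined_score))
    bad <- which(is.na(tbl$protein1) | is.na(tbl$protein2) |
                   is.na(raw) | raw < 0 | raw > 1000)
    if (length(bad) > 0) {
      abort(sprintf("malformed string_links row at line %d of %s",
                    bad[1] + 1L, path))
    }
    out <- tibble(id_a = tbl$protein1, id_b = tbl$protein2,
                  symbol_a = NA_character_, symbol_b = NA_character_,
                  taxon_a = as.integer(organism),
                  taxon_b = as.integer(organism),
                  score = raw / 1000, evidence = NA_character_)
  }
  attr(out, "dialect") <- dialect
  out
}

#' Construct a PPI network from node and edge tables
#'
#' Low-level constructor shared by the parsers, the set algebra and the
#' tests. The result is an undirected simple [igraph][igraph::igraph-package]
#' graph with vertex attributes `name` (gene id), `symbol` and `is_seed`, edge
#' attributes `score` and `evidence`, and graph attribute `label`. Self-loops
#' are dropped and parallel edges collapsed keeping the maximum score.
#'
#' @param edges Data frame with columns `id_a`, `id_b` and optionally
#'   `score`, `evidence`.
#' @param nodes Optional data frame with `gene_id` and optionally
#'   `gene_symbol`, `is_seed`; nodes appearing only here are kept as isolated
#'   vertices.
#' @param label Network name (for example disease by database).
#' @return A PPI network (igraph object).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, label = "") {
  edges <- if (is.null(edges) || nrow(edges) == 0) {
    tibble(id_a = character(), id_b = character(),
           score = numeric(), evidence = character())
  } else as_tibble(edges)
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  if (!"evidence" %in% names(edges)) edges$evidence <- NA_character_
  edges <- filter(edges, .data$id_a != .data$id_b)
  # canonical unordered orientation, then max-score dedup
  flip <- edges$id_a > edges$id_b
  tmp <- edges$id_a[flip]
  edges$id_a[flip] <- edges$id_b[flip]
  edges$id_b[flip] <- tmp
  edges <- edges |>
    arrange(.data$id_a, .data$id_b, desc(.data$score)) |>
    distinct(.data$id_a, .data$id_b, .keep_all = TRUE)

  node_ids <- unique(c(edges$id_a, edges$id_b,
                       if (!is.null(nodes)) as.character(nodes$gene_id)))
  node_ids <- sort(node_ids)
  vattr <- tibble(name = node_ids,
                  symbol = NA_character_, is_seed = FALSE)
  if (!is.null(nodes) && nrow(nodes) > 0) {
    nodes <- as_tibble(nodes)
    idx <- match(vattr$name, nodes$gene_id)
    if ("gene_symbol" %in% names(nodes)) {
      vattr$symbol <- as.character(nodes$gene_symbol[idx])
    }
    if ("is_seed" %in% names(nodes)) {
      vattr$is_seed <- !is.na(idx) & isTRUE_vec(nodes$is_seed[idx])
    }
  }
  g <- igraph::graph_from_data_frame(
    d = edges[c("id_a", "id_b", "score", "evidence")],
    directed = FALSE, vertices = vattr)
  igraph::graph_attr(g, "label") <- label
  g
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Build a first-order PPI network around seed genes
#'
#' Keeps an interaction record iff it passes the confidence filter
#' (`score >= min_score`, when a threshold is given; records without a score
#' fail any threshold), the taxonomy filter (*both* interactors equal
#' `taxon`, when given), the optional evidence-label filter, and touches at
#' least one seed. The resulting graph contains every surviving endpoint
#' plus every seed: seeds none of whose interactions survive are retained as
#' isolated nodes. A STRING-style "90% confidence" filter corresponds to
#' `min_score = 0.9` (combined score 900 on the native scale).
#'
#' @param records Interaction tibble from [parse_interactions()].
#' @param seeds A [gene_set()] in the same id space as the records.
#' @param min_score Confidence threshold in `[0, 1]`, or `NULL` for none.
#' @param taxon NCBI taxon id that both interactors must carry, or `NULL`.
#' @param evidence Optional character vector of admissible evidence labels.
#' @param label Network name.
#' @return A PPI network (igraph object) whose `is_seed` vertex attribute
#'   marks the seeds.
#' @export
build_first_order_network <- function(records, seeds, min_score = NULL,
                                      taxon = NULL, evidence = NULL,
                                      label = "") {
  if (nrow(seeds) == 0) abort("seed gene set is empty")
  if (!is.null(min_score) &&
      (!is.numeric(min_score) || min_score < 0 || min_score > 1)) {
    abort("min_score must lie in [0, 1]")
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(min_score)) {
    keep <- keep & !is.na(records$score) & records$score >= min_score
  }
  if (!is.null(taxon)) {
    keep <- keep & records$taxon_a == taxon & records$taxon_b == taxon
  }
  if (!is.null(evidence)) {
    keep <- keep & records$evidence %in% evidence
  }
  seed_ids <- seeds$gene_id
  keep <- keep & (records$id_a %in% seed_ids | records$id_b %in% seed_ids)
  kept <- records[keep, , drop = FALSE]

  symbols <- symbol_lookup(kept, seeds)
  node_ids <- unique(c(kept$id_a, kept$id_b, seed_ids))
  nodes <- tibble(gene_id = node_ids,
                  gene_symbol = symbols[node_ids],
                  is_seed = node_ids %in% seed_ids)
  ppi_network(kept, nodes, label = label)
}

symbol_lookup <- function(records, seeds) {
  ids <- c(records$id_a, records$id_b, seeds$gene_id)
  seed_syms <- if ("gene_symbol" %in% names(seeds)) seeds$gene_symbol else
    rep(NA_character_, nrow(seeds))
  syms <- c(records$symbol_a, records$symbol_b, seed_syms)
  ok <- !is.na(syms)
  lut <- syms[ok]
  names(lut) <- ids[ok]
  lut <- lut[!duplicated(names(lut))]
  out <- setNames(rep(NA_character_, length(unique(ids))), unique(ids))
  out[names(lut)] <- lut
  out
}

#' Seed vertices of a network
#' @param g A PPI network.
#' @return Character vector of seed gene ids.
#' @export
network_seeds <- function(g) {
  flag <- igraph::V(g)$is_seed
  if (is.null(flag)) character() else igraph::V(g)$name[isTRUE_vec(flag)]
}
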