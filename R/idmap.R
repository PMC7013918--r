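ID_SPACES <- c("ensembl_gene", "ensembl_protein", "entrez", "symbol")

#' Gene identifier maps
#'
#' An id map is a tibble with one row per mapping record and the columns
#' `ensembl_gene`, `ensembl_protein`, `entrez` and `symbol` (all character,
#' `NA` = missing) plus a `provenance` label naming the source of the row.
#' Symbols are normalised to upper case and trimmed on construction, because
#' HGNC-style labels are written differently depending on database, format
#' and tool. Row order encodes precedence: earlier rows win when several rows
#' resolve the same identifier.
#'
#' @param rows Data frame with some of the four id columns; missing columns
#'   are filled with `NA`.
#' @param provenance Source label applied to rows lacking one.
#' @return A tibble of class `id_map`.
#' @export
id_map <- function(rows, provenance = "unknown") {
  rows <- as_tibble(rows)
  for (col in ID_SPACES) {
    if (!col %in% names(rows)) rows[[col]] <- NA_character_
    rows[[col]] <- as.character(rows[[col]])
  }
  if (!"provenance" %in% names(rows)) rows$provenance <- provenance
  rows$symbol <- stringr::str_to_upper(stringr::str_trim(rows$symbol))
  rows <- distinct(rows[c(ID_SPACES, "provenance")])
  class(rows) <- unique(c("id_map", class(rows)))
  rows
}

#' Read an id map TSV
#'
#' Expects tab-separated columns `ensembl_gene_id`, `ensembl_protein_id`,
#' `entrez_id`, `symbol`; blank cells are missing.
#'
#' @param path Input TSV path.
#' @param provenance Source label recorded on every row.
#' @return An [id_map()].
#' @export
read_idmap <- function(path, provenance = basename(path)) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  need <- c("ensembl_gene_id", "ensembl_protein_id", "entrez_id", "symbol")
  missing_col <- setdiff(need, names(tbl))
  if (length(missing_col) > 0) {
    abort(sprintf("id map %s lacks column '%s'", path, missing_col[1]))
  }
  id_map(tibble(ensembl_gene = tbl$ensembl_gene_id,
                ensembl_protein = tbl$ensembl_protein_id,
                entrez = tbl$entrez_id,
                symbol = tbl$symbol),
         provenance = provenance)
}

#' Write an id map TSV
#' @param x An [id_map()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_idmap <- function(x, path) {
  readr::write_tsv(tibble(ensembl_gene_id = x$ensembl_gene,
                          ensembl_protein_id = x$ensembl_protein,
                          entrez_id = x$entrez,
                          symbol = x$symbol), path)
  invisible(x)
}

#' Map a gene set into another identifier space
#'
#' Every input id either resolves to exactly one target id or is returned in
#' `unmapped` — identifiers are never silently dropped. When several map rows
#' give different targets for one id, the earliest row (highest-precedence
#' source) wins, ties broken by the lexicographically smallest target; every
#' such ambiguous resolution is recorded in the `ambiguous` component.
#'
#' @param genes A [gene_set()].
#' @param idmap An [id_map()].
#' @param target Target id space, distinct from the gene set's space.
#' @return A list with `mapped` (a [gene_set()] in the target space, with a
#'   `mapping` attribute giving the source-to-target table), `unmapped`
#'   (character vector of unresolvable ids) and `ambiguous` (tibble of logged
#'   one-to-many resolutions).
#' @export
map_ids <- function(genes, idmap, target) {
  target <- match.arg(target, ID_SPACES)
  source <- id_space(genes)
  if (source == target) abort("target id space equals the source space")
  query <- genes$gene_id
  key <- if (source == "symbol") {
    stringr::str_to_upper(stringr::str_trim(query))
  } else query

  prov_rank <- match(idmap$provenance, unique(idmap$provenance))
  lut <- tibble(key = idmap[[source]], value = idmap[[target]],
                prec = prov_rank)
  lut <- filter(lut, !is.na(.data$key), !is.na(.data$value))

  hits <- lut[lut$key %in% key, , drop = FALSE]
  if (nrow(hits) > 0) {
    n_targets <- hits |> group_by(.data$key) |>
      summarise(n = dplyr::n_distinct(.data$value), .groups = "drop")
    # highest-precedence source first, then lexicographically smallest target
    resolved <- hits |> group_by(.data$key) |>
      summarise(value = sort(.data$value[.data$prec == min(.data$prec)])[1],
                .groups = "drop")
  } else {
    n_targets <- tibble(key = character(), n = integer())
    resolved <- tibble(key = character(), value = character())
  }

  idx <- match(key, resolved$key)
  mapping <- tibble(source_id = query, target_id = resolved$value[idx])
  unmapped <- query[is.na(mapping$target_id)]
  ambiguous_keys <- n_targets$key[n_targets$n > 1]
  ambiguous <- filter(mapping, key %in% ambiguous_keys,
                      !is.na(.data$target_id))

  mapped <- gene_set(mapping$target_id[!is.na(mapping$target_id)],
                     id_space = target)
  attr(mapped, "mapping") <- mapping
  list(mapped = mapped, unmapped = unmapped, ambiguous = ambiguous)
}

#' Merge id maps with source precedence
#'
#' Rows from all maps (earlier = higher precedence) that refer to the same
#' entity — i.e. share any non-missing identifier in any of the four id
#' columns — are coalesced into one record, each field taken from the
#' highest-precedence row where it is non-missing. This is how a partial
#' symbol-to-Ensembl map is completed by an Entrez-sourced map that shares,
#' say, protein identifiers with it. Disagreements between sources on a
#' coalesced field are resolved in favour of the first-listed source and
#' logged in the `conflicts` attribute.
#'
#' @param maps List of [id_map()] objects, highest precedence first.
#' @return A merged [id_map()] with a `conflicts` attribute.
#' @export
merge_idmaps <- function(maps) {
  if (length(maps) < 1) abort("merge_idmaps needs at least one map")
  merged <- id_map(bind_rows(maps))
  n <- nrow(merged)
  # union-find over rows linked by any shared identifier
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (col in ID_SPACES) {
    vals <- merged[[col]]
    for (rows in split(which(!is.na(vals)), vals[!is.na(vals)])) {
      if (length(rows) > 1) {
        r0 <- find(rows[1])
        for (r in rows[-1]) parent[find(r)] <- r0
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  conflicts <- list()
  coalesced <- map(split(seq_len(n), comp), function(rows) {
    rows <- sort(rows)
    out <- merged[rows[1], ]
    for (col in c(ID_SPACES, "provenance")) {
      vals <- unique(merged[[col]][rows])
      vals <- vals[!is.na(vals)]
      if (length(vals) >= 1) out[[col]] <- vals[1]
      if (col != "provenance" && length(vals) > 1) {
        conflicts[[length(conflicts) + 1]] <<- tibble(
          key_column = col, kept = vals[1],
          dropped = paste(vals[-1], collapse = ","))
      }
    }
    out
  })
  out <- id_map(bind_rows(coalesced[order(map_int(
    split(seq_len(n), comp), min))]))
  attr(out, "conflicts") <- if (length(conflicts) > 0) {
    bind_rows(conflicts)
  } else {
    tibble(key_column = character(), kept = character(),
           dropped = character())
  }
  out
}

#' Apply manual patches to an id map
#'
#' Patch rows (for example, Ensembl gene ids added by hand for symbols no
#' automated source could resolve) are given provenance `"manual"` and
#' prepended, so they take precedence over every existing row. Patches that
#' override an existing mapping are logged in the `overrides` attribute.
#'
#' @param idmap An [id_map()].
#' @param patches Data frame of patch rows with a subset of the four id
#'   columns; each row must carry at least two non-missing identifiers.
#' @return The patched [id_map()].
#' @export
manual_patch <- function(idmap, patches) {
  patches <- as_tibble(patches)
  if (nrow(patches) == 0) return(idmap)
  present <- intersect(ID_SPACES, names(patches))
  n_ids <- rowSums(!is.na(patches[present]))
  if (length(present) < 2 || any(n_ids < 2)) {
    abort(sprintf("malformed patch row %d: need at least two identifiers",
                  if (length(present) < 2) 1L else which(n_ids < 2)[1]))
  }
  patch_map <- id_map(patches, provenance = "manual")
  patch_map$provenance <- "manual"
  overrides <- list()
  for (keycol in c("symbol", "entrez", "ensembl_gene")) {
    pk <- patch_map[[keycol]]
    ok <- !is.na(pk) & pk %in% idmap[[keycol]]
    if (any(ok)) {
      overrides[[keycol]] <- tibble(key_column = keycol, key = pk[ok])
    }
  }
  out <- id_map(bind_rows(patch_map, idmap))
  attr(out, "overrides") <- bind_rows(overrides)
  out
}
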