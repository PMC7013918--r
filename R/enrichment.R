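#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a background of `N` genes of which `K`
#' carry the annotation:
#' `P(X >= k) = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#' Computed through the stable tail of the hypergeometric distribution.
#'
#' @param k Observed study-set count (vectorised).
#' @param n Study-set size.
#' @param K Background count annotated to the term.
#' @param N Background size.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0)) {
    abort("hypergeometric bounds violated: need 0 <= k <= min(n, K) <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO over-representation analysis
#'
#' One-sided hypergeometric over-representation test per GO term with at
#' least one annotated background gene, using direct annotations only (no
#' propagation along the GO graph). Raw p-values are corrected by
#' Benjamini-Hochberg across all tested terms; rows are sorted by p
#' ascending, ties by accession, so output order is deterministic.
#'
#' @param study A [gene_set()] (for example the nodes of a unique difference
#'   network); must be a subset of `background`.
#' @param background A [gene_set()] defining the sampling universe
#'   (typically every gene occurring in the relevant interaction database,
#'   or the whole annotation table).
#' @param annotations An [annotation_table()].
#' @param alpha FDR level used for the `significant` flag (default 0.05).
#' @return A tibble of class `ppi_enrichment` with columns `accession`,
#'   `name`, `namespace`, `k`, `n`, `K`, `N`, `p_value`, `q_value`,
#'   `significant`.
#' @export
enrich <- function(study, background, annotations, alpha = 0.05) {
  study_ids <- unique(study$gene_id)
  bg_ids <- unique(background$gene_id)
  if (length(study_ids) == 0 || length(bg_ids) == 0) {
    abort("study and background sets must be non-empty")
  }
  outside <- setdiff(study_ids, bg_ids)
  if (length(outside) > 0) {
    abort(sprintf("study set is not contained in the background (e.g. %s)",
                  outside[1]))
  }
  entries <- filter(annotations$entries, .data$gene_id %in% bg_ids)
  n_study <- length(study_ids)
  n_bg <- length(bg_ids)
  per_term <- entries |>
    group_by(.data$accession) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = dplyr::n_distinct(.data$gene_id[
                .data$gene_id %in% study_ids]),
              .groups = "drop")
  out <- per_term |>
    left_join(annotations$terms, by = "accession") |>
    mutate(n = n_study, N = n_bg,
           p_value = hypergeom_upper_tail(.data$k, n_study, .data$K, n_bg))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out |>
    mutate(significant = .data$q_value <= alpha) |>
    arrange(.data$p_value, .data$accession) |>
    select("accession", "name", "namespace", "k", "n", "K", "N",
           "p_value", "q_value", "significant")
  attr(out, "alpha") <- alpha
  class(out) <- unique(c("ppi_enrichment", class(out)))
  out
}

#' Count network nodes annotated to a term
#'
#' @param g A PPI network.
#' @param accession GO accession.
#' @param annotations An [annotation_table()].
#' @return Number of nodes of `g` directly annotated to the term.
#' @export
term_node_count <- function(g, accession, annotations) {
  annotated <- annotations$entries$gene_id[
    annotations$entries$accession == accession]
  sum(net_nodes(g)$gene_id %in% annotated)
}
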