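#' Tidy a clustering result
#'
#' One row per network node with its role (`cluster` / `overlap` /
#' `outlier`), the number of complexes containing it, and a comma-joined
#' list of complex indices.
#'
#' @param x A `ppi_clustering`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ppi_clustering
#' @export
tidy.ppi_clustering <- function(x, ...) {
  membership <- cluster_membership_of(x, x$roles$gene_id)
  mutate(x$roles,
         cluster_indices = map_chr(membership$cluster_indices,
                                   paste, collapse = ","))
}

#' Summarise a clustering result in one row
#'
#' @param x A `ppi_clustering`.
#' @param ... Unused.
#' @return A one-row tibble with complex counts, role counts, and mean
#'   complex size/density/cohesiveness.
#' @method glance ppi_clustering
#' @export
glance.ppi_clustering <- function(x, ...) {
  tibble(n_clusters = length(x$clusters),
         n_nodes = nrow(x$roles),
         n_cluster_nodes = sum(x$roles$role == "cluster"),
         n_overlap = sum(x$roles$role == "overlap"),
         n_outlier = sum(x$roles$role == "outlier"),
         mean_size = mean(x$summary$size),
         mean_density = mean(x$summary$density),
         mean_cohesiveness = mean(x$summary$cohesiveness))
}

#' Tidy an enrichment table
#' @param x A `ppi_enrichment`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy ppi_enrichment
#' @export
tidy.ppi_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ppi_enrichment")
  as_tibble(out)
}

#' Summarise an enrichment table in one row
#' @param x A `ppi_enrichment`.
#' @param ... Unused.
#' @return A one-row tibble with the number of tested and significant terms
#'   and the smallest p/q values.
#' @method glance ppi_enrichment
#' @export
glance.ppi_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_significant = sum(x$significant),
         min_p = if (nrow(x) > 0) min(x$p_value) else NA_real_,
         min_q = if (nrow(x) > 0) min(x$q_value) else NA_real_,
         alpha = attr(x, "alpha") %||% NA_real_)
}

#' Tidy a recovery report
#'
#' Long table of per-network recovery metrics.
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return A tibble with columns `database`, `disease`, `metric`, `value`.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) {
  bind_rows(
    tidyr::pivot_longer(x$hub_recovery, "hub_recovery",
                        names_to = "metric", values_to = "value"),
    tidyr::pivot_longer(x$complex_recovery, "mean_best_jaccard",
                        names_to = "metric", values_to = "value"),
    tidyr::pivot_longer(select(x$difference_purity, -"n_unique_nodes"),
                        "purity", names_to = "metric", values_to = "value"),
    tidyr::pivot_longer(mutate(x$enrichment_rank,
                               enriched_term_rank =
                                 as.numeric(.data$enriched_term_rank)),
                        "enriched_term_rank",
                        names_to = "metric", values_to = "value"))
}

#' @rdname tidy.recovery_report
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) x$summary
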