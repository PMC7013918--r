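# Greedy overlapping complex detection by cohesiveness maximisation.
# A candidate complex V is scored f(V) = w_in / (w_in + w_bound + p*|V|),
# where w_in is the total weight of edges inside V, w_bound the total weight
# of edges with exactly one endpoint in V, and p a per-member penalty that
# models unobserved interactions. Confidence scores are used as edge weights
# when present; unscored edges count 1.

weighted_adjacency <- function(g) {
  e <- net_edges(g)
  w <- ifelse(is.na(e$score), 1, e$score)
  ids <- net_nodes(g)$gene_id
  n <- length(ids)
  ai <- match(e$id_a, ids)
  bi <- match(e$id_b, ids)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(), w = numeric())
  if (length(ai) > 0) {
    for (k in seq_along(ai)) {
      adj[[ai[k]]]$nbr <- c(adj[[ai[k]]]$nbr, bi[k])
      adj[[ai[k]]]$w <- c(adj[[ai[k]]]$w, w[k])
      adj[[bi[k]]]$nbr <- c(adj[[bi[k]]]$nbr, ai[k])
      adj[[bi[k]]]$w <- c(adj[[bi[k]]]$w, w[k])
    }
  }
  list(ids = ids, adj = adj,
       strength = map_dbl(adj, ~ sum(.x$w)),
       degree = map_int(adj, ~ length(.x$nbr)))
}

#' Cohesiveness of a node set
#'
#' `f(V) = w_in / (w_in + w_bound + p * |V|)`: the fraction of the weight
#' incident to the set that stays inside it, with a size penalty `p` per
#' member accounting for interactions that were never observed. Returns 0
#' when the denominator is 0.
#'
#' @param g A PPI network.
#' @param members Character vector of node ids, all present in `g`.
#' @param penalty Per-member penalty `p >= 0` (default 2).
#' @return Cohesiveness in `[0, 1]`.
#' @export
cohesiveness <- function(g, members, penalty = 2) {
  wa <- weighted_adjacency(g)
  idx <- match(members, wa$ids)
  if (anyNA(idx)) {
    abort(sprintf("member '%s' is not a node of the network",
                  members[which(is.na(idx))[1]]))
  }
  state <- cluster_state(wa, idx, penalty)
  state$f
}

cluster_state <- function(wa, idx, penalty) {
  n <- length(wa$ids)
  in_set <- rep(FALSE, n)
  in_set[idx] <- TRUE
  w_to_set <- rep(0, n)
  for (i in idx) {
    a <- wa$adj[[i]]
    for (k in seq_along(a$nbr)) {
      w_to_set[a$nbr[k]] <- w_to_set[a$nbr[k]] + a$w[k]
    }
  }
  w_in <- sum(w_to_set[idx]) / 2
  w_bound <- sum(wa$strength[idx]) - 2 * w_in
  list(in_set = in_set, w_to_set = w_to_set, w_in = w_in, w_bound = w_bound,
       size = length(idx), penalty = penalty,
       f = cohesiveness_value(w_in, w_bound, penalty, length(idx)))
}

cohesiveness_value <- function(w_in, w_bound, penalty, size) {
  denom <- w_in + w_bound + penalty * size
  if (denom <= 0) 0 else w_in / denom
}

#' Grow a cluster greedily from a seed node
#'
#' Starts from the singleton `{seed}` and repeatedly evaluates every single
#' move — adding an external neighbour of the current set or removing a
#' current member — applying the move with the largest cohesiveness
#' increase; the search stops when no move strictly increases cohesiveness.
#' Ties are broken by the lexicographically smallest node id, so the
#' procedure is fully deterministic.
#'
#' @param g A PPI network.
#' @param seed A node id present in `g`.
#' @param penalty Per-member penalty (default 2).
#' @return A list of class `ppi_cluster` with `members` (sorted ids),
#'   `cohesiveness` and `density` (unweighted; 0 for singletons).
#' @export
grow_cluster <- function(g, seed, penalty = 2) {
  wa <- weighted_adjacency(g)
  i0 <- match(seed, wa$ids)
  if (is.na(i0)) abort(sprintf("seed '%s' is not a node of the network", seed))
  members <- grow_cluster_impl(wa, i0, penalty)
  as_ppi_cluster(g, wa$ids[members], penalty)
}

grow_cluster_impl <- function(wa, i0, penalty, max_steps = 1000L) {
  st <- cluster_state(wa, i0, penalty)
  eps <- 1e-12
  for (step in seq_len(max_steps)) {
    best_f <- st$f
    best_move <- NULL
    consider <- function(type, v, f2) {
      # eligible only if it strictly improves on the current set; among
      # eligible moves prefer larger f, ties by smaller node id
      if (f2 <= st$f + eps) return()
      if (is.null(best_move) || f2 > best_f + eps ||
          (f2 >= best_f - eps && wa$ids[v] < wa$ids[best_move$v])) {
        best_f <<- max(best_f, f2)
        best_move <<- list(type = type, v = v)
      }
    }
    for (v in which(!st$in_set & st$w_to_set > 0)) {
      w_in2 <- st$w_in + st$w_to_set[v]
      w_bound2 <- st$w_bound - st$w_to_set[v] +
        (wa$strength[v] - st$w_to_set[v])
      consider("add", v,
               cohesiveness_value(w_in2, w_bound2, penalty, st$size + 1L))
    }
    if (st$size > 1L) {
      for (v in which(st$in_set)) {
        w_in2 <- st$w_in - st$w_to_set[v]
        w_bound2 <- st$w_bound - (wa$strength[v] - st$w_to_set[v]) +
          st$w_to_set[v]
        consider("remove", v,
                 cohesiveness_value(w_in2, w_bound2, penalty, st$size - 1L))
      }
    }
    if (is.null(best_move)) break
    st <- apply_move(wa, st, best_move, penalty)
  }
  which(st$in_set)
}

apply_move <- function(wa, st, move, penalty) {
  v <- move$v
  a <- wa$adj[[v]]
  if (move$type == "add") {
    st$w_in <- st$w_in + st$w_to_set[v]
    st$w_bound <- st$w_bound - st$w_to_set[v] +
      (wa$strength[v] - st$w_to_set[v])
    st$in_set[v] <- TRUE
    st$size <- st$size + 1L
    for (k in seq_along(a$nbr)) {
      st$w_to_set[a$nbr[k]] <- st$w_to_set[a$nbr[k]] + a$w[k]
    }
  } else {
    st$w_in <- st$w_in - st$w_to_set[v]
    st$w_bound <- st$w_bound - (wa$strength[v] - st$w_to_set[v]) +
      st$w_to_set[v]
    st$in_set[v] <- FALSE
    st$size <- st$size - 1L
    for (k in seq_along(a$nbr)) {
      st$w_to_set[a$nbr[k]] <- st$w_to_set[a$nbr[k]] - a$w[k]
    }
  }
  st$f <- cohesiveness_value(st$w_in, st$w_bound, penalty, st$size)
  st
}

as_ppi_cluster <- function(g, members, penalty) {
  members <- sort(members)
  structure(list(members = members,
                 cohesiveness = cohesiveness(g, members, penalty),
                 density = cluster_density(g, members)),
            class = "ppi_cluster")
}

cluster_density <- function(g, members) {
  s <- length(members)
  if (s < 2) return(0)
  e <- net_edges(g)
  m_in <- sum(e$id_a %in% members & e$id_b %in% members)
  2 * m_in / (s * (s - 1))
}

#' Overlap score between two clusters
#'
#' `omega(A, B) = |A n B|^2 / (|A| * |B|)`; clusters whose overlap exceeds a
#' threshold are merged during [cluster_network()].
#'
#' @param a,b Character vectors of member ids.
#' @return Overlap score in `[0, 1]`.
#' @export
overlap_score <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Detect overlapping protein complexes in a network
#'
#' Candidate complexes are grown greedily (see [grow_cluster()]) from every
#' node in decreasing degree order (ties by id), skipping nodes already
#' covered by a previously grown candidate. Candidate pairs with overlap
#' score `omega > overlap_max` are merged (set union) repeatedly until no
#' pair exceeds the threshold; merged candidates with fewer than `min_size`
#' members or unweighted density below `min_density` are then discarded.
#' Finally every node is assigned a role: `"cluster"` (member of exactly one
#' accepted complex), `"overlap"` (member of at least two) or `"outlier"`
#' (member of none).
#'
#' @param g A PPI network.
#' @param penalty Cohesiveness penalty `p` (default 2).
#' @param min_size Minimum accepted complex size (default 3).
#' @param min_density Minimum accepted unweighted density (default 0.5).
#' @param overlap_max Overlap-score merge threshold (default 0.8).
#' @return An object of class `ppi_clustering`: a list with `clusters` (list
#'   of member-id vectors, largest first, ties by smallest member id),
#'   `summary` (one row per accepted complex), `roles` (one row per node)
#'   and `params`.
#' @export
cluster_network <- function(g, penalty = 2, min_size = 3, min_density = 0.5,
                            overlap_max = 0.8) {
  if (min_size < 1 || min_density < 0 || min_density > 1 ||
      overlap_max < 0 || overlap_max > 1 || penalty < 0) {
    abort("clustering parameter outside its valid range")
  }
  wa <- weighted_adjacency(g)
  n <- length(wa$ids)
  order_idx <- order(-wa$degree, wa$ids)
  covered <- rep(FALSE, n)
  candidates <- list()
  for (i in order_idx) {
    if (covered[i] || wa$degree[i] == 0) next
    members <- grow_cluster_impl(wa, i, penalty)
    covered[members] <- TRUE
    candidates[[length(candidates) + 1]] <- wa$ids[members]
  }
  candidates <- unique(map(candidates, sort))

  # merge highly overlapping candidates to fixpoint
  repeat {
    merged_any <- FALSE
    k <- length(candidates)
    if (k < 2) break
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        if (overlap_score(candidates[[a]], candidates[[b]]) > overlap_max) {
          candidates[[a]] <- sort(union(candidates[[a]], candidates[[b]]))
          candidates[[b]] <- NULL
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }

  kept <- keep(candidates, function(m) {
    length(m) >= min_size && cluster_density(g, m) >= min_density
  })
  # largest first, ties by smallest member id
  ord <- order(-lengths(kept), map_chr(kept, ~ .x[1] %||% ""))
  kept <- kept[ord]

  ids <- wa$ids
  counts <- as.integer(table(factor(unlist(kept), levels = ids)))
  role <- dplyr::case_when(counts >= 2 ~ "overlap",
                           counts == 1 ~ "cluster",
                           TRUE ~ "outlier")
  roles <- tibble(gene_id = ids, role = role, n_clusters = counts)
  summary <- tibble(
    cluster = seq_along(kept),
    size = lengths(kept),
    density = map_dbl(kept, ~ cluster_density(g, .x)),
    cohesiveness = map_dbl(kept, ~ cohesiveness(g, .x, penalty)))
  structure(list(clusters = kept, summary = summary, roles = roles,
                 params = list(penalty = penalty, min_size = min_size,
                               min_density = min_density,
                               overlap_max = overlap_max),
                 label = igraph::graph_attr(g, "label") %||% ""),
            class = "ppi_clustering")
}

#' @export
print.ppi_clustering <- function(x, ...) {
  cat("# Cohesiveness clustering:", length(x$clusters), "complexes;",
      sum(x$roles$role == "overlap"), "overlap nodes;",
      sum(x$roles$role == "outlier"), "outliers\n")
  print(x$summary)
  invisible(x)
}

#' Cluster membership of selected genes
#'
#' @param result A `ppi_clustering` from [cluster_network()].
#' @param genes A [gene_set()] or character vector of gene ids.
#' @return A tibble with `gene_id` and a list-column `cluster_indices`
#'   (integer vector of complex indices containing the gene; empty for
#'   outliers and genes absent from the network).
#' @export
cluster_membership_of <- function(result, genes) {
  ids <- if (is.data.frame(genes)) genes$gene_id else as.character(genes)
  tibble(gene_id = ids,
         cluster_indices = map(ids, function(id) {
           which(map_lgl(result$clusters, ~ id %in% .x))
         }))
}

#' Write clustering results as plain text
#'
#' Writes one complex per line (members tab-separated) plus a node-attribute
#' table (`gene_id`, `role`, comma-joined cluster indices) suitable for
#' joining back onto a network for external visualisation.
#'
#' @param x A `ppi_clustering`.
#' @param clusters_path,roles_path Output paths.
#' @return `x`, invisibly.
#' @export
write_clustering <- function(x, clusters_path, roles_path) {
  writeLines(map_chr(x$clusters, paste, collapse = "\t"), clusters_path)
  membership <- cluster_membership_of(x, x$roles$gene_id)
  tbl <- mutate(x$roles,
                cluster_indices = map_chr(membership$cluster_indices,
                                          paste, collapse = ","))
  readr::write_tsv(tbl, roles_path)
  invisible(x)
}
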