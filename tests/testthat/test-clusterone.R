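triangle <- function() net_from_pairs(c("A-B", "B-C", "A-C"))

test_that("cohesiveness matches the defining formula on small sets", {
  tri <- triangle()
  expect_equal(cohesiveness(tri, c("A", "B", "C"), penalty = 0), 1.0)
  expect_equal(cohesiveness(tri, c("A", "B"), penalty = 0), 1 / 3)
  expect_equal(cohesiveness(tri, c("A", "B", "C"), penalty = 2), 1 / 3)
  expect_error(cohesiveness(tri, c("A", "NOPE")), "NOPE")
  # weighted edges: scores act as weights
  gw <- net_from_pairs(c("A-B", "B-C"), scores = c(0.5, 1))
  expect_equal(cohesiveness(gw, c("A", "B"), penalty = 0), 0.5 / (0.5 + 1))
})

test_that("greedy growth recovers an isolated clique and stops there", {
  clique5 <- net_from_pairs(apply(utils::combn(LETTERS[1:5], 2), 2,
                                  paste, collapse = "-"))
  cl <- grow_cluster(clique5, "C", penalty = 2)
  expect_setequal(cl$members, LETTERS[1:5])
  expect_equal(cl$cohesiveness, 10 / 20)  # w_in 10, penalty 2*5
  expect_equal(cl$density, 1)
})

test_that("a degree-zero seed grows to a singleton", {
  g <- net_from_pairs("A-B", extra_nodes = "Z")
  cl <- grow_cluster(g, "Z")
  expect_equal(cl$members, "Z")
  expect_error(grow_cluster(g, "MISSING"), "MISSING")
})

test_that("a pendant node is not absorbed when it lowers cohesiveness", {
  clique <- apply(utils::combn(LETTERS[1:6], 2), 2, paste, collapse = "-")
  g <- net_from_pairs(c(clique, "F-P"))  # pendant P hangs off F
  cl <- grow_cluster(g, "A", penalty = 2)
  expect_false("P" %in% cl$members)
  # adding P would give f = 16/(16 + 0 + 14) < 15/(15 + 1 + 12)
  f_without <- cohesiveness(g, LETTERS[1:6], 2)
  f_with <- cohesiveness(g, c(LETTERS[1:6], "P"), 2)
  expect_lt(f_with, f_without)
})

test_that("two disjoint cliques plus isolated nodes are recovered exactly", {
  c1 <- apply(utils::combn(paste0("A", 1:4), 2), 2, paste, collapse = "-")
  c2 <- apply(utils::combn(paste0("B", 1:4), 2), 2, paste, collapse = "-")
  g <- net_from_pairs(c(c1, c2), extra_nodes = c("X1", "X2"))
  res <- cluster_network(g)
  expect_equal(length(res$clusters), 2)
  expect_setequal(res$clusters[[1]], paste0("A", 1:4))
  expect_setequal(res$clusters[[2]], paste0("B", 1:4))
  roles <- res$roles
  expect_equal(roles$role[roles$gene_id %in% c("X1", "X2")],
               c("outlier", "outlier"))
  expect_equal(sum(roles$role == "cluster"), 8)
})

test_that("duplicate candidates merge at overlap 1 and shared nodes overlap", {
  expect_equal(overlap_score(c("A", "B"), c("A", "B")), 1)
  expect_equal(overlap_score(c("A", "B", "C"), c("B", "C", "D")), 4 / 9)
  # two 4-cliques sharing exactly one vertex S
  left <- apply(utils::combn(c("S", paste0("L", 1:3)), 2), 2,
                paste, collapse = "-")
  right <- apply(utils::combn(c("S", paste0("R", 1:3)), 2), 2,
                 paste, collapse = "-")
  g <- net_from_pairs(c(left, right))
  res <- cluster_network(g)
  expect_equal(length(res$clusters), 2)
  expect_equal(res$roles$role[res$roles$gene_id == "S"], "overlap")
  mem <- cluster_membership_of(res, gene_set("S"))
  expect_equal(mem$cluster_indices[[1]], c(1L, 2L))
  out <- cluster_membership_of(res, "ABSENT")
  expect_equal(length(out$cluster_indices[[1]]), 0)
})

test_that("role partition is exhaustive and filters are honoured", {
  set.seed(8)
  for (rep in 1:5) {
    g <- random_network(25, 0.12)
    res <- cluster_network(g)
    roles <- res$roles
    expect_equal(nrow(roles), igraph::vcount(g))
    expect_equal(sum(roles$role == "cluster") + sum(roles$role == "overlap") +
                   sum(roles$role == "outlier"), igraph::vcount(g))
    # overlap iff >= 2 clusters, cluster iff exactly 1, outlier iff 0
    expect_true(all((roles$n_clusters >= 2) == (roles$role == "overlap")))
    expect_true(all((roles$n_clusters == 1) == (roles$role == "cluster")))
    if (length(res$clusters) > 0) {
      expect_true(all(res$summary$size >= res$params$min_size))
      expect_true(all(res$summary$density >= res$params$min_density))
    }
    # determinism: identical rerun
    expect_identical(res$clusters, cluster_network(g)$clusters)
  }
})

test_that("adding an internal edge never lowers a set's cohesiveness", {
  set.seed(21)
  for (rep in 1:10) {
    g <- random_network(12, 0.25)
    nodes <- net_nodes(g)$gene_id
    members <- sample(nodes, 5)
    inside <- utils::combn(sort(members), 2)
    present <- paste(net_edges(g)$id_a, net_edges(g)$id_b)
    free <- which(!paste(inside[1, ], inside[2, ]) %in% present)
    if (length(free) == 0) next
    pick <- free[1]
    g2 <- ppi_network(dplyr::bind_rows(
      net_edges(g),
      tibble::tibble(id_a = inside[1, pick], id_b = inside[2, pick])),
      net_nodes(g))
    expect_gte(cohesiveness(g2, members, 2), cohesiveness(g, members, 2))
  }
})

test_that("hub membership queries report clusters in rank order", {
  sim <- simulate_planted_cliques(k = 3, m = 5, n_isolated = 2, seed = 4)
  res <- cluster_network(sim$graph)
  # clusters sorted by size then smallest member id; equal sizes here
  firsts <- vapply(res$clusters, `[`, "", 1)
  expect_equal(firsts, sort(firsts))
  mem <- cluster_membership_of(res, gene_set(sim$cliques[[1]][1]))
  expect_equal(mem$cluster_indices[[1]], 1L)
})
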