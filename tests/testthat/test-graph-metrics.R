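triangle_pendant <- function() {
  # triangle {1,2,3} plus pendant node 4 attached to node 1
  adj <- matrix(0L, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[1, 3] <- adj[3, 1] <- 1L
  adj[2, 3] <- adj[3, 2] <- 1L
  adj[1, 4] <- adj[4, 1] <- 1L
  adj
}

complete_graph <- function(n) {
  adj <- matrix(1L, n, n); diag(adj) <- 0L; adj
}

star_graph <- function(n) {
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1L
  adj
}

path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  adj
}

test_that("clustering matches closed forms on canonical graphs", {
  expect_equal(node_clustering(complete_graph(3), 1), 1)
  expect_equal(node_clustering(star_graph(5), 1), 0)
  tp <- triangle_pendant()
  expect_equal(node_clustering(tp, 1), 1 / 3)
  expect_equal(network_clustering(tp), (1 / 3 + 1 + 1 + 0) / 4)
  expect_equal(network_clustering(complete_graph(6)), 1)
  expect_equal(network_clustering(path_graph(5)), 0)   # tree: no triangles
})

test_that("path length and efficiencies match closed forms", {
  expect_equal(characteristic_path_length(complete_graph(5)), 1,
               ignore_attr = TRUE)
  expect_equal(as.numeric(characteristic_path_length(path_graph(3))), 4 / 3)
  expect_equal(global_efficiency(complete_graph(5)), 1)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
  expect_equal(global_efficiency(matrix(0L, 4, 4)), 0)
  expect_equal(local_efficiency(complete_graph(4)), 1)
  expect_equal(local_efficiency(star_graph(6)), 0)
  # node 1's neighbour subgraph is {2,3,4} with the single edge 2-3:
  # GE = 1/3; nodes 2 and 3 contribute 1, the pendant contributes 0
  expect_equal(local_efficiency(triangle_pendant()), 7 / 12)
  expect_equal(local_efficiency(triangle_pendant()),
               brute_local_efficiency(triangle_pendant()))
  # two disjoint K2 components: only connected pairs at distance 1
  two_k2 <- matrix(0L, 4, 4)
  two_k2[1, 2] <- two_k2[2, 1] <- two_k2[3, 4] <- two_k2[4, 3] <- 1L
  expect_equal(as.numeric(characteristic_path_length(two_k2, "exclude")), 1)
  expect_equal(as.numeric(characteristic_path_length(two_k2, "substitute")),
               mean(c(1, 1, 4, 4, 4, 4)))
})

test_that("edgeless graph path length is NaN with a warning", {
  expect_warning(L <- characteristic_path_length(matrix(0L, 3, 3)))
  expect_true(is.nan(as.numeric(L)))
})

test_that("all metrics equal brute-force oracles on a random-graph battery", {
  withr::with_seed(404, {
    for (rep in 1:220) {
      n <- sample(4:11, 1)
      adj <- random_graph(n, stats::runif(1, 0.15, 0.85))
      D <- graph_distances(adj)
      expect_equal(D, fw_distances(adj))
      C <- network_clustering(adj)
      L <- suppressWarnings(as.numeric(characteristic_path_length(adj)))
      GE <- global_efficiency(adj)
      LE <- local_efficiency(adj)
      expect_equal(C, brute_clustering(adj))
      expect_equal(L, suppressWarnings(brute_path_length(adj)))
      expect_equal(as.numeric(characteristic_path_length(adj, "substitute")),
                   brute_path_length(adj, "substitute"))
      expect_equal(GE, brute_global_efficiency(adj))
      expect_equal(LE, brute_local_efficiency(adj))
      # range and ordering invariants
      expect_true(C >= 0 && C <= 1)
      expect_true(GE >= 0 && GE <= 1)
      expect_true(LE >= 0 && LE <= 1)
      if (all(is.finite(D[upper.tri(D)])) && is.finite(L))
        expect_true(GE >= 1 / L - 1e-12)   # Jensen on reciprocals
    }
  })
})

test_that("printed local-efficiency prefactor scales the standard mean", {
  withr::with_seed(7, adj <- random_graph(8, 0.5))
  expect_equal(local_efficiency(adj, "printed"),
               local_efficiency(adj, "standard") * 8 / (8 * 7))
})

test_that("metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  withr::with_seed(11, {
    for (rep in 1:25) {
      adj <- random_graph(sample(5:12, 1), stats::runif(1, 0.25, 0.8))
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      expect_equal(network_clustering(adj),
                   mean(replace(igraph::transitivity(g, "local"),
                                is.na(igraph::transitivity(g, "local")), 0)))
      expect_equal(global_efficiency(adj), igraph::global_efficiency(g))
    }
  })
})

test_that("degree-preserving randomization keeps degrees, kills triangles", {
  ring <- generate_topology(22, topology_params(4, 0), seed = 1)$adjacency
  dropped <- vapply(1:100, function(s) {
    R <- degree_preserving_randomize(ring, seed = s)
    expect_identical(colSums(R), colSums(ring))
    expect_true(all(diag(R) == 0))
    expect_identical(R, t(R))
    count_triangles(R) < count_triangles(ring)
  }, logical(1))
  expect_gte(mean(dropped), 0.95)
  # complete graph: no legal swap, returned unchanged
  K <- matrix(1L, 6, 6); diag(K) <- 0L
  expect_equal(unname(degree_preserving_randomize(K, seed = 3)), K,
               ignore_attr = TRUE)
})

test_that("small-worldness separates lattice-like from fully rewired graphs", {
  sig_sw <- vapply(1:15, function(s) {
    net <- generate_topology(22, topology_params(4, 0.1), seed = s)
    small_worldness(net$adjacency, n_rand = 30, seed = s)$sigma
  }, numeric(1))
  expect_gt(median(sig_sw), 1)
  # p = 1 graphs are draws from (almost) the reference ensemble itself
  sig_rand <- vapply(1:15, function(s) {
    net <- generate_topology(22, topology_params(4, 1), seed = 100 + s)
    small_worldness(net$adjacency, n_rand = 30, seed = s)$sigma
  }, numeric(1))
  expect_lt(abs(mean(sig_rand) - 1), 0.1)
  # complete graph is its own reference
  K <- matrix(1L, 8, 8); diag(K) <- 0L
  sw <- small_worldness(K, n_rand = 5, seed = 1)
  expect_equal(sw$sigma, 1)
  expect_true(sw$degenerate)
})

test_that("metric curves cover the stack, are seeded, and GE is monotone", {
  hemo <- noise_hemo(n = 900L, p = 10L, seed = 21)
  stack <- build_threshold_stack(correlation_matrix(hemo))
  cv1 <- metric_curves(stack, n_rand = 5, seed = 9)
  cv2 <- metric_curves(stack, n_rand = 5, seed = 9)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1), 51L)
  # nested edge sets: GE never increases as the threshold rises
  expect_true(all(diff(cv1$GE) <= 1e-12))
  expect_true(all(diff(cv1$L[is.finite(cv1$L)]) >= -1e-12) ||
                all(is.finite(cv1$L)))
})

test_that("threshold-AUC matches closed forms and a fine-grid Riemann sum", {
  x <- seq(0.3, 0.8, by = 0.01)
  const <- data.frame(threshold = x, C = 2, L = 2, GE = 2, LE = 2,
                      gamma = 1, lambda = 1, sigma = 2)
  expect_equal(unname(auc_over_thresholds(const)), rep(0.5 * 2, 5))
  lin <- data.frame(threshold = x, C = seq(1, 3, length.out = 51),
                    L = seq(4, 0, length.out = 51),
                    GE = seq(0, 1, length.out = 51),
                    LE = seq(2, 2, length.out = 51),
                    gamma = 1, lambda = 1,
                    sigma = seq(-1, 1, length.out = 51))
  a <- auc_over_thresholds(lin)
  expect_equal(unname(a["aC"]), 0.25 * (1 + 3))
  expect_equal(unname(a["aL"]), 0.25 * (4 + 0))
  expect_equal(unname(a["aSigma"]), 0, tolerance = 1e-12)
  withr::with_seed(5, {
    y <- stats::runif(51)
    curve <- data.frame(threshold = x, C = y, L = y, GE = y, LE = y,
                        gamma = y, lambda = y, sigma = y)
    fine_x <- seq(0.3, 0.8, length.out = 5001)
    fine <- sum(diff(fine_x) * (stats::approx(x, y, fine_x)$y[-1] +
                                  stats::approx(x, y, fine_x)$y[-5001]) / 2)
    expect_equal(unname(auc_over_thresholds(curve)["aC"]), fine,
                 tolerance = 1e-3)
  })
  # NaN entries are excluded pairwise
  gap <- const
  gap$C[c(10, 20)] <- NaN
  expect_true(is.finite(auc_over_thresholds(gap)["aC"]))
})
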