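# Independent brute-force oracles, deliberately written with different
# algorithms than the package (Floyd-Warshall triple loop instead of BFS
# matrix products, explicit neighbour-pair loops instead of matrix traces).

fw_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

brute_node_clustering <- function(adj, i) {
  nb <- which(adj[i, ] > 0)
  if (length(nb) < 2L) return(0)
  e <- 0L
  for (a in seq_along(nb))
    for (b in seq_along(nb))
      if (b > a && adj[nb[a], nb[b]] > 0) e <- e + 1L
  2 * e / (length(nb) * (length(nb) - 1))
}

brute_clustering <- function(adj)
  mean(vapply(seq_len(nrow(adj)), function(i) brute_node_clustering(adj, i),
              numeric(1)))

brute_path_length <- function(adj, policy = "exclude") {
  D <- fw_distances(adj)
  d <- D[upper.tri(D)]
  if (policy == "substitute") d[!is.finite(d)] <- nrow(adj)
  d <- d[is.finite(d)]
  if (!length(d)) NaN else mean(d)
}

brute_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  D <- fw_distances(adj)
  tot <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  tot / (n * (n - 1))
}

brute_local_efficiency <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2L) return(0)
    brute_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

count_triangles <- function(adj) {
  n <- nrow(adj)
  t <- 0L
  for (i in seq_len(n))
    for (j in seq_len(n))
      for (k in seq_len(n))
        if (i < j && j < k && adj[i, j] && adj[j, k] && adj[i, k]) t <- t + 1L
  t
}

pair_values <- function(m) m[upper.tri(m)]

random_graph <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(stats::runif(sum(up)) < p_edge)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

# small fast cohort spec for end-to-end tests
tiny_spec <- function(seed = 1L, duration = 120, ...) {
  cohort_spec(n_group_a = 4L, n_group_b = 3L, n_channels = 12L,
              duration = duration, seed = seed,
              topology_a = topology_params(4L, 0.1),
              topology_b = topology_params(4L, 0.5), ...)
}

# a deterministic synthetic hemo_series from white noise
noise_hemo <- function(n = 600L, p = 6L, fs = 10, seed = 1L) {
  withr::with_seed(seed, {
    hemo_series(matrix(rnorm(n * p), n, p), matrix(rnorm(n * p), n, p), fs = fs)
  })
}
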