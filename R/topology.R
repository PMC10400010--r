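#' Ground-truth topology parameters
#'
#' Parameters of the ring-lattice-plus-rewiring (Watts-Strogatz style)
#' ground-truth network generator. Low rewiring probability gives a
#' lattice-like graph (high clustering, long paths); high probability gives
#' a random-like graph (low clustering, high global efficiency) — the axis
#' along which the two study groups differ.
#'
#' @param k even ring degree (each node initially linked to its `k` nearest
#'   ring neighbours).
#' @param p rewiring probability in `[0, 1]`.
#' @return An object of class `topology_params`.
#' @export
topology_params <- function(k = 4L, p = 0.1) {
  k <- as.integer(k)
  if (k %% 2L != 0L) stopf("ring degree k must be even, got %d", k)
  if (p < 0 || p > 1) stopf("rewiring probability must be in [0, 1]")
  structure(list(k = k, p = p), class = "topology_params")
}

#' Generate a ground-truth small-world network
#'
#' Builds a ring lattice on `n_nodes` nodes with even degree `k`, then
#' rewires each edge with probability `p` to a uniformly chosen new
#' endpoint (no self-loops, no multi-edges), preserving the edge count
#' `n_nodes * k / 2`. The whole rewiring pass is redrawn until the graph is
#' connected, so characteristic path length is always defined on the truth
#' network.
#'
#' @param n_nodes number of nodes (network channels).
#' @param params a [topology_params()].
#' @param seed integer seed; the draw is reproducible.
#' @param max_tries redraw attempts before giving up on connectivity.
#' @return An object of class `truth_network` with elements `adjacency`
#'   (symmetric binary matrix, zero diagonal), `params` and `seed`.
#' @export
generate_topology <- function(n_nodes, params = topology_params(),
                              seed = 1L, max_tries = 200L) {
  if (!inherits(params, "topology_params")) params <- do.call(topology_params, params)
  k <- params$k; p <- params$p
  if (k >= n_nodes) stopf("ring degree k = %d must be smaller than n_nodes = %d",
                          k, n_nodes)
  withr::with_seed(as.integer(seed), {
    for (try in seq_len(max_tries)) {
      adj <- ring_lattice(n_nodes, k)
      if (p > 0) adj <- rewire_lattice(adj, n_nodes, k, p)
      if (all(is.finite(graph_distances(adj)))) {
        return(structure(list(adjacency = adj, params = params, seed = seed),
                         class = "truth_network"))
      }
    }
  })
  stopf("could not draw a connected network in %d tries (n = %d, k = %d, p = %g)",
        max_tries, n_nodes, k, p)
}

ring_lattice <- function(n, k) {
  adj <- matrix(0L, n, n)
  for (off in seq_len(k %/% 2L)) {
    j <- (seq_len(n) - 1L + off) %% n + 1L
    adj[cbind(seq_len(n), j)] <- 1L
    adj[cbind(j, seq_len(n))] <- 1L
  }
  adj
}

# one Watts-Strogatz rewiring pass over the lattice edges, edge count kept
rewire_lattice <- function(adj, n, k, p) {
  for (off in seq_len(k %/% 2L)) {
    for (i in seq_len(n)) {
      if (stats::runif(1) >= p) next
      j_old <- (i - 1L + off) %% n + 1L
      if (!adj[i, j_old]) next   # already rewired away by an earlier step
      cand <- which(adj[i, ] == 0L)
      cand <- cand[cand != i]
      if (!length(cand)) next
      j_new <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      adj[i, j_old] <- adj[j_old, i] <- 0L
      adj[i, j_new] <- adj[j_new, i] <- 1L
    }
  }
  adj
}

#' Map a truth network to a valid correlation model
#'
#' Builds the model covariance (a correlation matrix) from the truth
#' adjacency `A` with a random-walk (resolvent) kernel:
#' `Sigma0 = (I - alpha A)^{-1}` with `alpha = coupling / lambda_max(A)`,
#' rescaled to unit diagonal, then optionally mixed with a channel-common
#' floor: `Sigma = (1 - base) Sigma0 + base J`. The kernel gives graded
#' correlations that decay with topological distance — adjacent pairs
#' strongest, two-hop pairs intermediate — the way functional coupling
#' spreads over a connectome; `coupling` is the fraction of the spectral
#' critical point, so any value in (0, 1) yields a positive-definite
#' model (eigenvalues `1 / (1 - alpha lambda)` are all positive below the
#' critical point). The `base` term adds channel-common correlation
#' (systemic physiology shared by all channels), needed to reach the high
#' mean functional-connectivity levels seen in resting fNIRS; mixing two
#' PSD terms convexly keeps the PSD guarantee.
#'
#' @param net a [truth_network()][generate_topology].
#' @param coupling network coupling strength in (0, 1), the fraction of
#'   the spectral critical point `1 / lambda_max(A)`.
#' @param base common correlation floor in `[0, 1)`, default 0.
#' @return Correlation matrix with attributes `alpha`, `base` and
#'   `model_mean_fc` (model mean off-diagonal correlation).
#' @export
topology_to_covariance <- function(net, coupling, base = 0) {
  adj <- if (inherits(net, "truth_network")) net$adjacency else as.matrix(net)
  if (coupling <= 0 || coupling >= 1) stopf("coupling must be in (0, 1)")
  if (base < 0 || base >= 1) stopf("base correlation must be in [0, 1)")
  n <- nrow(adj)
  ev_max <- max(eigen(adj, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_max <= 0) {   # empty graph: identity model
    sigma <- (1 - base) * diag(n) + base
    return(structure(sigma, alpha = 0, base = base,
                     model_mean_fc = mean(pair_values(sigma))))
  }
  alpha <- coupling / ev_max
  s0 <- solve(diag(n) - alpha * adj)
  d <- 1 / sqrt(diag(s0))
  s0 <- s0 * outer(d, d)
  sigma <- (1 - base) * s0 + base
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stopf("internal error: covariance model is not PSD (min eigenvalue %g)",
          min(ev))
  structure(sigma, alpha = alpha, base = base,
            model_mean_fc = mean(pair_values(sigma)))
}

#' Calibrate the common correlation floor to a target mean connectivity
#'
#' Solves for the `base` term of [topology_to_covariance()] such that the
#' model's mean off-diagonal correlation equals `target_mean_r`, given the
#' coupling. With `m0` the kernel's mean off-diagonal correlation at
#' `base = 0`, the model mean is `base + (1 - base) m0`, so
#' `base = (target - m0) / (1 - m0)`.
#'
#' @param net a truth network.
#' @param target_mean_r desired model mean off-diagonal Pearson r.
#' @param coupling coupling passed to [topology_to_covariance()].
#' @return The `base` value in `[0, 1)`.
#' @export
calibrate_base_correlation <- function(net, target_mean_r, coupling = 0.9) {
  m0 <- attr(topology_to_covariance(net, coupling, base = 0), "model_mean_fc")
  base <- (target_mean_r - m0) / (1 - m0)
  if (base < 0 || base >= 1)
    stopf("target mean r = %g not reachable with coupling %g (implied base %g)",
          target_mean_r, coupling, base)
  base
}
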