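#' Shortest-path distance matrix of a binary network
#'
#' Breadth-first expansion by boolean matrix products; distances are hop
#' counts, `Inf` for disconnected pairs, 0 on the diagonal.
#'
#' @param adj symmetric binary adjacency matrix, zero diagonal.
#' @return Numeric matrix of shortest-path lengths.
#' @export
graph_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n < 2L) return(D)
  A <- (adj > 0) + 0
  reach <- A
  D[reach > 0 & !is.finite(D)] <- 1
  d <- 1L
  while (d < n) {
    reach <- (reach %*% A > 0) + 0
    new <- reach > 0 & !is.finite(D)
    if (!any(new)) break
    d <- d + 1L
    D[new] <- d
  }
  D
}

#' Node clustering coefficient
#'
#' `C_i = 2 e_i / (n_i (n_i - 1))` where `e_i` counts edges among the
#' neighbours of node `i` and `n_i` is its degree; nodes with degree < 2
#' get `C_i = 0` by convention.
#'
#' @param adj binary adjacency matrix.
#' @param i node index; if `NULL`, the vector for all nodes is returned.
#' @return Clustering coefficient(s) in `[0, 1]`.
#' @export
node_clustering <- function(adj, i = NULL) {
  A <- (adj > 0) + 0
  deg <- colSums(A)
  tri <- diag(A %*% A %*% A)       # 2 * e_i
  ci <- ifelse(deg >= 2, tri / (deg * (deg - 1)), 0)
  if (is.null(i)) ci else ci[i]
}

#' Network clustering coefficient
#'
#' Mean of the node clustering coefficients over all nodes.
#' @param adj binary adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
network_clustering <- function(adj) mean(node_clustering(adj))

#' Characteristic path length
#'
#' Mean shortest-path length over node pairs. Sparse networks fragment, so
#' two policies for disconnected pairs are exposed: `"exclude"` (default)
#' drops them from the mean; `"substitute"` scores them with the
#' pseudo-distance `N` (one more than the longest possible path). The
#' policy in force is attached as an attribute.
#'
#' @param adj binary adjacency matrix.
#' @param policy `"exclude"` or `"substitute"`.
#' @return Scalar path length (`NaN` with a warning if the graph has no
#'   edges).
#' @export
characteristic_path_length <- function(adj,
                                       policy = c("exclude", "substitute")) {
  policy <- match.arg(policy)
  n <- nrow(adj)
  D <- graph_distances(adj)
  d <- D[upper.tri(D)]
  if (policy == "substitute") d[!is.finite(d)] <- n
  d <- d[is.finite(d)]
  if (!length(d)) {
    warning("network has no connected pairs; characteristic path length undefined")
    return(structure(NaN, policy = policy))
  }
  structure(mean(d), policy = policy)
}

#' Global efficiency
#'
#' Mean reciprocal shortest-path length over ordered node pairs, with
#' `1/Inf = 0` for disconnected pairs.
#'
#' @param adj binary adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(0)
  D <- graph_distances(adj)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbours (the node itself excluded); nodes with degree < 2 contribute
#' 0. `normalization = "standard"` averages over nodes (1/N, the mean its
#' defining prose describes); `"printed"` applies a 1/(N(N-1)) prefactor
#' instead, reproducing the formula exactly as typeset in the source
#' method.
#'
#' @param adj binary adjacency matrix.
#' @param normalization `"standard"` or `"printed"`.
#' @return Scalar (in `[0, 1]` under `"standard"`).
#' @export
local_efficiency <- function(adj, normalization = c("standard", "printed")) {
  normalization <- match.arg(normalization)
  A <- (adj > 0) + 0
  n <- nrow(A)
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  if (normalization == "standard") mean(eff) else sum(eff) / (n * (n - 1))
}

#' Degree-preserving network randomization
#'
#' Maslov-Sneppen double-edge swaps: repeatedly pick two edges (a,b), (c,d)
#' and rewire them to (a,d), (c,b) when that creates no self-loop or
#' multi-edge. The degree sequence is preserved exactly. Complete (or
#' empty) graphs have no legal swap and are returned unchanged.
#'
#' @param adj binary adjacency matrix.
#' @param n_swaps number of swap attempts; default `10 *` edge count.
#' @param seed integer seed.
#' @return Randomized adjacency with attribute `swaps` (successful swap
#'   count). Warns if no swap succeeded on a swappable graph.
#' @export
degree_preserving_randomize <- function(adj, n_swaps = NULL, seed = 1L) {
  A <- (adj > 0) + 0
  n <- nrow(A)
  p <- pair_index(n)
  sel <- A[p] > 0
  E <- p[sel, , drop = FALSE]
  m <- nrow(E)
  if (m < 2L) return(structure(A, swaps = 0L))
  n_swaps <- n_swaps %||% (10L * m)
  withr::with_seed(as.integer(seed), {
    e1 <- sample.int(m, n_swaps, replace = TRUE)
    e2 <- sample.int(m, n_swaps, replace = TRUE)
    flip <- stats::runif(n_swaps) < 0.5
  })
  swaps <- 0L
  for (s in seq_len(n_swaps)) {
    i <- e1[s]; j <- e2[s]
    if (i == j) next
    a <- E[i, 1L]; b <- E[i, 2L]
    c <- E[j, 1L]; d <- E[j, 2L]
    if (flip[s]) { tmp <- c; c <- d; d <- tmp }
    # propose (a,d) and (c,b)
    if (a == d || c == b || a == c || b == d) next
    if (A[a, d] || A[c, b]) next
    A[a, b] <- A[b, a] <- 0
    A[c, d] <- A[d, c] <- 0
    A[a, d] <- A[d, a] <- 1
    A[c, b] <- A[b, c] <- 1
    E[i, ] <- c(a, d); E[j, ] <- c(c, b)
    swaps <- swaps + 1L
  }
  complete <- m == n * (n - 1) / 2
  if (swaps == 0L && !complete)
    warning("no legal double-edge swap found; returning the input network")
  structure(A, swaps = swaps)
}

#' Small-worldness against degree-preserving random references
#'
#' Computes `gamma = C / C_rand`, `lambda = L / L_rand` and
#' `sigma = gamma / lambda`, where `C_rand` and `L_rand` are means over
#' `n_rand` degree-preserving randomizations of the network. Degenerate
#' networks (empty or complete, which randomization leaves unchanged)
#' return 1 for all three ratios with `degenerate = TRUE`.
#'
#' @param adj binary adjacency matrix.
#' @param n_rand number of random reference networks.
#' @param seed integer seed; replicate `r` uses `seed + r`.
#' @param policy disconnected-pair policy for path lengths, see
#'   [characteristic_path_length()].
#' @return List with `gamma`, `lambda`, `sigma`, `C`, `L`, `C_rand`,
#'   `L_rand`, `degenerate`.
#' @export
small_worldness <- function(adj, n_rand = 100L, seed = 1L,
                            policy = c("exclude", "substitute")) {
  policy <- match.arg(policy)
  A <- (adj > 0) + 0
  n <- nrow(A)
  m <- sum(A) / 2
  if (m == 0 || m == n * (n - 1) / 2) {
    C <- network_clustering(A)
    L <- suppressWarnings(as.numeric(characteristic_path_length(A, policy)))
    return(list(gamma = 1, lambda = 1, sigma = 1, C = C, L = L,
                C_rand = C, L_rand = L, degenerate = TRUE))
  }
  C <- network_clustering(A)
  L <- suppressWarnings(as.numeric(characteristic_path_length(A, policy)))
  cr <- lr <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    R <- suppressWarnings(degree_preserving_randomize(A, seed = seed + r))
    cr[r] <- network_clustering(R)
    lr[r] <- suppressWarnings(as.numeric(characteristic_path_length(R, policy)))
  }
  C_rand <- mean(cr)
  L_rand <- mean(lr, na.rm = TRUE)
  gamma <- if (C_rand > 0) C / C_rand else NaN
  lambda <- if (is.finite(L_rand) && L_rand > 0) L / L_rand else NaN
  sigma <- if (is.finite(gamma) && is.finite(lambda) && lambda > 0)
    gamma / lambda else NaN
  list(gamma = gamma, lambda = lambda, sigma = sigma, C = C, L = L,
       C_rand = C_rand, L_rand = L_rand, degenerate = FALSE)
}

#' Metric-versus-threshold curves for one subject
#'
#' Evaluates clustering, characteristic path length, global and local
#' efficiency, and the normalized ratios gamma/lambda/sigma at every level
#' of a binary network stack. The random-reference seed at threshold index
#' `t` is `seed + t`, so curves are reproducible level by level.
#'
#' @param stack a [build_threshold_stack()] result.
#' @param n_rand random references per threshold for sigma.
#' @param seed master integer seed.
#' @param policy disconnected-pair policy, see
#'   [characteristic_path_length()].
#' @param le_normalization local-efficiency prefactor, see
#'   [local_efficiency()].
#' @return A data frame of class `metric_curves` with columns `threshold`,
#'   `C`, `L`, `GE`, `LE`, `gamma`, `lambda`, `sigma`.
#' @export
metric_curves <- function(stack, n_rand = 100L, seed = 1L,
                          policy = c("exclude", "substitute"),
                          le_normalization = c("standard", "printed")) {
  stopifnot(inherits(stack, "network_stack"))
  policy <- match.arg(policy)
  le_normalization <- match.arg(le_normalization)
  nt <- length(stack$thresholds)
  out <- data.frame(threshold = stack$thresholds, C = NA_real_, L = NA_real_,
                    GE = NA_real_, LE = NA_real_, gamma = NA_real_,
                    lambda = NA_real_, sigma = NA_real_)
  for (t in seq_len(nt)) {
    A <- stack$adjacency[[t]]
    sw <- small_worldness(A, n_rand = n_rand, seed = seed + t, policy = policy)
    out$C[t] <- sw$C
    out$L[t] <- sw$L
    out$GE[t] <- global_efficiency(A)
    out$LE[t] <- local_efficiency(A, le_normalization)
    out$gamma[t] <- sw$gamma
    out$lambda[t] <- sw$lambda
    out$sigma[t] <- sw$sigma
  }
  structure(out, class = c("metric_curves", "data.frame"),
            policy = policy, le_normalization = le_normalization,
            n_rand = n_rand, seed = seed)
}

#' Threshold-AUC features of metric curves
#'
#' Trapezoidal area of each metric over the sparsity-threshold interval, a
#' threshold-free scalar summary of the curve. Non-finite curve entries are
#' dropped pairwise with their abscissae; an all-NaN curve yields `NaN`.
#'
#' @param curves a [metric_curves()] data frame.
#' @return Named numeric vector `aC`, `aL`, `aGE`, `aLE`, `aSigma`.
#' @export
auc_over_thresholds <- function(curves) {
  stopifnot(is.data.frame(curves), nrow(curves) >= 2L)
  x <- curves$threshold
  c(aC = trapz_na(x, curves$C),
    aL = trapz_na(x, curves$L),
    aGE = trapz_na(x, curves$GE),
    aLE = trapz_na(x, curves$LE),
    aSigma = trapz_na(x, curves$sigma))
}
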