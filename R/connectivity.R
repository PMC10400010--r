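#' Per-subject connectivity matrix
#'
#' Pearson correlation of every channel pair over the analysis window,
#' with the diagonal forced to zero by convention, plus the Fisher
#' r-to-z transform of the off-diagonal values.
#'
#' @param hemo a windowed [hemo_series()]; correlations are computed on
#'   the oxyhemoglobin series (the species analysed downstream).
#' @return An object of class `connectivity_matrix` with elements `r`,
#'   `z` (both n x n, zero diagonal) and `channel_ids`.
#' @export
correlation_matrix <- function(hemo) {
  stopifnot(inherits(hemo, "hemo_series"))
  X <- hemo$hbo2
  if (nrow(X) < 3L) stopf("need at least 3 samples to correlate channels")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance channel(s): %s",
          paste(hemo$channel_ids[sds == 0], collapse = ", "))
  r <- stats::cor(X)
  diag(r) <- 0
  out <- structure(list(r = r, z = NULL, channel_ids = hemo$channel_ids),
                   class = "connectivity_matrix")
  fisher_z(out)
}

#' Fisher r-to-z transform of a connectivity matrix
#'
#' Elementwise `z = atanh(r)` on the off-diagonal, improving normality of
#' the correlation values; `|r| >= 1 - 1e-7` is clipped before the
#' transform so boundary values stay finite. The diagonal stays zero.
#'
#' @param conn a `connectivity_matrix` (or a plain correlation matrix).
#' @return The input with its `z` slot filled (or, for matrix input, the
#'   z matrix).
#' @export
fisher_z <- function(conn) {
  if (is.matrix(conn)) {
    z <- atanh(clip_r(conn))
    diag(z) <- 0
    return(z)
  }
  stopifnot(inherits(conn, "connectivity_matrix"))
  conn$z <- atanh(clip_r(conn$r))
  diag(conn$z) <- 0
  conn
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d, mean off-diagonal r = %.3f\n",
              nrow(x$r), ncol(x$r), mean_fc(x)))
  invisible(x)
}

# retained edge count at a proportional threshold
retained_edges <- function(n_pairs, theta, convention) {
  frac <- if (convention == "one_minus_theta") 1 - theta else theta
  as.integer(round_half_up(frac * n_pairs))
}

#' Proportional binarization of a connectivity matrix
#'
#' Ranks the absolute Fisher-z values of the `n(n-1)/2` channel pairs in
#' descending order and keeps the strongest fraction as edges, so every
#' subject's network has the identical edge count at a given threshold
#' ("compared under the same connection"). Under the default convention
#' the retained fraction is `1 - theta` (a threshold of 0.6 keeps the top
#' 40% of pairs); `convention = "theta"` retains fraction `theta`
#' instead. The retained count is `round(frac * n(n-1)/2)`, rounding half
#' away from zero; ties in `|z|` are broken by stable row-major pair
#' order, making the output deterministic.
#'
#' @param conn a `connectivity_matrix`.
#' @param theta sparsity threshold in (0, 1).
#' @param convention `"one_minus_theta"` (default) or `"theta"`.
#' @return Binary adjacency matrix (symmetric, zero diagonal) with
#'   attribute `retained_fraction`.
#' @export
proportional_binarize <- function(conn, theta,
                                  convention = c("one_minus_theta", "theta")) {
  convention <- match.arg(convention)
  if (theta <= 0 || theta >= 1) stopf("threshold must be in (0, 1)")
  stopifnot(inherits(conn, "connectivity_matrix"))
  n <- nrow(conn$z)
  p <- pair_index(n)
  w <- abs(conn$z[p])
  k <- retained_edges(length(w), theta, convention)
  ord <- order(-w, seq_along(w))    # stable: ties by row-major pair order
  adj <- matrix(0L, n, n)
  if (k > 0L) {
    keep <- p[ord[seq_len(k)], , drop = FALSE]
    adj[keep] <- 1L
    adj[keep[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  structure(adj, retained_fraction = k / length(w))
}

#' Binary network stack over a sparsity-threshold range
#'
#' Applies [proportional_binarize()] at every threshold of the range
#' (default 0.30 to 0.80 in steps of 0.01: 51 levels). The pair ranking is
#' computed once and shared by all levels, so the stack is nested: the
#' edge set at a larger threshold is a subset of the edge set at a smaller
#' one.
#'
#' @param conn a `connectivity_matrix`.
#' @param lo,hi,step threshold range and step.
#' @param convention see [proportional_binarize()].
#' @return An object of class `network_stack`: `thresholds`, `adjacency`
#'   (list of binary matrices), `retained_fraction`, `convention`.
#' @export
build_threshold_stack <- function(conn, lo = 0.30, hi = 0.80, step = 0.01,
                                  convention = c("one_minus_theta", "theta")) {
  convention <- match.arg(convention)
  stopifnot(inherits(conn, "connectivity_matrix"), lo < hi, step > 0)
  thresholds <- round(seq(lo, hi, by = step), 10)
  n <- nrow(conn$z)
  p <- pair_index(n)
  w <- abs(conn$z[p])
  ord <- order(-w, seq_along(w))
  adjacency <- lapply(thresholds, function(th) {
    k <- retained_edges(length(w), th, convention)
    adj <- matrix(0L, n, n)
    if (k > 0L) {
      keep <- p[ord[seq_len(k)], , drop = FALSE]
      adj[keep] <- 1L
      adj[keep[, c(2L, 1L), drop = FALSE]] <- 1L
    }
    structure(adj, retained_fraction = k / length(w))
  })
  structure(list(thresholds = thresholds, adjacency = adjacency,
                 retained_fraction = vapply(adjacency, attr, numeric(1),
                                            "retained_fraction"),
                 convention = convention),
            class = "network_stack")
}

#' @export
print.network_stack <- function(x, ...) {
  cat(sprintf("<network_stack> %d thresholds in [%.2f, %.2f], convention %s\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              x$convention))
  invisible(x)
}

#' Mean functional connectivity of one subject
#'
#' Mean of the unique off-diagonal Pearson correlations; the group-level
#' mean FC is the average of this value over a group's subjects.
#'
#' @param conn a `connectivity_matrix` (or plain correlation matrix with
#'   zero diagonal).
#' @return Scalar mean off-diagonal r.
#' @export
mean_fc <- function(conn) {
  r <- if (inherits(conn, "connectivity_matrix")) conn$r else as.matrix(conn)
  mean(pair_values(r))
}
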