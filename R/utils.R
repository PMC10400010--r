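# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom withr with_seed
NULL

# round-half-away-from-zero; base round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

# clip correlations away from +/-1 before atanh
clip_r <- function(r, eps = 1e-7) pmin(pmax(r, -(1 - eps)), 1 - eps)

# trapezoidal integral, NaN/NA entries dropped pairwise with their abscissae
trapz_na <- function(x, y) {
  keep <- is.finite(y)
  if (sum(keep) < 2L) return(NaN)
  x <- x[keep]; y <- y[keep]
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# upper-triangle pairs in row-major order: (1,2),(1,3),...,(1,n),(2,3),...
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

# values of a symmetric matrix at the row-major upper-triangle pairs
pair_values <- function(m) {
  p <- pair_index(nrow(m))
  m[cbind(p[, 1L], p[, 2L])]
}
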