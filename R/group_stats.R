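# scalar pooled / Welch two-sample t; the vectorised core used by
# threshold-wise comparisons and permutation tests
t_core <- function(a, b, variant = "student", strict = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) return(c(t = NaN, p = NaN, df = NaN))
  va <- stats::var(a); vb <- stats::var(b)
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) {
      if (strict) stopf("zero pooled variance: groups are constant")
      return(c(t = NaN, p = NaN, df = NaN))
    }
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (va == 0 && vb == 0) {
      if (strict) stopf("zero variance in both groups")
      return(c(t = NaN, p = NaN, df = NaN))
    }
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  c(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Two-independent-sample t-test
#'
#' Classical pooled-variance Student test by default (`variant =
#' "student"`); `"welch"` drops the equal-variance assumption. Two-sided.
#'
#' @param a,b numeric vectors (each with >= 2 finite values).
#' @param variant `"student"` or `"welch"`.
#' @return Named vector `t`, `p`, `df`.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  t_core(a, b, match.arg(variant))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values with monotonicity enforcement (wraps the
#' standard BH adjustment); `NA`s are passed through.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return Adjusted q-values, same length.
#' @export
fdr_correct <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# contiguous TRUE runs of a logical vector as (from, to) index pairs
contiguous_ranges <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(from = starts[r$values], to = ends[r$values])
}

#' Threshold-wise group comparison of metric curves
#'
#' At every sparsity threshold, compares the two groups' metric values
#' with a two-sample t-test; p-values are FDR-corrected within each
#' metric's threshold family (the tests that share one curve panel), or
#' globally across all metrics with `fdr_family = "global"`. Non-finite
#' curve entries are dropped per threshold with counts reported.
#'
#' @param curves list of [metric_curves()] data frames, one per subject.
#' @param labels character/factor group labels, two groups, >= 2 subjects
#'   each.
#' @param metrics metric columns to compare.
#' @param alpha significance level for the FDR-corrected mask.
#' @param fdr_family `"per_metric"` or `"global"`.
#' @param variant t-test variant, see [two_sample_t()].
#' @return Object of class `group_stats`: per metric a data frame
#'   (`threshold`, group means, `t`, `p`, `q`, `significant`,
#'   `n_dropped`), plus `significant_ranges` (contiguous threshold runs
#'   with `q < alpha`).
#' @export
threshold_wise_comparison <- function(curves, labels,
                                      metrics = c("C", "L", "GE", "LE", "sigma"),
                                      alpha = 0.05,
                                      fdr_family = c("per_metric", "global"),
                                      variant = c("student", "welch")) {
  fdr_family <- match.arg(fdr_family)
  variant <- match.arg(variant)
  labels <- as.character(labels)
  grp <- sort(unique(labels))
  if (length(grp) != 2L) stopf("need exactly two groups, got %d", length(grp))
  if (min(table(labels)) < 2L) stopf("need >= 2 subjects per group")
  thresholds <- curves[[1L]]$threshold
  tables <- lapply(metrics, function(m) {
    M <- vapply(curves, function(cv) cv[[m]], numeric(length(thresholds)))
    A <- M[, labels == grp[1L], drop = FALSE]
    B <- M[, labels == grp[2L], drop = FALSE]
    res <- t(vapply(seq_along(thresholds), function(i) {
      a <- A[i, ]; b <- B[i, ]
      dropped <- sum(!is.finite(a)) + sum(!is.finite(b))
      c(t_core(a, b, variant, strict = FALSE)[c("t", "p")],
        mean_a = mean(a[is.finite(a)]), mean_b = mean(b[is.finite(b)]),
        n_dropped = dropped)
    }, numeric(5)))
    data.frame(threshold = thresholds, metric = m,
               mean_a = res[, "mean_a"], mean_b = res[, "mean_b"],
               t = res[, "t"], p = res[, "p"],
               n_dropped = as.integer(res[, "n_dropped"]))
  })
  names(tables) <- metrics
  if (fdr_family == "per_metric") {
    tables <- lapply(tables, function(tb) { tb$q <- fdr_correct(tb$p); tb })
  } else {
    all_p <- unlist(lapply(tables, `[[`, "p"))
    all_q <- fdr_correct(all_p)
    idx <- 0L
    tables <- lapply(tables, function(tb) {
      tb$q <- all_q[idx + seq_len(nrow(tb))]
      idx <<- idx + nrow(tb)
      tb
    })
  }
  tables <- lapply(tables, function(tb) {
    tb$significant <- !is.na(tb$q) & tb$q < alpha
    tb
  })
  ranges <- lapply(tables, function(tb) {
    rg <- contiguous_ranges(tb$significant)
    if (nrow(rg))
      data.frame(from = tb$threshold[rg$from], to = tb$threshold[rg$to])
    else data.frame(from = numeric(0), to = numeric(0))
  })
  structure(list(tables = tables, significant_ranges = ranges,
                 groups = grp, alpha = alpha, fdr_family = fdr_family,
                 variant = variant),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> groups %s vs %s, alpha = %g, FDR family: %s\n",
              x$groups[1L], x$groups[2L], x$alpha, x$fdr_family))
  for (m in names(x$tables)) {
    rg <- x$significant_ranges[[m]]
    cat(sprintf("  %-6s significant thresholds: %s\n", m,
                if (nrow(rg)) paste(sprintf("[%.2f, %.2f]", rg$from, rg$to),
                                    collapse = ", ") else "none"))
  }
  invisible(x)
}

#' Group comparison of mean functional connectivity
#'
#' Group descriptive statistics (mean, sd with `n - 1` denominator) of
#' per-subject mean FC values plus the two-sample t-test.
#'
#' @param fc numeric per-subject mean FC values.
#' @param labels group labels.
#' @param variant t-test variant.
#' @return List with `summary` (per-group n, mean, sd), `t`, `p`, `df`.
#' @export
compare_mean_fc <- function(fc, labels, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  labels <- as.character(labels)
  grp <- sort(unique(labels))
  if (length(grp) != 2L) stopf("need exactly two groups")
  a <- fc[labels == grp[1L]]
  b <- fc[labels == grp[2L]]
  tt <- t_core(a, b, variant)
  list(summary = data.frame(group = grp,
                            n = c(length(a), length(b)),
                            mean = c(mean(a), mean(b)),
                            sd = c(stats::sd(a), stats::sd(b))),
       t = unname(tt["t"]), p = unname(tt["p"]), df = unname(tt["df"]))
}

#' Select threshold-AUC features for classification
#'
#' Compares each threshold-AUC feature between groups with a two-sample
#' t-test and selects those significant at `alpha`. Selection uses raw
#' p-values by default (the selection rule as stated); `select_on =
#' "fdr"` selects on BH-adjusted values instead. Statistics for all
#' features are always reported.
#'
#' @param auc matrix/data frame subjects x features (e.g. columns `aC`,
#'   `aL`, `aGE`, `aLE`, `aSigma`).
#' @param labels group labels.
#' @param alpha selection level.
#' @param select_on `"raw"` or `"fdr"`.
#' @param variant t-test variant.
#' @return List with `table` (feature, t, p, q, selected) and `selected`
#'   (character vector of feature names).
#' @export
select_auc_features <- function(auc, labels, alpha = 0.05,
                                select_on = c("raw", "fdr"),
                                variant = c("student", "welch")) {
  select_on <- match.arg(select_on)
  variant <- match.arg(variant)
  auc <- as.matrix(auc)
  labels <- as.character(labels)
  grp <- sort(unique(labels))
  if (length(grp) != 2L) stopf("need exactly two groups")
  res <- t(apply(auc, 2L, function(v)
    t_core(v[labels == grp[1L]], v[labels == grp[2L]], variant)[c("t", "p")]))
  tb <- data.frame(feature = colnames(auc), t = res[, "t"], p = res[, "p"])
  tb$q <- fdr_correct(tb$p)
  tb$selected <- if (select_on == "raw") tb$p < alpha else tb$q < alpha
  tb$selected[is.na(tb$selected)] <- FALSE
  list(table = tb, selected = tb$feature[tb$selected])
}
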