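test_that("two-sample t matches stats::t.test for both variants", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      a <- stats::rnorm(sample(3:12, 1), sd = stats::runif(1, 0.5, 2))
      b <- stats::rnorm(sample(3:12, 1), mean = stats::runif(1, -1, 1))
      s <- two_sample_t(a, b, "student")
      ref <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(unname(s["t"]), unname(ref$statistic))
      expect_equal(unname(s["p"]), ref$p.value)
      w <- two_sample_t(a, b, "welch")
      refw <- stats::t.test(a, b)
      expect_equal(unname(w["t"]), unname(refw$statistic))
      expect_equal(unname(w["p"]), refw$p.value)
      expect_equal(unname(w["df"]), unname(refw$parameter))
    }
  })
  same <- c(1, 2, 3)
  r <- two_sample_t(same, same)
  expect_equal(unname(r["t"]), 0)
  expect_equal(unname(r["p"]), 1)
  r2 <- two_sample_t(same, same + 100)
  expect_lt(unname(r2["p"]), 0.01)
  expect_error(two_sample_t(c(1, 1, 1), c(1, 1)), "variance")
})

# independent BH step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

test_that("FDR correction equals the hand step-up oracle", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(fdr_correct(0.03), 0.03)
  withr::with_seed(52, {
    for (rep in 1:20) {
      p <- stats::runif(sample(3:60, 1))
      q <- fdr_correct(p)
      expect_equal(q, bh_oracle(p))
      expect_true(all(q >= p - 1e-15))
    }
  })
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

fake_curves <- function(n_subj, shift = 0, seed = 1, nt = 51) {
  withr::with_seed(seed, lapply(seq_len(n_subj), function(i)
    data.frame(threshold = seq(0.3, 0.8, length.out = nt),
               C = stats::rnorm(nt, shift), L = stats::rnorm(nt, shift),
               GE = stats::rnorm(nt), LE = stats::rnorm(nt),
               gamma = stats::rnorm(nt), lambda = stats::rnorm(nt),
               sigma = stats::rnorm(nt))))
}

test_that("threshold-wise comparison reports t/p/q and significant ranges", {
  curves <- c(fake_curves(8, shift = 3, seed = 3), fake_curves(6, seed = 4))
  labels <- rep(c("A", "B"), c(8, 6))
  gs <- threshold_wise_comparison(curves, labels)
  tb <- gs$tables$C
  expect_equal(nrow(tb), 51L)
  expect_true(all(tb$q >= tb$p - 1e-15, na.rm = TRUE))
  expect_true(all(tb$significant == (tb$q < 0.05)))
  expect_gt(nrow(gs$significant_ranges$C), 0)
  expect_true(all(sign(tb$t) == 1))   # A shifted up
  # identical groups: empty significant mask after FDR
  curves0 <- c(fake_curves(6, seed = 5), fake_curves(6, seed = 5))
  gs0 <- threshold_wise_comparison(curves0, rep(c("A", "B"), each = 6))
  expect_equal(nrow(gs0$significant_ranges$C), 0)
  # per-threshold t matches the scalar test on extracted columns
  colC <- vapply(curves, function(cv) cv$C[10], numeric(1))
  ref <- two_sample_t(colC[labels == "A"], colC[labels == "B"])
  expect_equal(tb$t[10], unname(ref["t"]))
  expect_equal(tb$p[10], unname(ref["p"]))
})

test_that("NaN curve entries are dropped pairwise with counts", {
  curves <- c(fake_curves(5, seed = 6), fake_curves(5, seed = 7))
  curves[[1]]$C[3] <- NaN
  gs <- threshold_wise_comparison(curves, rep(c("A", "B"), each = 5))
  expect_equal(gs$tables$C$n_dropped[3], 1L)
  expect_true(is.finite(gs$tables$C$t[3]))
})

test_that("label permutation of a null cohort is calibrated near alpha", {
  curves <- c(fake_curves(21, seed = 8), fake_curves(12, seed = 9))
  labels <- rep(c("A", "B"), c(21, 12))
  rate <- mean(vapply(1:150, function(i) {
    perm <- withr::with_seed(1000 + i, sample(labels))
    gs <- threshold_wise_comparison(curves, perm, metrics = "C")
    mean(gs$tables$C$p < 0.05)
  }, numeric(1)))
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("mean-FC comparison returns exact descriptives and test", {
  fc <- c(0.7, 0.75, 0.8, 0.9, 0.85, 0.95)
  lab <- rep(c("A", "B"), each = 3)
  res <- compare_mean_fc(fc, lab)
  expect_equal(res$summary$mean, c(mean(fc[1:3]), mean(fc[4:6])))
  # sd with n-1 denominator, by hand
  expect_equal(res$summary$sd[1],
               sqrt(sum((fc[1:3] - mean(fc[1:3]))^2) / 2))
  ref <- stats::t.test(fc[1:3], fc[4:6], var.equal = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  same <- compare_mean_fc(c(1, 2, 3, 1, 2, 3), lab)
  expect_equal(same$t, 0)
})

test_that("AUC feature selection follows the stated p < alpha rule", {
  withr::with_seed(53, {
    auc <- cbind(aC = stats::rnorm(20), aL = stats::rnorm(20),
                 aGE = stats::rnorm(20), aLE = stats::rnorm(20),
                 aSigma = stats::rnorm(20))
    lab <- rep(c("A", "B"), each = 10)
    auc[lab == "A", "aGE"] <- auc[lab == "A", "aGE"] + 5   # 5-sd shift
    sel <- select_auc_features(auc, lab)
    expect_true("aGE" %in% sel$selected)
    expect_equal(nrow(sel$table), 5L)
    expect_identical(sel$table$selected, sel$table$p < 0.05)
    # alpha = 0 selects nothing
    expect_length(select_auc_features(auc, lab, alpha = 0)$selected, 0L)
    # shifted feature is always found across replicates
    hits <- vapply(1:50, function(i) {
      a2 <- cbind(aC = stats::rnorm(20), aLE = stats::rnorm(20))
      a2[lab == "A", "aLE"] <- a2[lab == "A", "aLE"] + 5
      "aLE" %in% select_auc_features(a2, lab)$selected
    }, logical(1))
    expect_true(all(hits))
    # under the null the per-feature selection rate is near alpha
    null_rate <- mean(vapply(1:200, function(i) {
      a0 <- cbind(aC = stats::rnorm(20))
      length(select_auc_features(a0, lab)$selected) > 0
    }, logical(1)))
    expect_lt(abs(null_rate - 0.05), 0.04)
  })
})
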