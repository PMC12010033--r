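test_that("exact Mann-Whitney p matches hand enumeration on worked examples", {
  # {1,2} vs {3,4}: U = 0; among the 6 labelings of 4 distinct ranks,
  # |U - 2| >= 2 for exactly {0, 4} -> p = 2/6
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 1 / 3)
  expect_identical(mw$method, "exact")

  # complete symmetry under ties
  mw2 <- mann_whitney(c(5, 5), c(5, 5))
  expect_equal(mw2$u_statistic, 2)   # n1*n2/2
  expect_equal(mw2$p_value, 1)
  expect_equal(mw2$z_statistic, 0)

  # interleaved groups vs brute force over C(6,3) = 20 labelings
  mw3 <- mann_whitney(c(1, 3, 5), c(2, 4, 6))
  expect_equal(mw3$u_statistic, oracle_u(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(mw3$p_value, oracle_mw_exact_p(c(1, 3, 5), c(2, 4, 6)))
})

test_that("exact Mann-Whitney equals brute-force enumeration with ties", {
  set.seed(11)
  for (rep in 1:60) {
    d <- random_tied_pair()
    mw <- mann_whitney(d$a, d$b, method = "exact")
    expect_equal(mw$u_statistic, oracle_u(d$a, d$b))
    expect_equal(mw$p_value, oracle_mw_exact_p(d$a, d$b), tolerance = 1e-12)
  }
})

test_that("mann_whitney is symmetric in its two groups", {
  set.seed(12)
  for (rep in 1:20) {
    d <- random_tied_pair()
    f <- mann_whitney(d$a, d$b, method = "exact")
    r <- mann_whitney(d$b, d$a, method = "exact")
    expect_equal(f$u_statistic + r$u_statistic, f$n1 * f$n2)
    expect_equal(f$z_statistic, -r$z_statistic)
    expect_equal(f$p_value, r$p_value)
  }
})

test_that("normal approximation agrees with the reference implementation", {
  set.seed(13)
  for (rep in 1:20) {
    a <- sample(0:12, 15, replace = TRUE)
    b <- sample(0:12, 15, replace = TRUE) + rbinom(15, 2, 0.4)
    mw <- mann_whitney(a, b, method = "normal")
    ref <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(mw$u_statistic, unname(ref$statistic))
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("mann_whitney validates its inputs and capability limits", {
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  expect_error(mann_whitney(c(1, NA), c(2, 3)), "NA")
  expect_error(mann_whitney(rnorm(150), rnorm(150), method = "exact"),
               "exact method not available")
  # auto switches to the normal approximation above n = 14
  expect_identical(mann_whitney(rnorm(10), rnorm(10))$method, "normal_approx")
  expect_identical(mann_whitney(rnorm(7), rnorm(7))$method, "exact")
})

test_that("ROC/AUC matches pair counting, the U identity, and flips cleanly", {
  # worked example: positives {1,2,3}, negatives {2,3,4} -> 9 pairs:
  # concordant (pos > neg): (2,... ) none except 3>2 -> 1; ties: 2=2, 3=3 -> 2
  # AUC = (1 + 0.5*2)/9 = 2/9
  r <- roc_auc(c(1, 2, 3, 2, 3, 4), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 2 / 9, tolerance = 1e-12)
  expect_equal(r$auc, oracle_auc(c(1, 2, 3, 2, 3, 4),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               tolerance = 1e-12)

  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(roc_auc(rep(2, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 0.5)

  set.seed(21)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    s <- sample(0:12, n, replace = TRUE)
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    hi <- roc_auc(s, l)
    expect_equal(hi$auc, oracle_auc(s, l), tolerance = 1e-12)
    # U identity: U of positives over negatives
    expect_equal(hi$auc,
                 mann_whitney(s[l], s[!l], method = "normal")$u_statistic /
                   (sum(l) * sum(!l)),
                 tolerance = 1e-12)
    lo <- roc_auc(s, l, direction = "lower_score_positive")
    expect_equal(lo$auc, 1 - hi$auc, tolerance = 1e-12)
  }
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(22)
  s <- sample(0:6, 25, replace = TRUE)
  l <- rep(c(TRUE, FALSE), length.out = 25)
  r <- roc_auc(s, l)
  p <- r$points
  expect_equal(p$fpr[1], 0)
  expect_equal(p$tpr[1], 0)
  expect_equal(p$fpr[nrow(p)], 1)
  expect_equal(p$tpr[nrow(p)], 1)
  expect_true(all(diff(p$fpr) >= 0))
  expect_true(all(diff(p$tpr) >= 0))
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  expect_error(roc_auc(1:3, c(TRUE, FALSE)), "equal length")
})

test_that("spearman equals Pearson-on-midranks and honours monotone maps", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$r, 1)
  expect_equal(spearman_cor(1:3, c(30, 20, 10))$r, -1)
  # tied worked example: oracle is cor() of the midrank vectors
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 4)
  expect_equal(spearman_cor(x, y)$r, stats::cor(rank(x), rank(y)),
               tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    x <- sample(0:8, n, replace = TRUE)
    y <- sample(0:8, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    s <- spearman_cor(x, y)
    expect_equal(s$r, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(s$r, stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
    # invariance under strictly increasing transforms of either argument
    # (-1/(y+1) is increasing for y >= 0); sign flips under decreasing ones
    expect_equal(spearman_cor(exp(x), y)$r, s$r, tolerance = 1e-12)
    expect_equal(spearman_cor(x, -1 / (y + 1))$r, s$r, tolerance = 1e-12)
    expect_equal(spearman_cor(x, -y)$r, -s$r, tolerance = 1e-12)
  }
})

test_that("spearman p-values: exact for small n, t-approximation beyond", {
  # n = 4, no ties: permutation distribution enumerable by hand oracle
  x <- c(1, 2, 3, 4)
  y <- c(2, 1, 4, 3)
  s <- spearman_cor(x, y)
  expect_identical(s$method, "exact_permutation")
  all_p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  all_p <- all_p[apply(all_p, 1, function(z) length(unique(z)) == 4), ]
  r_all <- apply(all_p, 1, function(p) stats::cor(x, y[unlist(p)]))
  expect_equal(s$p_value, mean(abs(r_all) >= abs(s$r) - 1e-12),
               tolerance = 1e-12)

  # large-n t-approximation against the reference implementation
  set.seed(32)
  x <- rnorm(25); y <- x + rnorm(25)
  s2 <- spearman_cor(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_identical(s2$method, "t_approx")
  expect_equal(s2$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(s2$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("correlation bands partition |r| per the published thresholds", {
  expect_identical(interpret_correlation(-0.757), "strong")
  expect_identical(interpret_correlation(0.05), "negligible")
  expect_identical(interpret_correlation(0.40), "moderate")
  expect_identical(
    interpret_correlation(c(0, 0.0999, 0.10, 0.399, 0.699, 0.70, 0.899, 0.90, 1, -1)),
    c("negligible", "negligible", "weak", "weak", "moderate", "strong",
      "strong", "very_strong", "very_strong", "very_strong"))
  expect_error(interpret_correlation(1.2), "exceed")
})
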