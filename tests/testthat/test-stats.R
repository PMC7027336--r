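test_that("Kruskal-Wallis reproduces the hand-computed three-group example", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  out <- kruskal_wallis(g)
  expect_equal(out$statistic, 7.2, tolerance = 1e-12)
  expect_equal(out$statistic, hand_kruskal_H(g), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, pchisq(7.2, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups: H = 0 (tie-corrected), p ~ 1
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(kruskal_wallis(same)$statistic, 0, tolerance = 1e-12)
  expect_gt(kruskal_wallis(same)$p_value, 0.99)

  # permuting values within groups leaves H unchanged
  set.seed(61)
  g2 <- list(rnorm(8), rnorm(8, 1), rnorm(8, 2))
  g2p <- lapply(g2, sample)
  expect_equal(kruskal_wallis(g2)$statistic, kruskal_wallis(g2p)$statistic)

  expect_error(kruskal_wallis(list(1:5)), "at least 2 groups")
})

test_that("Dunn-Bonferroni applies the pair-count factor and matches a permutation null", {
  # k = 2: single pair, corrected = raw
  two <- dunn_bonferroni(list(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8)))
  expect_equal(two$pairwise$p_adj, two$pairwise$p_raw)

  # k = 3: corrected = min(1, 3 x raw)
  set.seed(62)
  three <- dunn_bonferroni(list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6)))
  expect_equal(three$pairwise$p_adj,
               pmin(1, three$pairwise$p_raw * 3))
  expect_true(all(three$pairwise$p_adj >= three$pairwise$p_raw))

  # permutation oracle for the raw pairwise p (normal-tail approximation
  # should agree within Monte-Carlo + approximation error at n = 8)
  set.seed(63)
  g <- list(a = rnorm(8), b = rnorm(8, 0.8), c = rnorm(8, 0.3))
  obs <- dunn_bonferroni(g)$pairwise
  z_ab <- function(gl) {
    all_v <- unlist(gl)
    r <- rank(all_v)
    n <- lengths(gl)
    idx <- rep(seq_along(gl), n)
    mr <- tapply(r, idx, mean)
    N <- length(all_v)
    (mr[1] - mr[2]) / sqrt((N * (N + 1) / 12) * (1 / n[1] + 1 / n[2]))
  }
  z_obs <- abs(z_ab(g))
  perm <- replicate(4000, {
    v <- sample(unlist(g))
    abs(z_ab(list(v[1:8], v[9:16], v[17:24])))
  })
  p_perm <- mean(perm >= z_obs)
  p_raw_ab <- obs$p_raw[obs$group1 == "a" & obs$group2 == "b"]
  expect_lt(abs(p_raw_ab - p_perm), 0.05)
})

test_that("Wilcoxon signed rank matches exact enumeration for all n <= 8", {
  x <- c(1, 2, 3); y <- c(0, 0, 0)
  out <- wilcoxon_signed_rank(x, y)
  expect_equal(out$statistic, 6)       # all three differences positive
  expect_equal(out$p_value, 0.25)      # 2/8 sign assignments as extreme

  set.seed(64)
  for (n in 4:8) {
    for (rep in 1:5) {
      xx <- round(rnorm(n, 0.3), 3)
      yy <- rep(0, n)
      if (any(xx == 0) || anyDuplicated(abs(xx))) next
      expect_equal(wilcoxon_signed_rank(xx, yy)$p_value,
                   enum_signed_rank_p(xx),
                   tolerance = 1e-12, label = sprintf("n=%d rep=%d", n, rep))
    }
  }

  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "nonzero")
  # swapping the samples leaves p unchanged
  a <- c(1.2, -0.4, 2.2, 0.7, -1.9); b <- c(0.3, 0.1, -0.5, 1.4, 0.2)
  expect_equal(wilcoxon_signed_rank(a, b)$p_value,
               wilcoxon_signed_rank(b, a)$p_value)
})

test_that("Mann-Whitney matches exact enumeration and the U identity", {
  out <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1 / 3, tolerance = 1e-12)

  set.seed(65)
  for (rep in 1:10) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    x <- round(rnorm(nx), 3); y <- round(rnorm(ny, 0.5), 3)
    if (anyDuplicated(c(x, y))) next
    expect_equal(mann_whitney_u(x, y)$p_value, enum_mann_whitney_p(x, y),
                 tolerance = 1e-12)
    # U identity
    expect_equal(mann_whitney_u(x, y)$statistic +
                   mann_whitney_u(y, x)$statistic, nx * ny)
  }

  # identical multisets: p ~ 1 (ties force the approximate route)
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("paired t-test matches the hand formula and its degenerate contract", {
  v <- c(1, 2, 3); t0 <- paired_t_test(v, c(0, 2, 4))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$estimate, 0)

  x <- c(2.3, 1.1, 4.5, 3.2, 2.8); y <- c(1.9, 1.4, 3.6, 2.2, 2.9)
  d <- x - y
  expect_equal(paired_t_test(x, y)$statistic,
               mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  swapped <- paired_t_test(y, x)
  expect_equal(swapped$estimate, -paired_t_test(x, y)$estimate)
  expect_equal(abs(swapped$statistic), abs(paired_t_test(x, y)$statistic))

  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "zero-variance")
})

test_that("normality tests separate normal from uniform data", {
  expect_error(test_normality(c(1, 2)), "at least 3")
  expect_error(test_normality(rep(1, 10)), "constant")

  hits_norm <- hits_unif <- 0
  for (s in 1:50) {
    set.seed(s)
    hits_norm <- hits_norm +
      (test_normality(rnorm(500), "kolmogorov-smirnov")$p_value > 0.05)
    hits_unif <- hits_unif +
      (test_normality(runif(500), "kolmogorov-smirnov")$p_value < 0.05)
  }
  expect_gte(hits_norm, 45)
  expect_gte(hits_unif, 45)

  set.seed(66)
  sw <- test_normality(rnorm(100), "shapiro-wilk")
  expect_s3_class(sw, "test_outcome")
  expect_true(sw$p_value >= 0 && sw$p_value <= 1)
})

test_that("tidy and glance provide broom-style views of outcomes", {
  out <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  td <- generics::tidy(out)
  expect_named(td, c("method", "statistic", "df", "p.value", "estimate"))
  gl <- generics::glance(out)
  expect_true(all(c("significant", "alpha") %in% names(gl)))
  ph <- dunn_bonferroni(list(a = 1:4, b = 5:8, c = 9:12))
  expect_named(generics::tidy(ph),
               c("group1", "group2", "z", "p_raw", "p_adj", "significant"))
})
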