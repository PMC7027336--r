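#' Uniform container for a statistical test outcome
#'
#' @param method test name.
#' @param statistic test statistic value.
#' @param p_value two-sided p-value.
#' @param df degrees of freedom, or `NA`.
#' @param estimate point estimate (e.g. mean difference), or `NA`.
#' @param pairwise optional tibble of pairwise results (post hoc tests).
#' @param note optional character note (caveats, approximation used).
#' @param alpha significance level (default 0.05).
#' @return an object of class `test_outcome`.
#' @export
test_outcome <- function(method, statistic, p_value, df = NA_real_,
                         estimate = NA_real_, pairwise = NULL, note = NULL,
                         alpha = 0.05) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(method = method, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 estimate = unname(estimate), pairwise = pairwise,
                 note = note, alpha = alpha,
                 significant = !is.na(p_value) && p_value < alpha),
            class = "test_outcome")
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g%s, p = %.4g%s\n", x$method, x$statistic,
              if (!is.na(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value, if (x$significant) " *" else ""))
  if (!is.null(x$pairwise)) print(x$pairwise)
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @rdname test_outcome
#' @param x a `test_outcome`.
#' @param ... unused.
#' @export
tidy.test_outcome <- function(x, ...) {
  if (!is.null(x$pairwise)) return(x$pairwise)
  tibble(method = x$method, statistic = x$statistic, df = x$df,
         p.value = x$p_value, estimate = x$estimate)
}

#' @rdname test_outcome
#' @export
glance.test_outcome <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, df = x$df,
         p.value = x$p_value, significant = x$significant, alpha = x$alpha)
}

#' Test a sample for normality
#'
#' `"shapiro-wilk"` uses the Shapiro-Wilk test; `"kolmogorov-smirnov"` uses
#' the Lilliefors-corrected Kolmogorov-Smirnov test, i.e. against a normal
#' distribution with mean and sd estimated from the data (the plain KS test
#' would be anticonservative with estimated parameters).
#'
#' @param x numeric vector, n >= 3 (>= 4 for the KS variant), nonconstant.
#' @param method `"shapiro-wilk"` or `"kolmogorov-smirnov"`.
#' @return a [test_outcome()].
#' @export
test_normality <- function(x, method = c("shapiro-wilk", "kolmogorov-smirnov")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 3) abort("need at least 3 values")
  if (sd(x) == 0) abort("constant values: normality test undefined")
  if (method == "shapiro-wilk") {
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    r <- shapiro.test(x)
    test_outcome("Shapiro-Wilk normality test", r$statistic, r$p.value)
  } else {
    if (length(x) < 4) abort("Lilliefors KS variant needs at least 4 values")
    r <- nortest::lillie.test(x)
    test_outcome("Kolmogorov-Smirnov (Lilliefors) normality test",
                 r$statistic, r$p.value,
                 note = "normal reference with estimated mean/sd")
  }
}

as_group_list <- function(groups, values = NULL) {
  if (is.list(groups) && is.null(values)) return(groups)
  split(values, groups)
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus comparison of >= 2 unpaired groups; H statistic with tie
#' correction and the chi-square approximation on k - 1 degrees of freedom.
#'
#' @param groups a (named) list of numeric vectors, or a factor/character
#'   vector of labels if `values` is given.
#' @param values optional numeric vector parallel to `groups`.
#' @return a [test_outcome()].
#' @export
kruskal_wallis <- function(groups, values = NULL) {
  g <- as_group_list(groups, values)
  if (length(g) < 2) abort("need at least 2 groups")
  if (any(vapply(g, length, 0L) < 2)) abort("every group needs >= 2 values")
  r <- kruskal.test(g)
  test_outcome("Kruskal-Wallis rank sum test", r$statistic,
               r$p.value, df = r$parameter)
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' All pairwise comparisons of mean ranks after a Kruskal-Wallis omnibus
#' test. For groups i, j the statistic is
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T)(1/ni + 1/nj))` with the tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))`; raw two-sided p-values come
#' from the normal tail and are Bonferroni-multiplied by the number of pairs
#' (capped at 1).
#'
#' @inheritParams kruskal_wallis
#' @return a [test_outcome()] whose `pairwise` tibble has columns `group1`,
#'   `group2`, `z`, `p_raw`, `p_adj`, `significant`.
#' @export
dunn_bonferroni <- function(groups, values = NULL) {
  g <- as_group_list(groups, values)
  k <- length(g)
  if (k < 2) abort("need at least 2 groups")
  if (is.null(names(g))) names(g) <- paste0("g", seq_len(k))
  all_v <- unlist(g, use.names = FALSE)
  n <- vapply(g, length, 0L)
  N <- length(all_v)
  rk <- rank(all_v)
  mean_rank <- vapply(split(rk, rep(names(g), n)), mean, 0)[names(g)]
  ties <- table(all_v)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_corr
  pairs <- utils::combn(names(g), 2)
  n_pairs <- ncol(pairs)
  tab <- purrr::map_dfr(seq_len(n_pairs), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(var_term * (1 / n[[i]] + 1 / n[[j]]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    p_raw <- 2 * pnorm(-abs(z))
    tibble(group1 = i, group2 = j, z = z, p_raw = p_raw,
           p_adj = min(1, p_raw * n_pairs))
  })
  tab$significant <- tab$p_adj < 0.05
  test_outcome("Dunn's test (Bonferroni-corrected)",
               statistic = max(abs(tab$z)), p_value = min(tab$p_adj),
               pairwise = tab,
               note = sprintf("%d pairwise comparisons, Bonferroni factor %d",
                              n_pairs, n_pairs))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's convention). The exact
#' distribution is used for up to 25 nonzero differences when there are no
#' ties among their absolute values; otherwise the normal approximation with
#' tie correction and continuity correction is used (and noted).
#'
#' @param x,y paired numeric vectors.
#' @return a [test_outcome()]; the statistic is `V` (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) < 3) abort("need at least 3 nonzero paired differences")
  has_ties <- anyDuplicated(abs(nz)) > 0
  exact <- length(nz) <= 25 && !has_ties
  r <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = exact,
                                    correct = !exact))
  test_outcome("Wilcoxon signed rank test", r$statistic, r$p.value,
               note = if (exact) "exact distribution"
                      else "normal approximation with tie/zero handling")
}

#' Mann-Whitney U test (Wilcoxon rank-sum) for two unpaired samples
#'
#' Exact p-value for small samples without ties; normal approximation with
#' tie correction otherwise. The reported statistic is `U` for `x` (the
#' number of pairs `(xi, yj)` with `xi > yj`, counting ties as 1/2);
#' `U(x) + U(y) = nx * ny`.
#'
#' @param x,y numeric vectors, each nonempty, combined length >= 3.
#' @return a [test_outcome()].
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) abort("both groups must be nonempty")
  if (length(x) + length(y) < 3) abort("combined sample too small")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && length(x) <= 25 && length(y) <= 25
  r <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  test_outcome("Mann-Whitney U test", r$statistic, r$p.value,
               note = if (exact) "exact distribution"
                      else "normal approximation with tie correction")
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors, >= 3 pairs, nonconstant differences.
#' @return a [test_outcome()]; `estimate` is the mean difference `x - y`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x - y) == 0)
    abort("zero-variance differences: paired t-test degenerate")
  r <- t.test(x, y, paired = TRUE)
  test_outcome("Paired t-test", r$statistic, r$p.value, df = r$parameter,
               estimate = unname(r$estimate))
}
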