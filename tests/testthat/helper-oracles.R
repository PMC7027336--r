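# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they share no code
# path with the package implementation.

# brute-force nearest-positive distance: all-pairs minimization
bf_nearest_distances <- function(positive, spacing, queries) {
  pos <- which(positive, arr.ind = TRUE)
  apply(queries, 1, function(q) {
    d2 <- (pos[, 1] - q[1])^2 * spacing[1]^2 +
          (pos[, 2] - q[2])^2 * spacing[2]^2 +
          (pos[, 3] - q[3])^2 * spacing[3]^2
    sqrt(min(d2))
  })
}

# exhaustive Otsu scan: try every observed value as threshold, compute the
# two-class between-class variance directly from the raw values
bf_otsu <- function(values) {
  u <- sort(unique(values))
  cand <- u[-length(u)]
  sb <- vapply(cand, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    w0 <- length(lo) / length(values)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, 0)
  cand[which.max(sb)]
}

# exhaustive integer-shift NCC search (translation-only registration oracle)
bf_shift_ncc <- function(fixed, moving, max_shift) {
  best <- c(dx = 0, dy = 0); best_s <- -Inf
  nr <- nrow(fixed); nc <- ncol(fixed)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    rf <- max(1, 1 + dy):min(nr, nr + dy)
    cf <- max(1, 1 + dx):min(nc, nc + dx)
    a <- fixed[rf, cf]
    b <- moving[rf - dy, cf - dx]
    s <- cor(as.vector(a), as.vector(b))
    if (s > best_s) { best_s <- s; best <- c(dx = dx, dy = dy) }
  }
  best
}

# exact signed-rank p by enumeration of all 2^n sign assignments, using the
# same two-sided doubling convention as the analytic route
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  cdf_lo <- mean(v_all <= v_obs)
  cdf_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(cdf_lo, cdf_hi))
}

# exact Mann-Whitney p by enumeration of all group labelings
enum_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all_v <- c(x, y)
  u_stat <- function(xi) {
    xs <- all_v[xi]; ys <- all_v[-xi]
    sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, u_stat)
  u_obs <- u_stat(seq_len(nx))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# hand Kruskal-Wallis H (no-ties formula)
hand_kruskal_H <- function(groups) {
  all_v <- unlist(groups)
  N <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  Rk <- tapply(r, idx, sum)
  nk <- lengths(groups)
  12 / (N * (N + 1)) * sum(Rk^2 / nk) - 3 * (N + 1)
}

# 6-connectivity check that a positive set is one connected component
is_single_component <- function(pos) {
  idx <- which(pos, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  seen <- rep(FALSE, nrow(idx))
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  lookup <- setNames(seq_len(nrow(idx)), key)
  queue <- 1L; seen[1] <- TRUE
  nbr <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    for (j in 1:6) {
      k <- paste(idx[i, 1] + nbr[j, 1], idx[i, 2] + nbr[j, 2],
                 idx[i, 3] + nbr[j, 3])
      m <- lookup[k]
      if (!is.na(m) && !seen[m]) { seen[m] <- TRUE; queue <- c(queue, m) }
    }
  }
  all(seen)
}

# small random binary volume for property tests
random_binary_volume <- function(shape = c(8, 8, 4), p = 0.1,
                                 spacing = NULL) {
  if (is.null(spacing)) spacing <- runif(3, 0.5, 5)
  pos <- array(runif(prod(shape)) < p, shape)
  if (!any(pos)) pos[sample(length(pos), 1)] <- TRUE
  binary_volume(pos, spacing)
}

small_phantom_spec <- function(...) {
  phantom_spec(shape = c(8, 48, 48), ...)
}
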