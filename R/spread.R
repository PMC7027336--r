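#' Exact anisotropic Euclidean distance transform
#'
#' For every voxel, the exact Euclidean distance in physical units to the
#' nearest positive voxel center, with per-axis spacing. Computed by the
#' separable lower-envelope (feature-transform) algorithm, which is exact —
#' not a chamfer approximation — so it can be checked voxel-for-voxel
#' against brute-force nearest-neighbor search.
#'
#' @param binary a `binary_volume`.
#' @return numeric array of distances (micrometres); `Inf` if no positive
#'   voxel exists.
#' @export
distance_transform <- function(binary) {
  stopifnot(inherits(binary, "binary_volume"))
  .edt_aniso_cpp(binary$positive, dim(binary$positive), binary$spacing)
}

#' Distances from query voxels to the nearest positive voxel
#'
#' @param binary a `binary_volume` with at least one positive voxel.
#' @param queries integer matrix or data frame with columns `z`, `y`, `x`
#'   (1-based voxel coordinates); must be non-positive voxels inside the
#'   brain mask. `NULL` means every masked non-positive voxel.
#' @return a tibble with columns `z`, `y`, `x`, `distance_um`.
#' @export
nearest_positive_distances <- function(binary, queries = NULL) {
  stopifnot(inherits(binary, "binary_volume"))
  if (!any(binary$positive))
    abort("no positive voxels: nearest-positive distances are undefined")
  if (is.null(queries)) {
    queries <- which(binary$mask & !binary$positive, arr.ind = TRUE)
    colnames(queries) <- c("z", "y", "x")
  }
  q <- as.matrix(as.data.frame(queries)[, c("z", "y", "x")])
  storage.mode(q) <- "integer"
  pos_at_q <- binary$positive[q]
  if (any(pos_at_q)) abort("queries must be non-positive voxels")
  if (!all(binary$mask[q])) abort("queries must lie inside the brain mask")
  dt <- distance_transform(binary)
  tibble(z = q[, 1], y = q[, 2], x = q[, 3], distance_um = dt[q])
}

#' Sample non-positive voxels inside the brain mask
#'
#' Uniform sampling without replacement; used to mirror analyses that
#' evaluate the spread statistic on a voxel subsample (on the order of 3450
#' voxels per brain) rather than exhaustively.
#'
#' @param binary a `binary_volume`.
#' @param n number of voxels, or `"all"` for the exhaustive set; if `n`
#'   exceeds the available voxels the full set is returned.
#' @param seed integer seed (ignored for `"all"`).
#' @return a tibble with columns `z`, `y`, `x`.
#' @export
sample_nonpositive_voxels <- function(binary, n = "all", seed = 1L) {
  stopifnot(inherits(binary, "binary_volume"))
  cand <- which(binary$mask & !binary$positive, arr.ind = TRUE)
  if (nrow(cand) == 0) abort("no masked non-positive voxels to sample")
  colnames(cand) <- c("z", "y", "x")
  if (!identical(n, "all")) {
    stopifnot(is.numeric(n), n >= 1)
    if (n < nrow(cand))
      cand <- local_seed(seed,
                         cand[sample.int(nrow(cand), n), , drop = FALSE])
  }
  as_tibble(as.data.frame(cand))
}

#' Build a labeled distance sample for one brain
#'
#' Runs the spread statistic end to end for a single binary volume: sample
#' (or enumerate) masked non-positive voxels and measure each one's distance
#' to the nearest positive voxel.
#'
#' @param binary a `binary_volume`.
#' @param brain_id identifier for the brain.
#' @param group group label, one of `"L30"`, `"L90"`, `"S30"`, `"S90"` (or
#'   any label for synthetic experiments).
#' @param n,seed as [sample_nonpositive_voxels()].
#' @return a tibble: `brain_id`, `group`, `z`, `y`, `x`, `distance_um`.
#' @export
distance_sample <- function(binary, brain_id, group, n = "all", seed = 1L) {
  q <- sample_nonpositive_voxels(binary, n = n, seed = seed)
  d <- nearest_positive_distances(binary, q)
  dplyr::bind_cols(tibble(brain_id = brain_id, group = group), d)
}

#' Summarize spread distances by group
#'
#' Pools voxel-level distances within each group and reports order
#' statistics (quartiles by linear interpolation, R quantile type 7).
#' Per-brain medians are reported alongside: the pooled summary treats
#' voxels of the same brain as exchangeable, which overstates the effective
#' sample size (pseudo-replication), so any between-group claim should be
#' sanity-checked against the per-brain numbers.
#'
#' @param samples a tibble as from [distance_sample()] (rows from several
#'   brains/groups bound together).
#' @return a list of class `spread_summary` with tibbles `by_group`
#'   (`group`, `n_voxels`, `n_brains`, `min`, `q25`, `median`, `q75`, `max`)
#'   and `by_brain` (`brain_id`, `group`, `n_voxels`, `median`).
#' @export
summarize_spread <- function(samples) {
  stopifnot(all(c("brain_id", "group", "distance_um") %in% names(samples)))
  empty <- setdiff(unique(samples$group),
                   unique(samples$group[!is.na(samples$distance_um)]))
  if (length(empty) > 0)
    warn(paste("excluding empty group(s):", paste(empty, collapse = ", ")))
  by_group <- samples |>
    dplyr::filter(!is.na(.data$distance_um)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_voxels = dplyr::n(),
      n_brains = dplyr::n_distinct(.data$brain_id),
      min = min(.data$distance_um),
      q25 = quantile(.data$distance_um, 0.25, names = FALSE),
      median = median(.data$distance_um),
      q75 = quantile(.data$distance_um, 0.75, names = FALSE),
      max = max(.data$distance_um),
      .groups = "drop")
  by_brain <- samples |>
    dplyr::filter(!is.na(.data$distance_um)) |>
    dplyr::group_by(.data$brain_id, .data$group) |>
    dplyr::summarise(n_voxels = dplyr::n(),
                     median = median(.data$distance_um), .groups = "drop")
  structure(list(by_group = by_group, by_brain = by_brain,
                 quantile_type = 7L),
            class = "spread_summary")
}

#' @export
print.spread_summary <- function(x, ...) {
  cat("Spread summary (pooled voxel-level distances, um):\n")
  print(x$by_group)
  cat("Per-brain medians (pseudo-replication check):\n")
  print(x$by_brain)
  invisible(x)
}

#' Compare spread distances between groups
#'
#' The full comparison applied to distance data: a normality check per group
#' (Lilliefors-corrected Kolmogorov-Smirnov against a normal with estimated
#' moments), the Kruskal-Wallis omnibus test on pooled voxel-level
#' distances, and all pairwise Dunn tests with Bonferroni correction.
#' Significance is declared at p < 0.05. Note the pooled voxel-level n
#' treats voxels as independent; see [summarize_spread()].
#'
#' @param samples a tibble as from [distance_sample()] with >= 2 groups,
#'   each with >= 2 distances.
#' @return a list of class `spread_comparison`: `normality` (tibble, one row
#'   per group), `omnibus` (a `test_outcome`), `posthoc` (a `test_outcome`
#'   with a pairwise table).
#' @export
compare_spread <- function(samples) {
  stopifnot(all(c("group", "distance_um") %in% names(samples)))
  groups <- split(samples$distance_um, samples$group)
  if (length(groups) < 2) abort("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    abort("every group needs at least 2 values")
  normality <- purrr::map_dfr(names(groups), function(g) {
    out <- test_normality(groups[[g]], method = "kolmogorov-smirnov")
    tibble(group = g, statistic = out$statistic, p_value = out$p_value,
           normal_at_0.05 = out$p_value >= 0.05)
  })
  omnibus <- kruskal_wallis(groups)
  posthoc <- dunn_bonferroni(groups)
  structure(list(normality = normality, omnibus = omnibus,
                 posthoc = posthoc, alpha = 0.05),
            class = "spread_comparison")
}

#' @export
print.spread_comparison <- function(x, ...) {
  cat("Normality (Lilliefors-corrected Kolmogorov-Smirnov):\n")
  print(x$normality)
  cat("\nOmnibus: ")
  print(x$omnibus)
  cat("\nPost hoc (Dunn, Bonferroni-corrected):\n")
  print(x$posthoc$pairwise)
  invisible(x)
}

#' @rdname compare_spread
#' @param x a `spread_comparison`.
#' @param ... unused.
#' @export
tidy.spread_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tibble(comparison = "omnibus", test = x$omnibus$method,
           statistic = x$omnibus$statistic, p_value = x$omnibus$p_value),
    x$posthoc$pairwise |>
      dplyr::transmute(comparison = paste(.data$group1, "vs", .data$group2),
                       test = "Dunn (Bonferroni)",
                       statistic = .data$z, p_value = .data$p_adj)
  )
}
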