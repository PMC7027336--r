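test_that("single-source distances match the closed form", {
  pos <- array(FALSE, c(4, 4, 4)); pos[1, 1, 1] <- TRUE
  bv <- binary_volume(pos, c(2, 1, 1))
  d <- nearest_positive_distances(bv, data.frame(z = 2, y = 2, x = 2))
  expect_equal(d$distance_um, sqrt(6))

  # anisotropic section geometry: 70 um axial, 10.4 um in-plane; a query one
  # column from a positive voxel is 10.4 um away
  pos2 <- array(FALSE, c(3, 3, 3)); pos2[2, 2, 2] <- TRUE
  bv2 <- binary_volume(pos2, c(70, 10.4, 10.4))
  d2 <- nearest_positive_distances(bv2, data.frame(z = 2, y = 2, x = 3))
  expect_equal(d2$distance_um, 10.4)
  d3 <- nearest_positive_distances(bv2, data.frame(z = 3, y = 2, x = 2))
  expect_equal(d3$distance_um, 70)
})

test_that("distance transform equals brute force on random anisotropic volumes", {
  set.seed(51)
  for (i in 1:100) {
    bv <- random_binary_volume(c(8, 8, 4), p = runif(1, 0.03, 0.3))
    dt <- distance_transform(bv)
    q <- which(!bv$positive, arr.ind = TRUE)
    expect_equal(as.vector(dt[q]),
                 bf_nearest_distances(bv$positive, bv$spacing, q),
                 tolerance = 1e-12, label = sprintf("volume %d", i))
  }
})

test_that("distances are translation invariant and monotone in the positive set", {
  set.seed(52)
  pos <- array(FALSE, c(6, 6, 6)); pos[2, 2, 2] <- TRUE; pos[3, 4, 5] <- TRUE
  bv <- binary_volume(pos, c(3, 2, 1))
  q <- data.frame(z = c(1, 4), y = c(3, 5), x = c(2, 2))
  d0 <- nearest_positive_distances(bv, q)$distance_um

  shift <- function(a, k) {
    out <- array(FALSE, dim(a))
    out[(1 + k):dim(a)[1], , ] <- a[1:(dim(a)[1] - k), , ]
    out
  }
  bvs <- binary_volume(shift(pos, 1), c(3, 2, 1))
  qs <- transform(q, z = z + 1)
  expect_equal(nearest_positive_distances(bvs, qs)$distance_um, d0)

  pos_more <- pos; pos_more[5, 5, 1] <- TRUE
  bvm <- binary_volume(pos_more, c(3, 2, 1))
  expect_true(all(nearest_positive_distances(bvm, q)$distance_um <= d0))
})

test_that("distance queries validate their preconditions", {
  bv <- binary_volume(array(FALSE, c(3, 3, 3)), c(1, 1, 1))
  expect_error(nearest_positive_distances(bv), "no positive voxels")
  pos <- array(FALSE, c(3, 3, 3)); pos[1, 1, 1] <- TRUE
  bv2 <- binary_volume(pos, c(1, 1, 1))
  expect_error(nearest_positive_distances(bv2, data.frame(z = 1, y = 1, x = 1)),
               "non-positive")
})

test_that("non-positive voxel sampling is deterministic, exclusive and exhaustive", {
  set.seed(53)
  bv <- random_binary_volume(c(6, 6, 6), p = 0.2)
  all_q <- sample_nonpositive_voxels(bv, "all")
  expect_equal(nrow(all_q), sum(bv$mask & !bv$positive))

  s1 <- sample_nonpositive_voxels(bv, 20, seed = 7)
  s2 <- sample_nonpositive_voxels(bv, 20, seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 20)

  for (i in 1:10) {
    bvr <- random_binary_volume(c(5, 5, 5), p = 0.3)
    s <- sample_nonpositive_voxels(bvr, 15, seed = i)
    expect_false(any(bvr$positive[as.matrix(s)]))
  }

  # n beyond availability returns everything
  big <- sample_nonpositive_voxels(bv, 1e6, seed = 1)
  expect_equal(nrow(big), nrow(all_q))
})

test_that("spread summaries reproduce hand order statistics and pooling behavior", {
  one <- tibble::tibble(brain_id = "b1", group = "L30",
                        z = 1:5, y = 1, x = 1, distance_um = c(1, 2, 3, 4, 5))
  s <- summarize_spread(one)
  expect_equal(s$by_group$median, 3)
  expect_equal(s$by_group$q25, 2)    # linear interpolation (type 7)
  expect_equal(s$by_group$q75, 4)
  expect_equal(s$by_group$min, 1)
  expect_equal(s$by_group$max, 5)

  two <- dplyr::bind_rows(one, dplyr::mutate(one, brain_id = "b2"))
  s2 <- summarize_spread(two)
  expect_equal(s2$by_group$median, 3)   # pooling identical brains: unchanged
  expect_equal(s2$by_group$n_voxels, 10)
  expect_equal(s2$by_group$n_brains, 2)
  expect_equal(nrow(s2$by_brain), 2)
})

test_that("advective phantoms show shorter distances than diffusive at matched count", {
  meds <- sapply(1:3, function(s) {
    shape <- c(12, 64, 64)
    fa <- simulate_advective_tracer(
      phantom_spec(shape = shape, mode = "advective", seed = s))
    fd <- simulate_diffusive_tracer(
      phantom_spec(shape = shape, mode = "diffusive", seed = s))
    mask <- brain_mask(phantom_spec(shape = shape, seed = s))
    sp <- phantom_spacing(phantom_spec(shape = shape, seed = s))
    k <- 1500
    median_dist <- function(f) {
      thr <- sort(f[f > 0], decreasing = TRUE)[k]
      bv <- binary_volume(f >= thr, sp, mask)
      median(nearest_positive_distances(bv)$distance_um)
    }
    c(adv = median_dist(fa), dif = median_dist(fd))
  })
  expect_true(all(meds["adv", ] < meds["dif", ]))
})

test_that("group comparison wires normality, omnibus and post hoc together", {
  set.seed(54)
  samples <- dplyr::bind_rows(
    tibble::tibble(brain_id = "a", group = "L30",
                   z = 1, y = 1, x = 1, distance_um = runif(60, 0, 100)),
    tibble::tibble(brain_id = "b", group = "S30",
                   z = 1, y = 1, x = 1, distance_um = runif(60, 80, 250)),
    tibble::tibble(brain_id = "c", group = "S90",
                   z = 1, y = 1, x = 1, distance_um = runif(60, 90, 260)))
  cmp <- compare_spread(samples)
  expect_equal(nrow(cmp$normality), 3)
  expect_s3_class(cmp$omnibus, "test_outcome")
  expect_true(cmp$omnibus$significant)
  expect_equal(nrow(cmp$posthoc$pairwise), 3)
  td <- generics::tidy(cmp)
  expect_equal(nrow(td), 4)   # omnibus + 3 pairs
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})

test_that("plot functions return ggplot objects", {
  samples <- tibble::tibble(brain_id = "a", group = c("L30", "S30"),
                            z = 1, y = 1, x = 1, distance_um = c(10, 20))
  expect_s3_class(plot_spread(samples), "ggplot")
  full <- dplyr::bind_rows(samples, dplyr::mutate(samples, distance_um = 15))
  expect_s3_class(ggplot2::autoplot(summarize_spread(full)), "ggplot")
  counts <- tibble::tibble(brain_id = c("a", "b"), group = "L30",
                           ipsi = c(5, 7), contra = c(1, 2))
  expect_s3_class(plot_hemisphere_counts(counts), "ggplot")
  expect_s3_class(plot_projection(matrix(runif(12), 3)), "ggplot")
})
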