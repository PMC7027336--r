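test_that("autofluorescence subtraction obeys its arithmetic contracts", {
  g <- matrix(c(10, 5, 2, 0), 2)
  zero <- matrix(0, 2, 2)
  expect_equal(unclass(correct_autofluorescence(g, zero)), g,
               ignore_attr = TRUE)
  expect_true(all(correct_autofluorescence(g, g) == 0))
  r <- matrix(4, 2, 2)
  expect_equal(correct_autofluorescence(matrix(10, 2, 2), r)[1, 1], 6)
  expect_error(correct_autofluorescence(g, matrix(0, 3, 3)), "shapes differ")
  # negatives clip at zero
  expect_true(all(correct_autofluorescence(zero, r) == 0))
})

test_that("autofluorescent particles vanish and tracer particles survive correction", {
  for (s in 1:20) {
    g <- generate_lymphnode_image(n_tracer = 5, n_autofluor = 20, seed = s)
    corr <- correct_autofluorescence(g$image[, , "green"], g$image[, , "red"])
    q <- suppressWarnings(count_tracer_pixels(corr))
    expect_lt(abs(q$pixel_count - g$truth$tracer_pixels) /
                g$truth$tracer_pixels, 0.10,
              label = sprintf("tracer preservation, seed %d", s))

    g0 <- generate_lymphnode_image(n_tracer = 0, n_autofluor = 20, seed = s)
    corr0 <- correct_autofluorescence(g0$image[, , "green"],
                                      g0$image[, , "red"])
    q0 <- suppressWarnings(count_tracer_pixels(corr0))
    expect_lte(q0$pixel_count, 0.01 * g0$truth$autofluor_pixels,
               label = sprintf("autofluorescence null, seed %d", s))
  }
})

test_that("blank and constant corrected images count zero", {
  expect_equal(suppressWarnings(
    count_tracer_pixels(matrix(0, 10, 10)))$pixel_count, 0)
  expect_warning(count_tracer_pixels(matrix(0.3, 5, 5)), "degenerate")
})

test_that("normalized region intensity matches hand sums and is linear", {
  img <- matrix(0, 4, 4)
  vessel <- matrix(FALSE, 4, 4); vessel[1, 1:3] <- TRUE
  img[1, 1:3] <- c(5, 10, 15)           # sums to 30 over 3 px -> 10
  tissue <- matrix(FALSE, 4, 4); tissue[3:4, ] <- TRUE
  img[3:4, ] <- 2
  masks <- region_mask_set(vessel, tissue)
  res <- normalized_region_intensity(img, masks, image_id = "im1")
  expect_equal(res$normalized_intensity[res$region == "vessel"], 10)
  expect_equal(res$normalized_intensity[res$region == "tissue"], 2)

  res3 <- normalized_region_intensity(3 * img, masks)
  expect_equal(res3$normalized_intensity, 3 * res$normalized_intensity)

  # uniform image reports the same value for both regions
  resu <- normalized_region_intensity(matrix(7, 4, 4), masks)
  expect_equal(resu$normalized_intensity, c(7, 7))

  # artifact pixels are excluded and cannot change counts
  artifact <- matrix(FALSE, 4, 4); artifact[2, ] <- TRUE
  img2 <- img; img2[2, ] <- 1e6
  masks2 <- region_mask_set(vessel, tissue, artifact)
  res_a <- normalized_region_intensity(img2, masks2)
  expect_equal(res_a$normalized_intensity, res$normalized_intensity)

  # empty region after artifact exclusion errors by name
  all_art <- region_mask_set(vessel, tissue, !vessel & !tissue)
  expect_silent(normalized_region_intensity(img, all_art))
  bad <- region_mask_set(matrix(FALSE, 4, 4), tissue)
  expect_error(normalized_region_intensity(img, bad), "vessel")

  expect_error(region_mask_set(vessel, vessel), "disjoint")
})

test_that("paired region comparison is symmetric and detects a real shift", {
  res <- dplyr::bind_rows(lapply(1:3, function(i)
    tibble::tibble(image_id = paste0("im", i), region = c("vessel", "tissue"),
                   normalized_intensity = c(c(1, 2, 3)[i], c(0, 2, 4)[i]))))
  cmp <- paired_region_comparison(res)
  expect_equal(mean(cmp$pairs$difference), 0)
  expect_equal(cmp$t_test$statistic, 0)
  expect_equal(cmp$t_test$p_value, 1)

  # constant positive shift with noise is detected
  set.seed(71)
  tissue_v <- rnorm(12, 1, 0.05)
  res2 <- dplyr::bind_rows(lapply(1:12, function(i)
    tibble::tibble(image_id = sprintf("im%02d", i),
                   region = c("vessel", "tissue"),
                   normalized_intensity = c(tissue_v[i] + 0.25 +
                                              rnorm(1, 0, 0.05),
                                            tissue_v[i]))))
  cmp2 <- paired_region_comparison(res2)
  expect_true(cmp2$t_test$significant)
  expect_gt(cmp2$t_test$estimate, 0)

  # swapping region labels flips the sign, |t| unchanged
  res_sw <- dplyr::mutate(res2,
                          region = ifelse(region == "vessel", "tissue",
                                          "vessel"))
  cmp_sw <- paired_region_comparison(res_sw)
  expect_equal(cmp_sw$t_test$estimate, -cmp2$t_test$estimate)
  expect_equal(abs(cmp_sw$t_test$statistic), abs(cmp2$t_test$statistic))

  expect_error(paired_region_comparison(res[1:2, ]), "at least 3")
})
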