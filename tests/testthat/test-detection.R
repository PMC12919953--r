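test_that("log-normalization maps the clip percentiles to [0, 1]", {
  img <- matrix(c(0, exp(1) - 1), 1, 2)
  expect_equal(log_normalize(img, c(0, 100)), matrix(c(0, 1), 1, 2))
  expect_true(all(log_normalize(matrix(7, 5, 5)) == 0))
})

test_that("log-normalization weakly preserves pixel rank order", {
  set.seed(21)
  img <- matrix(sample(0:65535, 40 * 40, replace = TRUE), 40, 40)
  norm <- log_normalize(img, c(1, 99.9))
  ord <- order(as.vector(img))
  expect_true(all(diff(as.vector(norm)[ord]) >= -1e-12))
  expect_true(all(norm >= 0 & norm <= 1))
})

test_that("Otsu splits a bimodal image at the gap", {
  img <- matrix(c(rep(0.1, 900), rep(0.9, 100)), 25, 40)
  mask <- threshold_image(img, "otsu")
  expect_equal(mean(mask), 0.1)
  expect_equal(attr(otsu_threshold(img), "level"), otsu_oracle_level(img))
})

test_that("quantile thresholding keeps strictly-above-quantile pixels", {
  set.seed(22)
  img <- matrix(sample(seq(0, 1, length.out = 100)), 10, 10)
  mask <- threshold_image(img, "quantile", quantile = 0.95)
  expect_equal(sum(mask), 5)
})

test_that("a constant image thresholds to an empty mask under both methods", {
  img <- matrix(0.5, 10, 10)
  expect_equal(sum(threshold_image(img, "otsu")), 0)
  expect_equal(sum(threshold_image(img, "quantile", 0.95)), 0)
})

test_that("cluster labeling reports area, centroid and intensity", {
  mask <- matrix(FALSE, 30, 30)
  mask[10:12, 10:12] <- TRUE
  img <- matrix(0.5, 30, 30)
  cl <- find_clusters(mask, img, connectivity = 8)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$area, 9L)
  expect_equal(c(cl$x, cl$y), c(11, 11))
  expect_equal(cl$integrated_intensity, 9 * 0.5)
  expect_equal(nrow(find_clusters(matrix(FALSE, 5, 5), matrix(0, 5, 5), 8)), 0)
})

test_that("diagonal contact joins under 8- and splits under 4-connectivity", {
  mask <- matrix(FALSE, 10, 10)
  mask[3, 3] <- TRUE
  mask[4, 4] <- TRUE
  img <- matrix(1, 10, 10)
  expect_equal(nrow(find_clusters(mask, img, connectivity = 8)), 1)
  expect_equal(nrow(find_clusters(mask, img, connectivity = 4)), 2)
})

test_that("size filter bounds are inclusive and removals are counted", {
  cl <- data.frame(cluster_id = 1:4, area = c(2L, 4L, 9L, 500L))
  kept <- filter_clusters_by_size(cl, 4, 400)
  expect_equal(kept$area, c(4L, 9L))
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_equal(nrow(filter_clusters_by_size(cl, 1, Inf)), 4)
  none <- filter_clusters_by_size(cl, 1000, 2000)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_removed"), 4L)
})

test_that("clusters go to the plurality cell, ties to the smaller label", {
  lab <- matrix(0L, 12, 12)
  lab[1:6, 1:6] <- 3L
  cl_in <- data.frame(cluster_id = 1L, cell_id = NA_integer_, x = 3, y = 3,
                      area = 4L, integrated_intensity = 1)
  cl_in$pixels <- list(which(matrix(seq_len(144), 12, 12) %in%
                               c(2 + 12 * 1, 3 + 12 * 1, 2 + 12 * 2,
                                 3 + 12 * 2)))
  out <- assign_clusters_to_cells(cl_in, lab)
  expect_equal(out$cell_id, 3L)

  lab2 <- matrix(0L, 10, 10)
  lab2[1:10, 1:6] <- 2L
  lab2[1:10, 7:10] <- 5L
  cl2 <- data.frame(cluster_id = 1L, cell_id = NA_integer_, x = 6, y = 5,
                    area = 10L, integrated_intensity = 1)
  # 6 px in columns 5:6 (cell 2), 4 px in column 7 (cell 5)
  cl2$pixels <- list(c((5 - 1) * 10 + 1:3, (6 - 1) * 10 + 1:3,
                       (7 - 1) * 10 + 1:4))
  expect_equal(assign_clusters_to_cells(cl2, lab2)$cell_id, 2L)

  # 5 px each in cells 4 and 2: tie goes to label 2
  cl3 <- cl2
  cl3$pixels <- list(c((6 - 1) * 10 + 1:5, (7 - 1) * 10 + 1:5))
  lab3 <- lab2
  lab3[lab3 == 5L] <- 4L
  lab3[lab3 == 2L] <- 2L
  expect_equal(assign_clusters_to_cells(cl3, lab3)$cell_id, 2L)

  # 7 of 10 px on background: dropped and counted
  cl4 <- cl2
  cl4$pixels <- list(c((1 - 1) * 10 + 1:7, (5 - 1) * 10 + 1:3))
  lab4 <- matrix(0L, 10, 10)
  lab4[1:10, 5] <- 1L
  out4 <- assign_clusters_to_cells(cl4, lab4)
  expect_equal(nrow(out4), 0)
  expect_equal(attr(out4, "n_dropped_background"), 1L)
})

test_that("per-cell mean intensity is the raw arithmetic mean", {
  mask <- matrix(0L, 4, 4)
  mask[1:2, 1:2] <- 1L
  img <- matrix(0, 4, 4)
  img[1:2, 1:2] <- c(1, 2, 3, 4)
  m <- cell_mean_intensity(img, mask)
  expect_equal(m$mean_intensity, 2.5)
  const <- cell_mean_intensity(matrix(7, 4, 4), mask)
  expect_equal(const$mean_intensity, 7)
  empty <- cell_mean_intensity(img, matrix(0L, 4, 4))
  expect_equal(nrow(empty), 0)
})

test_that("cluster areas sum to the foreground count when nothing is dropped", {
  set.seed(23)
  mask <- matrix(runif(40 * 40) < 0.3, 40, 40)
  img <- matrix(runif(40 * 40), 40, 40)
  cl <- find_clusters(mask, img, connectivity = 8)
  expect_equal(sum(cl$area), sum(mask))
  kept <- filter_clusters_by_size(cl, 2, 20)
  expect_lte(sum(kept$area), sum(mask))
})

test_that("connected components match the flood-fill oracle", {
  set.seed(24)
  img <- matrix(1, 24, 24)
  for (i in 1:5) {
    mask <- matrix(runif(24 * 24) < 0.4, 24, 24)
    for (conn in c(4, 8)) {
      cl <- find_clusters(mask, img, connectivity = conn)
      lab_impl <- matrix(0L, 24, 24)
      for (k in seq_len(nrow(cl))) lab_impl[cl$pixels[[k]]] <- k
      expect_true(same_partition(lab_impl, flood_components(mask, conn)))
    }
  }
})
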