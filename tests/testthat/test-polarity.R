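make_clusters <- function(x, y, area = NULL, intensity = NULL) {
  n <- length(x)
  data.frame(cluster_id = seq_len(n), cell_id = 1L, x = x, y = y,
             area = if (is.null(area)) rep(1L, n) else area,
             integrated_intensity = if (is.null(intensity)) rep(1, n) else
               intensity)
}

test_that("cell centroids are unweighted pixel-coordinate means", {
  mask <- matrix(0L, 8, 8)
  mask[1:3, 1:3] <- 1L
  expect_equal(cell_centroid(mask, 1L), c(x = 2, y = 2))
  mask2 <- matrix(0L, 8, 8)
  mask2[1, 1] <- 2L
  mask2[1, 3] <- 2L   # pixels (x, y) = (1, 1) and (3, 1)
  expect_equal(cell_centroid(mask2, 2L), c(x = 2, y = 1))
  mask3 <- matrix(0L, 8, 8)
  mask3[1, 1] <- 3L
  mask3[1, 2] <- 3L
  mask3[2, 1] <- 3L   # L-shape {(1,1),(2,1),(1,2)}
  expect_equal(cell_centroid(mask3, 3L), c(x = 4 / 3, y = 4 / 3))
  expect_error(cell_centroid(mask3, 9L), "absent")
})

test_that("a single offset cluster gives a unit polarity vector", {
  pv <- cell_polarity_vector(c(10, 10), make_clusters(13, 14))
  expect_equal(c(pv$dx, pv$dy), c(0.6, 0.8))
  expect_equal(pv$magnitude, 1)
  expect_true(pv$defined)
})

test_that("opposite equal-weight clusters cancel to an undefined polarity", {
  pv <- cell_polarity_vector(c(10, 10), make_clusters(c(13, 7), c(10, 10)))
  expect_false(pv$defined)
  expect_true(is.na(pv$angle_deg))
})

test_that("weights tilt the polarity vector as direct arithmetic predicts", {
  # clusters at 0 and 90 degrees with area weights 3 and 1:
  # v = (3*(1,0) + 1*(0,1)) / 4 = (0.75, 0.25), angle = atan2(1, 3)
  pv <- cell_polarity_vector(c(0, 0), make_clusters(c(5, 0), c(0, 5),
                                                    area = c(3L, 1L)),
                             weight_mode = "area")
  expect_equal(c(pv$dx, pv$dy), c(0.75, 0.25))
  expect_equal(pv$angle_deg, atan2(1, 3) * 180 / pi, tolerance = 1e-9)
  expect_equal(pv$angle_deg, 18.434949, tolerance = 1e-6)
})

test_that("a cluster sitting on the centroid is skipped, not an error", {
  pv <- cell_polarity_vector(c(5, 5), make_clusters(c(5, 8), c(5, 5)))
  expect_equal(pv$n_skipped, 1L)
  expect_equal(pv$n_clusters, 1L)
  expect_equal(c(pv$dx, pv$dy), c(1, 0))
})

test_that("equal-weight clusters make area and intensity modes agree", {
  set.seed(31)
  for (i in 1:10) {
    cl <- make_clusters(runif(5, 0, 20), runif(5, 0, 20),
                        area = rep(3L, 5), intensity = rep(1.7, 5))
    a <- cell_polarity_vector(c(10, 10), cl, "area")
    b <- cell_polarity_vector(c(10, 10), cl, "intensity")
    expect_equal(c(a$dx, a$dy), c(b$dx, b$dy), tolerance = 1e-12)
  }
})

test_that("polarity magnitude never exceeds 1", {
  set.seed(32)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    cl <- make_clusters(runif(n, 0, 30), runif(n, 0, 30),
                        area = sample(1:50, n, replace = TRUE),
                        intensity = runif(n, 0, 10))
    for (mode in c("area", "intensity")) {
      pv <- cell_polarity_vector(c(15, 15), cl, mode)
      if (!is.na(pv$magnitude)) expect_lte(pv$magnitude, 1 + 1e-9)
    }
  }
})

test_that("the reference field resolves per mode and flags degeneracy", {
  fixed <- reference_field("fixed_angle", angle_deg = 90)
  expect_equal(reference_angle_at(fixed, c(0, 0)), 90)
  expect_equal(reference_angle_at(fixed, c(100, -50)), 90)
  tgt <- reference_field("target_point", target = c(10, 0))
  expect_equal(reference_angle_at(tgt, c(0, 0)), 0)
  tgt2 <- reference_field("target_point", target = c(0, 10))
  expect_equal(reference_angle_at(tgt2, c(0, 0)), 90)
  expect_true(is.na(reference_angle_at(tgt, c(10, 0))))
  expect_error(reference_field("target_point"), "target")
})

test_that("pooling concatenates defined cells and keeps per-field provenance", {
  spec <- field_spec(n_cells = 30, image_height = 128, image_width = 128,
                     bias_kappa = 2, seed = 8)
  ds <- generate_dataset(spec, n_fields = 2)
  cfg <- analysis_config()
  res <- lapply(ds, function(f) {
    run_pipeline(f$image, f$mask, cfg)$per_field[[1]]
  })
  pooled <- pool_fields(res)
  n1 <- sum(res[[1]]$defined & !res[[1]]$excluded)
  n2 <- sum(res[[2]]$defined & !res[[2]]$excluded)
  expect_equal(nrow(pooled), n1 + n2)
  expect_equal(attr(pooled, "per_field_n"), c(n1, n2))
  expect_equal(nrow(pool_fields(res[1])), n1)
  # a field with zero defined cells contributes nothing but stays listed
  empty <- res[[1]][0, ]
  attr(empty, "config") <- attr(res[[1]], "config")
  pooled3 <- pool_fields(list(res[[1]], empty))
  expect_equal(attr(pooled3, "per_field_n"), c(n1, 0L))
  # config mismatch across fields is refused
  other <- res[[2]]
  cfg2 <- attr(other, "config")
  cfg2$weight_mode <- "intensity"
  attr(other, "config") <- cfg2
  expect_error(pool_fields(list(res[[1]], other)), "configuration")
})
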