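test_that("bins are centered on the reference with a left-closed edge rule", {
  h <- bin_angles(c(0, 44, -44, 179), n_bins = 8)
  # bin centers: 0, 45, 90, 135, 180, -135, -90, -45
  expect_equal(h$counts, c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 1L))
  expect_equal(h$bin_edges_deg, seq(-22.5, 337.5, by = 45))
  expect_equal(h$bin_centers_deg[1], 0)
  # an angle exactly on an interior edge goes to the higher bin
  edge <- bin_angles(22.5, n_bins = 8)
  expect_equal(which(edge$counts == 1L), 2L)
  # the wrap seam closes the circle: 180 and just-below--180 share a bin
  seam <- bin_angles(c(180, -179.9), n_bins = 8)
  expect_equal(seam$counts[5], 2L)
})

test_that("binning conserves counts and weights", {
  set.seed(41)
  for (nb in c(4, 8, 12)) {
    a <- wrap_angle(runif(200, -180, 180))
    w <- runif(200, 0, 3)
    h <- bin_angles(a, w, n_bins = nb)
    expect_equal(sum(h$counts), 200L)
    expect_equal(sum(h$weights), sum(w))
    expect_equal(h$total_cells, 200L)
  }
  h0 <- bin_angles(numeric(0), n_bins = 8)
  expect_equal(sum(h0$counts), 0L)
})

test_that("chi-square statistic and p-value match the arithmetic oracles", {
  # perfectly uniform counts
  h <- bin_angles(rep(seq(-180 + 22.5, 180, by = 45), each = 12), n_bins = 8)
  expect_equal(h$counts, rep(12L, 8))
  t0 <- chi_square_uniformity(h)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # 100 cells in one bin: (100 - 12.5)^2/12.5 + 7 * 12.5 = 700
  h1 <- bin_angles(rep(0, 100), n_bins = 8)
  t1 <- chi_square_uniformity(h1)
  expect_equal(t1$statistic, 700)
  expect_equal(t1$df, 7L)
  # counts {20,10,10,10,10,10,10,20}: statistic 12, p ~ 0.1006
  centers <- c(0, 45, 90, 135, 180, -135, -90, -45)
  a2 <- rep(centers, times = c(20, 10, 10, 10, 10, 10, 10, 20))
  t2 <- chi_square_uniformity(bin_angles(a2, n_bins = 8))
  expect_equal(t2$statistic, 12)
  expect_equal(t2$p_value, chisq_tail_oracle(12, 7), tolerance = 1e-6)
  expect_equal(t2$p_value, 0.1006, tolerance = 1e-3)
})

test_that("the tail probability matches numerical integration for df <= 32", {
  set.seed(43)
  for (nb in c(2, 4, 8, 16, 33)) {
    a <- wrap_angle(rvonmises(40 * nb, 0, 0.5))
    t <- chi_square_uniformity(bin_angles(a, n_bins = nb))
    expect_equal(t$df, nb - 1L)
    expect_equal(t$p_value, chisq_tail_oracle(t$statistic, t$df),
                 tolerance = 1e-6)
  }
})

test_that("the statistic is invariant under circular relabeling of bins", {
  set.seed(42)
  a <- wrap_angle(rvonmises(120, 30, 1))
  s0 <- chi_square_uniformity(bin_angles(a, n_bins = 8))$statistic
  for (shift in c(45, 90, 180)) {
    s <- chi_square_uniformity(bin_angles(wrap_angle(a + shift),
                                          n_bins = 8))$statistic
    expect_equal(s, s0, tolerance = 1e-12)
  }
})

test_that("low expected counts raise the warning flag; n = 0 is undefined", {
  t_low <- chi_square_uniformity(bin_angles(rep(0, 30), n_bins = 8))
  expect_true(t_low$low_expected_warning)
  t_na <- chi_square_uniformity(bin_angles(numeric(0), n_bins = 8))
  expect_false(t_na$defined)
  expect_true(is.na(t_na$p_value))
})

test_that("the test has high power against a moderate von Mises bias", {
  cal <- calibrate_uniformity(n_reps = 100, n_cells = 150,
                              mean_puncta_per_cell = 6, kappa = 1.5,
                              alpha = 0.001, seed = 7)
  expect_gt(cal$rejection_rate, 0.95)
})

test_that("rose plots render deterministically and annotate n", {
  h <- bin_angles(c(0, 30, 60, -20, 175), n_bins = 8)
  ts <- chi_square_uniformity(h)
  p <- render_rose_plot(h, ts)
  expect_s3_class(p, "ggplot")
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_rose_plot(h, ts, f1)
  render_rose_plot(h, ts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # degenerate all-zero histogram still renders
  f3 <- withr::local_tempfile(fileext = ".png")
  h0 <- bin_angles(numeric(0), n_bins = 8)
  render_rose_plot(h0, chi_square_uniformity(h0), f3)
  expect_true(file.size(f3) > 0)
})
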