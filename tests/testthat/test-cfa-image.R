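test_that("blank or flat images yield zero regions, not errors", {
  expect_length(segment_cells(matrix(0, 32, 32))$regions, 0)
  expect_length(segment_cells(matrix(7.5, 32, 32))$regions, 0)
  cfg <- segmentation_config(threshold_method = "fixed", fixed_threshold = 100)
  expect_length(segment_cells(matrix(0, 32, 32), cfg)$regions, 0)
})

test_that("multi-channel input violates the contract", {
  expect_error(segment_cells(array(0, c(8, 8, 3))), "2-D")
})

test_that("segmentation recall is 100% on oracle fields", {
  f <- render_field(image_sim_config(n_cells = 50, seed = 3))
  cells <- measure_cells(f$image)
  ok <- cells[cells$qc_pass, ]
  expect_equal(nrow(ok), 50)
  idx <- match_to_truth(ok, f$truth)
  expect_length(unique(idx), 50)  # one region per planted cell
})

test_that("border-touching cells are flagged, not dropped", {
  # paste one disc straddling the border and one interior disc
  img <- matrix(0, 64, 64)
  co_border <- ellipse_coords(cx = 2, cy = 32, a_semi = 6, b_semi = 6, theta = 0)
  co_border <- co_border[co_border[, 2] >= 0, ]
  co_inner <- ellipse_coords(cx = 40, cy = 32, a_semi = 6, b_semi = 6, theta = 0)
  img[co_border + 1] <- 200
  img[co_inner + 1] <- 200
  cfg <- segmentation_config(threshold_method = "fixed", fixed_threshold = 100,
                             min_area_px = 10)
  cells <- measure_cells(img, cfg)
  expect_equal(nrow(cells), 2)
  expect_equal(sum(cells$qc_pass), 1)
  expect_equal(cells$qc_reason[!cells$qc_pass], "touches_border")
  cfg2 <- segmentation_config(threshold_method = "fixed", fixed_threshold = 100,
                              min_area_px = 10, exclude_border = FALSE)
  expect_equal(sum(measure_cells(img, cfg2)$qc_pass), 2)
})

test_that("components touching only diagonally merge under 8-connectivity", {
  img <- matrix(0, 16, 16)
  img[3:4, 3:4] <- 200   # two 2x2 squares meeting corner-to-corner
  img[5:6, 5:6] <- 200
  cfg <- segmentation_config(threshold_method = "fixed", fixed_threshold = 100,
                             min_area_px = 1, exclude_border = FALSE)
  expect_length(segment_cells(img, cfg)$regions, 1)
})

test_that("moment axes recover discs and ellipses within 2%", {
  disc <- ellipse_coords(30, 30, 20, 20, 0)
  m <- measure_elongation(disc)
  expect_equal(m$er, 1, tolerance = 0.02)

  # rotation invariance at 12 orientations, truth ER = 2 (well-resolved
  # cell: 30 px semi-major)
  ers <- vapply(0:11, function(k) {
    measure_elongation(ellipse_coords(50, 50, 30, 15, pi * k / 12))$er
  }, 0.0)
  expect_true(all(abs(ers - 2) / 2 < 0.02))
  expect_lt((max(ers) - min(ers)) / mean(ers), 0.02)

  # scale invariance: same shape at 2x scale
  small <- measure_elongation(ellipse_coords(50, 50, 30, 15, 0.4))$er
  big <- measure_elongation(ellipse_coords(100, 100, 60, 30, 0.4))$er
  expect_lt(abs(big - small) / small, 0.01)
})

test_that("measured elongation increases strictly with truth elongation", {
  truth_er <- seq(1.0, 2.0, by = 0.2)
  measured <- vapply(seq_along(truth_er), function(i) {
    f <- render_field(image_sim_config(image_width = 128, image_height = 128,
                                       n_cells = 1, er_values = truth_er[i],
                                       noise_sd = 0, seed = 20 + i))
    measure_cells(f$image)$er
  }, 0.0)
  expect_true(all(diff(measured) > 0))
  expect_true(all(abs(measured - truth_er) / truth_er < 0.02))
})

test_that("measurement stays accurate at 10% contrast noise", {
  # contrast 170 gray levels; noise sd 17 = 10%
  f <- render_field(image_sim_config(n_cells = 50, noise_sd = 17, seed = 9))
  cells <- measure_cells(f$image)
  ok <- cells[cells$qc_pass & is.finite(cells$er), ]
  idx <- match_to_truth(ok, f$truth)
  expect_lte(mean(abs(ok$er[idx] - f$truth$er)), 0.05)
})

test_that("degenerate and tiny regions are handled per contract", {
  line <- cbind(row = rep(5, 10), col = 0:9)
  expect_equal(measure_elongation(line)$er, Inf)
  expect_error(measure_elongation(cbind(1:2, 1:2)), "at least 5 pixels")

  # a 1-pixel-wide line inside an image: flagged degenerate, not dropped
  img <- matrix(0, 32, 32)
  img[10, 5:25] <- 200
  cfg <- segmentation_config(threshold_method = "fixed", fixed_threshold = 100,
                             min_area_px = 5, exclude_border = FALSE)
  cells <- measure_cells(img, cfg)
  expect_false(cells$qc_pass)
  expect_equal(cells$qc_reason, "degenerate_shape")
})

test_that("analyze_sample pools fields and accounts for rejections", {
  fields <- lapply(1:3, function(i) {
    render_field(image_sim_config(image_width = 256, image_height = 256,
                                  n_cells = 12, seed = 30 + i))$image
  })
  res <- analyze_sample(fields)
  expect_s3_class(res$distribution, "er_distribution")
  expect_equal(res$distribution$n_cells, sum(res$cells$qc_pass))
  expect_equal(nrow(res$cells), 36)
  expect_setequal(unique(res$cells$field), 1:3)
  expect_error(analyze_sample(matrix(0, 32, 32)), "no measurable cells")
})

test_that("sample-level AER tracks the rendered truth", {
  fs <- lapply(1:4, function(i) {
    render_field(image_sim_config(n_cells = 40, seed = 40 + i))
  })
  truth_mean <- mean(unlist(lapply(fs, function(f) f$truth$er)))
  res <- analyze_sample(lapply(fs, function(f) f$image))
  expect_lt(abs(res$distribution$aer - truth_mean), 0.02)
})
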