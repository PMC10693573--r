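empty_sample <- tibble::tibble(element = integer(), kind = character(),
                               feature = character(), value = numeric())

test_that("an empty feature sample renders pure background", {
  sc <- render_image(empty_sample, image_spec(size_px = c(120, 120)), seed = 1)
  expect_length(sc$truth$pores, 0)
  expect_length(sc$truth$vessels, 0)
  expect_equal(dim(sc$image), c(120, 120))
  expect_lt(diff(range(sc$image)), 0.25) # noise texture only
})

test_that("a single circular pore renders with the stated truth area", {
  fs <- tibble::tibble(element = 1L, kind = "pore",
                       feature = c("pore_area", "pore_length",
                                   "pore_curvature", "pore_tortuosity"),
                       value = c(pi * 100, 20, 0.1, 1.0))
  sc <- render_image(fs, image_spec(size_px = c(200, 200), pixel_size_um = 1),
                     seed = 2)
  expect_length(sc$truth$pores, 1)
  expect_equal(vped:::polygon_area(sc$truth$pores[[1]]), pi * 100,
               tolerance = 0.02)
  expect_equal(sc$truth$pore_features$area, pi * 100, tolerance = 0.02)
})

test_that("all requested non-overlapping pores appear in the truth", {
  fs <- dplyr::filter(sample_features(18, 50, seed = 3), kind == "pore")
  sc <- render_image(fs, image_spec(), seed = 4)
  expect_length(sc$truth$pores, 50)
  expect_equal(nrow(sc$truth$pore_features), 50)
  # truth polygons are simple, closed and inside the extent
  ext <- sc$truth$spec$size_px * sc$truth$spec$pixel_size_um
  for (p in sc$truth$pores) {
    expect_true(vped:::polygon_is_simple(p))
    expect_true(all(p[, 1] >= 0 & p[, 1] <= ext[1]))
    expect_true(all(p[, 2] >= 0 & p[, 2] <= ext[2]))
  }
})

test_that("rendering is reproducible under a fixed seed", {
  fs <- sample_features(21, 10, seed = 5)
  a <- render_image(fs, image_spec(), seed = 6)
  b <- render_image(fs, image_spec(), seed = 6)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$pore_features, b$truth$pore_features)
})

test_that("overcrowded scenes are refused explicitly", {
  fs <- tibble::tibble(
    element = rep(1:40, each = 4), kind = "pore",
    feature = rep(c("pore_area", "pore_length", "pore_curvature",
                    "pore_tortuosity"), 40),
    value = rep(c(8000, 100, 0.05, 1.1), 40)
  )
  expect_error(
    render_image(fs, image_spec(size_px = c(100, 100), pixel_size_um = 1),
                 seed = 7),
    "overcrowded|too crowded|does not fit"
  )
})

test_that("truth morphometry recovers sampled pore areas and lengths", {
  fs <- dplyr::filter(sample_features(21, 40, seed = 8), kind == "pore")
  sc <- render_image(fs, image_spec(), seed = 9)
  truth <- sc$truth$pore_features
  sampled <- tidyr::pivot_wider(fs, names_from = feature,
                                values_from = value)
  sampled <- sampled[match(truth$element, sampled$element), ]
  rel_err <- abs(truth$area - sampled$pore_area) / sampled$pore_area
  expect_lt(mean(rel_err), 0.05)
  # rim perturbation tracks the sampled tortuosity monotonically
  expect_gt(stats::cor(truth$tortuosity, sampled$pore_tortuosity), 0.6)
})

test_that("the defocus quadrant is recorded in the in-focus truth mask", {
  fs <- dplyr::filter(sample_features(20, 10, seed = 10), kind == "pore")
  sc <- render_image(fs, image_spec(blur_quadrant = 2), seed = 11)
  expect_equal(mean(sc$truth$focus_mask), 0.75, tolerance = 0.01)
})

test_that("images survive a 16-bit TIFF round trip", {
  sc <- render_image(empty_sample, image_spec(size_px = c(60, 60)), seed = 12)
  path <- withr::local_tempfile(fileext = ".tif")
  write_tissue_image(sc$image, path)
  back <- read_tissue_image(path)
  expect_equal(dim(back), dim(sc$image))
  expect_lt(max(abs(back - sc$image)), 1 / 65535 + 1e-9)
})
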