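test_that("focus mask covers sharp images and rejects blur and flatness", {
  sc <- benchmark_scene(1)
  m <- focus_mask(sc$image)
  expect_gt(mean(m), 0.99 * mean(sc$truth$focus_mask))
  # constant image: no texture, no focus evidence
  expect_equal(sum(focus_mask(matrix(0.5, 200, 200))), 0)
})

test_that("a blurred quadrant is mostly excluded from the focus mask", {
  fs <- dplyr::filter(sample_features(20, 20, seed = 31), kind == "pore")
  sc <- render_image(fs, image_spec(blur_quadrant = 3), seed = 32)
  m <- focus_mask(sc$image)
  blurred <- !sc$truth$focus_mask
  expect_gt(mean(!m[blurred]), 0.90)
})

test_that("blank images yield no detections", {
  blank <- matrix(0.75, 200, 200)
  set.seed(1)
  blank <- blank + matrix(rnorm(length(blank), 0, 0.02), 200, 200)
  m <- focus_mask(blank)
  expect_length(detect_pores(blank, m), 0)
  expect_length(detect_vessels(blank, m), 0)
})

test_that("pore detection meets the ground-truth benchmark on one scene", {
  sc <- benchmark_scene(2)
  res <- segment_image(sc$image, sc$truth$spec$pixel_size_um)
  mt <- match_pores(sc, res$detections, sc$truth$spec$pixel_size_um)
  precision <- mt$tp / mt$n_det
  recall <- mt$tp / mt$n_truth
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("pores below the minimum area are excluded by the filter", {
  sc <- benchmark_scene(3)
  cfg <- segmentation_config(pore_min_area_px = 100)
  m <- focus_mask(sc$image, cfg)
  det <- detect_pores(sc$image, m, cfg)
  expect_true(all(vapply(det, function(d) d$area_px, numeric(1)) >= 100))
})

test_that("detections stay inside the focus mask", {
  fs <- dplyr::filter(sample_features(21, 30, seed = 33), kind == "pore")
  sc <- render_image(fs, image_spec(blur_quadrant = 1), seed = 34)
  cfg <- segmentation_config()
  m <- focus_mask(sc$image, cfg)
  det <- detect_pores(sc$image, m, cfg)
  for (d in det) {
    px <- round(d$polygon + 0.5)
    px[, 1] <- pmin(pmax(px[, 1], 1), ncol(m))
    px[, 2] <- pmin(pmax(px[, 2], 1), nrow(m))
    inside <- m[cbind(px[, 2], px[, 1])]
    expect_gte(mean(inside), 0.95)
  }
})

test_that("a straight vessel's detected width matches the rendered width", {
  fs <- tibble::tibble(element = 1L, kind = "vessel",
                       feature = c("bv_diameter", "bv_segment_length"),
                       value = c(8, 300))
  sc <- render_image(fs, image_spec(), seed = 35)
  res <- segment_image(sc$image, 2)
  v <- dplyr::filter(res$features, kind == "vessel")
  expect_gt(nrow(v), 0)
  mean_w <- stats::weighted.mean(v$diameter, v$segment_length)
  expect_lt(abs(mean_w - 8) / 8, 0.2)
})

test_that("a Y-shaped vessel splits into three skeleton segments", {
  # build the truth mask directly and exercise the skeleton topology path
  img <- matrix(0.75, 200, 200)
  stamp <- function(img, from, to) {
    vped:::stamp_band(img, rbind(from, to), 3, 0.3)
  }
  img <- stamp(img, c(100, 20), c(100, 100))
  img <- stamp(img, c(100, 100), c(40, 170))
  img <- stamp(img, c(100, 100), c(160, 170))
  set.seed(2)
  img <- img + matrix(rnorm(length(img), 0, 0.01), 200, 200)
  m <- matrix(TRUE, 200, 200)
  det <- detect_vessels(img, m)
  expect_equal(length(det), 3)
})

test_that("vessel centerlines are recalled on the benchmark scene", {
  sc <- benchmark_scene(4)
  px <- sc$truth$spec$pixel_size_um
  res <- segment_image(sc$image, px)
  det <- res$detections
  segs <- det[vapply(det, function(d) d$kind, "") == "vessel"]
  det_pts <- do.call(rbind, lapply(segs, function(s) s$centerline * px))
  # fraction of truth centerline points with a detected point within 6 um
  truth_pts <- do.call(rbind, lapply(sc$truth$vessels,
                                     function(v) v$centerline))
  hit <- vapply(seq_len(nrow(truth_pts)), function(i) {
    min(sqrt(rowSums(sweep(det_pts, 2, truth_pts[i, ])^2))) < 6
  }, logical(1))
  expect_gte(mean(hit), 0.85)
})

test_that("collation conserves counts and partitions magnifications", {
  mk_result <- function(spec, img, mag, n) {
    structure(list(
      detections = list(),
      features = tibble::tibble(
        specimen = spec, image = img, magnification = mag, kind = "pore",
        area = runif(n, 50, 500), equiv_radius = 1, length = 1,
        curvature = 1, tortuosity = 1, quality = 1
      ),
      analyzed_area_um2 = 1e5, mask = NULL,
      specimen = spec, image = img, magnification = mag
    ), class = "vped_image_result")
  }
  results <- c(lapply(1:20, function(i) mk_result("s1", paste0("i", i), "4X", 10)),
               lapply(1:3, function(i) mk_result("s1", paste0("j", i), "2X", 5)))
  ens <- collate_specimen(results)
  expect_equal(nrow(ens$elements), 20 * 10 + 3 * 5)
  expect_equal(sort(ens$analyzed_area$magnification), c("2X", "4X"))
  expect_equal(ens$analyzed_area$area_um2[ens$analyzed_area$magnification == "4X"],
               20 * 1e5)
  expect_error(collate_specimen(c(results, list(mk_result("s2", "x", "4X", 1)))),
               "mixed specimen")
  empty <- collate_specimen(list())
  expect_equal(empty$n_images, 0L)
  expect_equal(nrow(empty$analyzed_area), 0L)
})

test_that("per-image detections serialize to JSON with metadata", {
  fs <- dplyr::filter(sample_features(20, 8, seed = 51), kind == "pore")
  sc <- render_image(fs, image_spec(size_px = c(250, 250)), seed = 52)
  res <- segment_image(sc$image, 2, image_id = "imgA", specimen_id = "S1")
  path <- withr::local_tempfile(fileext = ".json")
  write_detections(res, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$specimen, "S1")
  expect_equal(length(js$detections), length(res$detections))
  expect_true(all(vapply(js$detections, function(d) d$kind, "") %in%
                    c("pore", "vessel")))
})

test_that("measured physical areas are stable under resolution change", {
  fs <- dplyr::filter(sample_features(21, 25, seed = 36), kind == "pore")
  sc1 <- render_image(fs, image_spec(size_px = c(400, 400), pixel_size_um = 2),
                      seed = 37)
  sc2 <- render_image(fs, image_spec(size_px = c(800, 800), pixel_size_um = 1),
                      seed = 37)
  r1 <- segment_image(sc1$image, 2)
  r2 <- segment_image(sc2$image, 1)
  # compare per-pore physical areas of truth-matched detections, so the
  # (pixel-denominated) minimum-size cut does not change the population
  m1 <- match_pores(sc1, r1$detections, 2)
  m2 <- match_pores(sc2, r2$detections, 1)
  a1 <- vapply(m1$pores[m1$pairs[, 2]],
               function(p) p$area_px_corrected * 4, numeric(1))
  a2 <- vapply(m2$pores[m2$pairs[, 2]],
               function(p) p$area_px_corrected * 1, numeric(1))
  common <- intersect(m1$pairs[, 1], m2$pairs[, 1])
  a1 <- a1[match(common, m1$pairs[, 1])]
  a2 <- a2[match(common, m2$pairs[, 1])]
  # restrict to pores above the digitization floor at the coarser scale
  big <- a2 >= 80
  expect_gt(sum(big), 10)
  expect_lt(mean(abs(a1[big] - a2[big]) / a2[big]), 0.05)
})
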