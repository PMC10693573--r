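test_that("circle features match the analytic identities", {
  f <- pore_features(circle_polygon(10, 128), pixel_size = 1)
  expect_equal(f$area, pi * 100, tolerance = 0.02)
  expect_equal(f$equiv_radius, sqrt(f$area / pi))
  expect_equal(f$length, 20, tolerance = 0.02)
  expect_equal(f$curvature, 0.1, tolerance = 0.03)
  expect_equal(f$tortuosity, 1, tolerance = 0.005)
})

test_that("ellipse length equals the major axis (max Feret)", {
  f <- pore_features(ellipse_polygon(20, 10, 128), pixel_size = 1)
  expect_equal(f$length, 40, tolerance = 0.02)
  expect_equal(f$area, pi * 200, tolerance = 0.02)
})

test_that("star tortuosity matches the vertex-by-vertex hull oracle", {
  poly <- star_polygon(10, 7, 16)
  # brute-force oracle on the same smoothed resampled boundary the
  # implementation uses
  res <- vped:::resample_closed(poly, 128)
  sm <- vped:::smooth_closed(res, round(0.05 * 128))
  per <- sum(sqrt(rowSums((sm[c(2:nrow(sm), 1), ] - sm)^2)))
  hull <- sm[chull(sm[, 1], sm[, 2]), ]
  hper <- sum(sqrt(rowSums((hull[c(2:nrow(hull), 1), ] - hull)^2)))
  f <- pore_features(poly, 1)
  expect_equal(f$tortuosity, per / hper, tolerance = 1e-10)
  expect_gt(f$tortuosity, 1.01)
})

test_that("degenerate pore boundaries are rejected", {
  expect_error(pore_features(circle_polygon(10, 6)), ">= 8 vertices")
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2),
               c(-1, 3), c(-2, 2), c(-2, 1), c(-1, 0))
  expect_error(pore_features(bow), "self-intersecting")
})

test_that("pixel size scales features physically", {
  f1 <- pore_features(circle_polygon(10, 64), pixel_size = 1)
  f2 <- pore_features(circle_polygon(10, 64), pixel_size = 2)
  expect_equal(f2$area, 4 * f1$area)
  expect_equal(f2$length, 2 * f1$length)
  expect_equal(f2$curvature, f1$curvature / 2)
  expect_equal(f2$tortuosity, f1$tortuosity)
})

test_that("pore features are invariant to rigid motions", {
  set.seed(8)
  poly <- star_polygon(12, 9, 12)
  f0 <- pore_features(poly, 1)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- sweep(poly %*% R, 2, c(55, -20), "+")
  f1 <- pore_features(moved, 1)
  for (col in names(f0)) {
    expect_lt(abs(f1[[col]] - f0[[col]]) / abs(f0[[col]]), 0.01)
  }
})

test_that("curvature and tortuosity converge under vertex refinement", {
  f1 <- pore_features(star_polygon(10, 8, 16), 1)
  # same shape, doubled vertex density
  f2 <- pore_features(vped:::resample_closed(star_polygon(10, 8, 16), 64), 1)
  expect_lt(abs(f2$curvature - f1$curvature) / f1$curvature, 0.03)
  expect_lt(abs(f2$tortuosity - f1$tortuosity) / f1$tortuosity, 0.03)
})

test_that("vessel features follow arc-length arithmetic", {
  f <- vessel_features(cbind(c(0, 100), c(0, 0)), c(6, 6), 1)
  expect_equal(f$diameter, 6)
  expect_equal(f$segment_length, 100)
  # semicircular arc of radius 50
  th <- seq(0, pi, length.out = 200)
  arc <- cbind(50 * cos(th), 50 * sin(th))
  fa <- vessel_features(arc, rep(4, 200), 1)
  expect_equal(fa$segment_length, pi * 50, tolerance = 1e-3)
  # linear width profile, equal spacing: trapezoid mean
  fv <- vessel_features(cbind(c(0, 1, 2), c(0, 0, 0)), c(4, 6, 8), 1)
  expect_equal(fv$diameter, 6)
  expect_error(vessel_features(cbind(1, 1), 5, 1), ">= 2 points")
  expect_error(vessel_features(cbind(c(0, 1), c(0, 0)), c(1, -1), 1), "> 0")
})

test_that("global attributes follow the density definitions", {
  el <- tibble::tibble(
    specimen = "s", image = "i", magnification = "4X",
    kind = c(rep("pore", 10), "vessel"),
    area = c(rep(1000, 10), NA),
    equiv_radius = NA, length = NA, curvature = NA, tortuosity = NA,
    diameter = c(rep(NA, 10), 8), segment_length = c(rep(NA, 10), 2000),
    quality = 1
  )
  ens <- structure(
    list(specimen = "s", elements = el,
         analyzed_area = tibble::tibble(magnification = "4X", area_um2 = 1e6),
         n_images = 1L),
    class = "vped_ensemble"
  )
  g <- global_attributes(ens)
  expect_equal(g$pore_density_mm2, 10)
  expect_equal(g$filling_factor, 0.01)
  expect_equal(g$vessel_density_mm_per_mm2, 2)
  # no pores: zero density and filling factor
  ens0 <- ens; ens0$elements <- el[11, ]
  g0 <- global_attributes(ens0)
  expect_equal(g0$pore_density_mm2, 0)
  expect_equal(g0$filling_factor, 0)
  enszero <- ens
  enszero$analyzed_area$area_um2 <- 0
  expect_error(global_attributes(enszero), "zero analyzed area")
})
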