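#' Image specification for synthetic scene rendering
#'
#' @param size_px Image side lengths, `c(width, height)` in pixels.
#' @param pixel_size_um Physical pixel size, µm per pixel.
#' @param magnification Magnification tag carried through the pipeline.
#' @param background Background intensity in `[0, 1]`.
#' @param pore_contrast,vessel_contrast Intensity drop of rendered elements.
#' @param noise_sd Standard deviation of the additive Gaussian background
#'   texture.
#' @param blur_quadrant Optional integer 1-4; that image quadrant is rendered
#'   out of focus (Gaussian blur) and excluded from the in-focus truth mask.
#' @param blur_sigma_px Blur strength for the out-of-focus quadrant.
#' @param max_fill Maximum allowed pore filling factor before placement is
#'   refused as overcrowded.
#' @return A list of class `vped_image_spec`.
#' @export
image_spec <- function(size_px = c(400L, 400L), pixel_size_um = 2,
                       magnification = "4X", background = 0.75,
                       pore_contrast = 0.35, vessel_contrast = 0.25,
                       noise_sd = 0.02, blur_quadrant = NULL,
                       blur_sigma_px = 6, max_fill = 0.35) {
  stopifnot(length(size_px) == 2L, all(size_px > 0), pixel_size_um > 0)
  structure(
    list(size_px = as.integer(size_px), pixel_size_um = pixel_size_um,
         magnification = magnification, background = background,
         pore_contrast = pore_contrast, vessel_contrast = vessel_contrast,
         noise_sd = noise_sd, blur_quadrant = blur_quadrant,
         blur_sigma_px = blur_sigma_px, max_fill = max_fill),
    class = "vped_image_spec"
  )
}

# Build one pore boundary polygon (µm, centred at origin) from sampled
# features: an ellipse with the sampled max-Feret length as major axis and
# the sampled area, rim-perturbed by a radial Fourier series whose amplitude
# is tuned to the sampled tortuosity, then rescaled to the exact target area.
pore_polygon <- function(area, length, tortuosity, n_vertices = 96L,
                         max_aspect = 3.5) {
  # couple length to area: the rendered ellipse keeps the sampled max-Feret
  # length unless it would exceed the maximum physical aspect ratio
  a_max <- sqrt(area * max_aspect / pi)
  a <- min(max(length / 2, sqrt(area / pi) * 1.001), a_max, 90)
  a <- max(a, sqrt(area / pi) * 1.001)
  b <- area / (pi * a)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  base <- cbind(a * cos(th), b * sin(th))
  target_t <- max(1, tortuosity)
  # initial amplitude from the small-perturbation quadratic relation between
  # rim excess length and radial modulation; refined by one measure step
  amp <- sqrt(max(0, target_t - 1)) * 0.35
  modes <- c(5L, 8L, 11L)
  ph <- stats::runif(3, 0, 2 * pi)
  build <- function(amp) {
    r_mod <- 1 + amp * (0.5 * sin(modes[1] * th + ph[1]) +
                          0.3 * sin(modes[2] * th + ph[2]) +
                          0.2 * sin(modes[3] * th + ph[3]))
    r_mod <- pmax(r_mod, 0.25)
    poly <- base * r_mod
    poly * sqrt(area / polygon_area(poly))
  }
  poly <- build(amp)
  # a couple of fixed-point refinements of the amplitude-to-tortuosity map
  for (it in 1:2) {
    if (amp <= 0) break
    sm <- smooth_closed(resample_closed(poly, 128L), 7L)
    got <- polygon_perimeter(sm) / convex_hull_perimeter(sm)
    if (got <= 1.0005) break
    amp <- min(amp * sqrt(max(0, target_t - 1) / (got - 1)), 0.9)
    poly <- build(amp)
  }
  poly
}

# smooth random vessel centerline of a given arc length (µm), starting at
# `start` with heading `theta0`; gentle random curvature
vessel_centerline <- function(length_um, start, theta0, step_um = 6) {
  n <- max(2L, ceiling(length_um / step_um) + 1L)
  dth <- stats::rnorm(n - 1L, 0, 0.12)
  th <- theta0 + cumsum(c(0, dth[-1]))
  steps <- cbind(cos(th), sin(th)) * (length_um / (n - 1L))
  rbind(start, sweep(apply(steps, 2, cumsum), 2, start, "+"))
}

#' Render a synthetic tissue image with ground truth
#'
#' Rasterizes one cycle-day feature sample (from [sample_features()]) into a
#' brightfield-style single-channel image: pores as darker blobs with
#' irregular rims, vessels as darker curvilinear bands, plus Gaussian
#' background texture and an optional out-of-focus quadrant. Placement is by
#' rejection sampling with non-overlap constraints.
#'
#' The returned `truth` (scene ground truth) holds every pore boundary
#' polygon and vessel centerline in µm coordinates, the measured ("true")
#' feature values of each rendered element, and the in-focus mask. Rendered
#' pore area and length match the sampled values by construction; rim
#' tortuosity is matched approximately through the calibrated perturbation
#' amplitude, and rim curvature is emergent from size and perturbation.
#'
#' @param feature_sample Long feature tibble (`element`, `kind`, `feature`,
#'   `value`) as produced by [sample_features()]; may be empty.
#' @param spec An [image_spec()].
#' @param seed Optional integer seed.
#' @param max_retries Placement retries per element before giving up.
#' @return List of class `vped_scene`: `image` (numeric matrix, rows = y),
#'   `truth` (list with `pores`, `pore_features`, `vessels`,
#'   `vessel_features`, `focus_mask`, `spec`).
#' @export
render_image <- function(feature_sample, spec = image_spec(), seed = NULL,
                         max_retries = 600L) {
  stopifnot(inherits(spec, "vped_image_spec"))
  with_seed(seed, render_image_impl(feature_sample, spec, max_retries))
}

render_image_impl <- function(feature_sample, spec, max_retries) {
  w_px <- spec$size_px[1]; h_px <- spec$size_px[2]
  px <- spec$pixel_size_um
  w_um <- w_px * px; h_um <- h_px * px
  img <- matrix(spec$background, nrow = h_px, ncol = w_px)

  pores_w <- vessels_w <- NULL
  if (nrow(feature_sample) > 0) {
    wide <- tidyr::pivot_wider(feature_sample, names_from = "feature",
                               values_from = "value")
    pores_w <- dplyr::filter(wide, .data$kind == "pore")
    vessels_w <- dplyr::filter(wide, .data$kind == "vessel")
  }

  total_pore_area <- if (!is.null(pores_w) && nrow(pores_w)) sum(pores_w$pore_area) else 0
  if (total_pore_area / (w_um * h_um) > spec$max_fill) {
    stop("overcrowded scene: requested pore filling factor ",
         signif(total_pore_area / (w_um * h_um), 3), " exceeds max_fill = ",
         spec$max_fill, call. = FALSE)
  }

  vessel_list <- list()
  vessel_feats <- NULL
  if (!is.null(vessels_w) && nrow(vessels_w) > 0) {
    for (i in seq_len(nrow(vessels_w))) {
      len <- min(vessels_w$bv_segment_length[i], 0.8 * min(w_um, h_um))
      dia <- vessels_w$bv_diameter[i]
      placed <- FALSE
      for (r in seq_len(max_retries)) {
        start <- c(stats::runif(1, 0.1 * w_um, 0.9 * w_um),
                   stats::runif(1, 0.1 * h_um, 0.9 * h_um))
        cl <- vessel_centerline(len, start, stats::runif(1, 0, 2 * pi))
        if (all(cl[, 1] > dia & cl[, 1] < w_um - dia &
                  cl[, 2] > dia & cl[, 2] < h_um - dia)) {
          placed <- TRUE; break
        }
      }
      if (!placed) stop("could not place vessel ", i, " within the image extent",
                        call. = FALSE)
      widths <- rep(dia, nrow(cl))
      vessel_list[[length(vessel_list) + 1L]] <- list(centerline = cl,
                                                      widths = widths)
      vessel_feats <- dplyr::bind_rows(
        vessel_feats,
        dplyr::mutate(vessel_features(cl, widths, 1),
                      element = vessels_w$element[i], .before = 1)
      )
      img <- stamp_band(img, cl / px, dia / (2 * px), spec$vessel_contrast)
    }
  }

  pore_list <- list()
  pore_feats <- NULL
  placed_centers <- matrix(numeric(0), ncol = 3) # x, y, radius (µm)
  if (!is.null(pores_w) && nrow(pores_w) > 0) {
    vessel_pts <- if (length(vessel_list)) {
      do.call(rbind, lapply(vessel_list, `[[`, "centerline"))
    } else matrix(numeric(0), ncol = 2)
    max_dia <- if (length(vessel_list)) max(vessels_w$bv_diameter) else 0
    # place large pores first: improves rejection-packing success
    pores_w <- pores_w[order(-pores_w$pore_area), ]
    for (i in seq_len(nrow(pores_w))) {
      poly0 <- pore_polygon(pores_w$pore_area[i], pores_w$pore_length[i],
                            pores_w$pore_tortuosity[i])
      rad <- max(sqrt(rowSums(poly0^2)))
      if (2 * rad + 8 > min(w_um, h_um)) {
        stop("pore ", i, " (circumscribed radius ", round(rad),
             " um) does not fit in the image extent", call. = FALSE)
      }
      placed <- FALSE
      # pore-pore overlap is never allowed; the pore-vessel clearance is
      # relaxed stepwise (vessels may pass beneath pores: pores are stamped
      # opaquely last, so their shapes stay intact)
      for (vessel_margin in c(8, 4, 0)) {
        for (r in seq_len(max_retries)) {
          c_xy <- c(stats::runif(1, rad + 2, w_um - rad - 2),
                    stats::runif(1, rad + 2, h_um - rad - 2))
          ok <- TRUE
          if (nrow(placed_centers) > 0) {
            d <- sqrt((placed_centers[, 1] - c_xy[1])^2 +
                        (placed_centers[, 2] - c_xy[2])^2)
            ok <- all(d > placed_centers[, 3] + rad + 8)
          }
          if (ok && vessel_margin > 0 && nrow(vessel_pts) > 0) {
            dv <- sqrt((vessel_pts[, 1] - c_xy[1])^2 + (vessel_pts[, 2] - c_xy[2])^2)
            ok <- min(dv) > rad + max_dia / 2 + vessel_margin
          }
          if (ok) { placed <- TRUE; break }
        }
        if (placed) break
      }
      if (!placed) {
        stop("could not place pore ", i, " without overlap; scene too crowded",
             call. = FALSE)
      }
      poly <- sweep(poly0, 2, c_xy, "+")
      placed_centers <- rbind(placed_centers, c(c_xy, rad))
      pore_list[[length(pore_list) + 1L]] <- poly
      pore_feats <- dplyr::bind_rows(
        pore_feats,
        dplyr::mutate(pore_features(poly, 1),
                      element = pores_w$element[i], .before = 1)
      )
      img <- stamp_polygon(img, poly / px, spec$pore_contrast, spec$background)
    }
  }

  # background texture, soft rims, optional defocus quadrant
  img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                      nrow = nrow(img))
  img <- ebi_blur(img, 0.8)
  focus <- matrix(TRUE, nrow = h_px, ncol = w_px)
  if (!is.null(spec$blur_quadrant)) {
    q <- spec$blur_quadrant
    rows <- if (q %in% c(1, 2)) seq_len(h_px %/% 2) else (h_px %/% 2 + 1L):h_px
    cols <- if (q %in% c(1, 4)) seq_len(w_px %/% 2) else (w_px %/% 2 + 1L):w_px
    blurred <- ebi_blur(img, spec$blur_sigma_px)
    img[rows, cols] <- blurred[rows, cols]
    focus[rows, cols] <- FALSE
  }
  img <- pmin(pmax(img, 0), 1)

  structure(
    list(
      image = img,
      truth = list(
        pores = pore_list,
        pore_features = pore_feats,
        vessels = vessel_list,
        vessel_features = vessel_feats,
        focus_mask = focus,
        spec = spec
      )
    ),
    class = "vped_scene"
  )
}

# set pixels inside a polygon to an absolute darkened level (opaque stamp:
# anything rendered earlier beneath the pore is occluded)
stamp_polygon <- function(img, poly_px, contrast, background) {
  h <- nrow(img); w <- ncol(img)
  xr <- pmax(1L, floor(min(poly_px[, 1]))):pmin(w, ceiling(max(poly_px[, 1])))
  yr <- pmax(1L, floor(min(poly_px[, 2]))):pmin(h, ceiling(max(poly_px[, 2])))
  gx <- rep(xr, each = length(yr)); gy <- rep(yr, times = length(xr))
  inside <- points_in_polygon(gx - 0.5, gy - 0.5, poly_px)
  idx <- cbind(gy[inside], gx[inside])
  img[idx] <- background - contrast
  img
}

# darken pixels within half-width of a polyline (pixel coords)
stamp_band <- function(img, line_px, halfwidth_px, contrast) {
  h <- nrow(img); w <- ncol(img)
  pad <- ceiling(halfwidth_px) + 1L
  xr <- pmax(1L, floor(min(line_px[, 1])) - pad):pmin(w, ceiling(max(line_px[, 1])) + pad)
  yr <- pmax(1L, floor(min(line_px[, 2])) - pad):pmin(h, ceiling(max(line_px[, 2])) + pad)
  gx <- rep(xr, each = length(yr)) - 0.5
  gy <- rep(yr, times = length(xr)) - 0.5
  dmin <- rep(Inf, length(gx))
  for (i in seq_len(nrow(line_px) - 1L)) {
    a <- line_px[i, ]; b <- line_px[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- pmin(1, pmax(0, ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len2))
    d <- sqrt((gx - (a[1] + t * ab[1]))^2 + (gy - (a[2] + t * ab[2]))^2)
    dmin <- pmin(dmin, d)
  }
  hit <- dmin <= halfwidth_px
  idx <- cbind(rep(yr, times = length(xr))[hit], rep(xr, each = length(yr))[hit])
  img[idx] <- img[idx] - contrast
  img
}

ebi_blur <- function(img, sigma) {
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
}

#' Write a rendered image to disk
#'
#' Single-channel 16-bit TIFF (default) or 8-bit PNG.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @export
write_tissue_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(image, path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read a tissue image from disk
#'
#' @param path TIFF or PNG path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_tissue_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
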