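#' Morphometric features of one pore boundary
#'
#' Computes the pore feature vector from a closed boundary polygon:
#' * **area** (µm²) by the shoelace formula, and the equivalent radius
#'   `sqrt(area / pi)` of the equal-area disc;
#' * **length** (µm): maximum Feret diameter, a proxy for deviation from
#'   circularity (configurable to the ellipse major axis via `length_method`);
#' * **rim curvature** (1/µm): mean absolute discrete curvature along the
#'   boundary after resampling to `n_resample` equidistant points and light
#'   circular smoothing (window 5% of the perimeter), which suppresses
#'   pixelation noise and makes curvature comparable across pore sizes;
#' * **rim tortuosity** (dimensionless, >= 1): smoothed-boundary perimeter
#'   divided by its convex-hull perimeter — a direct reading of rim
#'   "wiggliness".
#'
#' @param polygon n x 2 matrix of boundary vertices (pixel or µm coordinates),
#'   simple and implicitly closed, n >= 8.
#' @param pixel_size Physical size of one coordinate unit in µm (1 if the
#'   polygon is already in µm).
#' @param n_resample Boundary resampling density before curvature; default 128.
#' @param smooth_frac Smoothing window as a fraction of perimeter; default 0.05.
#' @param length_method `"feret"` (default) or `"hull_feret"` (identical here;
#'   kept as an explicit strategy switch).
#' @param check_simple Verify the polygon is non-self-intersecting (skip for
#'   boundaries that are simple by construction, e.g. traced contours of
#'   connected components).
#' @return One-row tibble: `area`, `equiv_radius`, `length`, `curvature`,
#'   `tortuosity`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 64)[-64]
#' pore_features(cbind(10 * cos(th), 10 * sin(th)), pixel_size = 1)
#' @export
pore_features <- function(polygon, pixel_size = 1, n_resample = 128L,
                          smooth_frac = 0.05,
                          length_method = c("feret", "hull_feret"),
                          check_simple = TRUE) {
  length_method <- match.arg(length_method)
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2L)
  if (nrow(polygon) < 8L) {
    stop("pore boundary needs >= 8 vertices, got ", nrow(polygon), call. = FALSE)
  }
  if (check_simple && !polygon_is_simple(polygon)) {
    stop("pore boundary polygon is self-intersecting", call. = FALSE)
  }
  poly_um <- polygon * pixel_size
  area <- polygon_area(poly_um)
  if (area <= 0) stop("degenerate (zero-area) pore boundary", call. = FALSE)
  res <- resample_closed(poly_um, n_resample)
  sm <- smooth_closed(res, round(smooth_frac * n_resample))
  tibble::tibble(
    area = area,
    equiv_radius = sqrt(area / pi),
    length = max_feret(poly_um),
    curvature = mean_abs_curvature(sm),
    tortuosity = max(1, polygon_perimeter(sm) / convex_hull_perimeter(sm))
  )
}

#' Morphometric features of one vessel segment
#'
#' Mean diameter is the arc-length-weighted average of the per-point local
#' widths (trapezoidal weights); segment length is the centerline polyline
#' arc length.
#'
#' @param centerline n x 2 matrix of centerline points (>= 2).
#' @param widths Per-point local widths, same length as the centerline,
#'   all > 0 (same coordinate units as the centerline).
#' @param pixel_size µm per coordinate unit.
#' @return One-row tibble: `diameter` (µm), `segment_length` (µm).
#' @examples
#' vessel_features(cbind(c(0, 100), c(0, 0)), c(6, 6), pixel_size = 1)
#' @export
vessel_features <- function(centerline, widths, pixel_size = 1) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 2L)
  if (nrow(centerline) < 2L) {
    stop("vessel centerline needs >= 2 points", call. = FALSE)
  }
  stopifnot(length(widths) == nrow(centerline))
  if (any(widths <= 0)) stop("vessel widths must be > 0", call. = FALSE)
  pts <- centerline * pixel_size
  w <- widths * pixel_size
  seg <- sqrt(rowSums(diff(pts)^2))
  segw <- (w[-length(w)] + w[-1]) / 2
  tibble::tibble(
    diameter = sum(segw * seg) / sum(seg),
    segment_length = sum(seg)
  )
}

#' Global tissue attributes of a specimen ensemble
#'
#' Per magnification partition: pore number density (pores per mm²), pore
#' filling factor (summed pore area over analyzed in-focus area) and blood
#' vessel density (summed centerline length per area, mm/mm²). Quantities are
#' computed over the collated elements and total analyzed area of all images
#' of the specimen, i.e. averaged over images weighted by their analyzed
#' area.
#'
#' @param ensemble A `vped_ensemble` from [collate_specimen()].
#' @return Tibble with one row per magnification: `magnification`,
#'   `analyzed_area_mm2`, `pore_density_mm2`, `filling_factor`,
#'   `vessel_density_mm_per_mm2`.
#' @export
global_attributes <- function(ensemble) {
  stopifnot(inherits(ensemble, "vped_ensemble"))
  areas <- ensemble$analyzed_area
  if (nrow(areas) == 0L || all(areas$area_um2 <= 0)) {
    stop("specimen has zero analyzed area", call. = FALSE)
  }
  el <- ensemble$elements
  purrr::map_dfr(split(areas, areas$magnification), function(a) {
    mm2 <- sum(a$area_um2) / 1e6
    sub <- dplyr::filter(el, .data$magnification == a$magnification[1])
    pores <- dplyr::filter(sub, .data$kind == "pore")
    vessels <- dplyr::filter(sub, .data$kind == "vessel")
    tibble::tibble(
      magnification = a$magnification[1],
      analyzed_area_mm2 = mm2,
      pore_density_mm2 = nrow(pores) / mm2,
      filling_factor = sum(pores$area) / (mm2 * 1e6),
      vessel_density_mm_per_mm2 = sum(vessels$segment_length) / 1e3 / mm2
    )
  })
}
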