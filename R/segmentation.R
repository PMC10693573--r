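#' Segmentation configuration
#'
#' All thresholds of the classical (non-learned) detection pipeline. Defaults
#' are calibrated for the synthetic renderer's contrast model at 2 µm/px.
#'
#' @param focus_window Side of the sliding window (px) for the local
#'   sharpness statistic (variance of the Laplacian response).
#' @param focus_rel Fraction of the image's robust noise-level Laplacian
#'   variance (squared scaled MAD of the Laplacian response) below which a
#'   region counts as out of focus.
#' @param focus_min_var Absolute sharpness floor; images with no texture at
#'   all yield an empty mask.
#' @param thresh_window Adaptive-threshold window side (px).
#' @param thresh_offset Adaptive-threshold offset (intensity units).
#' @param global_offset Offset below the median background intensity for the
#'   global threshold that backs up the adaptive one inside large dark blobs.
#' @param pore_min_area_px,pore_max_area_px Pore area bounds (px²).
#' @param pore_min_compactness Minimum `area / feret²` (circle: pi/4); rejects
#'   elongated vessel fragments from the pore channel.
#' @param pore_min_solidity Minimum area over convex-hull area.
#' @param vessel_scales Gaussian scales (px) of the multiscale ridge filter.
#' @param vessel_threshold Minimum mean multiscale ridge response within a
#'   component for it to qualify as a vessel.
#' @param vessel_elongation Minimum `feret² / area` of a candidate component
#'   to count as a vessel (bands of length L and width w score ~L/w).
#' @param vessel_width_cv Maximum coefficient of variation of the local width
#'   along a component's skeleton for the vessel class (vessels are bands of
#'   near-constant width; elongated pores are not).
#' @param vessel_elongation_hard Elongation above which a component is a
#'   vessel regardless of width variation.
#' @param vessel_min_length_px Minimum skeleton segment length kept (px).
#' @param quality_filter Optional minimum detection quality score in `[0,1]`;
#'   `NULL` (default) disables quality filtering.
#' @return List of class `vped_seg_config`.
#' @export
segmentation_config <- function(focus_window = 21L, focus_rel = 0.15,
                                focus_min_var = 1e-6,
                                thresh_window = 31L, thresh_offset = 0.1,
                                global_offset = 0.15,
                                pore_min_area_px = 3, pore_max_area_px = 5000,
                                pore_min_compactness = 0.12,
                                pore_min_solidity = 0.4,
                                vessel_scales = c(2, 4),
                                vessel_threshold = 0.003,
                                vessel_elongation = 6,
                                vessel_width_cv = 0.4,
                                vessel_elongation_hard = 12,
                                vessel_min_length_px = 8,
                                quality_filter = NULL) {
  structure(as.list(environment()), class = "vped_seg_config")
}

#' In-focus region mask
#'
#' Thresholds a local sharpness statistic — the sliding-window variance of
#' the Laplacian response — at a fraction of the image's robust noise-level
#' Laplacian variance (so regions carrying only sharp sensor texture still
#' count as in focus, while defocused regions, whose high-frequency content
#' is suppressed, fall below), then cleans the mask by morphological
#' opening. A fully blurred or constant image yields an empty mask (not an
#' error).
#'
#' @param image Numeric intensity matrix (rows = y).
#' @param config A [segmentation_config()].
#' @return Logical matrix of in-focus pixels.
#' @export
focus_mask <- function(image, config = segmentation_config()) {
  lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- ebi_filter(image, lap_k)
  w <- config$focus_window
  box <- matrix(1 / w^2, w, w)
  mu <- ebi_filter(lap, box)
  v <- pmax(ebi_filter(lap^2, box) - mu^2, 0)
  noise_var <- (1.4826 * stats::mad(as.vector(lap)))^2
  thr <- max(config$focus_min_var, config$focus_rel * noise_var)
  mask <- v > thr
  # close small holes, then open small specks; replicate-pad first so the
  # structuring element neither erodes nor invents mask at the border
  pad <- 5L
  ri <- pmin(pmax(seq_len(nrow(mask) + 2L * pad) - pad, 1L), nrow(mask))
  ci <- pmin(pmax(seq_len(ncol(mask) + 2L * pad) - pad, 1L), ncol(mask))
  padded <- mask[ri, ci, drop = FALSE]
  brush <- EBImage::makeBrush(9, "disc")
  cleaned <- EBImage::opening(EBImage::closing(EBImage::Image(padded * 1),
                                               brush), brush)
  as.matrix(cleaned)[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] > 0.5
}

ebi_filter <- function(img, kernel) {
  as.matrix(EBImage::filter2(EBImage::Image(img), kernel, boundary = "replicate"))
}

# Shared candidate segmentation and pore/vessel component classification.
#
# Dark components come from the union of an adaptive local-mean threshold
# and a global threshold below the median background (the global one catches
# the interior of blobs larger than the adaptive window). Each component is
# classified by shape: vessels are elongated (feret^2/area large) bands of
# near-constant local width along their skeleton that also carry a
# multiscale ridge-filter response; everything else is a pore candidate.
segment_candidates <- function(image, mask, config) {
  inv <- max(image) - image
  adaptive <- as.matrix(EBImage::thresh(EBImage::Image(inv),
                                        w = config$thresh_window,
                                        h = config$thresh_window,
                                        offset = config$thresh_offset)) > 0.5
  bg <- stats::median(image[mask])
  global <- image < (bg - config$global_offset)
  cand <- (adaptive | global) & mask
  cand <- as.matrix(EBImage::fillHull(EBImage::Image(cand * 1))) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  labm <- as.matrix(lab)
  n <- max(labm)
  if (n == 0) {
    return(list(n = 0L, cand = cand, labm = labm))
  }
  dm <- as.matrix(EBImage::distmap(EBImage::Image(cand * 1)))
  ridge <- matrix(0, nrow(image), ncol(image))
  for (s in config$vessel_scales) {
    g <- ebi_blur(inv, s)
    ridge <- pmax(ridge, s^2 * ridge_response(g))
  }
  contours <- EBImage::ocontour(lab)
  comps <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- which(labm == i, arr.ind = TRUE)
    # skeleton on the cropped bounding box (cheap per component)
    r0 <- min(idx[, 1]) - 1L; c0 <- min(idx[, 2]) - 1L
    crop <- matrix(FALSE, max(idx[, 1]) - r0 + 1L, max(idx[, 2]) - c0 + 1L)
    crop[cbind(idx[, 1] - r0, idx[, 2] - c0)] <- TRUE
    skm <- zhang_suen(crop)
    sk <- which(skm, arr.ind = TRUE)
    sk_global <- cbind(sk[, 1] + r0, sk[, 2] + c0)
    widths <- dm[sk_global]
    cv <- if (nrow(sk_global) >= 4L) {
      stats::sd(widths) / max(mean(widths), .Machine$double.eps)
    } else NA_real_
    # feret from the contour (attained on the hull, a subset of the contour)
    elong <- max_feret(contours[[i]])^2 / nrow(idx)
    is_vessel <- nrow(idx) >= config$vessel_min_length_px &&
      mean(ridge[idx]) > config$vessel_threshold &&
      ((is.finite(cv) && cv < config$vessel_width_cv &&
          elong >= config$vessel_elongation) ||
         elong >= config$vessel_elongation_hard)
    comps[[i]] <- list(idx = idx, contour = contours[[i]],
                       skeleton = sk_global, skeleton_crop = skm,
                       crop_origin = c(r0, c0), elong = elong, cv = cv,
                       class = if (is_vessel) "vessel" else "pore")
  }
  list(n = n, cand = cand, labm = labm, dm = dm, comps = comps)
}

#' Detect pores (gland outlets) on one image
#'
#' Dark blob-like regions inside the focus mask: the inverted image is
#' thresholded both adaptively (local mean + offset) and globally (median
#' background minus offset; catches the interiors of blobs larger than the
#' adaptive window), the union is hole-filled, connected components are
#' labelled, shape-classified against the vessel channel, and their outer
#' contours extracted; candidates are filtered by area, compactness and
#' solidity bounds. Merged pore candidates are kept as single detections.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical focus mask from [focus_mask()].
#' @param config A [segmentation_config()].
#' @param candidates Optional precomputed result of the internal candidate
#'   segmentation (used by [segment_image()] to avoid recomputation).
#' @return List of pore detections: each a list with `kind = "pore"`,
#'   `polygon` (n x 2 boundary, pixel coords, x right / y down), `area_px`,
#'   `area_px_corrected` (half-pixel boundary-corrected area), `centroid`
#'   (px) and `quality`.
#' @export
detect_pores <- function(image, mask = focus_mask(image, config),
                         config = segmentation_config(), candidates = NULL) {
  if (!any(mask)) return(list())
  sc <- candidates %||% segment_candidates(image, mask, config)
  if (sc$n == 0) return(list())
  grad <- image_gradient_mag(image)
  out <- list()
  for (comp in sc$comps) {
    if (comp$class != "pore") next
    area_px <- nrow(comp$idx)
    if (area_px < config$pore_min_area_px || area_px > config$pore_max_area_px) next
    oc <- comp$contour
    # ocontour is 0-based (row, col); convert to (x, y) pixel-centre coords
    poly <- cbind(oc[, 2] + 0.5, oc[, 1] + 0.5)
    if (nrow(poly) < 8L) {
      poly <- densify_contour(poly)
      if (nrow(poly) < 8L) next
    }
    feret <- max_feret(poly)
    if (feret > 0 && area_px / feret^2 < config$pore_min_compactness) next
    hull <- poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
    hull_area <- polygon_area(hull)
    if (hull_area > 0 && area_px / hull_area < config$pore_min_solidity) next
    quality <- min(1, mean(grad[oc + 1L]) / 0.2)
    if (!is.null(config$quality_filter) && quality < config$quality_filter) next
    # the true boundary lies between the outer-pixel-centre contour
    # (underestimates) and the full pixel count (overestimates); their mean
    # is close to unbiased
    area_corr <- (area_px + polygon_area(poly)) / 2
    out[[length(out) + 1L]] <- list(
      kind = "pore", polygon = poly, area_px = area_px,
      area_px_corrected = area_corr,
      centroid = c(mean(comp$idx[, 2]) - 0.5, mean(comp$idx[, 1]) - 0.5),
      quality = quality
    )
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# subdivide a short contour so downstream morphometry has >= 8 vertices
densify_contour <- function(poly) {
  closed <- rbind(poly, poly[1, , drop = FALSE])
  mid <- (closed[-1, , drop = FALSE] + closed[-nrow(closed), , drop = FALSE]) / 2
  out <- matrix(0, nrow = 2 * nrow(poly), ncol = 2)
  out[seq(1, nrow(out), 2), ] <- poly
  out[seq(2, nrow(out), 2), ] <- mid
  out
}

image_gradient_mag <- function(image) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3) / 4
  gx <- ebi_filter(image, kx)
  gy <- ebi_filter(image, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Detect blood vessels on one image
#'
#' Curvilinear structures are enhanced with a multiscale ridge (tubeness)
#' filter built from the Hessian of the Gaussian-smoothed inverted image,
#' thresholded, skeletonized (Zhang-Suen thinning), and the skeleton is split
#' at branch points into segments. Per-point local width is `2 x` the
#' distance-transform value of the vessel mask at the centerline.
#'
#' @inheritParams detect_pores
#' @return List of vessel detections: each a list with `kind = "vessel"`,
#'   `centerline` (ordered n x 2 polyline, pixel coords), `widths` (px) and
#'   `quality`. The binary vessel mask is attached as attribute `"mask"`.
#' @export
detect_vessels <- function(image, mask = focus_mask(image, config),
                           config = segmentation_config(), candidates = NULL) {
  empty_mask <- matrix(FALSE, nrow(image), ncol(image))
  if (!any(mask)) return(structure(list(), mask = empty_mask))
  sc <- candidates %||% segment_candidates(image, mask, config)
  if (sc$n == 0) return(structure(list(), mask = empty_mask))
  vm <- empty_mask
  out <- list()
  for (comp in sc$comps) {
    if (comp$class != "vessel") next
    vm[comp$idx] <- TRUE
    # split the component skeleton at branch points, trace each piece
    segs <- split_skeleton(comp$skeleton_crop)
    for (seg in segs) {
      if (nrow(seg) < 2L) next
      # crop (x, y) -> global (x, y)
      seg <- cbind(seg[, 1] + comp$crop_origin[2], seg[, 2] + comp$crop_origin[1])
      if (polyline_length(seg) < config$vessel_min_length_px) next
      widths <- 2 * sc$dm[cbind(round(seg[, 2] + 0.5), round(seg[, 1] + 0.5))]
      widths <- pmax(widths, 1)
      out[[length(out) + 1L]] <- list(
        kind = "vessel", centerline = seg, widths = widths, quality = 1
      )
    }
  }
  structure(out, mask = vm)
}

# negative-curvature ridge response: -lambda_min of the Hessian, clipped at 0
ridge_response <- function(g) {
  dxx <- ebi_filter(g, matrix(c(1, -2, 1), 1, 3))
  dyy <- ebi_filter(g, matrix(c(1, -2, 1), 3, 1))
  dxy <- ebi_filter(g, matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3) / 4)
  tr <- dxx + dyy
  det <- dxx * dyy - dxy^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  lmin <- tr / 2 - disc
  pmax(-lmin, 0)
}

# Zhang-Suen binary thinning, vectorized over whole-matrix shifts
zhang_suen <- function(mask) {
  m <- mask
  pad <- function(x) {
    out <- matrix(FALSE, nrow(x) + 2L, ncol(x) + 2L)
    out[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      ctr <- p[2:(nr + 1L), 2:(nc + 1L)]
      p2 <- p[1:nr, 2:(nc + 1L)]        # north
      p3 <- p[1:nr, 3:(nc + 2L)]        # north-east
      p4 <- p[2:(nr + 1L), 3:(nc + 2L)] # east
      p5 <- p[3:(nr + 2L), 3:(nc + 2L)] # south-east
      p6 <- p[3:(nr + 2L), 2:(nc + 1L)] # south
      p7 <- p[3:(nr + 2L), 1:nc]        # south-west
      p8 <- p[2:(nr + 1L), 1:nc]        # west
      p9 <- p[1:nr, 1:nc]               # north-west
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (step == 1) {
        cond <- ctr & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- ctr & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# split a skeleton at branch points and trace each piece into an ordered
# polyline of (x, y) pixel coordinates
# Split a skeleton mask into simple-path segments. The skeleton pixels are
# turned into a graph: 4-adjacent pixels are connected, and diagonal
# neighbours only when no shared 4-neighbour pixel provides the connection
# (this collapses the staircase patterns thinning leaves along diagonals).
# Nodes of degree >= 3 are branch points; removing them (and their incident
# edges) leaves the segments between splits.
split_skeleton <- function(skel) {
  idx <- which(skel, arr.ind = TRUE) # (row, col)
  n <- nrow(idx)
  if (n < 2L) return(list())
  key <- idx[, 1] * 1e5 + idx[, 2]
  lookup <- stats::setNames(seq_len(n), key)
  has <- function(r, c) !is.na(lookup[as.character(r * 1e5 + c)])
  nbrs <- vector("list", n)
  offs4 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  offsd <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (i in seq_len(n)) {
    r <- idx[i, 1]; c <- idx[i, 2]
    nb <- integer(0)
    for (k in 1:4) {
      j <- lookup[as.character((r + offs4[k, 1]) * 1e5 + (c + offs4[k, 2]))]
      if (!is.na(j)) nb <- c(nb, j)
    }
    for (k in 1:4) {
      rr <- r + offsd[k, 1]; cc <- c + offsd[k, 2]
      j <- lookup[as.character(rr * 1e5 + cc)]
      if (is.na(j)) next
      # drop the diagonal edge when a shared 4-neighbour carries the path
      if (has(r, cc) || has(rr, c)) next
      nb <- c(nb, j)
    }
    nbrs[[i]] <- nb
  }
  degree <- lengths(nbrs)
  keep <- degree <= 2L
  out <- list()
  visited <- !keep
  for (s in seq_len(n)) {
    if (visited[s]) next
    # collect this component (path) by BFS over kept nodes
    comp <- integer(0)
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in nbrs[[v]]) {
        if (!visited[w] && keep[w]) {
          visited[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    if (length(comp) < 2L) next
    # order the path from an endpoint
    sub <- nbrs[comp]
    sub <- lapply(sub, function(v) v[v %in% comp])
    deg <- lengths(sub)
    local_id <- stats::setNames(seq_along(comp), comp)
    start <- if (any(deg == 1L)) which(deg == 1L)[1] else 1L
    order_ <- integer(length(comp))
    used <- rep(FALSE, length(comp))
    cur <- start
    for (k in seq_along(comp)) {
      order_[k] <- cur
      used[cur] <- TRUE
      nxt <- local_id[as.character(sub[[cur]])]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) {
        order_ <- order_[1:k]
        break
      }
      cur <- nxt[[1]]
    }
    pix <- idx[comp[order_], , drop = FALSE]
    out[[length(out) + 1L]] <- cbind(pix[, 2] - 0.5, pix[, 1] - 0.5)
  }
  out
}

#' Segment one tissue image end to end
#'
#' Runs [focus_mask()], [detect_pores()] and [detect_vessels()] and converts
#' detections to physical-unit features.
#'
#' @param image Numeric intensity matrix.
#' @param pixel_size_um µm per pixel.
#' @param magnification Magnification tag ("2X"/"4X").
#' @param image_id,specimen_id Identifiers carried into the feature table.
#' @param config A [segmentation_config()].
#' @return List of class `vped_image_result`: `detections`, `features`
#'   (tibble, one row per element), `analyzed_area_um2`, `mask`.
#' @export
segment_image <- function(image, pixel_size_um, magnification = "4X",
                          image_id = "img", specimen_id = "spec",
                          config = segmentation_config()) {
  mask <- focus_mask(image, config)
  cands <- if (any(mask)) segment_candidates(image, mask, config) else NULL
  vessels <- detect_vessels(image, mask, config, candidates = cands)
  pores <- detect_pores(image, mask, config, candidates = cands)
  pf <- purrr::map_dfr(pores, function(d) {
    f <- tryCatch(pore_features(d$polygon, pixel_size_um,
                                check_simple = FALSE),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    # use the boundary-corrected digital area rather than the raw contour
    # shoelace (which undercuts the boundary pixels' outer halves)
    f$area <- d$area_px_corrected * pixel_size_um^2
    f$equiv_radius <- sqrt(f$area / pi)
    dplyr::mutate(f, kind = "pore", quality = d$quality, .before = 1)
  })
  vf <- purrr::map_dfr(vessels, function(d) {
    f <- vessel_features(d$centerline, d$widths, pixel_size_um)
    dplyr::mutate(f, kind = "vessel", quality = d$quality, .before = 1)
  })
  features <- dplyr::bind_rows(pf, vf)
  if (nrow(features) > 0) {
    features <- dplyr::mutate(features, specimen = specimen_id,
                              image = image_id,
                              magnification = magnification, .before = 1)
  }
  structure(
    list(detections = c(pores, vessels), features = features,
         analyzed_area_um2 = sum(mask) * pixel_size_um^2, mask = mask,
         specimen = specimen_id, image = image_id,
         magnification = magnification),
    class = "vped_image_result"
  )
}

#' Collate per-image segmentations into a specimen ensemble
#'
#' Concatenates the detections of all images of one specimen, keeping 2X and
#' 4X magnification sets as separate partitions, and accumulates the
#' analyzed (in-focus) area per magnification.
#'
#' @param results List of `vped_image_result` objects sharing one specimen
#'   identifier.
#' @return Object of class `vped_ensemble`: `specimen`, `elements` (tibble),
#'   `analyzed_area` (tibble per magnification), `n_images`.
#' @export
collate_specimen <- function(results) {
  stopifnot(length(results) >= 0)
  if (length(results) == 0L) {
    return(structure(list(specimen = NA_character_,
                          elements = tibble::tibble(),
                          analyzed_area = tibble::tibble(
                            magnification = character(), area_um2 = numeric()),
                          n_images = 0L),
                     class = "vped_ensemble"))
  }
  specs <- unique(vapply(results, function(r) r$specimen, character(1)))
  if (length(specs) > 1L) {
    stop("mixed specimen identifiers: ", paste(specs, collapse = ", "),
         call. = FALSE)
  }
  elements <- purrr::map_dfr(results, "features")
  areas <- purrr::map_dfr(results, function(r) {
    tibble::tibble(magnification = r$magnification,
                   area_um2 = r$analyzed_area_um2)
  })
  areas <- dplyr::summarise(dplyr::group_by(areas, .data$magnification),
                            area_um2 = sum(.data$area_um2), .groups = "drop")
  structure(
    list(specimen = specs, elements = elements, analyzed_area = areas,
         n_images = length(results)),
    class = "vped_ensemble"
  )
}

#' Serialize one image's detections to JSON
#'
#' Pore boundary polygons and vessel centerlines/widths in pixel
#' coordinates, with the image metadata embedded.
#'
#' @param result A [segment_image()] result.
#' @param path Output JSON path.
#' @export
write_detections <- function(result, path) {
  stopifnot(inherits(result, "vped_image_result"))
  det <- purrr::map(result$detections, function(d) {
    if (d$kind == "pore") {
      list(kind = "pore", polygon = unname(d$polygon),
           area_px = d$area_px, quality = d$quality)
    } else {
      list(kind = "vessel", centerline = unname(d$centerline),
           widths = d$widths, quality = d$quality)
    }
  })
  jsonlite::write_json(
    list(specimen = result$specimen, image = result$image,
         magnification = result$magnification,
         analyzed_area_um2 = result$analyzed_area_um2, detections = det),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
print.vped_ensemble <- function(x, ...) {
  cat("<vped_ensemble> specimen", x$specimen, "-", x$n_images, "image(s),",
      nrow(x$elements), "elements\n")
  invisible(x)
}
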