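# shared fixtures and independent oracles

circle_polygon <- function(r = 10, n = 64, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_polygon <- function(a, b, n = 64, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}

star_polygon <- function(r_out = 10, r_in = 7, points = 16) {
  th <- seq(0, 2 * pi, length.out = 2 * points + 1)[-(2 * points + 1)]
  r <- rep(c(r_out, r_in), points)
  cbind(r * cos(th), r * sin(th))
}

# brute-force two-sample KS statistic by direct counting at every union
# support point (independent of the package's weighted-ECDF machinery)
ks_brute <- function(a, b) {
  support <- sort(unique(c(a, b)))
  max(abs(vapply(support, function(t) mean(a <= t) - mean(b <= t),
                 numeric(1))))
}

# greedy centroid matching of pore detections against scene truth;
# a match requires centroids within `tol` micrometres
match_pores <- function(scene, detections, pixel_size_um, tol = 5) {
  truth_c <- t(vapply(scene$truth$pores, colMeans, numeric(2)))
  pores <- detections[vapply(detections, function(d) d$kind, "") == "pore"]
  if (length(pores) == 0) {
    return(list(tp = 0, n_truth = nrow(truth_c), n_det = 0, pairs = NULL))
  }
  det_c <- t(vapply(pores, function(d) d$centroid * pixel_size_um,
                    numeric(2)))
  D <- outer(seq_len(nrow(truth_c)), seq_len(nrow(det_c)),
             Vectorize(function(i, j) sqrt(sum((truth_c[i, ] - det_c[j, ])^2))))
  mt <- rep(FALSE, nrow(truth_c)); md <- rep(FALSE, nrow(det_c))
  pairs <- NULL
  for (k in order(D)) {
    if (D[k] > tol) break
    i <- (k - 1) %% nrow(truth_c) + 1
    j <- (k - 1) %/% nrow(truth_c) + 1
    if (!mt[i] && !md[j]) {
      mt[i] <- md[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  list(tp = sum(mt), n_truth = nrow(truth_c), n_det = nrow(det_c),
       pairs = pairs, pores = pores)
}

# benchmark scene used across segmentation tests: day-21 sample with
# 50 pores and 10 vessels at default contrast
benchmark_scene <- function(seed, n_pores = 50, n_vessels = 10, day = 21) {
  fs <- dplyr::bind_rows(
    dplyr::filter(sample_features(day, n_pores, seed = seed * 13 + 1),
                  kind == "pore"),
    dplyr::filter(sample_features(day, n_vessels, seed = seed * 13 + 2),
                  kind == "vessel")
  )
  render_image(fs, image_spec(), seed = seed * 13 + 3)
}

# small labelled cohort + dictionary for dating tests (built once per run)
shared_dict <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(42, noise = cohort_noise_zero(), seed = 101,
                            elements_per_sample = 1000)
      labels <- dplyr::transmute(co$patients, patient, day = true_day)
      cache <<- build_dictionary(co$features, labels,
                                 feature_set = pore_feature_names())
    }
    cache
  }
})
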