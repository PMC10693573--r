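#' Build a cycle-day dictionary from labelled feature tables
#'
#' For every (day, feature) pair, pools the per-patient empirical
#' distributions of all patients labelled with that day into one reference
#' distribution (weighted by each patient's effective element count). Day
#' labels are histology-based in the clinical workflow but any label source
#' is accepted. Days in the requested range with no patients are flagged
#' missing and excluded.
#'
#' @param features Long tibble with columns `patient`, `feature`, `value`.
#' @param labels Tibble with columns `patient`, `day` (integer labels).
#' @param feature_set Features to include; default all features present.
#' @param days Candidate day range; default the labels' range.
#' @param n_bins Bins for the shared per-feature histogram axes.
#' @param magnification Optional magnification tag stored on the dictionary.
#' @return A `vped_dictionary`: tibble with columns `day`, `feature`, `dist`
#'   (list of pooled [empirical_distribution()]s), `n_eff`, `n_patients`;
#'   attributes `days`, `missing_days`, `features`, `magnification`.
#' @export
build_dictionary <- function(features, labels,
                             feature_set = NULL, days = NULL,
                             n_bins = 24, magnification = NA_character_) {
  stopifnot(all(c("patient", "feature", "value") %in% names(features)))
  stopifnot(all(c("patient", "day") %in% names(labels)))
  if (nrow(features) == 0L) stop("empty cohort", call. = FALSE)
  feature_set <- feature_set %||% sort(unique(features$feature))
  tbl <- dplyr::inner_join(
    dplyr::filter(features, .data$feature %in% feature_set),
    dplyr::select(labels, "patient", "day"), by = "patient"
  )
  if (nrow(tbl) == 0L) stop("no labelled features", call. = FALSE)
  days <- days %||% seq(min(tbl$day), max(tbl$day))
  # shared bin edges per feature spanning [min, q99] of the pooled data
  edges <- purrr::map(stats::setNames(feature_set, feature_set), function(f) {
    v <- tbl$value[tbl$feature == f]
    lo <- min(v); hi <- stats::quantile(v, 0.99, names = FALSE)
    if (hi <= lo) hi <- lo + 1
    seq(lo, hi, length.out = n_bins + 1)
  })
  entries <- tidyr::expand_grid(day = days, feature = feature_set)
  entries <- purrr::pmap_dfr(entries, function(day, feature) {
    sub <- tbl[tbl$day == day & tbl$feature == feature, ]
    if (nrow(sub) == 0L) {
      return(tibble::tibble(day = day, feature = feature,
                            dist = list(NULL), n_eff = 0,
                            n_patients = 0L))
    }
    per_patient <- purrr::map(split(sub$value, sub$patient),
                              empirical_distribution,
                              edges = edges[[feature]], feature = feature)
    pooled <- pool_day_distribution(per_patient, edges = edges[[feature]])
    tibble::tibble(day = day, feature = feature, dist = list(pooled),
                   n_eff = pooled$n_eff,
                   n_patients = length(per_patient))
  })
  missing <- sort(unique(entries$day[entries$n_patients == 0L]))
  entries <- entries[!entries$day %in% missing, ]
  if (nrow(entries) == 0L) stop("no day has any labelled sample", call. = FALSE)
  structure(entries,
            class = c("vped_dictionary", class(entries)),
            days = sort(unique(entries$day)), missing_days = missing,
            features = feature_set, magnification = magnification)
}

#' @export
print.vped_dictionary <- function(x, ...) {
  cat("<vped_dictionary> days ", paste(range(attr(x, "days")), collapse = "-"),
      " (", length(attr(x, "days")), " days), features: ",
      paste(attr(x, "features"), collapse = ", "), "\n", sep = "")
  if (length(attr(x, "missing_days"))) {
    cat("  missing days:", paste(attr(x, "missing_days"), collapse = ", "), "\n")
  }
  invisible(x)
}

dictionary_dist <- function(dictionary, day, feature) {
  i <- which(dictionary$day == day & dictionary$feature == feature)
  if (length(i) != 1L) {
    stop("dictionary has no entry for day ", day, ", feature ", feature,
         call. = FALSE)
  }
  dictionary$dist[[i]]
}

#' Score one sample against every dictionary day
#'
#' For each candidate day, each feature's sample distribution is compared to
#' the day's pooled reference by the two-sample KS test, and the per-feature
#' p-values are combined with equal weights — the arithmetic mean by default,
#' or the geometric mean (`combine = "geometric"`). The profile is
#' unnormalized at this stage.
#'
#' @param sample Long tibble (`feature`, `value`) or a named list of
#'   [empirical_distribution()]s.
#' @param dictionary A [build_dictionary()] result.
#' @param feature_set Features entering the score; defaults to the four pore
#'   features when present, otherwise all dictionary features.
#' @param combine `"arithmetic"` (default) or `"geometric"`.
#' @return A `vped_profile`: tibble (`day`, `score`), attributes
#'   `normalized = FALSE`, `windowed = FALSE`.
#' @export
score_sample <- function(sample, dictionary, feature_set = NULL,
                         combine = c("arithmetic", "geometric")) {
  combine <- match.arg(combine)
  dict_features <- attr(dictionary, "features")
  feature_set <- feature_set %||% {
    pf <- intersect(pore_feature_names(), dict_features)
    if (length(pf)) pf else dict_features
  }
  if (is.data.frame(sample)) {
    sample <- purrr::map(stats::setNames(feature_set, feature_set),
                         function(f) {
                           v <- sample$value[sample$feature == f]
                           if (length(v) == 0L) NULL
                           else empirical_distribution(v, feature = f)
                         })
  }
  missing <- feature_set[vapply(sample[feature_set], is.null, logical(1))]
  if (length(missing)) {
    stop("sample is missing features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  days <- attr(dictionary, "days")
  scores <- vapply(days, function(d) {
    p <- vapply(feature_set, function(f) {
      ks_two_sample(sample[[f]], dictionary_dist(dictionary, d, f))$p_value
    }, numeric(1))
    if (combine == "arithmetic") mean(p) else exp(mean(log(pmax(p, 1e-300))))
  }, numeric(1))
  new_profile(days, scores, normalized = FALSE, windowed = FALSE)
}

new_profile <- function(days, scores, normalized, windowed) {
  out <- tibble::tibble(day = days, score = scores)
  structure(out, class = c("vped_profile", class(out)),
            normalized = normalized, windowed = windowed)
}

#' Smooth a day-probability profile with a top-hat window
#'
#' Convolves the per-day scores with a uniform (boxcar) window of odd width,
#' encoding the prior that neighbouring cycle days resemble each other, then
#' normalizes the profile to sum to one. At the range boundaries the window
#' is truncated; with the default `edge = "sum"` the truncated window is a
#' plain convolution (an interior delta becomes a plateau of `width` equal
#' values, an edge delta a shorter plateau), while `edge = "mean"`
#' renormalizes by the actual window size (which preserves a uniform
#' profile exactly but biases near-edge peaks outward).
#'
#' @param profile A `vped_profile`.
#' @param width Odd window width in days (default 5).
#' @param edge `"sum"` (default) or `"mean"` boundary handling.
#' @return A normalized, windowed `vped_profile`.
#' @export
tophat_convolve <- function(profile, width = 5L, edge = c("sum", "mean")) {
  edge <- match.arg(edge)
  stopifnot(inherits(profile, "vped_profile"))
  if (width %% 2L != 1L) stop("top-hat width must be odd, got ", width,
                              call. = FALSE)
  h <- (width - 1L) %/% 2L
  n <- nrow(profile)
  sc <- profile$score
  out <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    if (edge == "sum") sum(sc[j]) else mean(sc[j])
  }, numeric(1))
  if (sum(out) > 0) out <- out / sum(out)
  new_profile(profile$day, out, normalized = TRUE, windowed = TRUE)
}

#' Infer the cycle day from a day-probability profile
#'
#' The inferred day is the argmax of the (typically windowed) profile; exact
#' ties are broken deterministically by the score-weighted centroid of the
#' maximal plateau, rounded to the nearest day. The ± day error is attached
#' from [day_error_estimate()] when a confusion matrix is supplied.
#'
#' @param profile A `vped_profile`.
#' @param confusion Optional [day_confusion_matrix()] result for the error
#'   bars.
#' @param method Method tag stored on the estimate.
#' @return A `vped_estimate`: one-row tibble with `day`, `err_lo`, `err_hi`,
#'   `method`, plus the profile as attribute.
#' @export
infer_day <- function(profile, confusion = NULL, method = "vped") {
  stopifnot(inherits(profile, "vped_profile"))
  if (all(profile$score <= 0)) {
    stop("unclassifiable: all day scores are zero", call. = FALSE)
  }
  m <- max(profile$score)
  at_max <- which(profile$score >= m * (1 - 1e-12))
  day <- if (length(at_max) == 1L) {
    profile$day[at_max]
  } else {
    # contiguous maximal plateau around the first maximal run
    runs <- split(at_max, cumsum(c(1, diff(at_max) != 1)))
    plateau <- runs[[which.max(vapply(runs, length, integer(1)))]]
    round(stats::weighted.mean(profile$day[plateau],
                               profile$score[plateau]))
  }
  err <- c(NA_real_, NA_real_)
  if (!is.null(confusion)) {
    e <- day_error_estimate(confusion, day)
    err <- c(e$err_lo, e$err_hi)
  }
  out <- tibble::tibble(day = day, err_lo = err[1], err_hi = err[2],
                        method = method)
  structure(out, class = c("vped_estimate", class(out)), profile = profile)
}

#' Pairwise KS comparison of dictionary days (confusion matrix)
#'
#' `M[i, j]` is the equal-weight mean over features of the two-sample KS
#' p-value between the pooled distributions of day i and day j (diagonal 1
#' by construction, symmetric). The matrix is then smoothed with a 3x3 2D
#' Gaussian kernel (edge-renormalized) and each row is scaled to maximum 1,
#' giving the relative probability of assessing day j when the truth is
#' day i.
#'
#' @param dictionary A `vped_dictionary` with at least two days.
#' @param feature_set Features to combine; defaults as in [score_sample()].
#' @return A `vped_confusion`: list with `raw`, `smoothed`, `relative`
#'   matrices (day labels as dimnames) and `days`.
#' @export
day_confusion_matrix <- function(dictionary, feature_set = NULL) {
  days <- attr(dictionary, "days")
  if (length(days) < 2L) stop("need >= 2 dictionary days", call. = FALSE)
  dict_features <- attr(dictionary, "features")
  feature_set <- feature_set %||% {
    pf <- intersect(pore_feature_names(), dict_features)
    if (length(pf)) pf else dict_features
  }
  n <- length(days)
  raw <- matrix(1, n, n, dimnames = list(days, days))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- mean(vapply(feature_set, function(f) {
        ks_two_sample(dictionary_dist(dictionary, days[i], f),
                      dictionary_dist(dictionary, days[j], f))$p_value
      }, numeric(1)))
      raw[i, j] <- p
      raw[j, i] <- p
    }
  }
  sm <- gaussian_smooth_3x3(raw)
  rel <- sm / apply(sm, 1, max)
  structure(list(raw = raw, smoothed = sm, relative = rel, days = days),
            class = "vped_confusion")
}

# 3x3 Gaussian kernel smoothing with edge renormalization
gaussian_smooth_3x3 <- function(m) {
  k <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p, dimnames = dimnames(m))
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      ii <- max(1, i - 1):min(n, i + 1)
      jj <- max(1, j - 1):min(p, j + 1)
      kk <- k[ii - i + 2, jj - j + 2, drop = FALSE]
      out[i, j] <- sum(m[ii, jj] * kk) / sum(kk)
    }
  }
  out
}

#' Per-day dating error from the confusion matrix
#'
#' The half-width, in days toward each side, of the contiguous region around
#' the diagonal where the row-relative probability stays at or above 0.5.
#'
#' @param confusion A [day_confusion_matrix()] result.
#' @param day Day whose error is requested.
#' @param level Relative-probability threshold (default 0.5).
#' @return One-row tibble `day`, `err_lo`, `err_hi`.
#' @export
day_error_estimate <- function(confusion, day, level = 0.5) {
  stopifnot(inherits(confusion, "vped_confusion"))
  days <- confusion$days
  i <- match(day, days)
  if (is.na(i)) stop("day ", day, " not in confusion matrix", call. = FALSE)
  row <- confusion$relative[i, ]
  lo <- 0L
  while (i - lo - 1L >= 1L && row[i - lo - 1L] >= level) lo <- lo + 1L
  hi <- 0L
  while (i + hi + 1L <= length(days) && row[i + hi + 1L] >= level) hi <- hi + 1L
  tibble::tibble(day = day, err_lo = lo, err_hi = hi)
}

#' @export
autoplot.vped_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$day, .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cycle day",
                  y = if (isTRUE(attr(object, "normalized"))) {
                    "probability"
                  } else "mean KS p-value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vped_confusion <- function(object, ...) {
  df <- tidyr::expand_grid(truth = object$days, assessed = object$days)
  df$value <- as.vector(t(object$relative))
  ggplot2::ggplot(df, ggplot2::aes(.data$assessed, .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c("relative\nprobability") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "assessed day", y = "true (label) day") +
    ggplot2::theme_minimal()
}

#' Date one sample end to end
#'
#' Convenience wrapper: score against the dictionary, apply the top-hat
#' window, infer the day with errors from the dictionary's confusion matrix.
#'
#' @inheritParams score_sample
#' @param window Top-hat window width (odd; `NULL` skips windowing).
#' @param confusion Optional precomputed [day_confusion_matrix()].
#' @return A `vped_estimate`.
#' @export
vped_date <- function(sample, dictionary, feature_set = NULL, window = 5L,
                      confusion = NULL) {
  prof <- score_sample(sample, dictionary, feature_set)
  if (!is.null(window)) prof <- tophat_convolve(prof, window)
  infer_day(prof, confusion = confusion, method = "vped")
}

#' Serialize a dictionary to JSON
#'
#' Versioned schema holding, per (day, feature), the pooled values, weights,
#' histogram edges and heights.
#'
#' @param dictionary A `vped_dictionary`.
#' @param path Output path.
#' @export
write_dictionary <- function(dictionary, path) {
  entries <- purrr::pmap(dictionary, function(day, feature, dist, n_eff,
                                              n_patients) {
    list(day = day, feature = feature, n_eff = n_eff,
         n_patients = n_patients, values = dist$values,
         weights = dist$weights, edges = dist$edges, heights = dist$heights)
  })
  obj <- list(schema = "vped_dictionary/1",
              days = attr(dictionary, "days"),
              missing_days = attr(dictionary, "missing_days"),
              features = attr(dictionary, "features"),
              magnification = attr(dictionary, "magnification"),
              entries = entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dictionary written by [write_dictionary()]
#'
#' @param path JSON path.
#' @return A `vped_dictionary`.
#' @export
read_dictionary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$schema, "vped_dictionary/1"))
  entries <- purrr::pmap_dfr(obj$entries, function(day, feature, n_eff,
                                                   n_patients, values,
                                                   weights, edges, heights) {
    d <- empirical_distribution(values, weights, edges = edges,
                                feature = feature)
    tibble::tibble(day = day, feature = feature, dist = list(d),
                   n_eff = n_eff, n_patients = n_patients)
  })
  structure(entries,
            class = c("vped_dictionary", class(entries)),
            days = obj$days,
            missing_days = as.integer(obj$missing_days),
            features = obj$features,
            magnification = obj$magnification)
}
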