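#' Build an empirical feature distribution
#'
#' Wraps one feature's (optionally weighted) sample as an empirical
#' distribution: a normalized histogram PDF on fixed bin edges plus the
#' weighted step cPDF of the raw values. Per-day reference curves use the
#' histogram's cumulative integral; sample-vs-dictionary comparisons use the
#' step cPDF.
#'
#' @param values Numeric vector, at least one finite value. Non-finite values
#'   are dropped with a message.
#' @param weights Optional non-negative weights, recycled length-1 allowed.
#' @param edges Optional histogram bin edges (strictly increasing). When
#'   omitted, 24 equal bins spanning the data range are used.
#' @param n_bins Number of bins when `edges` is omitted.
#' @param feature,unit Optional feature name and unit tags carried through
#'   pooling and serialization.
#' @return An object of class `vped_empirical`: list with `values`, `weights`
#'   (aggregated over duplicates in `cdf`), `edges`, `heights` (density,
#'   integrates to 1), `feature`, `unit`, `n_eff` (weight sum) and
#'   `n_dropped`.
#' @examples
#' d <- empirical_distribution(c(1, 2, 3))
#' emp_cdf(d)(2) # 2/3
#' @export
empirical_distribution <- function(values, weights = NULL, edges = NULL,
                                   n_bins = 24, feature = NA_character_,
                                   unit = NA_character_) {
  values <- as.numeric(values)
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) == 1L) weights <- rep(weights, length(values))
  stopifnot(length(weights) == length(values))
  if (any(weights < 0, na.rm = TRUE)) stop("weights must be >= 0", call. = FALSE)
  keep <- is.finite(values) & is.finite(weights)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped, " non-finite value(s)")
  }
  values <- values[keep]; weights <- weights[keep]
  if (length(values) == 0L || sum(weights) == 0) {
    stop("empirical distribution needs at least one finite, positively weighted value",
         call. = FALSE)
  }
  if (is.null(edges)) {
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  stopifnot(length(edges) >= 2L, all(diff(edges) > 0))
  heights <- weighted_hist_density(values, weights, edges)
  structure(
    list(values = values, weights = weights, edges = edges, heights = heights,
         feature = feature, unit = unit, n_eff = sum(weights),
         n_dropped = n_dropped),
    class = "vped_empirical"
  )
}

# density-normalized weighted histogram; values outside the edges are clamped
# into the end bins so pooled histograms on shared axes lose no mass.
weighted_hist_density <- function(values, weights, edges) {
  k <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > k] <- k
  mass <- vapply(seq_len(k), function(i) sum(weights[idx == i]), numeric(1))
  mass <- mass / sum(mass)
  mass / diff(edges)
}

#' @export
print.vped_empirical <- function(x, ...) {
  cat("<vped_empirical> ", if (!is.na(x$feature)) x$feature else "feature",
      if (!is.na(x$unit)) paste0(" [", x$unit, "]") else "",
      ": n_eff = ", signif(x$n_eff, 5),
      ", range = [", signif(min(x$values), 4), ", ", signif(max(x$values), 4),
      "], ", length(x$edges) - 1L, " bins\n", sep = "")
  invisible(x)
}

#' Step cPDF of an empirical distribution
#'
#' Right-continuous weighted empirical CDF built from the raw values.
#'
#' @param dist A `vped_empirical` object.
#' @return A function mapping numeric vectors to cumulative probabilities.
#' @export
emp_cdf <- function(dist) {
  stopifnot(inherits(dist, "vped_empirical"))
  weighted_ecdf(dist$values, dist$weights)
}

#' Histogram-integrated cPDF of an empirical distribution
#'
#' Piecewise-linear cumulative integral of the histogram PDF, the per-day
#' reference-curve construction.
#'
#' @inheritParams emp_cdf
#' @return A function mapping numeric vectors to cumulative probabilities.
#' @export
hist_cdf <- function(dist) {
  stopifnot(inherits(dist, "vped_empirical"))
  edges <- dist$edges
  cum <- c(0, cumsum(dist$heights * diff(edges)))
  cum <- cum / cum[length(cum)]
  function(x) {
    p <- stats::approx(edges, cum, xout = x, yleft = 0, yright = 1,
                       ties = "ordered")$y
    p
  }
}

weighted_ecdf <- function(values, weights) {
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  # collapse exact duplicates, keeping the final cumulative weight
  keep <- c(diff(v) > 0, TRUE)
  uv <- v[keep]
  cw <- cw[keep]
  function(x) {
    i <- findInterval(x, uv)
    out <- numeric(length(x))
    out[i > 0] <- cw[i[i > 0]]
    out
  }
}

#' Two-sample Kolmogorov-Smirnov comparison of empirical distributions
#'
#' Computes the sup distance `D` between the two weighted step cPDFs over the
#' union of their support points, and the asymptotic p-value from the
#' Kolmogorov distribution at the effective sample size
#' `n1 * n2 / (n1 + n2)`, where each `n` is the weight sum of its sample.
#'
#' @param d1,d2 `vped_empirical` objects (or numeric vectors, which are
#'   wrapped with unit weights).
#' @return One-row tibble with `statistic` (D), `p_value` and `n_eff`.
#' @examples
#' ks_two_sample(c(1, 2, 3, 4), c(3, 4, 5, 6)) # D = 0.5
#' @export
ks_two_sample <- function(d1, d2) {
  d1 <- as_empirical(d1)
  d2 <- as_empirical(d2)
  f1 <- emp_cdf(d1); f2 <- emp_cdf(d2)
  support <- sort(unique(c(d1$values, d2$values)))
  D <- max(abs(f1(support) - f2(support)))
  n1 <- d1$n_eff; n2 <- d2$n_eff
  n_eff <- n1 * n2 / (n1 + n2)
  tibble::tibble(statistic = D, p_value = ks_pvalue(D, n_eff), n_eff = n_eff)
}

as_empirical <- function(x) {
  if (inherits(x, "vped_empirical")) x else empirical_distribution(x)
}

# Asymptotic two-sided Kolmogorov survival function Q(t) = 2 sum (-1)^(k-1) exp(-2 k^2 t^2)
ks_pvalue <- function(D, n_eff) {
  t <- sqrt(n_eff) * D
  if (t < 1e-3) return(1)
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' Pool same-day empirical distributions into a cycle-day reference
#'
#' Forms the weighted average histogram of all patients sharing a cycle day:
#' each patient's normalized histogram enters with weight equal to its
#' effective element count, so a patient contributing more elements counts
#' more. The pooled step cPDF is carried as the concatenated, reweighted
#' element values (per-element weight `sample_weight * element_weight /
#' sample_weight_sum`), which reproduces the weighted-average histogram
#' exactly on the shared bins.
#'
#' @param samples List of `vped_empirical` objects sharing a feature/unit.
#' @param edges Common bin edges; default spans the pooled data in 24 bins.
#' @return A pooled `vped_empirical` on the common edges.
#' @export
pool_day_distribution <- function(samples, edges = NULL) {
  stopifnot(length(samples) >= 1L)
  stopifnot(all(vapply(samples, inherits, logical(1), "vped_empirical")))
  feats <- unique(vapply(samples, function(s) s$feature, character(1)))
  units <- unique(vapply(samples, function(s) s$unit, character(1)))
  if (length(feats) > 1L || length(units) > 1L) {
    stop("cannot pool distributions of different features/units: ",
         paste(feats, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(lapply(samples, function(s) s$values))
  wts <- unlist(lapply(samples, function(s) s$n_eff * s$weights / sum(s$weights)))
  if (is.null(edges)) {
    rng <- range(vals)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = 25)
  }
  empirical_distribution(vals, wts, edges = edges,
                         feature = feats, unit = units)
}

#' @export
tidy.vped_empirical <- function(x, ...) {
  k <- length(x$edges) - 1L
  tibble::tibble(
    bin_left = x$edges[-(k + 1L)],
    bin_right = x$edges[-1L],
    density = x$heights
  )
}

#' Plot an empirical distribution as histogram plus step cPDF
#'
#' @param object A `vped_empirical` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vped_empirical <- function(object, ...) {
  bins <- tidy(object)
  grid <- sort(unique(object$values))
  cdf <- tibble::tibble(x = grid, p = emp_cdf(object)(grid))
  scale <- max(bins$density)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = bins,
      ggplot2::aes(xmin = .data$bin_left, xmax = .data$bin_right,
                   ymin = 0, ymax = .data$density),
      fill = "grey70", colour = "grey40"
    ) +
    ggplot2::geom_step(data = cdf,
                       ggplot2::aes(x = .data$x, y = .data$p * scale),
                       colour = "steelblue") +
    ggplot2::scale_y_continuous(
      "density",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "cPDF")
    ) +
    ggplot2::labs(x = if (!is.na(object$unit)) {
      paste0(object$feature, " [", object$unit, "]")
    } else object$feature) +
    ggplot2::theme_minimal()
}
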