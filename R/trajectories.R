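#' Feature names used throughout the package
#'
#' Four pore features and two blood-vessel features; pore features are the
#' default dating feature set.
#' @export
vped_features <- function() {
  c("pore_area", "pore_length", "pore_curvature", "pore_tortuosity",
    "bv_diameter", "bv_segment_length")
}

#' @rdname vped_features
#' @export
pore_feature_names <- function() {
  c("pore_area", "pore_length", "pore_curvature", "pore_tortuosity")
}

# anchor points (day, value) splined onto the integer day grid
traj_spline <- function(days, anchor_days, anchor_vals) {
  stats::spline(anchor_days, anchor_vals, xout = days, method = "natural")$y
}

#' Default per-day Weibull parameter trajectories
#'
#' The synthetic calibration table behind the tissue generator: for every
#' feature and secretory cycle day it gives the three Weibull cPDF parameters
#' `(b, lambda, gamma)`. The table is synthetic — it encodes the qualitative
#' secretory-phase behaviour of the feature ensembles (pore-area shape
#' `gamma < 1` throughout, with a mid-phase dip as pores merge; pore-length
#' `gamma > 1` only in the peak-merger window around days 20-22; vessel
#' diameter `gamma > 1` throughout, dipping near day 19; scale parameters
#' drifting smoothly as elements grow) — not measured clinical values. The
#' per-day drift was calibrated once so that neighbouring days are
#' statistically distinguishable at a few hundred elements per feature, the
#' regime the dating pipeline is designed for.
#'
#' @param days Integer vector of supported cycle days (standard 28-day
#'   calendar). Default secretory days 15-28.
#' @return Tibble with columns `feature`, `day`, `b`, `lambda`, `gamma`.
#' @examples
#' default_trajectories()
#' @export
default_trajectories <- function(days = 15:28) {
  stopifnot(all(days == round(days)), all(diff(days) == 1))
  t <- days - 15
  specs <- list(
    pore_area = list(
      b = 20, unit = "um^2",
      lambda = 150 * 1.20^t,
      gamma = traj_spline(days, c(15, 18, 21, 25, 28), c(0.72, 0.62, 0.52, 0.82, 0.70))
    ),
    pore_length = list(
      b = 6, unit = "um",
      lambda = 18 * 1.12^t,
      gamma = traj_spline(days, c(15, 18, 19.5, 21, 22.5, 24, 28),
                          c(0.85, 0.92, 1.02, 1.30, 1.02, 0.88, 0.80))
    ),
    pore_curvature = list(
      b = 0.02, unit = "1/um",
      lambda = 0.30 * 0.90^t,
      gamma = traj_spline(days, c(15, 17, 19, 21, 23, 25, 28),
                          c(1.35, 1.50, 1.00, 0.88, 0.98, 1.20, 1.02))
    ),
    pore_tortuosity = list(
      b = 1.0, unit = "",
      lambda = 0.10 * 1.14^t,
      gamma = traj_spline(days, c(15, 18, 21, 24, 28),
                          c(1.50, 1.18, 1.00, 1.30, 1.45))
    ),
    bv_diameter = list(
      b = 4, unit = "um",
      lambda = 5 * 1.05^t,
      gamma = traj_spline(days, c(15, 17, 19, 22, 25, 28),
                          c(2.40, 2.10, 1.80, 2.10, 2.50, 2.80))
    ),
    bv_segment_length = list(
      b = 30, unit = "um",
      lambda = 160 * 1.045^t,
      gamma = traj_spline(days, c(15, 19, 23, 28), c(1.40, 1.55, 1.65, 1.70))
    )
  )
  out <- purrr::imap_dfr(specs, function(s, feat) {
    tibble::tibble(feature = feat, day = as.integer(days), b = s$b,
                   lambda = s$lambda, gamma = s$gamma, unit = s$unit)
  })
  stopifnot(all(out$lambda > 0), all(out$gamma > 0), all(out$b >= 0))
  # qualitative regime constraints baked into the default table
  area_g <- out$gamma[out$feature == "pore_area"]
  stopifnot(all(area_g < 1))
  bv_g <- out$gamma[out$feature == "bv_diameter"]
  stopifnot(all(bv_g > 1))
  out
}

#' Look up the Weibull parameters for one feature on one cycle day
#'
#' @param day Integer cycle day within the table's supported range.
#' @param feature One of [vped_features()].
#' @param table Trajectory table, default [default_trajectories()].
#' @return One-row tibble with `b`, `lambda`, `gamma` (plus `feature`, `day`,
#'   `unit`).
#' @examples
#' trajectory(18, "pore_area")
#' @export
trajectory <- function(day, feature, table = default_trajectories()) {
  if (!feature %in% unique(table$feature)) {
    stop("unknown feature '", feature, "'; valid features: ",
         paste(unique(table$feature), collapse = ", "), call. = FALSE)
  }
  rng <- range(table$day)
  if (!is.finite(day) || day != round(day) || day < rng[1] || day > rng[2]) {
    stop("day ", day, " outside supported range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  dplyr::filter(table, .data$feature == !!feature, .data$day == !!day)
}

#' Draw a synthetic per-element feature table for one cycle day
#'
#' Inverse-transform sampling from the trajectory table's Weibull cPDFs:
#' `x = b + lambda * (-ln U)^(1/gamma)`, `U ~ Uniform(0,1)`. Each element
#' kind (pore, vessel) gets `n_elements` rows; features of an element are
#' drawn independently.
#'
#' @param day Cycle day.
#' @param n_elements Elements per kind (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @param table Trajectory table.
#' @return Long tibble with columns `element`, `kind`, `feature`, `value`.
#' @examples
#' sample_features(21, 5, seed = 1)
#' @export
sample_features <- function(day, n_elements, seed = NULL,
                            table = default_trajectories()) {
  stopifnot(n_elements >= 0)
  feats <- unique(table$feature)
  if (n_elements == 0) {
    return(tibble::tibble(element = integer(), kind = character(),
                          feature = character(), value = numeric()))
  }
  with_seed(seed, {
    purrr::map_dfr(feats, function(f) {
      p <- trajectory(day, f, table)
      kind <- if (startsWith(f, "bv_")) "vessel" else "pore"
      tibble::tibble(
        element = seq_len(n_elements), kind = kind, feature = f,
        value = weibull_sample(n_elements, p$b, p$lambda, p$gamma)
      )
    })
  })
}

#' Plot parameter trajectories across the supported day range
#'
#' @param table Trajectory table from [default_trajectories()].
#' @return A ggplot object faceted by feature, one line per parameter.
#' @export
plot_trajectories <- function(table = default_trajectories()) {
  long <- tidyr::pivot_longer(table, c("lambda", "gamma"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value,
                                     colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_wrap(~ .data$feature, scales = "free_y") +
    ggplot2::labs(x = "cycle day", y = "parameter value") +
    ggplot2::theme_minimal()
}
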