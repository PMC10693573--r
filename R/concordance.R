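#' Concordance between two dating methods
#'
#' Pearson correlation of paired day estimates, the adjusted correlation
#' coefficient derived from adjusted R² (`adjR² = 1 - (1-R²)(n-1)/(n-2)`),
#' an ordinary least-squares regression of `b` on `a`, and the two-sided
#' p-value for the no-correlation null via the t-transform. Per-point errors
#' are carried into the result for plotting bands; they do not weight the
#' fit.
#'
#' @param days_a,days_b Paired day estimates, length >= 3.
#' @param errors_a,errors_b Optional per-point errors (scalars recycled).
#' @param method_a,method_b Method tags.
#' @return A one-row `vped_comparison` tibble: `method_a`, `method_b`, `n`,
#'   `r`, `r_adjusted`, `slope`, `intercept`, `p_value`; the paired data are
#'   attached as attribute `pairs`.
#' @export
correlate <- function(days_a, days_b, errors_a = NULL, errors_b = NULL,
                      method_a = "a", method_b = "b") {
  stopifnot(length(days_a) == length(days_b))
  n <- length(days_a)
  if (n < 3L) stop("need >= 3 pairs, got ", n, call. = FALSE)
  if (stats::sd(days_a) == 0 || stats::sd(days_b) == 0) {
    stop("correlation undefined: constant input vector", call. = FALSE)
  }
  r <- stats::cor(days_a, days_b)
  r2_adj <- 1 - (1 - r^2) * (n - 1) / (n - 2)
  fit <- stats::lm(days_b ~ days_a)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  out <- tibble::tibble(
    method_a = method_a, method_b = method_b, n = n,
    r = r, r_adjusted = sign(r) * sqrt(max(r2_adj, 0)),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p_value = p
  )
  pairs <- tibble::tibble(
    a = days_a, b = days_b,
    err_a = if (is.null(errors_a)) NA_real_ else errors_a,
    err_b = if (is.null(errors_b)) NA_real_ else errors_b
  )
  structure(out, class = c("vped_comparison", class(out)), pairs = pairs)
}

#' @export
glance.vped_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
autoplot.vped_comparison <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(.data$a, .data$b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$b - .data$err_b,
                                        ymax = .data$b + .data$err_b),
                           width = 0, colour = "grey70", na.rm = TRUE) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$a - .data$err_a,
                                         xmax = .data$a + .data$err_a),
                            height = 0, colour = "grey70", na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "forestgreen") +
    ggplot2::labs(
      x = object$method_a, y = object$method_b,
      subtitle = sprintf("adjusted R = %.2f (n = %d)", object$r_adjusted,
                         object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Systematic offset between two dating methods
#'
#' Mean of `a - b` with an exact binomial sign test on the sign of the
#' non-zero offsets.
#'
#' @param days_a,days_b Paired day estimates, length >= 3.
#' @return One-row tibble: `offset` (mean `a - b`), `n_nonzero`,
#'   `sign_test_p`.
#' @export
systematic_bias <- function(days_a, days_b) {
  stopifnot(length(days_a) == length(days_b), length(days_a) >= 3L)
  d <- days_a - days_b
  nz <- d[d != 0]
  p <- if (length(nz) == 0L) 1 else {
    stats::binom.test(sum(nz > 0), length(nz))$p.value
  }
  tibble::tibble(offset = mean(d), n_nonzero = length(nz), sign_test_p = p)
}

#' Cohort-level concordance report
#'
#' Collects every patient's datings into one table, computes all pairwise
#' method comparisons (for methods with >= 3 complete pairs), and the
#' pairwise systematic biases.
#'
#' @param datings Tidy tibble `patient`, `method`, `day` (optionally
#'   `err_lo`, `err_hi`), one row per patient-method.
#' @return A `vped_report`: list with `per_patient` (wide tibble),
#'   `comparisons` (tibble of pairwise [correlate()] rows), `biases`.
#' @export
cohort_report <- function(datings) {
  stopifnot(all(c("patient", "method", "day") %in% names(datings)))
  if (nrow(datings) == 0L) stop("empty cohort", call. = FALSE)
  wide <- tidyr::pivot_wider(
    dplyr::select(datings, "patient", "method", "day"),
    names_from = "method", values_from = "day"
  )
  methods <- setdiff(names(wide), "patient")
  comparisons <- NULL
  biases <- NULL
  if (length(methods) >= 2L) {
    pairs <- utils::combn(methods, 2L, simplify = FALSE)
    for (pr in pairs) {
      ok <- stats::complete.cases(wide[pr])
      if (sum(ok) < 3L) next
      a <- wide[[pr[1]]][ok]; b <- wide[[pr[2]]][ok]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      comparisons <- dplyr::bind_rows(
        comparisons,
        tibble::as_tibble(correlate(a, b, method_a = pr[1], method_b = pr[2]))
      )
      biases <- dplyr::bind_rows(
        biases,
        dplyr::mutate(systematic_bias(a, b), method_a = pr[1],
                      method_b = pr[2], .before = 1)
      )
    }
  }
  structure(list(per_patient = wide, comparisons = comparisons,
                 biases = biases),
            class = "vped_report")
}

#' @export
print.vped_report <- function(x, ...) {
  cat("<vped_report> ", nrow(x$per_patient), " patients\n", sep = "")
  if (!is.null(x$comparisons)) {
    cmp <- dplyr::mutate(x$comparisons, dplyr::across(
      c("r", "r_adjusted", "slope", "intercept"), ~ round(.x, 3)))
    print(dplyr::select(cmp, "method_a", "method_b", "n", "r", "r_adjusted",
                        "slope", "p_value"))
  }
  invisible(x)
}

#' Write a cohort report to CSV files plus a JSON summary
#'
#' @param report A [cohort_report()] result.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_patient, file.path(dir, "per_patient.csv"),
                   row.names = FALSE)
  if (!is.null(report$comparisons)) {
    utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(n_patients = nrow(report$per_patient),
         comparisons = report$comparisons, biases = report$biases),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
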