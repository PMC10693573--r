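#' Renormalize a cycle day onto the standard 28-day calendar
#'
#' Non-28-day cycles are mapped onto the standard calendar by rescaling the
#' proliferative phase to 14 days while keeping the luteal phase fixed at 14
#' days (ovulation assumed at `O = cycle_length - 14`):
#' `day' = day * 14 / O` for `day <= O`, else `day' = 14 + (day - O)`.
#' The result is rounded to two decimals, not to an integer.
#'
#' @param day Day within the patient's own cycle, `1 <= day <= cycle_length`.
#' @param cycle_length The cycle's length in days, > 14.
#' @return Standard-calendar day (numeric, 2 decimals).
#' @examples
#' renormalize_day(16, 30) # 14
#' renormalize_day(25, 35) # 18
#' @export
renormalize_day <- function(day, cycle_length) {
  if (any(cycle_length <= 14)) {
    stop("cycle_length must exceed the fixed 14-day luteal phase",
         call. = FALSE)
  }
  stopifnot(all(day >= 1), all(day <= cycle_length))
  O <- cycle_length - 14
  out <- ifelse(day <= O, day * 14 / O, 14 + (day - O))
  round(out, 2)
}

#' Chi-square hormone dating
#'
#' Dates the cycle from a four-hormone serum panel by minimizing, over the
#' days of a reference cycle,
#' `chi2(d) = sum_h (x_h - mu_h(d))^2 / (sigma_meas,h^2 + sigma_ref,h(d)^2)`.
#' Hormones whose total variance is zero on a given day are excluded from
#' that day's sum with a warning. The best reference day is mapped to the
#' standard 28-day calendar via [renormalize_day()] (the reference cycle is
#' 30 days, anchored at the LH peak), and the ± error is the span of days
#' within `delta chi2 <= 1` of the minimum (the single-parameter confidence
#' convention).
#'
#' @param panel Tibble/data frame with columns `hormone`, `value`, `error`
#'   (measurement standard deviation), one row per hormone.
#' @param reference Reference table as from [hormone_reference()]: columns
#'   `day`, `hormone`, `mean`, `variance`.
#' @return A `vped_estimate` tibble: `day` (standard calendar), `err_lo`,
#'   `err_hi` (days), `method = "hormones"`, plus attributes `ref_day` (the
#'   winning reference-cycle day) and `chi2` (per-day profile).
#' @export
chi2_hormone_day <- function(panel, reference = hormone_reference()) {
  stopifnot(all(c("hormone", "value", "error") %in% names(panel)))
  stopifnot(all(c("day", "hormone", "mean", "variance") %in% names(reference)))
  stopifnot(all(is.finite(panel$value)), all(panel$error >= 0))
  days <- sort(unique(reference$day))
  cycle_len <- length(days)
  chi2 <- vapply(days, function(d) {
    ref_d <- reference[reference$day == d, ]
    m <- match(ref_d$hormone, panel$hormone)
    if (anyNA(m)) stop("panel is missing hormones: ",
                       paste(ref_d$hormone[is.na(m)], collapse = ", "),
                       call. = FALSE)
    tot_var <- panel$error[m]^2 + ref_d$variance
    use <- tot_var > 0
    if (!any(use)) return(NA_real_)
    if (!all(use)) {
      warning("excluding zero-variance hormone(s) on reference day ", d, ": ",
              paste(ref_d$hormone[!use], collapse = ", "), call. = FALSE)
    }
    sum((panel$value[m][use] - ref_d$mean[use])^2 / tot_var[use])
  }, numeric(1))
  if (all(is.na(chi2))) {
    stop("all hormones have zero total variance on every day", call. = FALSE)
  }
  best <- which.min(chi2)
  ref_day <- days[best]
  within <- days[!is.na(chi2) & chi2 <= chi2[best] + 1]
  est <- renormalize_day(ref_day, cycle_len)
  out <- tibble::tibble(
    day = est,
    err_lo = ref_day - min(within),
    err_hi = max(within) - ref_day,
    method = "hormones"
  )
  structure(out, class = c("vped_estimate", class(out)),
            ref_day = ref_day, chi2 = stats::setNames(chi2, days))
}

#' Cycle dating from the patient's own report
#'
#' The raw day is the day count from the reported first day of the last
#' menses to the sampling date (inclusive), renormalized to the standard
#' calendar with the reported average cycle length. The reported
#' cycle-length variance is propagated through the local slope of the
#' renormalization map.
#'
#' @param first_menses_date,sampling_date `Date`s (or coercible);
#'   `sampling_date` must not precede `first_menses_date`.
#' @param cycle_length Reported average cycle length (days).
#' @param cycle_sd Reported cycle-length standard deviation (days).
#' @return A `vped_estimate` tibble (`method = "report"`).
#' @examples
#' report_day(as.Date("2024-01-01"), as.Date("2024-01-20"), 28)
#' @export
report_day <- function(first_menses_date, sampling_date, cycle_length,
                       cycle_sd = 0) {
  first_menses_date <- as.Date(first_menses_date)
  sampling_date <- as.Date(sampling_date)
  if (anyNA(first_menses_date) || anyNA(sampling_date) ||
        is.na(cycle_length)) {
    stop("missing report fields", call. = FALSE)
  }
  if (sampling_date < first_menses_date) {
    stop("sampling date precedes the reported first menses date",
         call. = FALSE)
  }
  raw <- as.numeric(sampling_date - first_menses_date) + 1
  raw <- min(raw, cycle_length)
  est <- renormalize_day(raw, cycle_length)
  O <- cycle_length - 14
  # derivative of the renormalized day w.r.t. cycle length
  slope <- if (raw <= O) 14 * raw / O^2 else 1
  err <- round(cycle_sd * slope, 2)
  out <- tibble::tibble(day = est, err_lo = err, err_hi = err,
                        method = "report")
  structure(out, class = c("vped_estimate", class(out)), raw_day = raw)
}

#' Histology consensus dating (pass-through)
#'
#' Histology-based dating is already expressed on the standard calendar
#' through its own reference criteria, so the consensus day and its
#' asymmetric error bounds are passed through unchanged.
#'
#' @param day Consensus cycle day.
#' @param err_lo,err_hi Asymmetric error bounds (days, >= 0).
#' @return A `vped_estimate` tibble (`method = "histology"`).
#' @export
histology_day <- function(day, err_lo = 0, err_hi = 0) {
  if (is.na(day)) stop("missing histology consensus day", call. = FALSE)
  if (err_lo < 0 || err_hi < 0) {
    stop("histology error bounds must be >= 0", call. = FALSE)
  }
  out <- tibble::tibble(day = day, err_lo = err_lo, err_hi = err_hi,
                        method = "histology")
  structure(out, class = c("vped_estimate", class(out)))
}

#' All traditional datings for a cohort's patients
#'
#' Applies report, histology and chi-square hormone dating to every row of a
#' [generate_cohort()] patient table (or any table with the same columns).
#' Endometrial thickness is carried through for reporting but never turned
#' into a dating.
#'
#' @param patients Patient tibble (see [generate_cohort()]).
#' @param reference Hormone reference table.
#' @return Tidy tibble: `patient`, `method`, `day`, `err_lo`, `err_hi`.
#' @export
reference_datings <- function(patients, reference = hormone_reference()) {
  purrr::pmap_dfr(patients, function(...) {
    p <- list(...)
    panel <- tibble::tibble(
      hormone = c("estradiol", "progesterone", "lh", "fsh"),
      value = c(p$estradiol, p$progesterone, p$lh, p$fsh),
      error = c(p$estradiol_err, p$progesterone_err, p$lh_err, p$fsh_err)
    )
    dplyr::bind_rows(
      dplyr::mutate(report_day(p$first_menses_date, p$sampling_date,
                               p$reported_cycle_length,
                               p$reported_cycle_sd %||% 0),
                    patient = p$patient, .before = 1),
      dplyr::mutate(histology_day(p$histology_day, p$histology_err_lo,
                                  p$histology_err_hi),
                    patient = p$patient, .before = 1),
      dplyr::mutate(chi2_hormone_day(panel, reference),
                    patient = p$patient, .before = 1)
    )
  })
}
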