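test_that("renormalization maps the worked examples exactly", {
  expect_equal(renormalize_day(20, 28), 20)
  expect_equal(renormalize_day(16, 30), 14)
  expect_equal(renormalize_day(25, 35), 18)
  expect_error(renormalize_day(5, 14), "14-day luteal")
  expect_error(renormalize_day(0, 28))
  expect_error(renormalize_day(30, 28))
})

test_that("renormalization is monotone, continuous at ovulation, and ends at 28", {
  for (L in 25:35) {
    days <- seq(1, L, by = 0.25)
    out <- renormalize_day(days, L)
    expect_true(all(diff(out) >= -1e-9))
    expect_equal(renormalize_day(L, L), 28)
    O <- L - 14
    expect_equal(renormalize_day(O, L), 14)
    expect_gt(renormalize_day(1, L), 0)
  }
})

test_that("noiseless hormone panels recover every reference day exactly", {
  ref <- hormone_reference()
  for (d in 1:30) {
    rd <- ref[ref$day == d, ]
    panel <- tibble::tibble(hormone = rd$hormone, value = rd$mean, error = 0)
    est <- chi2_hormone_day(panel, ref)
    expect_equal(attr(est, "ref_day"), d)
    expect_equal(min(attr(est, "chi2")), 0)
    expect_equal(est$day, renormalize_day(d, 30))
  }
})

test_that("chi-square dating is invariant to per-hormone unit rescaling", {
  ref <- hormone_reference()
  rd <- ref[ref$day == 22, ]
  set.seed(4)
  panel <- tibble::tibble(hormone = rd$hormone,
                          value = rd$mean + rnorm(4) * sqrt(rd$variance),
                          error = 0.05 * rd$mean)
  est1 <- chi2_hormone_day(panel, ref)
  # estradiol reported in different units: value, mean and both sigmas x1000
  ref2 <- dplyr::mutate(ref,
    mean = ifelse(hormone == "estradiol", mean * 1000, mean),
    variance = ifelse(hormone == "estradiol", variance * 1e6, variance))
  panel2 <- dplyr::mutate(panel,
    value = ifelse(hormone == "estradiol", value * 1000, value),
    error = ifelse(hormone == "estradiol", error * 1000, error))
  est2 <- chi2_hormone_day(panel2, ref2)
  expect_equal(attr(est1, "chi2"), attr(est2, "chi2"))
  expect_equal(est1$day, est2$day)
})

test_that("zero-variance hormones are excluded with a warning; all-zero errors", {
  ref <- hormone_reference()
  ref0 <- dplyr::mutate(ref, variance = ifelse(hormone == "lh", 0, variance))
  rd <- ref0[ref0$day == 20, ]
  panel <- tibble::tibble(hormone = rd$hormone, value = rd$mean, error = 0)
  w <- capture_warnings(est <- chi2_hormone_day(panel, ref0))
  expect_true(any(grepl("lh", w)))
  expect_equal(attr(est, "ref_day"), 20)
  ref_allzero <- dplyr::mutate(ref, variance = 0)
  expect_error(
    suppressWarnings(chi2_hormone_day(panel, ref_allzero)),
    "zero total variance"
  )
})

test_that("report dating follows date arithmetic plus renormalization", {
  e28 <- report_day(as.Date("2024-01-01"), as.Date("2024-01-20"), 28)
  expect_equal(e28$day, 20)
  # same dates in a 30-day cycle: raw 20 > O = 16, so 14 + 4
  e30 <- report_day(as.Date("2024-01-01"), as.Date("2024-01-20"), 30)
  expect_equal(e30$day, 18)
  expect_error(report_day(as.Date("2024-01-10"), as.Date("2024-01-05"), 28),
               "precedes")
  expect_error(report_day(as.Date(NA), as.Date("2024-01-05"), 28), "missing")
  # luteal slope is one: error equals the reported cycle sd
  e <- report_day(as.Date("2024-01-01"), as.Date("2024-01-20"), 30,
                  cycle_sd = 2)
  expect_equal(e$err_lo, 2)
})

test_that("histology dating passes through with validated asymmetric errors", {
  e <- histology_day(21, err_lo = 2, err_hi = 1)
  expect_equal(e$day, 21)
  expect_equal(c(e$day - e$err_lo, e$day + e$err_hi), c(19, 22))
  e0 <- histology_day(18)
  expect_equal(c(e0$err_lo, e0$err_hi), c(0, 0))
  expect_error(histology_day(NA), "missing")
  expect_error(histology_day(21, err_lo = -1), ">= 0")
})

test_that("on a noiseless cohort all traditional datings equal the truth", {
  co <- generate_cohort(14, noise = cohort_noise_zero(), seed = 8)
  rd <- reference_datings(co$patients)
  wide <- tidyr::pivot_wider(rd[, c("patient", "method", "day")],
                             names_from = method, values_from = day)
  truth <- co$patients$true_day[match(wide$patient, co$patients$patient)]
  expect_equal(wide$histology, truth)
  expect_equal(wide$report, as.numeric(truth))
  expect_equal(wide$hormones, as.numeric(truth))
})
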