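#' Synthetic 30-day hormone reference profile
#'
#' A smooth, synthetic per-day table of serum hormone means and tabulated
#' variances over a 30-day reference cycle (ovulation/LH peak at day 16,
#' fixed 14-day luteal phase). The shapes follow the textbook cycle:
#' biphasic estradiol with a pre-ovulatory peak, a sharp mid-cycle LH surge
#' with a smaller FSH peak, and a luteal progesterone plateau. Values are
#' *not* assay-calibrated clinical references — they exist so the
#' chi-square dating machinery is exercised end to end; any table with the
#' same columns can be substituted.
#'
#' Mild monotone drifts are built into the baselines so that no two days
#' share an identical four-hormone mean vector.
#'
#' @return Tibble with columns `day` (1-30), `hormone`
#'   (`estradiol` pg/mL, `progesterone` ng/mL, `lh` IU/L, `fsh` IU/L),
#'   `mean`, `variance`.
#' @export
hormone_reference <- function() {
  day <- 1:30
  sp <- function(ad, av) stats::spline(ad, av, xout = day, method = "natural")$y
  means <- list(
    estradiol = pmax(20, sp(c(1, 4, 8, 12, 15, 17, 20, 23, 27, 30),
                            c(35, 48, 75, 150, 260, 130, 160, 195, 105, 45)) +
                      0.8 * day),
    progesterone = pmax(0.3, sp(c(1, 10, 15, 17, 20, 23, 26, 30),
                                c(0.5, 0.6, 0.9, 2.5, 9, 16, 11, 1.2)) +
                          0.02 * day),
    lh = pmax(1, 5 + 0.15 * day + 38 * exp(-((day - 16)^2) / (2 * 1.1^2))),
    fsh = pmax(1, sp(c(1, 5, 9, 12, 16, 20, 26, 30),
                     c(9.5, 7.5, 6, 5.2, 14, 3.5, 2.8, 4.5)) + 0.05 * day)
  )
  floors <- c(estradiol = 5, progesterone = 0.25, lh = 0.8, fsh = 0.5)
  purrr::imap_dfr(means, function(m, h) {
    tibble::tibble(day = day, hormone = h, mean = m,
                   variance = (0.09 * m + floors[[h]])^2)
  })
}

#' Noise configuration for synthetic cohorts
#'
#' @param histology_kernel Named numeric vector of probabilities over integer
#'   day offsets for the histology consensus day. Default
#'   `P(0)=0.6, P(±1)=0.15, P(±2)=0.05`.
#' @param hormone_scale Multiplier on the reference table's tabulated
#'   standard deviation for the simulated panel noise (0 = noiseless).
#' @param report_sd Standard deviation (days) of the patient-report error on
#'   the raw cycle day (rounded to whole days).
#' @param cycle_length_sd Standard deviation of the simulated cycle length
#'   around 28 days (rounded; clipped to 25-35; 0 = everyone at 28).
#' @param thickness_sd Noise on the simulated endometrial thickness (mm).
#' @return List of class `vped_noise`.
#' @export
cohort_noise <- function(histology_kernel = c("-2" = 0.05, "-1" = 0.15,
                                              "0" = 0.6, "1" = 0.15,
                                              "2" = 0.05),
                         hormone_scale = 1, report_sd = 1,
                         cycle_length_sd = 1.8, thickness_sd = 0.5) {
  stopifnot(abs(sum(histology_kernel) - 1) < 1e-8)
  structure(list(histology_kernel = histology_kernel,
                 hormone_scale = hormone_scale, report_sd = report_sd,
                 cycle_length_sd = cycle_length_sd,
                 thickness_sd = thickness_sd),
            class = "vped_noise")
}

#' @rdname cohort_noise
#' @export
cohort_noise_zero <- function() {
  cohort_noise(histology_kernel = c("0" = 1), hormone_scale = 0,
               report_sd = 0, cycle_length_sd = 0, thickness_sd = 0)
}

# expected pore area (um^2) for a cycle day under a trajectory table
expected_pore_area <- function(day, table) {
  p <- trajectory(day, "pore_area", table)
  p$b + p$lambda * gamma(1 + 1 / p$gamma)
}

#' Pores per image that keep the rendered filling factor realistic
#'
#' As the mean pore area grows through the secretory phase, the number of
#' pores that fit one region of interest at a given filling factor drops.
#'
#' @param day Cycle day.
#' @param spec An [image_spec()].
#' @param fill Target pore filling factor.
#' @param bounds Lower/upper bounds on the count.
#' @param table Trajectory table.
#' @return Integer pore count.
#' @export
pores_per_image <- function(day, spec = image_spec(), fill = 0.06,
                            bounds = c(15L, 50L),
                            table = default_trajectories()) {
  area_um2 <- prod(spec$size_px) * spec$pixel_size_um^2
  n <- round(fill * area_um2 / expected_pore_area(day, table))
  as.integer(min(max(n, bounds[1]), bounds[2]))
}

# invert the piecewise-linear 28-day renormalization for a given cycle length
raw_day_for <- function(standard_day, cycle_length) {
  O <- cycle_length - 14
  if (standard_day <= 14) standard_day * O / 14 else standard_day - 14 + O
}

#' Generate a synthetic patient cohort
#'
#' Emulates the structure of a clinical endometrial-dating study: each
#' patient has a true (standard-calendar) cycle day, a cycle length, a
#' patient-reported day (as last-menses/sampling dates), a histology
#' consensus day with asymmetric error, a four-hormone serum panel drawn
#' from the reference profile, an endometrial thickness, and tissue-element
#' features — either as a direct feature table drawn from the day's
#' trajectory, or as rendered images with ground truth.
#'
#' @param n_patients Cohort size.
#' @param days True-day assignment: `"round_robin"` (default; cycles through
#'   the supported range) or an integer vector of length `n_patients`.
#' @param noise A [cohort_noise()].
#' @param seed Integer seed; the cohort is fully reproducible given the seed.
#' @param images If `TRUE`, render `n_images` scenes per patient (slower);
#'   otherwise attach a feature table of `elements_per_sample` elements.
#' @param n_images Images per patient when `images = TRUE`.
#' @param elements_per_sample Elements per kind when `images = FALSE`.
#' @param vessels_per_image Vessel count per rendered image.
#' @param table Trajectory table defining the supported day range.
#' @param spec [image_spec()] used for rendering.
#' @param reference Hormone reference table.
#' @return Object of class `vped_cohort`: `patients` (tibble),
#'   `features` (long tibble: `patient`, `element`, `kind`, `feature`,
#'   `value`) or `scenes` (list of per-patient scene lists), plus the
#'   generating configuration.
#' @export
generate_cohort <- function(n_patients, days = "round_robin",
                            noise = cohort_noise(), seed = NULL,
                            images = FALSE, n_images = 4L,
                            elements_per_sample = 300L,
                            vessels_per_image = 8L,
                            table = default_trajectories(),
                            spec = image_spec(),
                            reference = hormone_reference()) {
  stopifnot(n_patients >= 1L, inherits(noise, "vped_noise"))
  supported <- sort(unique(table$day))
  if (identical(days, "round_robin")) {
    days <- rep(supported, length.out = n_patients)
  }
  stopifnot(length(days) == n_patients)
  if (!all(days %in% supported)) {
    stop("assigned days outside the trajectory table's supported range",
         call. = FALSE)
  }
  with_seed(seed, {
    patients <- purrr::map_dfr(seq_len(n_patients), function(i) {
      true_day <- days[i]
      cl <- if (noise$cycle_length_sd > 0) {
        min(35, max(25, round(stats::rnorm(1, 28, noise$cycle_length_sd))))
      } else 28
      raw <- raw_day_for(true_day, cl)
      raw_rep <- max(1, round(raw + stats::rnorm(1, 0, noise$report_sd)))
      sampling_date <- as.Date("2024-03-01") + (i - 1L)
      offs <- as.integer(names(noise$histology_kernel))
      hist_day <- true_day + sample(offs, 1, prob = noise$histology_kernel)
      hist_day <- min(max(hist_day, min(supported)), max(supported))
      ref_day <- round(raw_day_for(true_day, 30))
      panel <- dplyr::filter(reference, .data$day == ref_day)
      hv <- stats::setNames(
        panel$mean + noise$hormone_scale * stats::rnorm(nrow(panel)) *
          sqrt(panel$variance),
        panel$hormone
      )
      me <- stats::setNames(0.05 * panel$mean + c(4, 0.2, 0.5, 0.4),
                            panel$hormone)
      tibble::tibble(
        patient = sprintf("P%03d", i),
        true_day = true_day,
        cycle_length = cl,
        first_menses_date = sampling_date - (raw_rep - 1L),
        sampling_date = sampling_date,
        reported_cycle_length = cl,
        reported_cycle_sd = noise$cycle_length_sd,
        histology_day = hist_day,
        histology_err_lo = 1, histology_err_hi = 1,
        estradiol = hv[["estradiol"]], estradiol_err = me[["estradiol"]],
        progesterone = hv[["progesterone"]],
        progesterone_err = me[["progesterone"]],
        lh = hv[["lh"]], lh_err = me[["lh"]],
        fsh = hv[["fsh"]], fsh_err = me[["fsh"]],
        thickness_mm = 7 + 2 * sin((true_day - 15) / 13 * pi) +
          stats::rnorm(1, 0, noise$thickness_sd)
      )
    })
    out <- list(patients = patients, table = table, noise = noise,
                spec = spec, reference = reference)
    if (images) {
      out$scenes <- purrr::map(seq_len(n_patients), function(i) {
        purrr::map(seq_len(n_images), function(j) {
          np <- pores_per_image(days[i], spec, table = table)
          fs <- dplyr::bind_rows(
            dplyr::filter(sample_features(days[i], np, table = table),
                          .data$kind == "pore"),
            dplyr::filter(sample_features(days[i], vessels_per_image,
                                          table = table),
                          .data$kind == "vessel")
          )
          render_image(fs, spec)
        })
      })
    } else {
      out$features <- purrr::map_dfr(seq_len(n_patients), function(i) {
        dplyr::mutate(
          sample_features(days[i], elements_per_sample, table = table),
          patient = patients$patient[i], .before = 1
        )
      })
    }
    structure(out, class = "vped_cohort")
  })
}

#' @export
print.vped_cohort <- function(x, ...) {
  cat("<vped_cohort> ", nrow(x$patients), " patients, days ",
      min(x$patients$true_day), "-", max(x$patients$true_day),
      if (!is.null(x$scenes)) ", rendered scenes" else ", feature tables",
      "\n", sep = "")
  invisible(x)
}

#' Write cohort records and images to disk
#'
#' Patient records as CSV; rendered scenes (when present) as 16-bit TIFFs in
#' a directory, with a manifest CSV.
#'
#' @param cohort A `vped_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vped_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$features)) {
    utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$scenes)) {
    manifest <- purrr::imap_dfr(cohort$scenes, function(scenes, i) {
      purrr::imap_dfr(scenes, function(sc, j) {
        fn <- sprintf("%s_img%02d.tif", cohort$patients$patient[i], j)
        write_tissue_image(sc$image, file.path(dir, fn))
        tibble::tibble(path = fn, specimen = cohort$patients$patient[i],
                       pixel_size_um = sc$truth$spec$pixel_size_um,
                       magnification = sc$truth$spec$magnification)
      })
    })
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
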