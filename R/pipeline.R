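#' Segment all scenes of a cohort into per-patient feature tables
#'
#' Runs [segment_image()] on every rendered image of every patient and
#' collates per-patient ensembles, returning the long feature table the
#' dating machinery consumes.
#'
#' @param cohort A [generate_cohort()] result with `images = TRUE`.
#' @param config A [segmentation_config()].
#' @return Long tibble: `patient`, `kind`, `feature`, `value`.
#' @export
segment_cohort <- function(cohort, config = segmentation_config()) {
  stopifnot(inherits(cohort, "vped_cohort"))
  if (is.null(cohort$scenes)) {
    stop("cohort has no rendered scenes; generate with images = TRUE",
         call. = FALSE)
  }
  px <- cohort$spec$pixel_size_um
  purrr::imap_dfr(cohort$scenes, function(scenes, i) {
    pid <- cohort$patients$patient[i]
    results <- purrr::imap(scenes, function(sc, j) {
      segment_image(sc$image, px, magnification = cohort$spec$magnification,
                    image_id = sprintf("%s_img%02d", pid, j),
                    specimen_id = pid, config = config)
    })
    ens <- collate_specimen(results)
    features_long(ens$elements, patient = pid)
  })
}

# wide element table -> long (patient, kind, feature, value)
features_long <- function(elements, patient) {
  if (nrow(elements) == 0L) {
    return(tibble::tibble(patient = character(), kind = character(),
                          feature = character(), value = numeric()))
  }
  pores <- dplyr::filter(elements, .data$kind == "pore")
  vessels <- dplyr::filter(elements, .data$kind == "vessel")
  out <- dplyr::bind_rows(
    if (nrow(pores)) tidyr::pivot_longer(
      dplyr::transmute(pores, kind = .data$kind,
                       pore_area = .data$area, pore_length = .data$length,
                       pore_curvature = .data$curvature,
                       pore_tortuosity = .data$tortuosity),
      -"kind", names_to = "feature", values_to = "value"
    ),
    if (nrow(vessels)) tidyr::pivot_longer(
      dplyr::transmute(vessels, kind = .data$kind,
                       bv_diameter = .data$diameter,
                       bv_segment_length = .data$segment_length),
      -"kind", names_to = "feature", values_to = "value"
    )
  )
  dplyr::mutate(out, patient = patient, .before = 1)
}

#' Leave-one-out VPED dating of a labelled cohort
#'
#' For every patient, a dictionary is built from all *other* patients'
#' features (labelled by `label_col`), and the held-out patient is dated
#' against it. This is the honest end-to-end evaluation mode: a patient
#' never contributes to the reference it is scored against.
#'
#' @param features Long tibble `patient`, `feature`, `value`.
#' @param labels Tibble `patient`, `day`.
#' @param feature_set Dating features (default: the pore features).
#' @param window Top-hat window width.
#' @return Tibble: `patient`, `label_day`, `vped_day`.
#' @export
loo_date_cohort <- function(features, labels,
                            feature_set = pore_feature_names(),
                            window = 5L) {
  patients <- unique(labels$patient)
  purrr::map_dfr(patients, function(p) {
    train_labels <- labels[labels$patient != p, ]
    train_feats <- features[features$patient != p, ]
    dict <- build_dictionary(train_feats, train_labels,
                             feature_set = feature_set)
    sample <- features[features$patient == p, ]
    est <- tryCatch(
      vped_date(sample, dict, feature_set = feature_set, window = window),
      error = function(e) NULL
    )
    tibble::tibble(patient = p,
                   label_day = labels$day[labels$patient == p][1],
                   vped_day = if (is.null(est)) NA_real_ else est$day)
  })
}
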