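test_that("dictionaries pool per-day distributions with shared bins", {
  dict <- shared_dict()
  expect_s3_class(dict, "vped_dictionary")
  expect_equal(attr(dict, "days"), 15:28)
  expect_length(attr(dict, "missing_days"), 0)
  # every supported day has every configured feature
  counts <- dplyr::count(tibble::as_tibble(dict), day)
  expect_true(all(counts$n == length(attr(dict, "features"))))
  # pooled per-day cPDF stays within the KS band of the generating cPDF
  for (d in c(15, 22, 28)) {
    p <- trajectory(d, "pore_area")
    pooled <- dict$dist[[which(dict$day == d &
                                 dict$feature == "pore_area")]]
    grid <- sort(pooled$values)
    supd <- max(abs(emp_cdf(pooled)(grid) -
                      weibull_cdf(grid, p$b, p$lambda, p$gamma)))
    expect_lt(supd, 1.358 / sqrt(3000) * 1.5)
  }
})

test_that("single-day cohorts give single-day dictionaries; empty errors", {
  feats <- dplyr::mutate(sample_features(20, 100, seed = 1),
                         patient = "P1")
  labels <- tibble::tibble(patient = "P1", day = 20)
  d <- build_dictionary(feats, labels)
  expect_equal(attr(d, "days"), 20)
  expect_error(build_dictionary(feats[0, ], labels), "empty cohort")
})

test_that("days without samples are flagged missing and excluded", {
  co <- generate_cohort(26, days = rep(setdiff(15:28, 17), 2),
                        noise = cohort_noise_zero(), seed = 2,
                        elements_per_sample = 60)
  labels <- dplyr::transmute(co$patients, patient, day = true_day)
  dict <- build_dictionary(co$features, labels, days = 15:28)
  expect_equal(attr(dict, "missing_days"), 17)
  expect_false(17 %in% attr(dict, "days"))
})

test_that("a dictionary day's own pooled sample scores one at that day", {
  dict <- shared_dict()
  for (d in c(15, 21, 28)) {
    sample <- purrr::map(
      purrr::set_names(attr(dict, "features")),
      function(f) dict$dist[[which(dict$day == d & dict$feature == f)]]
    )
    prof <- score_sample(sample, dict)
    expect_equal(prof$score[prof$day == d], 1)
    expect_equal(infer_day(prof)$day, d)
  }
})

test_that("a disjoint-support sample scores near zero everywhere", {
  dict <- shared_dict()
  shifted <- purrr::map(
    purrr::set_names(attr(dict, "features")),
    function(f) {
      d0 <- dict$dist[[which(dict$day == 20 & dict$feature == f)]]
      empirical_distribution(d0$values + 100 * max(d0$values), feature = f)
    }
  )
  prof <- score_sample(shifted, dict)
  expect_true(all(prof$score < 1e-6))
  expect_error(infer_day(prof), "unclassifiable")
})

test_that("missing sample features are reported by name", {
  dict <- shared_dict()
  sample <- dplyr::filter(sample_features(20, 50, seed = 3),
                          feature != "pore_area")
  expect_error(score_sample(sample, dict), "pore_area")
})

test_that("top-hat window turns deltas into plateaus and normalizes", {
  delta <- function(at) {
    s <- numeric(14); s[at - 14] <- 1
    vped:::new_profile(15:28, s, FALSE, FALSE)
  }
  w <- tophat_convolve(delta(20))
  expect_equal(sum(w$score), 1)
  expect_equal(w$score[w$day %in% 18:22], rep(0.2, 5))
  expect_true(all(w$score[!w$day %in% 18:22] == 0))
  # edge delta: shorter plateau after the sum-to-one renormalization
  we <- tophat_convolve(delta(28))
  expect_equal(we$score[we$day %in% 26:28], rep(1 / 3, 3))
  expect_error(tophat_convolve(delta(20), width = 4), "odd")
})

test_that("mean-edge policy keeps a uniform profile uniform", {
  u <- vped:::new_profile(15:28, rep(0.3, 14), FALSE, FALSE)
  w <- tophat_convolve(u, edge = "mean")
  expect_equal(w$score, rep(1 / 14, 14))
  # sum policy: interior stays flat, edges are damped by truncation
  ws <- tophat_convolve(u, edge = "sum")
  interior <- ws$score[ws$day %in% 17:26]
  expect_equal(diff(range(interior)), 0)
  expect_lt(ws$score[1], interior[1])
})

test_that("day inference breaks exact ties by the plateau centroid", {
  two <- vped:::new_profile(15:28, c(rep(0, 5), 1, 1, rep(0, 7)),
                            FALSE, FALSE)
  expect_equal(infer_day(two)$day, 20) # round(20.5) -> 20, deterministic
  mono <- vped:::new_profile(15:28, seq(0.1, 1, length.out = 14),
                             FALSE, FALSE)
  expect_equal(infer_day(mono)$day, 28)
})

test_that("the confusion matrix is symmetric, unit-diagonal and diagonal-dominant", {
  dict <- shared_dict()
  conf <- day_confusion_matrix(dict)
  expect_true(all(diag(conf$raw) == 1))
  expect_identical(conf$raw, t(conf$raw))
  expect_true(all(apply(conf$relative, 1, max) == 1))
  # well-separated trajectories: distant days nearly zero
  far <- abs(outer(conf$days, conf$days, "-")) >= 3
  expect_lt(max(conf$relative[far]), 0.1)
})

test_that("day errors derive from the half-relative-probability width", {
  days <- 15:22
  mk <- function(rel) {
    structure(list(raw = rel, smoothed = rel, relative = rel, days = days),
              class = "vped_confusion")
  }
  ident <- mk(diag(8))
  e <- day_error_estimate(ident, 18)
  expect_equal(c(e$err_lo, e$err_hi), c(0, 0))
  unif <- mk(matrix(1, 8, 8))
  eu <- day_error_estimate(unif, 18)
  expect_equal(eu$err_lo, 3) # to the range start
  expect_equal(eu$err_hi, 4) # to the range end
  dict <- shared_dict()
  conf <- day_confusion_matrix(dict)
  errs <- purrr::map_dfr(conf$days, ~ day_error_estimate(conf, .x))
  expect_true(all(errs$err_lo <= 1 & errs$err_hi <= 1))
})

test_that("fresh samples are dated to their generating day", {
  dict <- shared_dict()
  conf <- day_confusion_matrix(dict)
  set.seed(11)
  for (d in c(16, 20, 24, 27)) {
    est <- vped_date(sample_features(d, 300), dict, confusion = conf)
    expect_lte(abs(est$day - d), 1)
    expect_false(is.na(est$err_lo))
  }
})

test_that("leave-one-out dating stays close to in-dictionary dating", {
  co <- generate_cohort(28, noise = cohort_noise_zero(), seed = 13,
                        elements_per_sample = 300)
  labels <- dplyr::transmute(co$patients, patient, day = true_day)
  loo <- loo_date_cohort(co$features, labels)
  in_dict <- build_dictionary(co$features, labels,
                              feature_set = pore_feature_names())
  in_days <- purrr::map_dbl(labels$patient, function(p) {
    vped_date(co$features[co$features$patient == p, ], in_dict)$day
  })
  acc_loo <- mean(abs(loo$vped_day - loo$label_day) <= 1)
  acc_in <- mean(abs(in_days - labels$day) <= 1)
  expect_gte(acc_in, acc_loo)       # held-out can only be harder
  expect_lt(acc_in - acc_loo, 0.10) # but not much harder
})

test_that("dictionaries survive a JSON round trip", {
  feats <- dplyr::bind_rows(
    dplyr::mutate(sample_features(20, 80, seed = 21), patient = "A"),
    dplyr::mutate(sample_features(21, 80, seed = 22), patient = "B")
  )
  labels <- tibble::tibble(patient = c("A", "B"), day = c(20, 21))
  dict <- build_dictionary(feats, labels)
  path <- withr::local_tempfile(fileext = ".json")
  write_dictionary(dict, path)
  back <- read_dictionary(path)
  expect_equal(attr(back, "days"), attr(dict, "days"))
  expect_equal(attr(back, "features"), attr(dict, "features"))
  for (i in seq_len(nrow(dict))) {
    expect_equal(back$dist[[i]]$values, dict$dist[[i]]$values)
    expect_equal(back$dist[[i]]$heights, dict$dist[[i]]$heights)
  }
  s <- sample_features(20, 100, seed = 23)
  expect_equal(score_sample(s, back)$score, score_sample(s, dict)$score)
})
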