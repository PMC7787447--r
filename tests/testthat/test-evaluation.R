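test_that("extraction precision counts true positives over judged strings", {
  extracted <- tibble::tibble(
    article_id = "a1",
    location_string = paste0("loc", 1:19)
  )
  judgments <- tibble::tibble(
    article_id = "a1",
    extracted_string = paste0("loc", 1:19),
    correct = c(rep(TRUE, 18), FALSE)
  )
  p <- extraction_precision(extracted, judgments)
  expect_equal(p, 18 / 19)
  expect_equal(round(p, 2), 0.95)

  expect_equal(
    extraction_precision(extracted, dplyr::mutate(judgments, correct = TRUE)),
    1
  )
  expect_true(is.na(extraction_precision(extracted[0, ], judgments)))
  expect_error(
    extraction_precision(extracted, judgments[-3, ]),
    "loc3"
  )
})

test_that("harmonic F1 matches closed-form values and brackets P and R", {
  expect_equal(round(harmonic_f1(0.628, 1), 3), 0.771)
  # 2 * 0.408 / 1.408 = 0.57954...; printed as 0.579 (truncated)
  expect_equal(harmonic_f1(0.408, 1), 0.816 / 1.408)
  expect_lt(abs(harmonic_f1(0.408, 1) - 0.579), 1e-3)
  expect_identical(harmonic_f1(0, 0), 0)
  expect_identical(harmonic_f1(1, 1), 1)
  expect_error(harmonic_f1(1.2, 0.5), "\\[0, 1\\]")

  set.seed(37)
  for (i in 1:200) {
    p <- runif(1); r <- runif(1)
    f1 <- harmonic_f1(p, r)
    expect_gte(f1, min(p, r) - 1e-12)
    expect_lte(f1, max(p, r) + 1e-12)
  }
})

test_that("article-unit scores average per-article values", {
  truth <- tibble::tibble(
    article_id = c("a1", "a1", "a2"),
    truth_string = c("Seville, Spain", "Valencia, Spain", "Nancy, France")
  )
  # a1: 2 extracted, 1 correct (P = 0.5), both truths... only 1 represented
  extracted <- tibble::tibble(
    article_id = c("a1", "a1", "a2", "a2"),
    location_string = c("Seville, Spain", "Atlantis", "Nancy, France",
                        "Nowhere City")
  )
  judgments <- tibble::tibble(
    article_id = c("a1", "a1", "a2", "a2"),
    extracted_string = extracted$location_string,
    correct = c(TRUE, FALSE, TRUE, FALSE)
  )
  res <- article_unit_scores(extracted, truth, judgments)
  expect_equal(res$per_article$precision, c(0.5, 0.5))
  expect_equal(res$per_article$recall, c(0.5, 1))
  expect_equal(res$precision, 0.5)
  expect_equal(res$recall, 0.75)
  expect_equal(res$f1, harmonic_f1(0.5, 0.75))

  # per-article (P, R) = (1, 0.5) and (0.5, 1) average to (0.75, 0.75)
  expect_equal(mean(c(1, 0.5)), 0.75)
  res2 <- article_unit_scores(
    extracted[c(1, 3, 4), ], truth, judgments[c(1, 3, 4), ]
  )
  expect_equal(res2$per_article$precision, c(1, 0.5))
  expect_equal(res2$per_article$recall, c(0.5, 1))
  expect_equal(res2$precision, 0.75)
  expect_equal(res2$recall, 0.75)

  expect_error(
    article_unit_scores(
      dplyr::mutate(extracted, article_id = "zz"), truth, NULL
    ),
    "not in truth"
  )
})

test_that("truth matching accepts containment, and metrics ignore article order", {
  truth <- tibble::tibble(
    article_id = c("b1", "b2"),
    truth_string = c("Seville", "Nancy, France")
  )
  extracted <- tibble::tibble(
    article_id = c("b1", "b2"),
    location_string = c("Seville, Spain", "Nancy")
  )
  res <- article_unit_scores(extracted, truth)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)

  perm <- article_unit_scores(extracted[2:1, ], truth[2:1, ])
  expect_equal(perm$precision, res$precision)
  expect_equal(perm$recall, res$recall)
  expect_equal(perm$f1, res$f1)
})

test_that("geocode correctness uses record ids, then distance by granularity", {
  truth <- tibble::tibble(
    article_id = "a1", truth_string = "Seville, Spain",
    truth_record_id = "c001", truth_lat = 37.39, truth_lon = -5.98
  )
  rec <- tibble::tibble(
    article_id = "a1", location_string = "Seville, Spain",
    record_id = "c001", formatted_name = "Seville, Andalusia, Spain",
    granularity = "locality", latitude = 37.39, longitude = -5.98
  )
  expect_equal(geocoding_accuracy(rec, truth), 1)

  # wrong id counts incorrect even at zero distance
  expect_equal(
    geocoding_accuracy(dplyr::mutate(rec, record_id = "c999"), truth),
    0
  )

  # no truth id: a locality result ~5 km away is within the 25 km tolerance
  truth2 <- dplyr::mutate(truth, truth_record_id = NA_character_)
  rec2 <- dplyr::mutate(rec, record_id = "other",
                        latitude = 37.39 + 0.045)  # ~5 km north
  expect_equal(geocoding_accuracy(rec2, truth2), 1)
  rec3 <- dplyr::mutate(rec2, latitude = 37.39 + 3)  # ~330 km north
  expect_equal(geocoding_accuracy(rec3, truth2), 0)

  # a true positive with no geocode result is incorrect
  rec4 <- dplyr::mutate(rec, record_id = NA_character_)
  expect_equal(geocoding_accuracy(rec4, truth), 0)
})

test_that("full-pipeline precision treats no-result false extractions as true negatives", {
  truth <- tibble::tibble(
    article_id = "a1", truth_string = "Seville, Spain",
    truth_record_id = "c001", truth_lat = NA_real_, truth_lon = NA_real_
  )
  recs <- tibble::tibble(
    article_id = "a1",
    location_string = c("Seville, Spain", "Wrongville", "Badland"),
    record_id = c("c001", NA, "c777"),
    formatted_name = c("Seville, Andalusia, Spain", NA, "Elsewhere"),
    granularity = c("locality", NA, "locality"),
    latitude = c(37.39, NA, 0), longitude = c(-5.98, NA, 0)
  )
  judgments <- tibble::tibble(
    article_id = "a1", extracted_string = recs$location_string,
    correct = c(TRUE, FALSE, FALSE)
  )
  # Wrongville: FP string, no geocode -> true negative, leaves denominator;
  # Badland: FP with a geocode -> stays as FP
  expect_equal(full_pipeline_precision(recs, judgments, truth), 1 / 2)

  # correct string, wrong geocode: overall false positive
  recs2 <- recs[1, ] |> dplyr::mutate(record_id = "c999")
  expect_equal(full_pipeline_precision(recs2, judgments[1, ], truth), 0)
})

test_that("error tallies reproduce printed percentages and always sum to ~100", {
  failures <- tibble::tibble(
    article_id = "x",
    category = rep(error_categories(), times = c(12, 8, 9, 7, 3, 3, 2))
  )
  tally <- tally_errors(failures)
  expect_identical(sum(tally$count), 44L)
  expect_equal(tally$percent, c(27.3, 18.2, 20.5, 15.9, 6.8, 6.8, 4.5))

  cancer <- rep(error_categories(), times = c(8, 7, 1, 0, 4, 0, 5))
  expect_equal(tally_errors(cancer)$percent,
               c(32.0, 28.0, 4.0, 0.0, 16.0, 0.0, 20.0))

  empty <- tally_errors(character())
  expect_true(all(empty$count == 0) && all(empty$percent == 0))
  expect_error(tally_errors("mystery_error"), "Unknown")

  set.seed(41)
  for (i in 1:200) {
    cats <- sample(error_categories(), sample(1:60, 1), replace = TRUE)
    # seven categories rounded to one decimal can drift at most 7 * 0.05
    expect_lte(abs(sum(tally_errors(cats)$percent) - 100), 0.35 + 1e-9)
  }
})
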