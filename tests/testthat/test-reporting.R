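sample_records <- function() {
  tibble::tibble(
    article_id = c("a1", "a1", "a2"),
    location_string = c("Seville, Spain", "Lost Place", "Nancy, France"),
    sentence_text = c('Sites were in Seville, Spain, "quoted".',
                      "An unresolvable mention.",
                      "Plots near Nancy, France."),
    heading = c("Study site", "Study site", "Methods"),
    para_idx = c(2L, 2L, 3L), sentence_idx = c(1L, 2L, 1L),
    n_duplicates = 0L,
    formatted_name = c("Seville, Andalusia, Spain", NA, "Nancy, Grand Est, France"),
    granularity = c("locality", NA, "locality"),
    latitude = c(37.39, NA, 48.69), longitude = c(-5.98, NA, 6.18),
    record_id = c("c001", NA, "c005"), backend_id = "gazetteer",
    variant = "full"
  )
}

test_that("GeoJSON features match geocoded records exactly and round-trip", {
  recs <- sample_records()
  path <- withr::local_tempfile(fileext = ".geojson")
  out <- write_geojson(recs, path)
  expect_identical(out$n_features, 2L)
  expect_identical(out$n_skipped, 1L)

  parsed <- jsonlite::read_json(path)
  expect_identical(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 2)
  # longitude first, latitude second; strings recoverable
  got <- purrr::map(parsed$features, function(f) {
    list(
      lon = f$geometry$coordinates[[1]], lat = f$geometry$coordinates[[2]],
      str = f$properties$location_string
    )
  })
  expect_equal(got[[1]]$lon, -5.98)
  expect_equal(got[[1]]$lat, 37.39)
  expect_setequal(
    purrr::map_chr(got, "str"),
    c("Seville, Spain", "Nancy, France")
  )
})

test_that("evaluation labels are attached to features when supplied", {
  recs <- sample_records()
  truth <- tibble::tibble(
    article_id = c("a1", "a2"),
    truth_string = c("Seville, Spain", "Nancy, France"),
    truth_record_id = c("c001", "c999")
  )
  ev <- evaluate_pipeline(recs, truth)
  out <- write_geojson(recs, evaluation = ev)
  labels <- purrr::map_chr(out$geojson$features, ~ .x$properties$label)
  expect_setequal(labels, c("TP", "FP"))
})

test_that("records tables escape awkward sentence text and round-trip", {
  recs <- sample_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_table(recs, path)
  back <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  expect_identical(nrow(back), 3L)
  expect_identical(back$sentence_text, recs$sentence_text)

  empty_path <- withr::local_tempfile(fileext = ".csv")
  write_records_table(recs[0, ], empty_path)
  expect_identical(length(readLines(empty_path)), 1L)  # header only

  jl <- withr::local_tempfile(fileext = ".jsonl")
  geosift:::write_records_jsonl(recs, jl)
  expect_identical(length(readLines(jl)), 3L)
  expect_identical(
    jsonlite::fromJSON(readLines(jl)[1])$location_string,
    "Seville, Spain"
  )
})

test_that("location plots are ggplot objects with and without evaluation", {
  recs <- sample_records()
  p1 <- plot_locations(recs)
  expect_s3_class(p1, "ggplot")
  truth <- tibble::tibble(article_id = c("a1", "a2"),
                          truth_string = c("Seville, Spain", "Nancy, France"))
  ev <- evaluate_pipeline(recs, truth)
  p2 <- plot_locations(recs, ev)
  expect_s3_class(p2, "ggplot")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(tidy(ev), "tbl_df")
  expect_identical(nrow(glance(ev)), 1L)
})
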