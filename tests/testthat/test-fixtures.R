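dir_digest <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(
    lapply(files, function(f) readBin(f, "raw", file.size(f))),
    list.files(dir, recursive = TRUE)
  )
}

test_that("the generator is byte-deterministic for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(generate_corpus(d1, seed = 3, n_articles = 5))
  suppressMessages(generate_corpus(d2, seed = 3, n_articles = 5))
  expect_identical(dir_digest(d1), dir_digest(d2))

  d3 <- withr::local_tempdir()
  suppressMessages(generate_corpus(d3, seed = 4, n_articles = 5))
  expect_false(identical(dir_digest(d1), dir_digest(d3)))
})

test_that("the annotation file lists exactly the planted locations", {
  d <- withr::local_tempdir()
  fix <- suppressMessages(generate_corpus(
    d, seed = 6, n_articles = 4, relevant_range = c(3L, 3L),
    distractor_range = c(0L, 0L)
  ))
  counts <- table(fix$truth$article_id)
  expect_true(all(counts == 3))
  expect_equal(as.data.frame(read_truth(fix$truth_path)),
               as.data.frame(fix$truth), ignore_attr = TRUE)

  # every planted location appears verbatim in its article's targeted text
  for (i in seq_len(nrow(fix$articles))) {
    doc <- parse_structured_article(fix$articles$xml_path[i])
    body <- paste(doc$paragraphs$text, collapse = " ")
    ts <- fix$truth$truth_string[fix$truth$article_id ==
                                   fix$articles$article_id[i]]
    for (t in ts) expect_true(grepl(t, body, fixed = TRUE))
  }
})

test_that("company distractors always carry a discard word", {
  d <- withr::local_tempdir()
  fix <- suppressMessages(generate_corpus(
    d, seed = 12, n_articles = 6, distractor_range = c(1L, 1L)
  ))
  discard_pat <- "\\b(Inc|Ltd|GmbH|Corp)\\b"
  for (p in fix$articles$xml_path) {
    doc <- parse_structured_article(p)
    body <- paste(doc$paragraphs$text, collapse = " ")
    expect_true(grepl(discard_pat, body))
  }
})

test_that("mock lexicon maps gazetteer names with LOCATION-over-ORGANIZATION precedence", {
  gaz <- load_toy_gazetteer()
  lex <- build_mock_lexicon(gaz)
  expect_true(all(c("San Francisco", "NYC", "Paris") %in% lex$phrase))
  expect_true(all(lex$tag[lex$phrase %in% c("San Francisco", "NYC")] ==
                    "LOCATION"))

  # institutional names become ORGANIZATION
  df <- dplyr::bind_rows(
    toy_gazetteer_df(),
    tibble::tibble(
      record_id = "h1", primary_name = "General Hospital",
      alternate_names = "", feature_class = "S", latitude = 1, longitude = 1,
      population = 0, country_code = "US", admin_path = "USA"
    )
  )
  lex2 <- build_mock_lexicon(load_toy_gazetteer(df))
  expect_identical(lex2$tag[lex2$phrase == "General Hospital"], "ORGANIZATION")

  # a phrase that is both a place and an extra organization stays LOCATION
  lex3 <- build_mock_lexicon(
    gaz, extra_entities = tibble::tibble(phrase = "Paris", tag = "ORGANIZATION")
  )
  expect_identical(lex3$tag[lex3$phrase == "Paris"], "LOCATION")

  # no extras: gazetteer names only
  expect_identical(nrow(build_mock_lexicon(gaz)),
                   length(unique(c(
                     gaz$records$primary_name,
                     unlist(gaz$records$alternate_names)
                   ))))
})

test_that("invalid generator bounds are rejected", {
  d <- withr::local_tempdir()
  expect_error(
    generate_corpus(d, seed = 1, relevant_range = c(3L, 1L)),
    "bounds"
  )
})
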