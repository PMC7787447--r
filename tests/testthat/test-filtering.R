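cand_row <- function(surfaces, tags, prev = NA_character_, nxt = NA_character_) {
  tibble::tibble(
    start = 1L, end = length(surfaces),
    candidate_string = geosift:::join_tokens(surfaces),
    surfaces = list(surfaces), tags = list(tags),
    prev_surface = prev, next_surface = nxt
  )
}

test_that("discard words, keep words and tag sequences drive full-mode filtering", {
  orch <- profile_orchards()
  cands <- dplyr::bind_rows(
    cand_row(c("Carl", "Zeiss", "GmbH", ",", "Jena", ",", "Germany"),
             c("ORGANIZATION", "ORGANIZATION", "ORGANIZATION", "OTHER",
               "LOCATION", "OTHER", "LOCATION")),
    cand_row(c("University", "of", "Helsinki"),
             c("ORGANIZATION", "OTHER", "ORGANIZATION")),
    cand_row(c("John", "Smith"), c("PERSON", "PERSON"))
  )

  full <- filter_candidates(cands, orch, mode = "full")
  expect_identical(full$rejected, c(TRUE, FALSE, TRUE))
  expect_identical(full$rejection_reason[1], "discard_word")
  expect_identical(full$rejection_reason[3], "no_location_tag")

  nof <- filter_candidates(cands, orch, mode = "no_filter")
  expect_false(any(nof$rejected))
})

test_that("citation and company tag-word rules fire on span context", {
  orch <- profile_orchards()
  # LOCATION followed by a trailing PERSON with a year right after the span
  cite <- cand_row(c("Berlin", "Smith"), c("LOCATION", "PERSON"),
                   nxt = "1998")
  out <- filter_candidates(cite, orch, mode = "full")
  expect_true(out$rejected)
  expect_identical(out$rejection_reason, "tag_word_combination")

  # all-ORGANIZATION span wrapped in parentheses is a company attribution
  comp <- cand_row(c("Acme", "Systems"), c("ORGANIZATION", "ORGANIZATION"),
                   prev = "(", nxt = ")")
  out2 <- filter_candidates(comp, orch, mode = "full")
  expect_true(out2$rejected)
})

test_that("locations-only mode truncates spans to their LOCATION core", {
  orch <- profile_orchards()
  cands <- dplyr::bind_rows(
    cand_row(c("Hospital", "in", "Nancy"),
             c("ORGANIZATION", "OTHER", "LOCATION")),
    cand_row(c("University", "of", "Helsinki"),
             c("ORGANIZATION", "OTHER", "ORGANIZATION"))
  )
  out <- filter_candidates(cands, orch, mode = "locations_only")
  expect_false(out$rejected[1])
  expect_identical(out$location_string[1], "Nancy")
  expect_true(out$rejected[2])
})

test_that("keep-word override is absolute over discard and tag rules", {
  orch <- profile_orchards()
  both <- cand_row(c("University", "Works", "Inc"),
                   c("ORGANIZATION", "ORGANIZATION", "ORGANIZATION"))
  out <- filter_candidates(both, orch, mode = "full")
  expect_false(out$rejected)

  set.seed(23)
  for (i in 1:200) {
    cand <- random_candidate()
    res <- filter_candidates(cand, orch, mode = "full")
    if (grepl("\\bUniversity\\b|\\bHospital\\b", cand$candidate_string)) {
      expect_false(res$rejected)
    }
  }
})

test_that("cleaning strips trailing junk, is idempotent, and never lengthens", {
  expect_identical(clean_location_string("Florence, Italy,"), "Florence, Italy")
  expect_identical(clean_location_string("Bern in"), "Bern")
  expect_identical(clean_location_string("Nancy (East of France)"),
                   "Nancy (East of France)")
  expect_identical(clean_location_string("Avignon ("), "Avignon")
  expect_identical(clean_location_string(",. ("), "")

  set.seed(29)
  for (i in 1:200) {
    s <- random_string()
    once <- clean_location_string(s)
    expect_identical(clean_location_string(once), once)
    expect_lte(nchar(once), nchar(s))
  }
})

test_that("full-mode kept strings are a subset of no-filter kept strings", {
  orch <- profile_orchards()
  set.seed(31)
  for (i in 1:60) {
    cands <- purrr::list_rbind(purrr::map(1:5, ~ random_candidate()))
    full <- filter_candidates(cands, orch, mode = "full")
    nof <- filter_candidates(cands, orch, mode = "no_filter")
    kept_full <- full$location_string[!full$rejected]
    kept_nof <- nof$location_string[!nof$rejected]
    expect_true(all(kept_full %in% kept_nof))
    # filtering never invents strings
    expect_true(all(kept_full %in% clean_location_string(cands$candidate_string)))
  }
})

test_that("deduplication folds case and diacritics, keeping the first occurrence", {
  locs <- tibble::tibble(
    location_string = c("Seville, Spain", "seville, Spain", "Seville"),
    para_idx = 1:3, sentence_idx = 1L, start = 1L
  )
  out <- deduplicate_locations(locs)
  expect_identical(out$location_string, c("Seville, Spain", "Seville"))
  expect_identical(out$n_duplicates[out$location_string == "Seville, Spain"], 1L)

  trip <- tibble::tibble(
    location_string = rep("Zürich", 3), para_idx = 1:3,
    sentence_idx = 1L, start = 1L
  )
  out2 <- deduplicate_locations(trip)
  expect_identical(nrow(out2), 1L)
  expect_identical(out2$n_duplicates, 2L)
})
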