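test_that("heading matching follows profile word lists, case-insensitively", {
  orch <- profile_orchards()
  canc <- profile_cancer()

  expect_true(match_heading("Study site", orch)$matched)
  expect_true(match_heading("2.1 Study site description", orch)$matched)
  expect_true(match_heading("STUDY AREA", orch)$matched)
  expect_true(match_heading("Patients and samples", canc)$matched)
  expect_false(match_heading("Results", orch)$matched)
  expect_false(match_heading("Results", canc)$matched)
  # references headings never match, whatever the pattern list says
  expect_false(match_heading("References", orch)$matched)
  expect_false(match_heading(NA_character_, orch)$matched)
  expect_false(match_heading("", orch)$matched)
})

doc_with_sections <- function(headings, texts, source = "structured_xml",
                              title = NULL, refs = rep(FALSE, length(headings))) {
  article_document(
    "fix", title,
    tibble::tibble(
      section_idx = seq_along(headings), heading = headings,
      is_references = refs, para_idx = seq_along(headings), text = texts
    ),
    source
  )
}

test_that("XML representation is preferred whenever it has a heading match", {
  orch <- profile_orchards()
  xml_doc <- doc_with_sections(c("Introduction", "Methods"),
                               c("intro text", "methods text"),
                               title = "A title")
  text_doc <- parse_plain_text(
    "Study area\n\nPlain text methods paragraph.", article_id = "fix"
  )

  t1 <- extract_target_text(xml_doc, text_doc, orch)
  expect_identical(t1$source_used, "structured_xml")
  expect_identical(t1$targets$text, "methods text")
  expect_identical(t1$title, "A title")

  # no XML match: fall back to plain text paragraph beginnings
  xml_nomatch <- doc_with_sections("Introduction", "intro text")
  t2 <- extract_target_text(xml_nomatch, text_doc, orch)
  expect_identical(t2$source_used, "plain_text")
  expect_true(any(grepl("Plain text methods", t2$targets$text)))

  # neither matches: empty targets, with a message
  expect_message(
    t3 <- extract_target_text(xml_nomatch, NULL, profile_cancer()),
    "No relevant headings"
  )
  expect_identical(nrow(t3$targets), 0L)

  expect_error(extract_target_text(NULL, NULL, orch), "at least one",
               ignore.case = TRUE)
})

test_that("whole-article mode returns all paragraphs except references", {
  doc <- doc_with_sections(
    c("Intro", "Methods", "References", "References", "References"),
    paste0("p", 1:5),
    refs = c(FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  out <- whole_article_text(doc)
  expect_identical(out$text, c("p1", "p2"))

  doc2 <- doc_with_sections(c("Intro", "Methods"), c("p1", "p2"))
  expect_identical(whole_article_text(doc2)$text, c("p1", "p2"))

  doc3 <- parse_plain_text("Body.\n\nLITERATURE CITED\n\nref one",
                           article_id = "lc")
  expect_identical(whole_article_text(doc3)$text, "Body.")
})

test_that("adding a heading pattern never decreases the number of targeted paragraphs", {
  set.seed(7)
  headings <- c("Introduction", "Methods", "Study site", "Results",
                "Sampling", "Discussion", "Field observations")
  for (rep in 1:40) {
    k <- sample(2:6, 1)
    hs <- sample(headings, k, replace = TRUE)
    doc <- doc_with_sections(hs, paste0("text ", seq_len(k)))
    base <- domain_profile("base", heading_patterns = c("methods?", "study site"))
    wider <- domain_profile("wide",
                            heading_patterns = c("methods?", "study site",
                                                 "sampling", "field"))
    n_base <- nrow(suppressMessages(extract_target_text(doc, NULL, base))$targets)
    n_wide <- nrow(suppressMessages(extract_target_text(doc, NULL, wider))$targets)
    expect_gte(n_wide, n_base)
  }
})
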