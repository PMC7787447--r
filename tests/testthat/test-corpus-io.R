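jats_fixture <- function() {
  paste0(
    "<article><front><article-meta><title-group>",
    "<article-title>Orchard biodiversity in Spain</article-title>",
    "</title-group></article-meta></front><body>",
    "<sec><title>Materials</title><p>Intro paragraph.</p>",
    "<sec><title>Study area</title><p>Sites were in Seville.</p>",
    "<p>Second site paragraph.</p></sec></sec>",
    "<sec><title>References</title><p>Smith J (1998) A paper.</p></sec>",
    "</body></article>"
  )
}

test_that("structured XML parsing extracts title and flattens nested sections depth-first", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(jats_fixture(), path)
  doc <- parse_structured_article(path, article_id = "a1")

  expect_s3_class(doc, "article_document")
  expect_identical(doc$title, "Orchard biodiversity in Spain")
  expect_identical(doc$source_kind, "structured_xml")
  # depth-first: Materials paragraph, then both Study area paragraphs
  expect_identical(
    doc$paragraphs$heading,
    c("Materials", "Study area", "Study area", "References")
  )
  expect_identical(
    doc$paragraphs$text[1:3],
    c("Intro paragraph.", "Sites were in Seville.", "Second site paragraph.")
  )
  expect_identical(doc$paragraphs$is_references,
                   c(FALSE, FALSE, FALSE, TRUE))
  # no body paragraph is dropped
  expect_setequal(
    doc$paragraphs$text,
    c("Intro paragraph.", "Sites were in Seville.",
      "Second site paragraph.", "Smith J (1998) A paper.")
  )
})

test_that("XML without body content and malformed XML raise informative errors", {
  empty <- withr::local_tempfile(fileext = ".xml")
  writeLines("<article><front/><body></body></article>", empty)
  expect_error(parse_structured_article(empty, article_id = "e1"),
               "no body content")

  nobody <- withr::local_tempfile(fileext = ".xml")
  writeLines("<article><front/></article>", nobody)
  expect_error(parse_structured_article(nobody, article_id = "e2"),
               "no body content")

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<article><body><p>unclosed", bad)
  expect_error(parse_structured_article(bad, article_id = "e3"),
               "e3")
})

test_that("plain text splits paragraphs on blank lines and flags references", {
  doc <- parse_plain_text("para1\n\npara2", article_id = "p1")
  expect_identical(doc$paragraphs$text, c("para1", "para2"))
  expect_null(doc$title)
  expect_identical(doc$source_kind, "plain_text")

  txt <- paste("First paragraph here.", "Second paragraph here.",
               "References", "Smith J (1998) A paper.", sep = "\n\n")
  doc2 <- parse_plain_text(txt, article_id = "p2")
  expect_identical(doc2$paragraphs$is_references, c(FALSE, FALSE, TRUE, TRUE))

  txt3 <- paste("Body text.", "LITERATURE CITED", "Ref one.", sep = "\n\n")
  doc3 <- parse_plain_text(txt3, article_id = "p3")
  expect_identical(doc3$paragraphs$is_references, c(FALSE, TRUE, TRUE))

  expect_error(parse_plain_text("", article_id = "p4"), "empty")
  expect_error(parse_plain_text("   \n \n ", article_id = "p5"), "empty")
})

test_that("plain-text parsing round-trips content up to blank-line normalization", {
  set.seed(42)
  for (rep in 1:25) {
    paras <- replicate(sample(1:6, 1), paste(
      sample(c("alpha", "bravo", "Study", "site", "text."),
             sample(1:8, 1), replace = TRUE),
      collapse = " "
    ))
    txt <- paste(paras, collapse = "\n\n")
    doc <- parse_plain_text(txt, article_id = "rt")
    expect_identical(paste(doc$paragraphs$text, collapse = "\n\n"), txt)
  }
})
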