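#' Article document model
#'
#' Both article representations — structured XML (JATS/NLM-style, as emitted
#' by PDF-to-XML converters) and plain text — parse into the same light
#' container: an `article_document` holding the title (or `NULL` when the
#' representation carries none; distinct from an empty string) and a tibble
#' of paragraphs in document order with their section heading and a
#' references flag.
#'
#' @param article_id Opaque identifier.
#' @param title Character scalar or `NULL`.
#' @param paragraphs Tibble with columns `section_idx`, `heading` (NA for
#'   untitled sections), `is_references`, `para_idx`, `text`.
#' @param source_kind `"structured_xml"` or `"plain_text"`.
#' @return An `article_document`.
#' @export
article_document <- function(article_id, title, paragraphs, source_kind) {
  stopifnot(source_kind %in% c("structured_xml", "plain_text"))
  stopifnot(is.null(title) || (is.character(title) && length(title) == 1))
  paragraphs <- as_tibble(paragraphs)
  needed <- c("section_idx", "heading", "is_references", "para_idx", "text")
  stopifnot(all(needed %in% names(paragraphs)))
  structure(
    list(
      article_id = article_id,
      title = title,
      paragraphs = paragraphs[needed],
      source_kind = source_kind
    ),
    class = "article_document"
  )
}

#' @export
print.article_document <- function(x, ...) {
  cat("<article_document> ", x$article_id, " [", x$source_kind, "]\n", sep = "")
  cat("  title: ", if (is.null(x$title)) "<absent>" else shQuote(x$title), "\n",
      sep = "")
  cat("  ", nrow(x$paragraphs), " paragraphs in ",
      length(unique(x$paragraphs$section_idx)), " sections\n", sep = "")
  invisible(x)
}

heading_is_references <- function(heading, references_patterns) {
  if (length(heading) == 0) return(logical(0))
  pat <- paste0("^\\s*(", paste(references_patterns, collapse = "|"), ")\\s*$")
  !is.na(heading) & str_detect(heading, regex(pat, ignore_case = TRUE))
}

#' Parse a structured (JATS/NLM-style) XML article
#'
#' Extracts the title and all body paragraphs in document order. Nested
#' sections are flattened depth-first with each subsection's own heading
#' retained. Both JATS `<sec><title>` and the NLM converter variant are
#' accepted; unknown body elements are skipped with a warning rather than
#' failing.
#'
#' @param path Path to an XML file, or an `xml2` document.
#' @param article_id Identifier for error messages and provenance; defaults
#'   to the file name without extension.
#' @param references_patterns Whole-line patterns marking references
#'   headings.
#' @return An [article_document()] with `source_kind = "structured_xml"`.
#' @export
parse_structured_article <- function(path,
                                     article_id = NULL,
                                     references_patterns = c(
                                       "references", "bibliography",
                                       "literature cited"
                                     )) {
  if (inherits(path, "xml_document")) {
    doc <- path
    article_id <- article_id %||% "article"
  } else {
    article_id <- article_id %||% tools::file_path_sans_ext(basename(path))
    doc <- tryCatch(
      xml2::read_xml(path, encoding = "UTF-8"),
      error = function(e) {
        abort(paste0("Malformed XML for article '", article_id, "': ",
                     conditionMessage(e)))
      }
    )
  }

  title_node <- xml2::xml_find_first(
    doc, ".//article-title | .//front//title-group/title | /article/title"
  )
  title <- if (inherits(title_node, "xml_missing")) NULL else {
    t <- str_trim(xml2::xml_text(title_node))
    if (nzchar(t)) t else NULL
  }

  body <- xml2::xml_find_first(doc, ".//body")
  if (inherits(body, "xml_missing")) {
    abort(paste0("Article '", article_id, "' has no body content."))
  }

  rows <- list()
  section_counter <- 0L
  walk_sec <- function(node, inherited_heading = NA_character_) {
    kids <- xml2::xml_children(node)
    heading <- inherited_heading
    pending <- character()
    flush <- function() {
      if (length(pending) > 0) {
        section_counter <<- section_counter + 1L
        rows[[length(rows) + 1L]] <<- tibble(
          section_idx = section_counter,
          heading = heading,
          text = pending
        )
        pending <<- character()
      }
    }
    for (kid in kids) {
      nm <- xml2::xml_name(kid)
      if (nm == "title") {
        flush()
        t <- str_trim(xml2::xml_text(kid))
        heading <- if (nzchar(t)) t else NA_character_
      } else if (nm == "p") {
        t <- str_trim(xml2::xml_text(kid))
        if (nzchar(t)) pending <- c(pending, t)
      } else if (nm == "sec") {
        flush()
        walk_sec(kid)
      } else {
        warn(paste0("Skipping unknown element <", nm, "> in article '",
                    article_id, "'."))
      }
    }
    flush()
  }
  walk_sec(body)

  if (length(rows) == 0) {
    abort(paste0("Article '", article_id, "' has no body content."))
  }
  paragraphs <- list_rbind(rows) |>
    mutate(
      is_references = heading_is_references(.data$heading, references_patterns),
      para_idx = row_number()
    )
  article_document(article_id, title, paragraphs, "structured_xml")
}

#' Parse a plain-text article representation
#'
#' Paragraphs are delimited by blank lines. The document forms one synthetic
#' untitled section; once a paragraph matching a references-heading pattern
#' is seen, that paragraph and all following ones are flagged
#' `is_references`. Each paragraph's "beginning" — the first line, capped at
#' 120 characters — is what heading matching later inspects (headings
#' converted from PDF usually occupy one short line).
#'
#' @param text Character scalar (the whole file) or a path to a UTF-8 text
#'   file.
#' @inheritParams parse_structured_article
#' @return An [article_document()] with `source_kind = "plain_text"`.
#' @export
parse_plain_text <- function(text,
                             article_id = "article",
                             references_patterns = c(
                               "references", "bibliography", "literature cited"
                             )) {
  if (length(text) == 1 && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    article_id <- if (identical(article_id, "article")) {
      tools::file_path_sans_ext(basename(text))
    } else article_id
    raw <- readBin(text, what = "raw", n = file.size(text))
    text <- rawToChar(raw)
    Encoding(text) <- "UTF-8"
    if (!validUTF8(text)) {
      warn(paste0("Undecodable bytes in '", article_id,
                  "' replaced with U+FFFD."))
      text <- iconv(text, "UTF-8", "UTF-8", sub = "�")
    }
  }
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  if (is.na(text) || !nzchar(str_trim(text))) {
    abort(paste0("Article '", article_id, "' is empty."))
  }
  chunks <- stringi::stri_split_regex(text, "\\n[ \\t]*\\n+")[[1]]
  chunks <- str_trim(chunks)
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0) {
    abort(paste0("Article '", article_id, "' is empty."))
  }
  begins <- paragraph_beginning(chunks)
  in_refs <- cumsum(heading_is_references(begins, references_patterns)) > 0
  paragraphs <- tibble(
    section_idx = 1L + as.integer(in_refs),
    heading = NA_character_,
    is_references = in_refs,
    para_idx = seq_along(chunks),
    text = chunks
  )
  article_document(article_id, NULL, paragraphs, "plain_text")
}

# First line of each paragraph, capped at 120 characters: the span that
# heading patterns are matched against for plain-text documents.
paragraph_beginning <- function(paragraphs) {
  first_line <- map_chr(
    stringi::stri_split_regex(paragraphs, "\\n"),
    ~ str_trim(.x[1])
  )
  str_sub(first_line, 1, 120)
}
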