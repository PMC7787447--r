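#' Match a heading against a profile's heading patterns
#'
#' Matching is case-insensitive substring-with-word-boundary, so numbered or
#' decorated headings like "2.1 Study site description" match the pattern
#' "study site". References headings never match, whatever the pattern list
#' says.
#'
#' @param heading Character vector of headings (NA allowed).
#' @param profile A [domain_profile()].
#' @return A tibble with one row per input heading: `heading`, `matched`
#'   (logical), `pattern_id` (index of the first matching pattern, NA when
#'   unmatched).
#' @examples
#' match_heading("Study site", profile_orchards())
#' @export
match_heading <- function(heading, profile) {
  stopifnot(inherits(profile, "domain_profile"))
  n <- length(heading)
  matched <- rep(FALSE, n)
  pattern_id <- rep(NA_integer_, n)
  usable <- !is.na(heading) & nzchar(str_trim(heading))
  is_refs <- heading_is_references(heading, profile$references_patterns)
  for (i in seq_along(profile$heading_patterns)) {
    pat <- regex(
      paste0("\\b(", profile$heading_patterns[i], ")\\b"),
      ignore_case = TRUE
    )
    hit <- usable & !is_refs & is.na(pattern_id) & str_detect(heading, pat)
    hit[is.na(hit)] <- FALSE
    matched[hit] <- TRUE
    pattern_id[hit] <- i
  }
  tibble(heading = heading, matched = matched, pattern_id = pattern_id)
}

# Plain-text heading candidate: a short line (or all-caps / numbered lead)
# that likely started a new section in the original PDF layout.
looks_like_heading <- function(paragraph_beginnings, paragraphs) {
  one_line <- !str_detect(paragraphs, "\\n")
  short <- str_length(paragraph_beginnings) <= 60
  sentence_like <- str_detect(paragraph_beginnings, "[.!?]$")
  allcaps <- str_detect(paragraph_beginnings, "^[A-Z0-9 .:\\-]+$") &
    str_detect(paragraph_beginnings, "[A-Z]")
  numbered <- str_detect(paragraph_beginnings, "^\\d+(\\.\\d+)*\\.?\\s+\\S")
  (one_line & short & !sentence_like) | allcaps | numbered
}

#' Select the relevant portions of an article
#'
#' Runs heading matching over the structured-XML representation and, as a
#' fallback, the plain-text representation, and returns the paragraphs under
#' matched headings. The XML representation is preferred: the plain-text
#' document is only used when it has a heading match and the XML document
#' has none (or is absent). For plain text, a matched paragraph beginning
#' contributes that paragraph and the following paragraphs up to the next
#' heading-like paragraph, capped at 10 paragraphs. The title is taken from
#' the XML document when the profile mines titles.
#'
#' @param xml_doc,text_doc [article_document()]s (either may be `NULL`, not
#'   both).
#' @param profile A [domain_profile()].
#' @return A `targeted_text` list: `source_used`, `title` (or `NULL`), and
#'   `targets`, a tibble with columns `heading`, `pattern_id`, `para_idx`,
#'   `text`.
#' @export
extract_target_text <- function(xml_doc = NULL, text_doc = NULL, profile) {
  stopifnot(inherits(profile, "domain_profile"))
  if (is.null(xml_doc) && is.null(text_doc)) {
    abort("At least one of `xml_doc`, `text_doc` must be supplied.")
  }

  title <- NULL
  if (profile$use_title && !is.null(xml_doc)) title <- xml_doc$title
  if (profile$use_title && is.null(title) && !is.null(text_doc)) {
    title <- text_doc$title
  }

  xml_targets <- NULL
  if (!is.null(xml_doc)) {
    paras <- xml_doc$paragraphs
    hm <- match_heading(
      paras$heading[!duplicated(paras$section_idx)], profile
    )
    sec_ids <- unique(paras$section_idx)
    matched_secs <- sec_ids[hm$matched]
    pat_by_sec <- stats::setNames(hm$pattern_id, sec_ids)
    if (length(matched_secs) > 0) {
      xml_targets <- paras |>
        filter(.data$section_idx %in% matched_secs, !.data$is_references) |>
        mutate(pattern_id = unname(pat_by_sec[as.character(.data$section_idx)])) |>
        select("heading", "pattern_id", "para_idx", "text")
    }
  }
  if (!is.null(xml_targets) && nrow(xml_targets) > 0) {
    return(structure(
      list(source_used = "structured_xml", title = title, targets = xml_targets),
      class = "targeted_text"
    ))
  }

  text_targets <- NULL
  if (!is.null(text_doc)) {
    paras <- filter(text_doc$paragraphs, !.data$is_references)
    begins <- paragraph_beginning(paras$text)
    hm <- match_heading(begins, profile)
    headingish <- looks_like_heading(begins, paras$text)
    rows <- list()
    i <- 1
    while (i <= nrow(paras)) {
      if (hm$matched[i]) {
        span_end <- i
        limit <- min(nrow(paras), i + 9)  # target span capped at 10 paragraphs
        j <- i + 1
        while (j <= limit && !(headingish[j])) {
          span_end <- j
          j <- j + 1
        }
        rows[[length(rows) + 1L]] <- tibble(
          heading = begins[i],
          pattern_id = hm$pattern_id[i],
          para_idx = paras$para_idx[i:span_end],
          text = paras$text[i:span_end]
        )
        i <- span_end + 1
      } else {
        i <- i + 1
      }
    }
    if (length(rows) > 0) text_targets <- distinct(list_rbind(rows))
  }
  if (!is.null(text_targets) && nrow(text_targets) > 0) {
    return(structure(
      list(source_used = "plain_text", title = title, targets = text_targets),
      class = "targeted_text"
    ))
  }

  inform("No relevant headings matched; returning empty targets.")
  structure(
    list(
      source_used = if (!is.null(xml_doc)) "structured_xml" else "plain_text",
      title = title,
      targets = tibble(
        heading = character(), pattern_id = integer(),
        para_idx = integer(), text = character()
      )
    ),
    class = "targeted_text"
  )
}

#' All paragraphs of an article, excluding references
#'
#' The whole-article processing mode (used when section targeting is turned
#' off) feeds every paragraph except those in a references section to
#' location identification.
#'
#' @param doc An [article_document()].
#' @return Tibble with columns `heading`, `pattern_id`, `para_idx`, `text`.
#' @export
whole_article_text <- function(doc) {
  stopifnot(inherits(doc, "article_document"))
  doc$paragraphs |>
    filter(!.data$is_references) |>
    mutate(pattern_id = NA_integer_) |>
    select("heading", "pattern_id", "para_idx", "text")
}
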