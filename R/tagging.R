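#' Entity-tagger contract
#'
#' The pipeline is agnostic to the named-entity engine behind it. Any tagger
#' is an object created by `entity_tagger()`: a pure function mapping an
#' ordered vector of token surfaces to one tag per token from
#' `{LOCATION, PERSON, ORGANIZATION, OTHER}` (same input, same output).
#' Adapters for pretrained 3-class NER models plug in here; the bundled
#' [lexicon_tagger()] is a deterministic stand-in used for testing and
#' synthetic corpora.
#'
#' @param id Backend name recorded in provenance.
#' @param tag_fn `function(surfaces)` returning a character vector of tags,
#'   one per surface.
#' @return An `entity_tagger` object.
#' @export
entity_tagger <- function(id, tag_fn) {
  stopifnot(is.character(id), is.function(tag_fn))
  structure(list(id = id, tag_fn = tag_fn), class = "entity_tagger")
}

ner_tag_values <- c("LOCATION", "PERSON", "ORGANIZATION", "OTHER")

tag_tokens <- function(tagger, surfaces) {
  stopifnot(inherits(tagger, "entity_tagger"))
  if (length(surfaces) == 0) return(character())
  tags <- tagger$tag_fn(surfaces)
  if (length(tags) != length(surfaces) || !all(tags %in% ner_tag_values)) {
    abort(paste0(
      "Tagger '", tagger$id, "' violated the contract: expected ",
      length(surfaces), " tags from {", paste(ner_tag_values, collapse = ", "),
      "}."
    ))
  }
  tags
}

#' Deterministic lexicon-based entity tagger
#'
#' Tags tokens by greedy longest-phrase match against a lexicon of (phrase,
#' tag) pairs. Matching is case-sensitive on normalized (diacritic-free)
#' surfaces, so "Nancy" the place matches while "nancy" in prose does not.
#' Unmatched tokens are tagged OTHER.
#'
#' @param lexicon A tibble/data frame with columns `phrase`, `tag`, or a path
#'   to a two-column TSV file (no header: phrase, tag).
#' @return An [entity_tagger()].
#' @export
lexicon_tagger <- function(lexicon) {
  if (is.character(lexicon) && length(lexicon) == 1) {
    lexicon <- readr::read_tsv(
      lexicon, col_names = c("phrase", "tag"),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  lexicon <- as_tibble(lexicon)
  stopifnot(all(c("phrase", "tag") %in% names(lexicon)))
  if (!all(lexicon$tag %in% ner_tag_values)) {
    abort("Lexicon tags must be LOCATION, PERSON, ORGANIZATION or OTHER.")
  }
  phrase_tokens <- map(normalize_text(lexicon$phrase), tokenize)
  lengths <- map_int(phrase_tokens, length)
  ord <- order(-lengths)  # longest phrases take precedence
  phrase_tokens <- phrase_tokens[ord]
  tags <- lexicon$tag[ord]
  lengths <- lengths[ord]

  entity_tagger("lexicon", function(surfaces) {
    norm <- normalize_text(surfaces)
    out <- rep("OTHER", length(surfaces))
    i <- 1
    while (i <= length(surfaces)) {
      matched <- FALSE
      for (k in seq_along(phrase_tokens)) {
        len <- lengths[k]
        if (len == 0 || i + len - 1 > length(surfaces)) next
        if (identical(norm[i:(i + len - 1)], phrase_tokens[[k]])) {
          out[i:(i + len - 1)] <- tags[k]
          i <- i + len
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1
    }
    out
  })
}

#' Segment a paragraph into tagged sentences
#'
#' Normalizes the paragraph, splits it into sentences with an
#' abbreviation-aware rule-based splitter (scientific abbreviations such as
#' "Fig.", "et al.", "e.g." never end a sentence, and sentence boundaries
#' are never placed inside a parenthetical shorter than 60 characters),
#' tokenizes each sentence, and attaches part-of-speech and named-entity
#' tags.
#'
#' @param paragraph Character scalar.
#' @param tagger An [entity_tagger()].
#' @return A tibble with one row per sentence: `sentence_idx`, `raw_text`,
#'   and a `tokens` list-column of tibbles (`surface`, `normalized`,
#'   `pos_tag`, `ner_tag`).
#' @export
segment_and_tag <- function(paragraph, tagger) {
  stopifnot(is.character(paragraph), length(paragraph) == 1)
  sentences <- split_sentences(normalize_text(paragraph))
  if (length(sentences) == 0) {
    return(tibble(
      sentence_idx = integer(), raw_text = character(), tokens = list()
    ))
  }
  tokens <- map(sentences, function(s) {
    surfaces <- tokenize(s)
    if (length(surfaces) == 0 || all(is.na(surfaces))) {
      return(tibble(
        surface = character(), normalized = character(),
        pos_tag = character(), ner_tag = character()
      ))
    }
    tibble(
      surface = surfaces,
      normalized = normalize_text(surfaces),
      pos_tag = pos_tag_tokens(surfaces),
      ner_tag = tag_tokens(tagger, surfaces)
    )
  })
  tibble(
    sentence_idx = seq_along(sentences),
    raw_text = sentences,
    tokens = tokens
  )
}
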