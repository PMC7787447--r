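#' Normalize text to a canonical ASCII-friendly form
#'
#' Compatibility-decomposes the input (NFKD), strips combining diacritical
#' marks, recomposes, and collapses all runs of whitespace (including
#' non-breaking and other exotic spaces) to single ASCII spaces. Leading and
#' trailing whitespace is trimmed. The function is idempotent:
#' `normalize_text(normalize_text(s))` equals `normalize_text(s)`.
#'
#' Location strings pass through this normalization before candidate
#' matching, deduplication and gazetteer lookup, so that e.g. `"Zürich"` and
#' `"Zurich"` resolve identically.
#'
#' @param s Character vector.
#' @return Character vector of the same length.
#' @examples
#' normalize_text("Zürich")      # "Zurich"
#' normalize_text("São  Paulo")  # "Sao Paulo"
#' @export
normalize_text <- function(s) {
  if (length(s) == 0) return(character())
  out <- stringi::stri_trans_general(s, "Any-NFKD; [:Nonspacing Mark:] Remove; Any-NFC")
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  stringi::stri_trim_both(out)
}

# Abbreviations whose trailing period never ends a sentence; matched at a
# word boundary (so "ca." does not fire inside "Africa.").
.sentence_abbrevs <- c(
  "Fig", "Figs", "et al", "e\\.g", "i\\.e", "approx", "ca", "cf",
  "vs", "Dr", "Prof", "St", "No", "sp", "spp", "var"
)

# Protect sentence-final punctuation inside abbreviations and short
# parentheticals with a placeholder character, split, then restore.
.protect_char <- rawToChar(as.raw(1L))

.protect_q <- rawToChar(as.raw(2L))
.protect_x <- rawToChar(as.raw(3L))

split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- text
  abbrev_pat <- paste0("\\b(", paste(.sentence_abbrevs, collapse = "|"), ")\\.")
  s <- stringi::stri_replace_all_regex(s, abbrev_pat,
                                       paste0("$1", .protect_char))
  # Parentheticals shorter than 60 characters never contain a sentence break
  # (they are typically coordinates, citations or company addresses).
  protect_paren <- function(piece) {
    piece <- stringi::stri_replace_all_fixed(piece, ".", .protect_char)
    piece <- stringi::stri_replace_all_fixed(piece, "?", .protect_q)
    stringi::stri_replace_all_fixed(piece, "!", .protect_x)
  }
  m <- stringi::stri_extract_all_regex(s, "\\([^()]{0,58}\\)")[[1]]
  if (!all(is.na(m))) {
    for (piece in unique(m[!is.na(m)])) {
      s <- stringi::stri_replace_all_fixed(s, piece, protect_paren(piece))
    }
  }
  parts <- stringi::stri_split_regex(
    s, "(?<=[.!?])\\s+(?=[\"'(\\[]?[A-Z0-9])"
  )[[1]]
  parts <- stringi::stri_replace_all_fixed(parts, .protect_char, ".")
  parts <- stringi::stri_replace_all_fixed(parts, .protect_q, "?")
  parts <- stringi::stri_replace_all_fixed(parts, .protect_x, "!")
  parts <- stringi::stri_trim_both(parts)
  parts[nzchar(parts)]
}

# Word/punctuation tokenizer. Words keep internal hyphens and apostrophes;
# every other non-space character is its own token.
tokenize <- function(sentence) {
  stringi::stri_extract_all_regex(
    sentence,
    "[\\p{L}\\p{N}]+(?:['\\-][\\p{L}\\p{N}]+)*|[^\\p{L}\\p{N}\\s]"
  )[[1]]
}

# Coarse rule-based part-of-speech labels carried for provenance: the
# downstream pipeline consumes NER tags only.
pos_tag_tokens <- function(surfaces) {
  dplyr::case_when(
    stringr::str_detect(surfaces, "^[\\p{N}]+([.,][\\p{N}]+)?$") ~ "CD",
    stringr::str_detect(surfaces, "^[^\\p{L}\\p{N}]$") ~ "PUNCT",
    str_to_lower(surfaces) %in% c(
      "in", "on", "of", "at", "near", "from", "to", "by", "with", "upon"
    ) ~ "IN",
    stringr::str_detect(surfaces, "^\\p{Lu}") ~ "NNP",
    TRUE ~ "NN"
  )
}

# Join token surfaces into a naturally reading string: no space before
# closing punctuation, none after an opening parenthesis.
join_tokens <- function(surfaces) {
  if (length(surfaces) == 0) return("")
  out <- surfaces[1]
  for (i in seq_along(surfaces)[-1]) {
    tok <- surfaces[i]
    prev <- surfaces[i - 1]
    no_space <- tok %in% c(",", ")", ".", ";", ":", "?", "!", "'") || prev == "("
    out <- paste0(out, if (no_space) "" else " ", tok)
  }
  out
}
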