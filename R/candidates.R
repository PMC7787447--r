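#' Assemble location candidates from a tagged sentence
#'
#' The high-recall chunking stage. Maximal token spans are formed around
#' named-entity tokens: runs of up to three non-entity tokens *between*
#' entities are bridged when every token in the run is a connector word
#' ("in", "upon", ...), a comma/parenthesis/period, a two-letter state
#' abbreviation, or a word from the profile's candidate-extension lexicon
#' (cardinal directions and feature-type words). Span edges may extend
#' beyond the outer entities with extension-lexicon words, a state
#' abbreviation (optionally after a comma, as in "Madison, WI"), or a
#' closing parenthesis that balances one opened inside the span, so that
#' "Nancy (East of France)" is kept as one candidate rather than "Nancy"
#' and "France" separately. No relevance judgment happens here; that is the
#' filtering stage's job.
#'
#' @param tokens A token tibble as produced by [segment_and_tag()] (columns
#'   `surface`, `normalized`, `ner_tag`).
#' @param profile A [domain_profile()].
#' @return A tibble with one row per candidate, spans non-overlapping and
#'   ordered left-to-right: `start`, `end` (token indices),
#'   `candidate_string`, list-columns `surfaces` and `tags`, and the
#'   neighbouring token surfaces `prev_surface` / `next_surface` (NA at
#'   sentence edges) used by the tag-word filter rules.
#' @export
assemble_candidates <- function(tokens, profile) {
  stopifnot(inherits(profile, "domain_profile"))
  tokens <- as_tibble(tokens)
  n <- nrow(tokens)
  empty <- tibble(
    start = integer(), end = integer(), candidate_string = character(),
    surfaces = list(), tags = list(),
    prev_surface = character(), next_surface = character()
  )
  if (n == 0) return(empty)

  cls <- classify_tokens(tokens, profile)
  ents <- which(cls$entity)
  if (length(ents) == 0) return(empty)

  # group entities across bridgeable gaps of <= 3 tokens
  groups <- list(c(ents[1], ents[1]))
  for (e in ents[-1]) {
    last <- groups[[length(groups)]][2]
    gap <- if (e - last <= 1) integer() else (last + 1):(e - 1)
    if (length(gap) <= 3 && all(cls$bridge[gap])) {
      groups[[length(groups)]][2] <- e
    } else {
      groups[[length(groups) + 1L]] <- c(e, e)
    }
  }

  spans <- list()
  prev_end <- 0L
  for (g in groups) {
    a <- g[1]; b <- g[2]
    start <- a
    while (start - 1 > prev_end && a - (start - 1) <= 3 && cls$ext[start - 1]) {
      start <- start - 1L
    }
    end <- b
    repeat {
      nxt <- end + 1L
      if (nxt > n || nxt - b > 3) break
      if (cls$ext[nxt] || cls$state[nxt]) {
        end <- nxt
      } else if (tokens$surface[nxt] == "," && nxt + 1 <= n &&
                 nxt + 1 - b <= 3 && cls$state[nxt + 1]) {
        end <- nxt + 1L
      } else if (tokens$surface[nxt] == ")" &&
                 open_parens(tokens$surface[start:end]) > 0) {
        end <- nxt
      } else {
        break
      }
    }
    spans[[length(spans) + 1L]] <- c(start, end)
    prev_end <- end
  }

  map(spans, function(sp) {
    idx <- sp[1]:sp[2]
    tibble(
      start = sp[1], end = sp[2],
      candidate_string = join_tokens(tokens$surface[idx]),
      surfaces = list(tokens$surface[idx]),
      tags = list(tokens$ner_tag[idx]),
      prev_surface = if (sp[1] > 1) tokens$surface[sp[1] - 1] else NA_character_,
      next_surface = if (sp[2] < n) tokens$surface[sp[2] + 1] else NA_character_
    )
  }) |> list_rbind()
}

# Token classes the bridging predicate is defined over.
classify_tokens <- function(tokens, profile) {
  lower <- str_to_lower(tokens$normalized)
  entity <- tokens$ner_tag != "OTHER"
  ext <- lower %in% profile$candidate_extension_lexicon
  state <- tokens$surface %in% profile$state_abbreviations
  conn <- lower %in% profile$connector_words
  punct <- tokens$surface %in% c(",", "(", ")", ".")
  list(
    entity = entity, ext = ext, state = state, conn = conn,
    bridge = ext | state | conn | punct
  )
}

open_parens <- function(surfaces) {
  sum(surfaces == "(") - sum(surfaces == ")")
}
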