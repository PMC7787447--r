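rejection_reasons <- c(
  "no_location_tag", "discard_word", "tag_word_combination", "empty_after_clean"
)

word_match <- function(strings, words, ignore_case) {
  if (length(words) == 0) return(rep(FALSE, length(strings)))
  escaped <- stringr::str_escape(words)
  pat <- regex(
    paste0("\\b(", paste(escaped, collapse = "|"), ")\\b"),
    ignore_case = ignore_case
  )
  str_detect(strings, pat)
}

#' Filter location candidates down to content locations
#'
#' The precision stage. In `mode = "full"` the rules apply in order:
#'
#' 1. *keep-word override*: a candidate containing a keep word
#'    (case-insensitive; "University", "Hospital", ...) is always kept —
#'    it survives every discard and tag rule;
#' 2. *discard words*: candidates containing a discard word
#'    (case-sensitive; "Inc", "GmbH", ...) are rejected as company
#'    locations;
#' 3. *tag sequence*: candidates with no LOCATION-tagged token anywhere in
#'    the span are rejected;
#' 4. *token (tag, word) combination rules* from the profile (citations,
#'    company parentheticals; see [default_tag_word_rules()]).
#'
#' `mode = "locations_only"` keeps only candidates whose span includes a
#' LOCATION-tagged token and truncates each span to the range between its
#' first and last LOCATION token. `mode = "no_filter"` passes every
#' candidate through unrejected. Kept strings are cleaned with
#' [clean_location_string()]; a string that is empty after cleaning is
#' rejected with reason `empty_after_clean`. Every rejection carries its
#' reason.
#'
#' @param candidates A candidate tibble from [assemble_candidates()]
#'   (extra provenance columns are carried through).
#' @param profile A [domain_profile()].
#' @param mode `"full"`, `"locations_only"` or `"no_filter"`.
#' @param country_names Optional character vector of gazetteer country
#'   names; when the profile sets `split_country_lists`, kept candidates
#'   that are comma-separated sequences of countries are split into one
#'   content location per country.
#' @return The input tibble with columns `location_string` (cleaned),
#'   `rejected` and `rejection_reason` added.
#' @export
filter_candidates <- function(candidates, profile,
                              mode = c("full", "locations_only", "no_filter"),
                              country_names = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "domain_profile"))
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) {
    return(mutate(candidates,
      location_string = character(), rejected = logical(),
      rejection_reason = character()
    ))
  }

  out <- candidates
  out$rejected <- FALSE
  out$rejection_reason <- NA_character_

  if (mode == "locations_only") {
    has_loc <- map_lgl(out$tags, ~ any(.x == "LOCATION"))
    out$rejected <- !has_loc
    out$rejection_reason[!has_loc] <- "no_location_tag"
    # truncate kept spans to their LOCATION-tagged core (plus interior
    # bridges between the first and last location token)
    for (i in which(has_loc)) {
      locs <- which(out$tags[[i]] == "LOCATION")
      keep <- locs[1]:locs[length(locs)]
      out$surfaces[[i]] <- out$surfaces[[i]][keep]
      out$tags[[i]] <- out$tags[[i]][keep]
      out$end[i] <- out$start[i] + keep[length(keep)] - 1L
      out$start[i] <- out$start[i] + keep[1] - 1L
      out$candidate_string[i] <- join_tokens(out$surfaces[[i]])
    }
  } else if (mode == "full") {
    keep_hit <- word_match(out$candidate_string, profile$keep_words,
                           ignore_case = TRUE)
    discard_hit <- word_match(out$candidate_string, profile$discard_words,
                              ignore_case = FALSE)
    no_loc <- !map_lgl(out$tags, ~ any(.x == "LOCATION"))
    rule_hit <- map_lgl(seq_len(nrow(out)), function(i) {
      cand <- list(
        tags = out$tags[[i]], surfaces = out$surfaces[[i]],
        prev_surface = out$prev_surface[i], next_surface = out$next_surface[i]
      )
      any(map_lgl(profile$tag_word_rules, ~ isTRUE(.x(cand))))
    })
    reason <- dplyr::case_when(
      keep_hit ~ NA_character_,
      discard_hit ~ "discard_word",
      no_loc ~ "no_location_tag",
      rule_hit ~ "tag_word_combination",
      TRUE ~ NA_character_
    )
    out$rejected <- !is.na(reason)
    out$rejection_reason <- reason
  }
  # mode == "no_filter": everything passes

  out$location_string <- clean_location_string(out$candidate_string)
  empty <- !out$rejected & !nzchar(out$location_string)
  out$rejected[empty] <- TRUE
  out$rejection_reason[empty] <- "empty_after_clean"

  if (profile$split_country_lists && !is.null(country_names)) {
    out <- split_country_list_candidates(out, country_names)
  }
  out
}

# Split kept candidates that are comma-separated sequences of country names
# ("France, Spain, Italy") into one row per country.
split_country_list_candidates <- function(out, country_names) {
  norm_countries <- str_to_lower(normalize_text(country_names))
  rows <- map(seq_len(nrow(out)), function(i) {
    row <- out[i, ]
    if (row$rejected) return(row)
    parts <- str_trim(str_split(row$location_string, ",")[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) >= 2 &&
        all(str_to_lower(normalize_text(parts)) %in% norm_countries)) {
      return(map(parts, function(p) mutate(row, location_string = p)) |>
               list_rbind())
    }
    row
  })
  list_rbind(rows)
}

#' Clean a location string
#'
#' Iteratively removes trailing connector words (prepositions/articles),
#' trailing commas, periods and semicolons, dangling opening parentheses at
#' the end, and dangling closing parentheses at the start, until a fixed
#' point is reached. Balanced parentheses are preserved, so
#' "Nancy (East of France)" is unchanged. Idempotent, and never lengthens a
#' string.
#'
#' @param s Character vector of candidate strings.
#' @param connector_words Trailing words to strip.
#' @return Character vector of cleaned strings (possibly empty).
#' @examples
#' clean_location_string("Florence, Italy,")  # "Florence, Italy"
#' clean_location_string("Bern in")           # "Bern"
#' @export
clean_location_string <- function(s, connector_words = c(
                                    "in", "upon", "of", "at", "near", "the",
                                    "and", "or", "from", "to"
                                  )) {
  conn_pat <- regex(
    paste0("\\s+(", paste(connector_words, collapse = "|"), ")$"),
    ignore_case = TRUE
  )
  vapply(s, function(x) {
    repeat {
      old <- x
      x <- str_trim(x)
      x <- str_replace_all(x, "[,.;:]+$", "")
      x <- str_replace_all(x, conn_pat, "")
      x <- str_replace_all(x, "\\($", "")       # dangling opener at end
      x <- str_replace_all(x, "^\\)", "")       # dangling closer at start
      if (sum(stringr::str_count(x, "\\)")) > stringr::str_count(x, "\\(")) {
        x <- str_replace_all(x, "\\)$", "")     # unbalanced closer at end
      }
      if (stringr::str_count(x, "\\(") > stringr::str_count(x, "\\)")) {
        x <- str_replace_all(x, "^\\(", "")     # unbalanced opener at start
      }
      if (identical(x, old)) break
    }
    x
  }, character(1), USE.NAMES = FALSE)
}

#' Deduplicate content locations within one article
#'
#' Repeated mentions of the same place are common and not equally
#' important; kept locations are deduplicated on their case-folded,
#' normalized string, retaining the first occurrence in document order and
#' recording how many duplicates were dropped.
#'
#' @param locations A content-location tibble (kept rows of
#'   [filter_candidates()], with `location_string`).
#' @return The deduplicated tibble with an `n_duplicates` column.
#' @export
deduplicate_locations <- function(locations) {
  locations <- as_tibble(locations)
  if (nrow(locations) == 0) {
    return(mutate(locations, n_duplicates = integer()))
  }
  key <- str_to_lower(normalize_text(locations$location_string))
  locations |>
    mutate(.dedup_key = key) |>
    group_by(.data$.dedup_key) |>
    mutate(n_duplicates = n() - 1L) |>
    slice(1) |>
    ungroup() |>
    arrange(dplyr::across(dplyr::any_of(c("para_idx", "sentence_idx", "start")))) |>
    select(-".dedup_key")
}
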